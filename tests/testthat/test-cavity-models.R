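# Cavity expansion models: parabolic profile, 2D Rayleigh oracle,
# viscous droplet cavity, train equivalence and superposition, and the
# cavity-velocity prediction.

test_that("cavity front grows linearly in time", {
  expect_equal(cavity_front_position(10, 0), 0)
  expect_equal(cavity_front_position(10, 1e-3), 1e-2)
  expect_equal(cavity_front_position(7, 2e-3), 2 * cavity_front_position(7, 1e-3))
  expect_error(cavity_front_position(10, -1), "non-negative")
})

test_that("inertial profile is parabolic, causal, and grows as sqrt(t)", {
  jet <- ref_jet(); U_c <- 10
  t <- 2e-4
  x <- seq(0, 3e-3, length.out = 200)
  R <- inertial_profile(x, t, jet, U_c)
  expect_true(all(R >= 0))
  # zero at and beyond the front
  Hc <- U_c * t
  expect_equal(inertial_profile(Hc, t, jet, U_c), 0)
  expect_true(all(R[x >= Hc] == 0))
  # R^2 affine in x behind the front (parabola)
  behind <- x < Hc
  fit <- lm(R[behind]^2 ~ x[behind])
  expect_equal(summary(fit)$r.squared, 1, tolerance = 1e-12)
  # t = 0 gives the undisturbed interface
  expect_true(all(inertial_profile(x, 0, jet, U_c) == 0))
  # sqrt growth at the impact point: R(0, 4t) = 2 R(0, t)
  expect_equal(inertial_profile(0, 4 * t, jet, U_c),
               2 * inertial_profile(0, t, jet, U_c))
})

test_that("2D Rayleigh integration holds equilibria and sqrt asymptotes", {
  # zero driving, from rest: constant radius
  tg <- seq(0, 1e-3, length.out = 50)
  sol0 <- rayleigh2d_integrate(function(t) 0, 1e-5, 0, tg)
  expect_equal(sol0$R, rep(1e-5, 50), tolerance = 1e-9)
  # impulsive driving: late-time log-log slope 0.50 +/- 0.02
  tg <- seq(0, 2e-3, length.out = 400)
  pulse <- function(t) if (t < 2e-5) 5e4 else 0
  sol <- rayleigh2d_integrate(pulse, 1e-6, 0, tg, R_inf = 0.1)
  late <- sol$t > 5e-4
  expo <- unname(coef(lm(log(sol$R[late]) ~ log(sol$t[late])))[2])
  expect_equal(expo, 0.50, tolerance = 0.02)
  # grid refinement: halving the step barely changes the solution
  tg2 <- seq(0, 2e-3, length.out = 799)
  sol2 <- rayleigh2d_integrate(pulse, 1e-6, 0, tg2, R_inf = 0.1)
  shared <- sol2$R[seq(1, 799, by = 2)]
  expect_lt(max(abs(sol$R - shared) / shared), 1e-6)
})

test_that("viscous drop cavity reduces to the inviscid limit and is
           monotone in viscosity", {
  jet <- ref_jet()
  train <- train_from_jet(jet, f = 0.5)
  tg <- seq(0, 3e-4, length.out = 150)
  nearly_inviscid <- material("eps", 998, 1e-7, 72.1e-3)
  sol_v <- viscous_drop_cavity(train, nearly_inviscid, tg)
  # inviscid oracle: same forcing through the bare 2D Rayleigh equation
  t_imp <- 2 * train$r_d / train$U_d
  p0 <- 1000 * train$U_d^2
  sol_i <- rayleigh2d_integrate(function(t) if (t < t_imp) p0 else 0,
                                1e-3 * train$r_d, 0, tg, rho = 998,
                                R_inf = 100 * train$r_d)
  expect_lt(max(abs(sol_v$R - sol_i$R) / pmax(sol_i$R, 1e-12)), 0.01)
  # maximum radius never increases with viscosity
  mus <- c(1e-3, 5e-3, 2e-2, 5e-2, 2e-1)
  rmax <- vapply(mus, function(mu) {
    m <- material("sweep", 998, mu, 72.1e-3)
    max(viscous_drop_cavity(train, m, tg)$R)
  }, numeric(1))
  expect_true(all(diff(rmax) <= 1e-12))
  # no impact, no growth
  still <- train; still$U_d <- 0
  expect_equal(viscous_drop_cavity(still, water_mat(), tg)$R,
               rep(1e-3 * train$r_d, length(tg)))
})

test_that("droplet train preserves the jet's volume flux and cavity speed", {
  jet <- ref_jet(U_0 = 20, D_0 = 100e-6)
  # printed worked example: r_cyl = 50 um, f = 1/2
  tr <- train_from_jet(jet, f = 0.5)
  expect_equal(tr$r_d, 86.6e-6, tolerance = 1e-3)
  expect_equal(tr$h_cyl, 346.4e-6, tolerance = 1e-3)
  for (f in c(0.1, 0.25, 0.5, 1, 2)) {
    tr <- train_from_jet(jet, f = f)
    # droplet volume equals the enclosing cylinder slice
    V_d <- (4 / 3) * pi * tr$r_d^3
    V_cyl <- pi * tr$r_cyl^2 * tr$h_cyl
    expect_lt(abs(V_d - V_cyl) / V_cyl, 1e-12)
    # volumetric flux of the train equals a cylinder advancing at U_d
    flux_train <- V_d * tr$U_d / tr$h_cyl
    flux_cyl <- pi * tr$r_cyl^2 * tr$U_d
    expect_lt(abs(flux_train - flux_cyl) / flux_cyl, 1e-9)
    # the train reproduces the jet's cavity speed by construction
    expect_equal(train_cavity_velocity(tr$U_d, f), jet$U_0 / 2,
                 tolerance = 1e-9)
  }
})

test_that("train cavity velocity is linear in U_d and vanishes at rest", {
  expect_equal(train_cavity_velocity(0, 0.5), 0)
  expect_equal(train_cavity_velocity(20, 0.5),
               2 * train_cavity_velocity(10, 0.5))
  # a continuous train (f = 1) halves the droplet speed
  expect_equal(train_cavity_velocity(10, 1), 5)
})

test_that("superposed train profile nests the single-drop solution and
           grows with drop count", {
  jet <- ref_jet(U_0 = 20, D_0 = 100e-6)
  train <- train_from_jet(jet, f = 0.5)
  gly <- glycerol_mat()
  t <- 2.5e-4
  # degenerate train = single drop
  p1 <- superposed_train_profile(train, gly, t, n_drops = 1)
  sol <- viscous_drop_cavity(train, gly, seq(0, t, length.out = 257))
  expect_equal(max(p1$R), sol$R[length(sol$R)], tolerance = 1e-6)
  # composite dominates every constituent and area grows with count
  pfull <- superposed_train_profile(train, gly, t)
  expect_true(all(pfull$R >= p1$R - 1e-15))
  dx <- diff(pfull$x[1:2])
  areas <- vapply(1:4, function(k)
    sum(superposed_train_profile(train, gly, t, n_drops = k)$R) * dx,
    numeric(1))
  expect_true(all(diff(areas) >= -1e-15))
  # water-like target: front agrees with the inertial model to 10%,
  # mouth radius to within a factor of two
  w <- water_mat()
  trw <- train_from_jet(jet, f = 0.5)
  pw <- superposed_train_profile(trw, w, t)
  front_inertial <- cavity_front_position(jet$U_0 / 2, t)
  expect_equal(attr(pw, "front"), front_inertial, tolerance = 0.1)
  mouth_inertial <- inertial_profile(0, t, jet, jet$U_0 / 2)
  ratio <- max(pw$R) / mouth_inertial
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
})

test_that("cavity velocity prediction respects its limits", {
  w <- water_mat()
  # dissipation-free density-matched limit: U_c -> U_0 / 2
  ideal <- material("ideal", 1000, 1e-9, 72.1e-3)
  jet <- ref_jet(U_0 = 20)
  expect_equal(cavity_velocity_model(jet, ideal,
                                     ratios = list(rho_r = 1, mu_r = 1)),
               10, tolerance = 1e-3)
  expect_equal(cavity_velocity_model(ref_jet(U_0 = 0), w), 0)
  # non-increasing in target viscosity
  mus <- c(1e-3, 1e-2, 5e-2, 0.25)
  ucs <- vapply(mus, function(mu)
    cavity_velocity_model(jet, material("sweep", 1000, mu, 72.1e-3)),
    numeric(1))
  expect_true(all(diff(ucs) < 0))
  # all bundled liquids and gels sit below the inviscid bound
  for (nm in material_table()$name) {
    u <- cavity_velocity_model(jet, as_material(nm))
    expect_gt(u, 0)
    expect_lt(u / jet$U_0, 0.5)
  }
})

test_that("cavity trajectories keep consistent bookkeeping", {
  jet <- ref_jet(); U_c <- 10
  times <- seq(1e-5, 3e-4, by = 1e-5)
  traj <- cavity_trajectory(jet, U_c, times)
  expect_true(all(traj$profiles >= 0))
  # causality: zero radius at and beyond the front
  for (i in c(1, 10, length(times))) {
    beyond <- traj$x >= traj$front[i]
    expect_true(all(traj$profiles[i, beyond] == 0))
  }
  expect_true(all(diff(traj$front) > 0))
  expect_equal(traj$L_max, max(traj$front))
  expect_equal(traj$A_max, max(traj$area))
  # CSV export round-trip
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  df <- read.csv(f)
  expect_identical(names(df), c("t_s", "x_m", "R_m"))
  expect_equal(nrow(df), length(times) * length(traj$x))
})
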
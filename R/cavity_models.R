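# Forward models of cavity expansion after jet impact: axial front motion,
# the inertial parabolic profile, the 2D Rayleigh radial equation, the
# viscous single-droplet cavity, droplet-train equivalence/superposition,
# and the dissipative cavity-velocity prediction.

#' Cavity front position under constant front speed
#'
#' During the early, inertia-dominated phase the cavity tip advances
#' linearly: `H_c(t) = U_c * t` with `U_c ~ U_0/2`.
#'
#' @param U_c cavity front speed (m s^-1).
#' @param t time(s) since impact (s), non-negative.
#' @return front position(s) (m).
#' @export
cavity_front_position <- function(U_c, t) {
  if (any(t < 0)) stop("t must be non-negative")
  U_c * t
}

#' Inertial parabolic cavity profile
#'
#' Momentum deposited by the passing jet front leaves each axial station
#' expanding radially such that `R^2` grows linearly in the time since the
#' front passed: `R(x,t)^2 = C_R * D_0 * (U_c*t - x)` for `x <= H_c(t)`,
#' zero beyond the front. The local opening time is `t0(x) = x / U_c`;
#' under linear front growth the alternative normalisation `t0 = (x/H_c)*t`
#' coincides with it exactly, so only one form is needed.
#'
#' @param x axial positions from the impact point (m), non-negative.
#' @param t time since impact (s), non-negative scalar.
#' @param jet a [jet_spec()] (supplies `D_0`).
#' @param U_c cavity front speed (m s^-1).
#' @param C_R dimensionless prefactor of the momentum-deposition law
#'   (default 1).
#' @return radii `R(x, t)` (m), zero at and beyond the front.
#' @export
inertial_profile <- function(x, t, jet, U_c, C_R = 1) {
  stopifnot(inherits(jet, "jet_spec"))
  if (any(x < 0)) stop("x must be non-negative")
  if (t < 0) stop("t must be non-negative")
  sqrt(pmax(0, C_R * jet$D_0 * (U_c * t - x)))
}

#' Integrate the two-dimensional Rayleigh equation
#'
#' Radial dynamics of a long cavity in cylindrical coordinates with a
#' logarithmically cut-off inertia (the 2D analogue of the Rayleigh
#' equation):
#' \deqn{\rho \ln(R_\infty/R)\,(R\ddot R + \dot R^2) =
#'   p(t) - \gamma/R - 4\mu\dot R/R}
#' where `p(t)` is the driving pressure and `R_inf` the outer cutoff of the
#' radial flow (physically the confinement scale). With zero driving,
#' surface tension and viscosity, any initial state with `Rdot = 0` is an
#' equilibrium; after an impulsive driving, the coasting solution conserves
#' `R*Rdot`, i.e. `R` grows as `(t - t0)^(1/2)` — the asymptote behind the
#' parabolic profile of [inertial_profile()].
#'
#' @param driving_pressure function of time returning the driving pressure
#'   (Pa).
#' @param R_init initial radius (m), positive.
#' @param Rdot_init initial radial speed (m s^-1).
#' @param t_grid output times (s), increasing, starting at the initial time.
#' @param rho liquid density (kg m^-3).
#' @param gamma surface tension (N m^-1); 0 disables the capillary term.
#' @param mu shear viscosity (Pa s); 0 disables the viscous term.
#' @param R_inf outer cutoff radius (m), must exceed any reached radius.
#' @param rtol,atol solver tolerances (lsoda).
#' @return data.frame with columns `t`, `R`, `Rdot`.
#' @export
rayleigh2d_integrate <- function(driving_pressure, R_init, Rdot_init, t_grid,
                                 rho = 1000, gamma = 0, mu = 0,
                                 R_inf = 1e3 * R_init,
                                 rtol = 1e-8, atol = 1e-12) {
  if (R_init <= 0) stop("R_init must be positive")
  if (R_inf <= R_init) stop("R_inf must exceed R_init")
  deriv <- function(t, y, parms) {
    R <- max(y[1], 1e-300); Rdot <- y[2]
    lg <- max(log(R_inf / R), 1e-6)  # clamped on trial steps; checked below
    p <- driving_pressure(t) - if (gamma > 0) gamma / R else 0
    p <- p - if (mu > 0) 4 * mu * Rdot / R else 0
    list(c(Rdot, (p / (rho * lg) - Rdot^2) / R))
  }
  out <- try(deSolve::ode(c(R = R_init, Rdot = Rdot_init), t_grid, deriv,
                          parms = NULL, rtol = rtol, atol = atol),
             silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(t_grid))
    stop("integration failed: ", if (inherits(out, "try-error"))
      attr(out, "condition")$message else "solver stopped early")
  if (any(!is.finite(out[, "R"])) || any(out[, "R"] <= 0))
    stop("integration failed: non-finite or non-positive radius")
  if (max(out[, "R"]) >= R_inf)
    stop(sprintf(
      "integration failed: radius reached the outer cutoff R_inf = %g m (max R = %g m); enlarge R_inf",
      R_inf, max(out[, "R"])))
  data.frame(t = out[, "time"], R = out[, "R"], Rdot = out[, "Rdot"])
}

#' Droplet-train equivalent of a jet
#'
#' A continuous jet of radius `r_cyl = D_0/2` is replaced by a train of
#' droplets with the same volumetric flux. Equating the droplet volume
#' `(4/3) pi r_d^3` to the enclosing cylinder slice `pi r_cyl^2 h_cyl`
#' with centre-to-centre distance `h_cyl = 2 r_d / f` gives
#' `r_d = r_cyl * sqrt(3/(2 f))`. The droplet speed `U_d` is chosen so the
#' train's cavity velocity ([train_cavity_velocity()]) equals the jet's
#' target cavity speed `U_c` (default `U_0/2`).
#'
#' @param jet a [jet_spec()].
#' @param f train frequency parameter (dimensionless duty factor),
#'   default 1/2 as used for the viscous-profile comparison.
#' @param U_c_target cavity speed the train must reproduce (m s^-1),
#'   default `U_0/2`.
#' @return An object of class `"droplet_train"` with fields `r_d`, `U_d`,
#'   `f`, `h_cyl`, `r_cyl`.
#' @export
train_from_jet <- function(jet, f = 0.5, U_c_target = jet$U_0 / 2) {
  stopifnot(inherits(jet, "jet_spec"))
  if (f <= 0) stop("f must be positive")
  r_cyl <- jet$D_0 / 2
  r_d <- r_cyl * sqrt(3 / (2 * f))
  h_cyl <- 2 * r_d / f
  # invert train_cavity_velocity: U_c = U_d * sqrt(f) / (1 + sqrt(f))
  U_d <- U_c_target * (1 + sqrt(f)) / sqrt(f)
  structure(list(r_d = r_d, U_d = U_d, f = f, h_cyl = h_cyl, r_cyl = r_cyl),
            class = "droplet_train")
}

#' @export
print.droplet_train <- function(x, ...) {
  cat(sprintf(
    "<droplet_train> r_d = %.3g um, U_d = %.3g m/s, f = %g, h_cyl = %.3g um\n",
    1e6 * x$r_d, x$U_d, x$f, 1e6 * x$h_cyl))
  invisible(x)
}

#' Cavity velocity of a droplet train
#'
#' Momentum balance at the advancing cavity front: droplets strike over
#' their own cross-section for a duty fraction `f` of each period, so the
#' time-averaged stagnation balance reads
#' `f * rho * (U_d - U_c)^2 = rho * U_c^2`, giving
#' `U_c = U_d * sqrt(f) / (1 + sqrt(f))`. A continuous jet (`f = 1`)
#' recovers `U_c = U_d / 2`.
#'
#' @param U_d droplet speed (m s^-1).
#' @param f train frequency parameter, positive.
#' @return cavity front speed (m s^-1), linear in `U_d`.
#' @export
train_cavity_velocity <- function(U_d, f) {
  if (f <= 0) stop("f must be positive")
  if (any(U_d < 0)) stop("U_d must be non-negative")
  U_d * sqrt(f) / (1 + sqrt(f))
}

#' Viscous single-droplet cavity expansion
#'
#' Radial cavity growth at the impact site of one droplet, from the 2D
#' Rayleigh equation with boundary-layer shear dissipation at the cavity
#' interface ([rayleigh2d_integrate()] with `mu = mu_cb`). The droplet
#' drives the cavity with its stagnation-scale pressure `rho_jet * U_d^2`
#' for the crossing time `2 r_d / U_d`, after which the cavity coasts.
#' Surface tension is neglected during the forced expansion by default
#' (the impacts of interest have `We >> 1`); set
#' `include_surface_tension = TRUE` to retain it.
#'
#' @param drop a [train_from_jet()] droplet-train object (a single drop of
#'   it is simulated).
#' @param target a [material()]; supplies `rho_cb`, `mu_cb` (and
#'   `gamma_cb` when surface tension is enabled).
#' @param t_grid output times (s) from contact.
#' @param rho_jet density of the droplet liquid (kg m^-3).
#' @param eps initial radius as a fraction of `r_d` (default 1e-3).
#' @param include_surface_tension logical, default `FALSE`.
#' @param R_inf outer cutoff radius (m), default `100 * r_d`.
#' @return data.frame with columns `t`, `R`, `Rdot` and attribute `t_imp`
#'   (the forcing duration).
#' @export
viscous_drop_cavity <- function(drop, target, t_grid, rho_jet = 1000,
                                eps = 1e-3, include_surface_tension = FALSE,
                                R_inf = 100 * drop$r_d) {
  stopifnot(inherits(drop, "droplet_train"), inherits(target, "material"))
  if (drop$r_d <= 0) stop("drop radius must be positive")
  if (drop$U_d < 0) stop("drop speed must be non-negative")
  R0 <- eps * drop$r_d
  if (drop$U_d == 0) {
    out <- data.frame(t = t_grid, R = R0, Rdot = 0)
    attr(out, "t_imp") <- Inf
    return(out)
  }
  t_imp <- 2 * drop$r_d / drop$U_d
  p0 <- rho_jet * drop$U_d^2
  drive <- function(t) if (t < t_imp) p0 else 0
  out <- rayleigh2d_integrate(
    drive, R_init = R0, Rdot_init = 0, t_grid = t_grid,
    rho = target$rho_cb,
    gamma = if (include_surface_tension) target$gamma_cb else 0,
    mu = target$mu_cb, R_inf = R_inf)
  attr(out, "t_imp") <- t_imp
  out
}

#' Composite cavity profile of a droplet train
#'
#' Successive droplets impact at the instantaneous cavity front, each
#' opening its own radial cavity per [viscous_drop_cavity()]. Drop `k`
#' impacts at `t_k = k * h_cyl / U_d` at axial position
#' `x_k = U_c_train * t_k`, and contributes its radius `R_k(t - t_k)` over
#' its axial slice; the composite profile is the pointwise maximum of the
#' contributions (preserving non-negativity and monotone growth).
#'
#' @param train a [train_from_jet()] object.
#' @param target a [material()].
#' @param t evaluation time (s), non-negative scalar.
#' @param n_drops optional cap on the number of drops included (e.g. 1
#'   degenerates to the single-drop solution).
#' @param n_axial number of axial samples (default 512).
#' @param ... passed to [viscous_drop_cavity()].
#' @return data.frame with columns `x`, `R` (m) on `[0, front]`, with
#'   attribute `front` (m).
#' @export
superposed_train_profile <- function(train, target, t, n_drops = NULL,
                                     n_axial = 512, ...) {
  stopifnot(inherits(train, "droplet_train"), t >= 0)
  U_ct <- train_cavity_velocity(train$U_d, train$f)
  dt_k <- train$h_cyl / train$U_d
  K <- max(1L, min(floor(t / dt_k) + 1L,
                   if (is.null(n_drops)) Inf else n_drops))
  front <- U_ct * t
  x <- seq(0, max(front, train$h_cyl), length.out = n_axial)
  R <- numeric(n_axial)
  if (t > 0) {
    # all drops are identical: one ODE solve, evaluated at shifted ages
    tg <- seq(0, t, length.out = 257L)
    sol <- viscous_drop_cavity(train, target, tg, ...)
    R_of <- function(age) approx(sol$t, sol$R, xout = age, rule = 2)$y
    for (k in seq_len(K) - 1L) {
      age <- t - k * dt_k
      if (age <= 0) next
      x_k <- U_ct * k * dt_k
      hi <- min(x_k + train$h_cyl, max(front, train$h_cyl))
      sel <- x >= x_k & x <= hi
      R[sel] <- pmax(R[sel], R_of(age))
    }
  }
  out <- data.frame(x = x, R = R)
  attr(out, "front") <- front
  out
}

#' Dissipative cavity-velocity prediction
#'
#' Stagnation-pressure balance at the cavity front with viscous normal
#' stresses on both the jet and the target side:
#' \deqn{\rho_0 (U_0-U_c)^2 - C\mu_0 (U_0-U_c)/D_0 =
#'   \rho_{cb} U_c^2 + C\mu_{cb} U_c/D_0.}
#' In the dissipation-free, density-matched limit this reduces to
#' `U_c = U_0/2`; target viscosity always lowers `U_c`. The density and
#' viscosity ratios are jet/target: `rho_r = rho_0/rho_cb`,
#' `mu_r = mu_0/mu_cb`.
#'
#' @param jet a [jet_spec()].
#' @param target a [material()].
#' @param ratios optional list with `rho_r` and `mu_r`; by default
#'   `rho_r = rho_0/rho_cb` and `mu_r` assumes a water-like jet viscosity
#'   of 1 mPa s.
#' @param C_visc dimensionless viscous-stress coefficient (default 4).
#' @return predicted cavity front speed `U_c` (m s^-1).
#' @export
cavity_velocity_model <- function(jet, target, ratios = NULL, C_visc = 4) {
  stopifnot(inherits(jet, "jet_spec"), inherits(target, "material"))
  if (jet$U_0 == 0) return(0)
  rho_r <- if (!is.null(ratios$rho_r)) ratios$rho_r
           else jet$rho_0 / target$rho_cb
  mu_r <- if (!is.null(ratios$mu_r)) ratios$mu_r
          else 1e-3 / target$mu_cb
  if (rho_r <= 0 || mu_r <= 0) stop("ratios must be positive")
  Re <- target$rho_cb * jet$U_0 * jet$D_0 / target$mu_cb
  bal <- function(u) {
    rho_r * (1 - u)^2 - (C_visc * mu_r / Re) * (1 - u) -
      u^2 - (C_visc / Re) * u
  }
  if (bal(0) <= 0) return(0)  # jet-side dissipation swallows the impact
  u <- uniroot(bal, c(0, 1), tol = 1e-12)$root
  u * jet$U_0
}

#' Kinematic cavity trajectory from the inertial model
#'
#' Builds the full time-resolved trajectory (profiles, front, projected
#' area) from the parabolic profile at a fitted or prescribed cavity speed.
#' The projected area is the trapezoid-integrated `2 R(x, t)` over the
#' axial grid.
#'
#' @param jet a [jet_spec()].
#' @param U_c cavity front speed (m s^-1).
#' @param times sample times (s), increasing.
#' @param x_max axial extent of the grid (m); defaults to the front
#'   position at the last time.
#' @param n_axial axial samples (default 512).
#' @param C_R prefactor passed to [inertial_profile()].
#' @return An object of class `"cavity_trajectory"`: list with `times`,
#'   `x`, `profiles` (time x axial matrix), `front`, `area`, `U_c`,
#'   `L_max`, `A_max`, `H_max`.
#' @export
cavity_trajectory <- function(jet, U_c, times, x_max = NULL,
                              n_axial = 512, C_R = 1) {
  stopifnot(inherits(jet, "jet_spec"), all(diff(times) > 0), all(times >= 0))
  if (is.null(x_max)) x_max <- max(U_c * max(times), jet$D_0)
  x <- seq(0, x_max, length.out = n_axial)
  profiles <- t(vapply(times, function(t)
    inertial_profile(x, t, jet, U_c, C_R = C_R), numeric(n_axial)))
  front <- cavity_front_position(U_c, times)
  dx <- x[2] - x[1]
  area <- apply(profiles, 1L, function(R)
    sum((R[-1] + R[-length(R)]) * dx))  # trapezoid of 2*R
  structure(list(times = times, x = x, profiles = profiles, front = front,
                 area = area, U_c = U_c, L_max = max(front),
                 A_max = max(area), H_max = max(front)),
            class = "cavity_trajectory")
}

#' @export
print.cavity_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cavity_trajectory> %d frames, U_c = %.3g m/s, L_max = %.3g mm, A_max = %.3g mm^2\n",
    length(x$times), x$U_c, 1e3 * x$L_max, 1e6 * x$A_max))
  invisible(x)
}

#' @export
plot.cavity_trajectory <- function(x, which = NULL, ...) {
  idx <- if (is.null(which)) unique(round(seq(1, length(x$times),
                                              length.out = 5))) else which
  matplot(1e3 * x$x, 1e3 * t(x$profiles[idx, , drop = FALSE]), type = "l",
          xlab = "x (mm)", ylab = "R (mm)", ...)
  invisible(x)
}

#' Export a trajectory as a tidy CSV table
#'
#' @param traj a [cavity_trajectory()].
#' @param path output CSV path; columns `t_s`, `x_m`, `R_m`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "cavity_trajectory"))
  df <- data.frame(
    t_s = rep(traj$times, each = length(traj$x)),
    x_m = rep(traj$x, times = length(traj$times)),
    R_m = as.vector(t(traj$profiles)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
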
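# Dimensionless groups, material records, and the agarose property
# relations.

test_that("Weber number follows its definition and scaling laws", {
  w <- water_mat()
  expect_equal(weber(ref_jet(U_0 = 0), w), 0)
  # hand arithmetic: 1000 * 1e-4 * 100 / 0.072
  m <- material("ref", 1000, 1e-3, 0.072)
  expect_equal(weber(jet_spec(10, 1e-4), m), 138.888, tolerance = 1e-4)
  # round trip through the published operating point: We = 495 at
  # D_0 = 93 um on water needs U_0 ~ 19.6 m/s
  U <- sqrt(495 * w$gamma_cb / (1000 * 93e-6))
  expect_equal(U, 19.6, tolerance = 0.01)
  expect_equal(weber(ref_jet(U_0 = U, D_0 = 93e-6), w), 495, tolerance = 1e-6)
  # strictly increasing in U_0
  We <- vapply(c(5, 10, 20, 40), function(u) weber(ref_jet(U_0 = u), w),
               numeric(1))
  expect_true(all(diff(We) > 0))
})

test_that("Froude number scales as U_0^2 and vanishes at rest", {
  expect_equal(froude(ref_jet(U_0 = 0)), 0)
  expect_equal(froude(jet_spec(10, 1e-4)), 100 / (9.81 * 1e-4),
               tolerance = 1e-12)
  expect_equal(froude(ref_jet(U_0 = 40)), 4 * froude(ref_jet(U_0 = 20)))
})

test_that("Ohnesorge number is linear in viscosity and matches water", {
  w <- water_mat()
  expect_equal(ohnesorge(w, 1e-4), 0.0118, tolerance = 0.01)
  m1 <- material("m1", 1000, 1e-3, 0.072)
  m4 <- material("m4", 1000, 4e-3, 0.072)
  expect_equal(ohnesorge(m4, 1e-4), 4 * ohnesorge(m1, 1e-4))
  # at the bridge scale water drops below the surface-seal bound
  expect_lt(ohnesorge(w, 6e-3), 0.004)
})

test_that("agarose property relations are affine with the stated slopes", {
  # published table rows
  expect_equal(1e3 * agarose_properties(3961)$gamma_cb, 4120.4,
               tolerance = 1e-4)
  expect_equal(1e3 * agarose_properties(536)$mu_cb, 40.53, tolerance = 1e-3)
  # intercepts at G = 0
  p0 <- agarose_properties(0)
  expect_equal(p0$gamma_cb, 0.072292)
  expect_equal(p0$mu_cb, 0.00834)
  # finite-difference slopes equal the stated coefficients
  dG <- 100
  p1 <- agarose_properties(500); p2 <- agarose_properties(500 + dG)
  expect_equal((p2$gamma_cb - p1$gamma_cb) / dG, 0.001022)
  expect_equal((p2$mu_cb - p1$mu_cb) / dG, 6.005e-5)
  expect_error(agarose_properties(-1), "non-negative")
})

test_that("Deborah and elastic Froude numbers behave definitionally", {
  geom <- bridge_geometry()
  peo <- as_material("peo_600k_10")
  tau <- capillary_time(peo, geom)
  expect_equal(deborah(peo, geom), peo$lambda_relax / tau)
  peo2 <- material("peo2", peo$rho_cb, peo$mu_cb, peo$gamma_cb,
                   lambda_relax = 2 * peo$lambda_relax)
  expect_equal(deborah(peo2, geom), 2 * deborah(peo, geom))
  expect_error(deborah(water_mat(), geom), "viscoelastic")
  # elastic Froude: rho U^2 / G
  gel <- material("gel", 1000, 0.019, 0.25, G_storage = 176)
  expect_equal(elastic_froude(gel, 40), 1000 * 1600 / 176)
  expect_equal(elastic_froude(gel, 0), 0)
  gel2 <- material("gel2", 1000, 0.019, 0.25, G_storage = 352)
  expect_equal(elastic_froude(gel2, 40), elastic_froude(gel, 40) / 2)
  expect_error(elastic_froude(water_mat(), 40), "gel")
})

test_that("impact shear rate is U_0 / D_0", {
  expect_equal(impact_shear_rate(jet_spec(10, 1e-4)), 1e5)
  expect_equal(impact_shear_rate(ref_jet(U_0 = 0)), 0)
  expect_equal(impact_shear_rate(ref_jet(U_0 = 40)),
               2 * impact_shear_rate(ref_jet(U_0 = 20)))
})

test_that("dimensionless numbers are invariant under a change of units", {
  # rescale length by L, time by T, mass by M and rebuild all inputs
  L <- 1000; T <- 1000; M <- 1e6  # m -> mm, s -> ms, kg -> g, say
  w <- water_mat()
  jet <- ref_jet(U_0 = 20, D_0 = 1e-4)
  w2 <- material("scaled", w$rho_cb * M / L^3, w$mu_cb * M / (L * T),
                 w$gamma_cb * M / T^2)
  jet2 <- suppressWarnings(jet_spec(U_0 = 20 * L / T, D_0 = 1e-4 * L,
                                    rho_0 = 1000 * M / L^3))
  expect_equal(weber(jet2, w2), weber(jet, w))
  expect_equal(ohnesorge(w2, 1e-4 * L), ohnesorge(w, 1e-4))
})

test_that("material records validate their invariants", {
  expect_error(material("bad", -1, 1e-3, 0.07), "rho")
  expect_error(material("bad", 1000, 1e-3, -0.07), "gamma")
  expect_error(material("bad", 1000, 1e-3, 0.07, lambda_relax = 1e-3,
                        G_storage = 100), "not both")
  expect_identical(material("w", 998, 1e-3, 0.072)$material_class,
                   "newtonian")
  expect_identical(
    material("p", 998, 1e-3, 0.072, lambda_relax = 1e-3)$material_class,
    "viscoelastic")
  expect_identical(
    material("g", 998, 1e-3, 0.072, G_storage = 176)$material_class, "gel")
  expect_warning(jet_spec(U_0 = 100, D_0 = 1e-4), "validity window")
  expect_warning(jet_spec(U_0 = 20, D_0 = 10e-6), "validity window")
})

test_that("the bundled material table round-trips into material objects", {
  tab <- material_table()
  expect_equal(nrow(tab), 9L)
  w <- as_material("water", tab)
  expect_equal(w$rho_cb, 998)
  expect_equal(w$gamma_cb, 72.1e-3)
  a <- as_material("agarose_050", tab)
  expect_identical(a$material_class, "gel")
  expect_equal(a$G_storage, 3961)
  # stored values are the measured ones, not the linear-relation values
  expect_equal(a$mu_cb, 256.34e-3)
  expect_error(as_material("kryptonite", tab), "unknown material")
})

test_that("capillary time defaults to the dimensionally consistent form", {
  w <- water_mat(); geom <- bridge_geometry()
  expect_equal(capillary_time(w, geom),
               sqrt(998 * 6e-3^3 / 72.1e-3))
  expect_equal(capillary_time(w, geom, form = "literal"),
               998 * 6e-3 / 72.1e-3)
})
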
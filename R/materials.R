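#' @importFrom stats lm coef uniroot rnorm runif sd approx setNames complete.cases
#' @importFrom utils read.csv write.csv modifyList
NULL

# gravitational acceleration (m s^-2)
.g <- 9.81

#' Material record for a capillary-bridge substance
#'
#' Bundles the bulk properties that enter the impact models: density, shear
#' viscosity, surface tension, and (where applicable) the viscoelastic
#' relaxation time or the gel storage modulus. The material class is derived
#' from which optional properties are present: a storage modulus makes a
#' `"gel"`, a relaxation time makes a `"viscoelastic"` liquid, otherwise the
#' material is `"newtonian"`.
#'
#' @param name label for the material.
#' @param rho_cb density (kg m^-3), positive.
#' @param mu_cb shear viscosity (Pa s), positive.
#' @param gamma_cb surface tension (N m^-1), positive.
#' @param lambda_relax viscoelastic relaxation time (s), optional,
#'   non-negative.
#' @param G_storage storage modulus (Pa), optional, non-negative.
#' @return An object of class `"material"`.
#' @examples
#' water <- material("water", 998, 1.0e-3, 72.1e-3)
#' gel   <- material("agarose", 1000, 18.96e-3, 252.9e-3, G_storage = 176)
#' @export
material <- function(name, rho_cb, mu_cb, gamma_cb,
                     lambda_relax = NULL, G_storage = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(rho_cb) || rho_cb <= 0) stop("rho_cb must be positive")
  if (!is.numeric(mu_cb) || mu_cb <= 0) stop("mu_cb must be positive")
  if (!is.numeric(gamma_cb) || gamma_cb <= 0)
    stop("invalid material: gamma_cb must be positive")
  if (!is.null(lambda_relax) && (!is.numeric(lambda_relax) || lambda_relax < 0))
    stop("lambda_relax must be non-negative")
  if (!is.null(G_storage) && (!is.numeric(G_storage) || G_storage < 0))
    stop("G_storage must be non-negative")
  if (!is.null(lambda_relax) && !is.null(G_storage))
    stop("a material is either viscoelastic (lambda) or a gel (G), not both")
  cls <- if (!is.null(G_storage)) "gel"
         else if (!is.null(lambda_relax)) "viscoelastic"
         else "newtonian"
  structure(
    list(name = name, rho_cb = rho_cb, mu_cb = mu_cb, gamma_cb = gamma_cb,
         lambda_relax = lambda_relax, G_storage = G_storage,
         material_class = cls),
    class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s [%s]\n", x$name, x$material_class))
  cat(sprintf("  rho = %g kg/m^3, mu = %g mPa s, gamma = %g mN/m\n",
              x$rho_cb, 1e3 * x$mu_cb, 1e3 * x$gamma_cb))
  if (!is.null(x$lambda_relax))
    cat(sprintf("  relaxation time lambda = %g ms\n", 1e3 * x$lambda_relax))
  if (!is.null(x$G_storage))
    cat(sprintf("  storage modulus G = %g Pa\n", x$G_storage))
  invisible(x)
}

#' Impacting microfluidic jet specification
#'
#' @param U_0 impact speed (m s^-1), positive. Values outside the study's
#'   validity window (default 8-69.5 m s^-1) trigger a warning, not an error.
#' @param D_0 jet diameter (m), positive; warning window 50-120 um.
#' @param rho_0 jet liquid density (kg m^-3).
#' @param L_0 jet length (m), optional (needed for kinetic energy).
#' @param gamma_0 jet liquid surface tension (N m^-1), optional; carried for
#'   reference but the impact Weber number uses the target's surface tension.
#' @param U_window,D_window validity windows used for the warnings.
#' @return An object of class `"jet_spec"`.
#' @examples
#' jet_spec(U_0 = 20, D_0 = 93e-6)
#' @export
jet_spec <- function(U_0, D_0, rho_0 = 1000, L_0 = NULL, gamma_0 = NULL,
                     U_window = c(8, 69.5), D_window = c(50e-6, 120e-6)) {
  for (v in c(U_0 = U_0, D_0 = D_0, rho_0 = rho_0)) {
    if (!is.numeric(v) || v < 0) stop("jet parameters must be non-negative")
  }
  if (D_0 <= 0 || rho_0 <= 0) stop("D_0 and rho_0 must be positive")
  if (!is.null(L_0) && L_0 <= 0) stop("L_0 must be positive")
  if (!is.null(gamma_0) && gamma_0 <= 0) stop("gamma_0 must be positive")
  if (U_0 > 0 && (U_0 < U_window[1] || U_0 > U_window[2]))
    warning(sprintf("U_0 = %g m/s outside the validity window [%g, %g] m/s",
                    U_0, U_window[1], U_window[2]))
  if (D_0 < D_window[1] || D_0 > D_window[2])
    warning(sprintf("D_0 = %g um outside the validity window [%g, %g] um",
                    1e6 * D_0, 1e6 * D_window[1], 1e6 * D_window[2]))
  structure(list(rho_0 = rho_0, D_0 = D_0, U_0 = U_0, L_0 = L_0,
                 gamma_0 = gamma_0),
            class = "jet_spec")
}

#' @export
print.jet_spec <- function(x, ...) {
  cat(sprintf("<jet_spec> U_0 = %g m/s, D_0 = %g um, rho_0 = %g kg/m^3\n",
              x$U_0, 1e6 * x$D_0, x$rho_0))
  if (!is.null(x$L_0)) cat(sprintf("  L_0 = %g mm\n", 1e3 * x$L_0))
  invisible(x)
}

#' Confinement geometry of the capillary bridge
#'
#' @param D_cb bridge diameter in the impact plane (m).
#' @param H_wall wall separation (m).
#' @param R_c contact radius on the walls (m).
#' @param theta_E_top,theta_E_bottom equilibrium contact angles (rad).
#' @param theta_a,theta_r advancing / receding contact angles (rad),
#'   `theta_a >= theta_r`.
#' @return An object of class `"bridge_geometry"`.
#' @export
bridge_geometry <- function(D_cb = 6e-3, H_wall = 1e-3, R_c = 2.5e-3,
                            theta_E_top = 23 * pi / 180,
                            theta_E_bottom = theta_E_top,
                            theta_a = theta_E_top + 9 * pi / 180,
                            theta_r = theta_E_top - 9 * pi / 180) {
  if (D_cb <= 0 || H_wall <= 0 || R_c <= 0)
    stop("D_cb, H_wall and R_c must be positive")
  for (th in c(theta_E_top, theta_E_bottom, theta_a, theta_r))
    if (th <= 0 || th >= pi) stop("contact angles must lie in (0, pi)")
  if (theta_a < theta_r) stop("theta_a must be >= theta_r")
  structure(list(D_cb = D_cb, H_wall = H_wall, R_c = R_c,
                 theta_E_top = theta_E_top, theta_E_bottom = theta_E_bottom,
                 theta_a = theta_a, theta_r = theta_r),
            class = "bridge_geometry")
}

#' Bundled material property table
#'
#' Loads the packaged table of the study materials (two Newtonian liquids,
#' the dyed jet liquid, three polyethylene-oxide solutions, three agarose
#' gels) with density, viscosity, surface tension, relaxation time and
#' storage modulus. Values are stored as measured/printed; the agarose
#' property relations are available separately via [agarose_properties()]
#' and are never used to overwrite the stored values.
#'
#' @param path optional path to an alternative CSV with the same columns
#'   (`name, rho_kg_m3, mu_mPa_s, gamma_mN_m, lambda_ms, G_Pa, class`).
#' @return A data.frame, one row per material.
#' @export
material_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "materials.csv", package = "jetcavity")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "rho_kg_m3", "mu_mPa_s", "gamma_mN_m",
            "lambda_ms", "G_Pa", "class")
  if (!all(need %in% names(df))) stop("materials table missing columns")
  if (nrow(df) == 0L) stop("empty materials table")
  df
}

#' Look up a material from the bundled table
#'
#' @param name material name as used in the bundled table
#'   (e.g. `"water"`, `"glycerol_78"`, `"agarose_015"`).
#' @param table a table from [material_table()].
#' @return A [material()] object in SI units.
#' @export
as_material <- function(name, table = material_table()) {
  i <- match(name, table$name)
  if (is.na(i)) stop("unknown material: ", name)
  row <- table[i, ]
  material(
    name = row$name,
    rho_cb = row$rho_kg_m3,
    mu_cb = row$mu_mPa_s * 1e-3,
    gamma_cb = row$gamma_mN_m * 1e-3,
    lambda_relax = if (!is.na(row$lambda_ms)) row$lambda_ms * 1e-3,
    G_storage = if (!is.na(row$G_Pa)) row$G_Pa)
}

#' Impact Weber number
#'
#' `We = rho_0 * D_0 * U_0^2 / gamma_cb`: jet inertia (jet density and
#' diameter) against the surface tension of the impacted bridge.
#'
#' @param jet a [jet_spec()].
#' @param target a [material()] (supplies `gamma_cb`).
#' @return Dimensionless Weber number (0 iff `U_0 = 0`).
#' @export
weber <- function(jet, target) {
  stopifnot(inherits(jet, "jet_spec"), inherits(target, "material"))
  jet$rho_0 * jet$D_0 * jet$U_0^2 / target$gamma_cb
}

#' Impact Froude number
#'
#' `Fr = U_0^2 / (g D_0)` with `g = 9.81` m s^-2.
#' @inheritParams weber
#' @export
froude <- function(jet) {
  stopifnot(inherits(jet, "jet_spec"))
  jet$U_0^2 / (.g * jet$D_0)
}

#' Ohnesorge number of the target at the jet scale
#'
#' `Oh = mu_cb / sqrt(rho_cb * gamma_cb * D_0)`: viscous forces of the
#' bridge material relative to its inertial-capillary scale at the jet
#' diameter.
#'
#' @param target a [material()].
#' @param D_0 reference length (m), normally the jet diameter.
#' @export
ohnesorge <- function(target, D_0) {
  stopifnot(inherits(target, "material"), D_0 > 0)
  target$mu_cb / sqrt(target$rho_cb * target$gamma_cb * D_0)
}

#' Agarose property relations
#'
#' Linear relations mapping the storage modulus of an agarose gel to an
#' effective surface tension and shear viscosity:
#' `gamma = 0.001022 * G + 0.072292` (N m^-1) and
#' `mu = 6.005e-5 * G + 0.00834` (Pa s). Established for dilute gels
#' (G below roughly 200 Pa); extrapolation to stiffer gels is the main
#' suspected source of the traversal-threshold misfit there.
#'
#' @param G storage modulus (Pa), non-negative.
#' @return A list with `gamma_cb` (N m^-1) and `mu_cb` (Pa s).
#' @examples
#' agarose_properties(176)
#' @export
agarose_properties <- function(G) {
  if (!is.numeric(G) || any(G < 0)) stop("G must be non-negative")
  list(gamma_cb = 0.001022 * G + 0.072292,
       mu_cb = 6.005e-5 * G + 0.00834)
}

#' Capillary time of the bridge
#'
#' Default is the standard inertio-capillary time
#' `tau_c = sqrt(rho_cb * D_cb^3 / gamma_cb)`. The dimensionally
#' inconsistent literal combination `rho_cb * D_cb / gamma_cb` is exposed
#' behind `form = "literal"` for comparison only.
#'
#' @param target a [material()].
#' @param geom a [bridge_geometry()].
#' @param form `"standard"` (default) or `"literal"`.
#' @return time scale (s) for `"standard"`; the literal combination
#'   otherwise.
#' @export
capillary_time <- function(target, geom, form = c("standard", "literal")) {
  form <- match.arg(form)
  stopifnot(inherits(target, "material"), inherits(geom, "bridge_geometry"))
  if (form == "standard")
    sqrt(target$rho_cb * geom$D_cb^3 / target$gamma_cb)
  else
    target$rho_cb * geom$D_cb / target$gamma_cb
}

#' Deborah number
#'
#' `De = lambda / tau_c`: viscoelastic relaxation time of the bridge
#' relative to its capillary time (see [capillary_time()]).
#'
#' @inheritParams capillary_time
#' @param tau_form passed to [capillary_time()].
#' @export
deborah <- function(target, geom, tau_form = "standard") {
  stopifnot(inherits(target, "material"))
  if (is.null(target$lambda_relax))
    stop("not viscoelastic: material has no relaxation time")
  target$lambda_relax / capillary_time(target, geom, form = tau_form)
}

#' Elastic Froude number
#'
#' `Fr_e = rho_cb * U_0^2 / G`: jet inertia against the gel's elastic
#' modulus.
#'
#' @param target a gel [material()].
#' @param U_0 impact speed (m s^-1).
#' @export
elastic_froude <- function(target, U_0) {
  stopifnot(inherits(target, "material"))
  if (is.null(target$G_storage) || target$G_storage <= 0)
    stop("not a gel: material has no positive storage modulus")
  target$rho_cb * U_0^2 / target$G_storage
}

#' Characteristic shear rate during impact
#'
#' `U_0 / D_0`, of order 1e5 s^-1 for the study's jets; relevant for the
#' shear-thinning response of polymer solutions near the impact point.
#'
#' @param jet a [jet_spec()].
#' @return shear rate (s^-1).
#' @export
impact_shear_rate <- function(jet) {
  stopifnot(inherits(jet, "jet_spec"))
  jet$U_0 / jet$D_0
}

#' All dimensionless groups for one impact configuration
#'
#' @param jet a [jet_spec()].
#' @param target a [material()].
#' @param geom a [bridge_geometry()].
#' @return A list of class `"dimensionless_set"` with `We`, `Fr`, `Oh`
#'   (at the jet diameter), `Oh_cb` (at the bridge diameter, the scale on
#'   which the seal-regime rules are stated), `Re`, `De` (NA for
#'   inelastic targets), `Fr_e` (NA for liquids), `tau_c` (s) and `g`.
#' @export
dimensionless_set <- function(jet, target, geom = bridge_geometry()) {
  structure(list(
    We = weber(jet, target),
    Fr = froude(jet),
    Oh = ohnesorge(target, jet$D_0),
    Oh_cb = ohnesorge(target, geom$D_cb),
    Re = target$rho_cb * jet$U_0 * jet$D_0 / target$mu_cb,
    De = if (!is.null(target$lambda_relax)) deborah(target, geom) else NA_real_,
    Fr_e = if (!is.null(target$G_storage) && target$G_storage > 0)
      elastic_froude(target, jet$U_0) else NA_real_,
    tau_c = capillary_time(target, geom),
    g = .g), class = "dimensionless_set")
}

#' @export
print.dimensionless_set <- function(x, ...) {
  cat(sprintf("<dimensionless_set> We = %.3g, Fr = %.3g, Oh = %.3g, Re = %.3g\n",
              x$We, x$Fr, x$Oh, x$Re))
  cat(sprintf("  De = %.3g, Fr_e = %.3g, tau_c = %.3g s\n",
              x$De, x$Fr_e, x$tau_c))
  invisible(x)
}
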
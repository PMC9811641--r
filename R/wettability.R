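# Wettability energetics of the capillary bridge on its confining walls:
# Laplace pressure, vertical adhesive force, contact-line dissipation and
# the Worthington-jet favourability argument.

#' Laplace pressure of a confined capillary bridge
#'
#' Axial-curvature form `dP = -2 * gamma_cb * cos(theta_E) / H_wall`:
#' negative for a concave bridge (hydrophilic walls, `theta_E < pi/2`),
#' positive for a convex bridge (hydrophobic walls, `theta_E > pi/2`),
#' zero for a flat meniscus. The variant including the in-plane curvature
#' term `gamma_cb / R_c` is available behind `form = "full"`; the
#' axial-only default is the one that reproduces both measured adhesion
#' forces downstream.
#'
#' @param gamma_cb surface tension (N m^-1).
#' @param theta_E equilibrium contact angle (rad), in (0, pi).
#' @param H_wall wall separation (m), positive.
#' @param form `"axial"` (default) or `"full"`.
#' @param R_c contact radius (m), required for `form = "full"`.
#' @return Laplace pressure (Pa).
#' @examples
#' laplace_pressure(72.1e-3, 23 * pi / 180, 1e-3)   # concave, negative
#' laplace_pressure(72.1e-3, 160 * pi / 180, 1e-3)  # convex, positive
#' @export
laplace_pressure <- function(gamma_cb, theta_E, H_wall,
                             form = c("axial", "full"), R_c = NULL) {
  form <- match.arg(form)
  if (theta_E <= 0 || theta_E >= pi) stop("theta_E must lie in (0, pi)")
  if (H_wall <= 0 || gamma_cb <= 0) stop("gamma_cb and H_wall must be positive")
  dP <- -2 * gamma_cb * cos(theta_E) / H_wall
  if (form == "full") {
    if (is.null(R_c) || R_c <= 0) stop("form = 'full' needs a positive R_c")
    dP <- dP + gamma_cb / R_c
  }
  dP
}

#' Vertical adhesive force of the bridge on the walls
#'
#' `F_a = 2 * pi * gamma_cb * R_c * sin(theta_E) - pi * R_c^2 * dP`:
#' the axial component of surface tension along the contact line plus the
#' Laplace-pressure contribution over the contact area. Positive values
#' mean the liquid is attracted to the walls, negative values repulsion.
#'
#' @param gamma_cb surface tension (N m^-1).
#' @param R_c contact radius (m), positive.
#' @param theta_E equilibrium contact angle (rad).
#' @param delta_P Laplace pressure (Pa), see [laplace_pressure()].
#' @return force (N).
#' @examples
#' dP <- laplace_pressure(72.1e-3, 23 * pi / 180, 1e-3)
#' adhesion_force(72.1e-3, 2.5e-3, 23 * pi / 180, dP)  # ~ +3 mN
#' @export
adhesion_force <- function(gamma_cb, R_c, theta_E, delta_P) {
  if (R_c <= 0) stop("R_c must be positive")
  2 * pi * gamma_cb * R_c * sin(theta_E) - pi * R_c^2 * delta_P
}

#' Contact-line dissipation term
#'
#' Magnitude of `2 * pi * R_c * gamma_cb * (cos(theta_a) - cos(theta_r))`,
#' the contact-angle-hysteresis pinning force along the contact line
#' (units of force). It vanishes exactly at zero hysteresis and grows with
#' the hysteresis split. Conversion to an energy requires a contact-line
#' travel distance; see [dissipation_energy()].
#'
#' @param R_c contact radius (m).
#' @param gamma_cb surface tension (N m^-1).
#' @param theta_a advancing contact angle (rad).
#' @param theta_r receding contact angle (rad), `theta_r <= theta_a`.
#' @return dissipation term magnitude (N).
#' @export
contact_line_dissipation <- function(R_c, gamma_cb, theta_a, theta_r) {
  if (theta_a < theta_r) stop("ordering error: theta_a must be >= theta_r")
  abs(2 * pi * R_c * gamma_cb * (cos(theta_a) - cos(theta_r)))
}

#' Contact-line dissipation energy over a travel distance
#'
#' Multiplies the pinning force of [contact_line_dissipation()] by an
#' explicit contact-line travel distance. The travel distance is a
#' property of the individual collapse event (how far the contact line is
#' dragged, possibly over repeated stick-slip cycles) and must be supplied
#' by the user.
#'
#' @param phi_cl dissipation term (N), see [contact_line_dissipation()].
#' @param travel contact-line travel distance (m), non-negative.
#' @return energy (J).
#' @export
dissipation_energy <- function(phi_cl, travel) {
  if (travel < 0) stop("travel must be non-negative")
  phi_cl * travel
}

#' Kinetic energy of the jet
#'
#' `E_kjet = (pi/8) * rho_0 * U_0^2 * D_0^2 * L_0` — the kinetic energy of
#' a liquid cylinder of diameter `D_0` and length `L_0` at speed `U_0`.
#'
#' @param jet a [jet_spec()] with `L_0` present.
#' @return energy (J).
#' @export
jet_kinetic_energy <- function(jet) {
  stopifnot(inherits(jet, "jet_spec"))
  if (is.null(jet$L_0)) stop("jet length L_0 is required")
  (pi / 8) * jet$rho_0 * jet$U_0^2 * jet$D_0^2 * jet$L_0
}

#' Is a Worthington jet energetically favourable?
#'
#' After cavity collapse a Worthington jet can only form if the contact
#' line is free to move: the contact-line dissipation energy must be small
#' against the jet kinetic energy (below `fraction` of it, default 0.5)
#' and the walls must not attract the liquid (`F_a <= 0`). Hydrophobic
#' walls (negligible hysteresis, repulsive adhesion) satisfy both;
#' hydrophilic walls fail both and suppress the jet.
#'
#' @param E_kjet jet kinetic energy (J), non-negative.
#' @param dissipation_energy contact-line dissipation energy (J),
#'   non-negative.
#' @param F_a vertical adhesive force (N).
#' @param fraction dissipation budget as a fraction of `E_kjet`
#'   (default 0.5).
#' @return logical.
#' @export
worthington_favourable <- function(E_kjet, dissipation_energy, F_a,
                                   fraction = 0.5) {
  if (E_kjet < 0 || dissipation_energy < 0)
    stop("energies must be non-negative")
  E_kjet > 0 && dissipation_energy < fraction * E_kjet && F_a <= 0
}

#' Wettability report for a wall scenario
#'
#' Evaluates the Laplace pressure, adhesion force, contact-line
#' dissipation and Worthington-jet favourability for a wall configuration.
#' A scenario is a named list (or a YAML file holding one) with fields
#' `walls` (`"hydrophilic"`, `"hydrophobic"` or `"mixed"`), `gamma_cb`,
#' `H_wall`, `R_c`, `theta_E` (deg), `hysteresis` (deg, split
#' symmetrically about `theta_E` unless `theta_a`/`theta_r` given),
#' `travel` (m) and the jet fields `U_0`, `D_0`, `L_0`. The mixed
#' hydrophilic-hydrophobic configuration is always unfavourable (the
#' cavity collapses asymmetrically between such walls), encoded as a rule.
#'
#' @param scenario named list or path to a YAML file.
#' @return list of class `"wettability_result"` with `delta_P`, `F_a`,
#'   `phi_cl`, `E_diss`, `E_kjet`, `worthington_favourable` and `rule`.
#' @export
wettability_report <- function(scenario) {
  if (is.character(scenario)) scenario <- yaml::read_yaml(scenario)
  s <- modifyList(list(
    walls = "hydrophilic", gamma_cb = 72.1e-3, H_wall = 1e-3,
    R_c = 2.5e-3, theta_E = 23, hysteresis = 18, theta_a = NULL,
    theta_r = NULL, travel = 5e-3, U_0 = 40, D_0 = 100e-6, L_0 = 19e-3),
    scenario[!vapply(scenario, is.null, logical(1))])
  if (s$walls == "mixed") {
    return(structure(list(
      delta_P = NA_real_, F_a = NA_real_, phi_cl = NA_real_,
      E_diss = NA_real_,
      E_kjet = jet_kinetic_energy(
        suppressWarnings(jet_spec(s$U_0, s$D_0, L_0 = s$L_0))),
      worthington_favourable = FALSE,
      rule = "mixed walls: asymmetric collapse, never favourable"),
      class = "wettability_result"))
  }
  thE <- s$theta_E * pi / 180
  tha <- if (!is.null(s$theta_a)) s$theta_a * pi / 180
         else thE + s$hysteresis / 2 * pi / 180
  thr <- if (!is.null(s$theta_r)) s$theta_r * pi / 180
         else thE - s$hysteresis / 2 * pi / 180
  dP <- laplace_pressure(s$gamma_cb, thE, s$H_wall)
  Fa <- adhesion_force(s$gamma_cb, s$R_c, thE, dP)
  phi <- contact_line_dissipation(s$R_c, s$gamma_cb, tha, thr)
  Ed <- dissipation_energy(phi, s$travel)
  Ek <- jet_kinetic_energy(
    suppressWarnings(jet_spec(s$U_0, s$D_0, L_0 = s$L_0)))
  structure(list(delta_P = dP, F_a = Fa, phi_cl = phi, E_diss = Ed,
                 E_kjet = Ek,
                 worthington_favourable =
                   worthington_favourable(Ek, Ed, Fa),
                 rule = sprintf("%s walls", s$walls)),
            class = "wettability_result")
}

#' @export
print.wettability_result <- function(x, ...) {
  cat("<wettability_result>", x$rule, "\n")
  if (!is.na(x$delta_P)) {
    cat(sprintf("  dP = %.4g Pa, F_a = %.4g mN, Phi_cl = %.4g mN\n",
                x$delta_P, 1e3 * x$F_a, 1e3 * x$phi_cl))
    cat(sprintf("  E_diss = %.4g mJ, E_kjet = %.4g mJ\n",
                1e3 * x$E_diss, 1e3 * x$E_kjet))
  }
  cat("  Worthington jet favourable:", x$worthington_favourable, "\n")
  invisible(x)
}
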
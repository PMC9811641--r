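# Four-way seal-regime logic: observational classification from cavity
# kinematics, predictive rules on (We, Oh, material class), the linear
# A_max-t_col law, and the qualitative bubble-outcome bands per regime.

.seal_regimes <- c("no_seal", "deep_seal", "shallow_seal", "surface_seal")

#' Seal outcome record
#'
#' @param regime one of `"no_seal"`, `"deep_seal"`, `"shallow_seal"`,
#'   `"surface_seal"`.
#' @param pinch_position deepest pinch position `x_p` (m) or `NA`.
#' @param pinch_count number of pinch events (>= 0).
#' @param dome_closed_during_expansion logical.
#' @param t_col collapse time from maximum area to closure (s) or `NA`.
#' @param rule optional character note naming the rule that produced the
#'   label.
#' @return An object of class `"seal_outcome"`.
#' @export
seal_outcome <- function(regime, pinch_position = NA_real_, pinch_count = 0L,
                         dome_closed_during_expansion = FALSE,
                         t_col = NA_real_, rule = NA_character_) {
  regime <- match.arg(regime, .seal_regimes)
  if (pinch_count < 0) stop("pinch_count must be >= 0")
  structure(list(regime = regime, pinch_position = pinch_position,
                 pinch_count = as.integer(pinch_count),
                 dome_closed_during_expansion = dome_closed_during_expansion,
                 t_col = t_col, rule = rule),
            class = "seal_outcome")
}

#' @export
print.seal_outcome <- function(x, ...) {
  cat(sprintf("<seal_outcome> %s (%d pinch event%s%s)\n", x$regime,
              x$pinch_count, if (x$pinch_count == 1) "" else "s",
              if (x$dome_closed_during_expansion) ", dome closed" else ""))
  if (!is.na(x$t_col)) cat(sprintf("  t_col = %.3g ms\n", 1e3 * x$t_col))
  if (!is.na(x$rule)) cat("  rule:", x$rule, "\n")
  invisible(x)
}

#' Observational seal classification from cavity kinematics
#'
#' Deterministic partition, applied in definitional order:
#' surface seal if an overarching dome closed on the entry side while the
#' cavity front was still advancing; else deep seal if any pinch occurred
#' deeper than `L_max / 3`; else shallow seal if any pinch occurred at all
#' (necessarily at `x_p <= L_max / 3`, the complement that makes the
#' partition exhaustive); else no seal.
#'
#' @param L_max maximum cavity depth reached (m); may come from a
#'   [cavity_trajectory()] (`$L_max`) or from image analysis.
#' @param pinch_positions numeric vector of pinch positions `x_p` (m),
#'   possibly empty.
#' @param dome_closed_during_expansion logical.
#' @param t_col collapse time to attach to the outcome (s), optional.
#' @return A [seal_outcome()].
#' @export
classify_seal_observed <- function(L_max, pinch_positions = numeric(0),
                                   dome_closed_during_expansion = FALSE,
                                   t_col = NA_real_) {
  if (inherits(L_max, "cavity_trajectory")) L_max <- L_max$L_max
  stopifnot(is.numeric(L_max), L_max >= 0)
  pinch_positions <- pinch_positions[!is.na(pinch_positions)]
  if (any(pinch_positions > L_max + 1e-12))
    stop("inconsistent events: pinch beyond L_max")
  n <- length(pinch_positions)
  if (dome_closed_during_expansion)
    return(seal_outcome("surface_seal", pinch_count = n,
                        pinch_position = if (n) max(pinch_positions) else NA_real_,
                        dome_closed_during_expansion = TRUE, t_col = t_col,
                        rule = "dome closed while cavity still expanding"))
  if (n && max(pinch_positions) > L_max / 3)
    return(seal_outcome("deep_seal", pinch_position = max(pinch_positions),
                        pinch_count = n, t_col = t_col,
                        rule = "pinch deeper than L_max/3"))
  if (n)
    return(seal_outcome("shallow_seal", pinch_position = max(pinch_positions),
                        pinch_count = n, t_col = t_col,
                        rule = "pinch at or above L_max/3 from the entry"))
  seal_outcome("no_seal", t_col = t_col,
               rule = "no pinch, no dome closure")
}

# deep-seal Weber windows per viscoelastic solution (closed intervals)
.deep_seal_windows <- list(
  peo_600k_01 = c(500, 600),
  peo_600k_10 = c(400, 700),
  peo_1m_10 = c(500, 900))

#' Predictive seal-regime rule
#'
#' Rule-based prediction from the Weber number, the Ohnesorge number and
#' the material class, with precedence: gels always shallow-seal;
#' viscoelastic solutions deep-seal inside their observed Weber windows
#' (closed intervals; the union 400-900 when the specific solution is not
#' named); Newtonian liquids with `Oh <= 0.004` and `We <= 700` are
#' surface-seal candidates; everything else no-seal.
#'
#' @param We Weber number.
#' @param Oh Ohnesorge number of the target.
#' @param material_class `"newtonian"`, `"viscoelastic"` or `"gel"`.
#' @param material_name optional bundled-table name selecting a specific
#'   deep-seal window (e.g. `"peo_600k_10"`).
#' @param oh_surface,we_surface Newtonian surface-seal bounds
#'   (defaults 0.004 and 700).
#' @return A [seal_outcome()] whose `rule` field names the source rule.
#' @export
predict_seal <- function(We, Oh, material_class,
                         material_name = NULL,
                         oh_surface = 0.004, we_surface = 700) {
  material_class <- match.arg(material_class,
                              c("newtonian", "viscoelastic", "gel"))
  if (We < 0 || Oh < 0) stop("We and Oh must be non-negative")
  if (material_class == "gel")
    return(seal_outcome("shallow_seal",
                        rule = "gel: shallow seal at all explored conditions"))
  if (material_class == "viscoelastic") {
    win <- if (!is.null(material_name) &&
               material_name %in% names(.deep_seal_windows))
      .deep_seal_windows[[material_name]] else c(400, 900)
    if (We >= win[1] && We <= win[2])
      return(seal_outcome("deep_seal",
                          rule = sprintf(
                            "viscoelastic: deep seal for We in [%g, %g]",
                            win[1], win[2])))
    return(seal_outcome("no_seal",
                        rule = "viscoelastic outside the deep-seal window"))
  }
  if (Oh <= oh_surface && We <= we_surface)
    return(seal_outcome("surface_seal",
                        rule = sprintf(
                          "newtonian, Oh <= %g and We <= %g", oh_surface,
                          we_surface)))
  seal_outcome("no_seal", rule = "newtonian outside the surface-seal bounds")
}

#' Linear law between maximum cavity area and collapse time
#'
#' Least-squares fit of `t_col ~ A_max`: in the no-seal regime the
#' retraction is capillary-driven and the collapse time grows linearly
#' with the maximum projected area.
#'
#' @param A_max maximum cavity areas (m^2), length >= 3, non-constant.
#' @param t_col collapse times (s), same length.
#' @return list of class `"collapse_scaling"`: `slope` (s m^-2),
#'   `intercept` (s), their standard errors, and `residual` (residual
#'   standard deviation; 0 for exactly collinear input).
#' @export
fit_collapse_scaling <- function(A_max, t_col) {
  if (is.list(A_max) && is.null(t_col)) {
    t_col <- vapply(A_max, `[[`, numeric(1), 2L)
    A_max <- vapply(A_max, `[[`, numeric(1), 1L)
  }
  if (length(A_max) < 3L || length(t_col) != length(A_max))
    stop("need at least 3 (A_max, t_col) pairs")
  if (sd(A_max) == 0) stop("rank error: A_max is constant")
  fit <- lm(t_col ~ A_max)
  s <- suppressWarnings(summary(fit))  # collinear input is legitimate
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = s$coefficients[2, 2],
                 intercept_se = s$coefficients[1, 2],
                 residual = s$sigma, n = length(A_max)),
            class = "collapse_scaling")
}

#' @export
print.collapse_scaling <- function(x, ...) {
  cat(sprintf(
    "<collapse_scaling> t_col = %.4g + %.4g * A_max (n = %d, resid sd %.3g)\n",
    x$intercept, x$slope, x$n, x$residual))
  invisible(x)
}

#' Expected bubble outcome for a seal regime
#'
#' Qualitative bands observed per regime: no seal traps no bubbles;
#' deep seal traps several pinch bubbles with an area ratio at most 0.6;
#' shallow seal traps several small bubbles with a ratio close to 0.5;
#' surface seal traps most of the cavity as one large bubble (ratio close
#' to 1).
#'
#' @param regime one of the four regime labels.
#' @return list with `ratio_range` (band for `A_bubbles/A_total`),
#'   `count_range` (integer band) and `description`.
#' @export
expected_bubble_outcome <- function(regime) {
  regime <- match.arg(regime, .seal_regimes)
  switch(regime,
    no_seal = list(ratio_range = c(0, 0), count_range = c(0L, 0L),
                   description = "no trapped bubbles"),
    deep_seal = list(ratio_range = c(0, 0.6), count_range = c(2L, 10L),
                     description = "several pinch bubbles, ratio at most 0.6"),
    shallow_seal = list(ratio_range = c(0.35, 0.65), count_range = c(4L, 10L),
                        description = "several small bubbles, ratio close to 0.5"),
    surface_seal = list(ratio_range = c(0.85, 1), count_range = c(1L, 2L),
                        description = "one large bubble, ratio close to 1"))
}
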
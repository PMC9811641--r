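# Orchestration: synthesize-or-load -> segment -> measure -> model ->
# classify -> report.

.default_run_config <- function() {
  list(mode = "synthetic",      # or "stacks"
       n_experiments = 20L,
       seed = 1L,
       materials = NULL,        # subset of bundled material names
       noise_sigma = 3,         # gray levels (0-255)
       threshold = 0.7,         # traverse/embed boundary on We/We*
       strategy = "otsu",       # segmentation strategy
       floor = 100e-6,          # bubble detection floor (m)
       f_train = 0.5,           # droplet-train frequency parameter
       stacks = NULL,           # directories for mode = "stacks"
       out_dir = NULL)
}

#' Read a pipeline configuration file
#'
#' Plain-text YAML with any subset of the run options (mode,
#' n_experiments, seed, materials, noise_sigma, threshold, strategy,
#' floor, stacks, out_dir); missing entries fall back to the defaults.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  modifyList(.default_run_config(), yaml::read_yaml(path))
}

# analyze one stack; every measured quantity or an explicit NA
.analyze_one <- function(stack, strategy, floor) {
  s <- .stack_series(stack, strategy)
  uc <- tryCatch(.front_fit_from_series(s),
                 error = function(e) NULL)
  areas <- .areas_from_series(s)
  seal <- .seal_from_series(s)
  last_mask <- stack$frames[[length(stack$frames)]] < s$threshold
  bub <- measure_bubbles(last_mask, pixel_size = stack$pixel_size,
                         floor = floor)
  list(U_c_fit = if (is.null(uc)) NA_real_ else uc$U_c,
       U_c_se = if (is.null(uc)) NA_real_ else uc$se,
       L_max = max(s$H[seq_len(s$i_end)]), A_max = areas$A_max,
       t_col = areas$t_col, open_ended = areas$open_ended,
       observed_regime = seal$regime,
       bubble_count = bub$count, bubble_ratio = bub$ratio,
       A_total = bub$A_total, A_bubbles = bub$A_bubbles)
}

#' Run the full pipeline
#'
#' Synthetic mode: draws `n_experiments` seeded experiments, renders and
#' noises their shadowgraph stacks, runs the full metrology, the
#' traversal model and both seal classifiers, and assembles one report
#' row per experiment. Stack mode: loads PNG stacks written by
#' [write_stack()] and runs the metrology columns only. Rows that fail
#' carry an explicit error note; the run continues. Reruns with the same
#' configuration and seed reproduce the report byte for byte.
#'
#' @param config a named list (see [read_run_config()]) or a YAML path.
#' @return An object of class `"run_report"`: list with `report`
#'   (data.frame) and `config`. When `out_dir` is set, `report.csv` and
#'   `run.log` are written there.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_run_config(config)
         else modifyList(.default_run_config(), config)
  rows <- list()
  log <- c(sprintf("mode=%s seed=%d threshold=%g floor=%g strategy=%s",
                   cfg$mode, cfg$seed, cfg$threshold, cfg$floor,
                   cfg$strategy))
  if (cfg$mode == "synthetic") {
    for (k in seq_len(cfg$n_experiments)) {
      sk <- cfg$seed + k
      row <- tryCatch({
        exp <- sample_experiment(sk, config = list(materials = cfg$materials))
        rend <- render_stack(exp)
        stack <- inject_noise(rend$stack, cfg$noise_sigma, seed = sk + 13L)
        meas <- .analyze_one(stack, cfg$strategy, cfg$floor)
        a <- suppressWarnings(assess_traversal(
          exp$jet, exp$material, exp$geometry, threshold = cfg$threshold))
        pred <- predict_seal(exp$dims$We, exp$dims$Oh_cb,
                             exp$material$material_class,
                             material_name = exp$material$name)
        data.frame(
          id = k, seed = sk, material = exp$material$name,
          U_0 = exp$jet$U_0, D_0 = exp$jet$D_0,
          We = exp$dims$We, Oh = exp$dims$Oh,
          We_star = a$We_star, ratio = a$ratio, decision = a$decision,
          predicted_regime = pred$regime,
          truth_regime = rend$truth$regime,
          observed_regime = meas$observed_regime,
          U_c_truth = rend$truth$U_c, U_c_fit = meas$U_c_fit,
          L_max = meas$L_max, A_max = meas$A_max, t_col = meas$t_col,
          bubble_count = meas$bubble_count,
          bubble_ratio = meas$bubble_ratio,
          caveat = a$caveat, error = NA_character_,
          stringsAsFactors = FALSE)
      }, error = function(e) data.frame(
        id = k, seed = sk, material = NA_character_, U_0 = NA_real_,
        D_0 = NA_real_, We = NA_real_, Oh = NA_real_, We_star = NA_real_,
        ratio = NA_real_, decision = NA_character_,
        predicted_regime = NA_character_, truth_regime = NA_character_,
        observed_regime = NA_character_, U_c_truth = NA_real_,
        U_c_fit = NA_real_, L_max = NA_real_, A_max = NA_real_,
        t_col = NA_real_, bubble_count = NA_integer_,
        bubble_ratio = NA_real_, caveat = NA_character_,
        error = conditionMessage(e), stringsAsFactors = FALSE))
      rows[[k]] <- row
      log <- c(log, sprintf("experiment %d (seed %d): %s", k, sk,
                            if (is.na(row$error)) "ok" else row$error))
    }
  } else if (cfg$mode == "stacks") {
    if (is.null(cfg$stacks)) stop("usage error: mode 'stacks' needs 'stacks'")
    for (k in seq_along(cfg$stacks)) {
      row <- tryCatch({
        stack <- read_stack(cfg$stacks[[k]])
        meas <- .analyze_one(stack, cfg$strategy, cfg$floor)
        data.frame(id = k, path = cfg$stacks[[k]],
                   U_c_fit = meas$U_c_fit, L_max = meas$L_max,
                   A_max = meas$A_max, t_col = meas$t_col,
                   observed_regime = meas$observed_regime,
                   bubble_count = meas$bubble_count,
                   bubble_ratio = meas$bubble_ratio,
                   error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) data.frame(
        id = k, path = cfg$stacks[[k]], U_c_fit = NA_real_,
        L_max = NA_real_, A_max = NA_real_, t_col = NA_real_,
        observed_regime = NA_character_, bubble_count = NA_integer_,
        bubble_ratio = NA_real_, error = conditionMessage(e),
        stringsAsFactors = FALSE))
      rows[[k]] <- row
      log <- c(log, sprintf("stack %d: %s", k,
                            if (is.na(row$error)) "ok" else row$error))
    }
  } else stop("usage error: unknown mode ", cfg$mode)
  report <- do.call(rbind, rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report, file.path(cfg$out_dir, "report.csv"),
              row.names = FALSE)
    writeLines(log, file.path(cfg$out_dir, "run.log"))
  }
  structure(list(report = report, config = cfg, log = log),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d row(s), mode = %s, seed = %d\n",
              nrow(x$report), x$config$mode, x$config$seed))
  if (nrow(x$report) && "observed_regime" %in% names(x$report))
    print(table(x$report$observed_regime, useNA = "ifany"))
  invisible(x)
}

#' Predicted seal-regime phase map
#'
#' Evaluates [predict_seal()] over a grid of Weber numbers, Ohnesorge
#' numbers and material classes, for replotting a regime phase diagram.
#' Every grid cell receives a label.
#'
#' @param We Weber numbers (default a log-spaced sweep 50-5000).
#' @param Oh Ohnesorge numbers (default a log-spaced sweep 0.001-1).
#' @param classes material classes to include.
#' @param out optional CSV path.
#' @return data.frame with columns `We`, `Oh`, `class`, `regime`.
#' @export
regime_map <- function(We = round(exp(seq(log(50), log(5000),
                                          length.out = 25))),
                       Oh = signif(exp(seq(log(0.001), log(1),
                                           length.out = 13)), 3),
                       classes = c("newtonian", "viscoelastic", "gel"),
                       out = NULL) {
  grid <- expand.grid(We = We, Oh = Oh, class = classes,
                      stringsAsFactors = FALSE)
  grid$regime <- vapply(seq_len(nrow(grid)), function(i)
    predict_seal(grid$We[i], grid$Oh[i], grid$class[i])$regime,
    character(1))
  if (!is.null(out)) write.csv(grid, out, row.names = FALSE)
  grid
}
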
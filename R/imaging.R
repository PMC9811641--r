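# Shadowgraph metrology: binarization, columnwise cavity-contour
# extraction, front tracking and velocity fitting, cavity-area series,
# pinch detection and entrained-bubble measurement.
#
# Image convention: frames are numeric matrices in [0, 1], rows = transverse
# (y) pixels, columns = axial (x) pixels; the jet travels along increasing
# column index on the axis row. Dark pixels are liquid/gel.

#' Shadowgraph frame stack
#'
#' @param frames list of numeric matrices in `[0, 1]`, all the same shape.
#' @param dt frame interval (s), default 1/50000 (50k frames per second).
#' @param pixel_size length per pixel (m), default 10 um.
#' @param origin impact-point pixel `c(row, col)`; the axial coordinate
#'   `x = 0` is this column, increasing along the jet axis.
#' @param axis unit vector of the jet axis in (col, row) image coordinates;
#'   only the axis-aligned `c(1, 0)` (left-to-right) is supported.
#' @return An object of class `"frame_stack"`.
#' @export
frame_stack <- function(frames, dt = 1 / 50000, pixel_size = 10e-6,
                        origin, axis = c(1, 0)) {
  stopifnot(is.list(frames), dt > 0, pixel_size > 0, length(origin) == 2)
  if (length(frames)) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
    if (!all(ok)) stop("all frames must have the same shape")
  }
  if (!identical(as.numeric(axis), c(1, 0)))
    stop("only the axis-aligned jet direction c(1, 0) is supported")
  structure(list(frames = frames, dt = dt, pixel_size = pixel_size,
                 origin = as.integer(origin), axis = axis),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0L, 0L)
  cat(sprintf(
    "<frame_stack> %d frames of %dx%d px, dt = %g us, pixel = %g um\n",
    length(x$frames), d[2], d[1], 1e6 * x$dt, 1e6 * x$pixel_size))
  invisible(x)
}

#' Binarize a shadowgraph frame
#'
#' Segments the dark (liquid/gel) region. `"otsu"` picks the threshold by
#' Otsu's method on the gray histogram; `"fixed"` uses the given
#' threshold. Deterministic for fixed inputs.
#'
#' @param frame numeric matrix in `[0, 1]`.
#' @param strategy `"otsu"` or `"fixed"`.
#' @param threshold gray threshold for `"fixed"` (default 0.5).
#' @param dark if `TRUE` (default) the mask marks pixels strictly below
#'   the threshold; if `FALSE`, strictly above.
#' @return logical matrix, `TRUE` on the segmented region.
#' @export
binarize <- function(frame, strategy = c("otsu", "fixed"), threshold = 0.5,
                     dark = TRUE) {
  strategy <- match.arg(strategy)
  if (is.null(frame) || length(frame) == 0L || !is.matrix(frame))
    stop("empty frame")
  thr <- if (strategy == "otsu") EBImage::otsu(EBImage::Image(frame))
         else threshold
  if (dark) frame < thr else frame > thr
}

# Columnwise cavity geometry at the axis row.
# For every column: is there a bright run at the axis row bounded by dark
# pixels above AND below (i.e. a cavity slice inside the bridge), and how
# wide is it? Returns per-column presence and bright-run width in pixels.
.cavity_columns <- function(mask, origin) {
  B <- !mask
  nr <- nrow(mask); nc <- ncol(mask)
  r0 <- origin[1]
  run_up <- numeric(nc); bounded_up <- rep(FALSE, nc)
  alive <- rep(TRUE, nc)
  if (r0 > 1) for (i in (r0 - 1):1) {
    isb <- B[i, ]
    bounded_up <- bounded_up | (alive & !isb)
    alive <- alive & isb
    run_up <- run_up + alive
  }
  run_dn <- numeric(nc); bounded_dn <- rep(FALSE, nc)
  alive <- rep(TRUE, nc)
  if (r0 < nr) for (i in (r0 + 1):nr) {
    isb <- B[i, ]
    bounded_dn <- bounded_dn | (alive & !isb)
    alive <- alive & isb
    run_dn <- run_dn + alive
  }
  present <- B[r0, ] & bounded_up & bounded_dn
  width <- ifelse(present, run_up + run_dn + 1, 0)
  list(present = present, width = width)
}

#' Extract the cavity profile from a binarized frame
#'
#' For each axial 1-pixel bin beyond the impact point, the cavity
#' half-width is half the bright run at the axis row, provided the run is
#' bounded by dark bridge material on both sides (averaging the two sides
#' of the cavity). The front is the furthest axial bin with cavity
#' present.
#'
#' @param mask logical matrix from [binarize()] (`TRUE` = dark).
#' @param origin impact-point pixel `c(row, col)`.
#' @param pixel_size length per pixel (m).
#' @param axis jet axis; only `c(1, 0)` supported.
#' @return data.frame with `x_m` (axial position) and `R_m` (half-width),
#'   ordered from the impact point to the front; zero rows when no cavity
#'   is present. Attributes: `front_m` (front position, 0 if empty) and
#'   `width_px` (raw per-column widths).
#' @export
extract_cavity_profile <- function(mask, origin, pixel_size = 10e-6,
                                   axis = c(1, 0)) {
  if (!identical(as.numeric(axis), c(1, 0)))
    stop("only the axis-aligned jet direction c(1, 0) is supported")
  cc <- .cavity_columns(mask, origin)
  c0 <- origin[2]
  sel <- seq(c0, ncol(mask))
  present <- cc$present[sel]
  if (!any(present)) {
    out <- data.frame(x_m = numeric(0), R_m = numeric(0))
    attr(out, "front_m") <- 0
    return(out)
  }
  j_front <- max(which(present))
  out <- data.frame(
    x_m = (seq_len(j_front) - 1L) * pixel_size,
    R_m = cc$width[sel][seq_len(j_front)] / 2 * pixel_size)
  attr(out, "front_m") <- j_front * pixel_size
  attr(out, "width_px") <- cc$width[sel][seq_len(j_front)]
  out
}

# Per-frame kinematics of a stack: front, area, mouth state.
# Threshold is established once (on the requested frame) and reused so the
# whole stack is segmented consistently.
.stack_series <- function(stack, strategy = "otsu", threshold = 0.5,
                          mouth_cols = 3L) {
  n <- length(stack$frames)
  thr <- if (strategy == "otsu")
    EBImage::otsu(EBImage::Image(stack$frames[[1]])) else threshold
  px <- stack$pixel_size
  c0 <- stack$origin[2]
  H <- numeric(n); A <- numeric(n); mouth_closed <- logical(n)
  gaps <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- stack$frames[[i]] < thr
    cc <- .cavity_columns(mask, stack$origin)
    sel <- seq(c0, ncol(mask))
    present <- cc$present[sel]
    if (any(present)) {
      j_front <- max(which(present))
      H[i] <- j_front * px
      A[i] <- sum(cc$width[sel]) * px^2
      mouth_closed[i] <- !any(present[seq_len(min(mouth_cols,
                                                  length(present)))])
      # interior gaps: absent runs strictly between present columns
      r <- rle(present[seq_len(j_front)])
      if (length(r$lengths) > 2) {
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        interior <- which(!r$values & seq_along(r$values) > 1L &
                            seq_along(r$values) < length(r$values))
        gp <- interior[r$lengths[interior] >= 2L]
        if (length(gp))
          gaps[[i]] <- ((starts[gp] + ends[gp]) / 2 - 1) * px
      }
    }
  }
  t <- (seq_len(n) - 1L) * stack$dt
  # the impact event ends at the first closed-cavity frame after opening;
  # later frames show the restored bridge and entrained bubbles and must
  # not feed the cavity kinematics
  i_pos <- which(A > 0)
  i_end <- if (length(i_pos)) {
    z <- which(A == 0 & seq_len(n) > i_pos[1])
    if (length(z)) min(z) else n
  } else n
  win <- seq_len(i_end)
  i_max <- win[which.max(A[win])]
  list(t = t, H = H, A = A, mouth_closed = mouth_closed, gaps = gaps,
       threshold = thr, i_end = i_end, i_max = i_max)
}

# metrics over a precomputed series (shared by the public wrappers and the
# one-pass pipeline analysis)
.areas_from_series <- function(s) {
  win <- seq_len(s$i_end)
  later <- which(s$A == 0 & seq_along(s$A) > s$i_max)
  open_ended <- length(later) == 0L || s$A[s$i_max] == 0
  structure(list(
    t = s$t, A = s$A, H_c = s$H, A_max = s$A[s$i_max],
    t_A_max = s$t[s$i_max],
    t_col = if (open_ended) NA_real_ else s$t[min(later)] - s$t[s$i_max],
    open_ended = open_ended, mouth_closed = s$mouth_closed),
    class = "cavity_area_series")
}

.front_fit_from_series <- function(s) {
  win <- seq_len(s$i_end)
  H <- s$H[win]
  # fit only expansion frames with a strictly advancing front below its
  # saturation value: once the front reaches its cap the plateau frames
  # would bias the slope low
  grow <- c(H[1] > 0, diff(H) > 0) & H > 0 & H < max(H) &
    win <= s$i_max
  use <- which(grow)
  if (length(use) < 3L) use <- which(H > 0)  # stationary / short plateau
  if (length(use) < 3L)
    stop("insufficient data: need >= 3 frames with a detected front")
  fit <- lm(s$H[use] ~ s$t[use])
  structure(list(U_c = unname(coef(fit)[2]),
                 se = suppressWarnings(summary(fit)$coefficients[2, 2]),
                 n = length(use)),
            class = "front_fit")
}

.pinch_from_series <- function(s, cluster_tol = 50e-6) {
  xs <- sort(unlist(s$gaps[seq_len(s$i_end)]))
  if (!length(xs)) return(data.frame(x_p = numeric(0)))
  grp <- cumsum(c(TRUE, diff(xs) > cluster_tol))
  data.frame(x_p = as.numeric(tapply(xs, grp, mean)))
}

.seal_from_series <- function(s, cluster_tol = 50e-6) {
  win <- seq_len(s$i_end)
  adv <- c(FALSE, diff(s$H[win]) > 0)
  dome <- any(s$mouth_closed[win] & adv & s$A[win] > 0)
  pp <- .pinch_from_series(s, cluster_tol)$x_p
  L_max <- max(s$H[win])
  pp <- pmin(pp, L_max)  # guard discretization at the front
  later <- which(s$A == 0 & seq_along(s$A) > s$i_max)
  t_col <- if (length(later)) s$t[min(later)] - s$t[s$i_max] else NA_real_
  classify_seal_observed(L_max, pp, dome, t_col = t_col)
}

#' Cavity area series, maximum area and collapse time
#'
#' Segments every frame, integrates the cavity cross-section area per
#' frame, and locates the maximum area and the collapse time `t_col`
#' (time from the maximum-area frame to the first later frame with a
#' closed cavity). When the cavity never closes within the stack the
#' result carries `open_ended = TRUE` and `t_col = NA`.
#'
#' @param stack a [frame_stack()].
#' @param strategy,threshold passed to the segmentation (threshold is
#'   established on the first frame and reused).
#' @return list of class `"cavity_area_series"`: `t`, `A` (m^2), `H_c`
#'   (m), `A_max`, `t_A_max`, `t_col`, `open_ended`, `mouth_closed`.
#' @export
cavity_area_series <- function(stack, strategy = "otsu", threshold = 0.5) {
  .areas_from_series(.stack_series(stack, strategy, threshold))
}

#' Fit the cavity front velocity
#'
#' Linear fit of the front position over the expansion phase (frames up
#' to the maximum cavity area with a detected front). Requires at least 3
#' usable frames.
#'
#' @param stack a [frame_stack()].
#' @param strategy,threshold segmentation options.
#' @return list of class `"front_fit"`: `U_c` (m s^-1), `se` (standard
#'   error), `n` (frames used).
#' @export
fit_front_velocity <- function(stack, strategy = "otsu", threshold = 0.5) {
  .front_fit_from_series(.stack_series(stack, strategy, threshold))
}

#' @export
print.front_fit <- function(x, ...) {
  cat(sprintf("<front_fit> U_c = %.4g m/s (se %.2g, n = %d)\n",
              x$U_c, x$se, x$n))
  invisible(x)
}

#' Detect pinch events across a stack
#'
#' A pinch is a frame where the cavity splits into two or more segments
#' along the axis: an interior run of closed columns (>= 2 px wide)
#' between open cavity columns. Gap centres across frames are clustered
#' (within half the detection floor) into distinct pinch positions.
#'
#' @param stack a [frame_stack()].
#' @param strategy,threshold segmentation options.
#' @param cluster_tol positions closer than this merge into one event (m),
#'   default 50 um.
#' @return data.frame with `x_p` (m), one row per distinct pinch position
#'   (possibly empty).
#' @export
detect_pinch_events <- function(stack, strategy = "otsu", threshold = 0.5,
                                cluster_tol = 50e-6) {
  .pinch_from_series(.stack_series(stack, strategy, threshold), cluster_tol)
}

#' Observational seal analysis of a stack
#'
#' Runs the area series, pinch detection and dome-closure detection, and
#' classifies the seal regime with [classify_seal_observed()]. Dome
#' closure is a frame where the cavity mouth is closed while the front is
#' still advancing and cavity area remains.
#'
#' @inheritParams cavity_area_series
#' @return A [seal_outcome()] with `t_col` attached.
#' @export
analyze_seal <- function(stack, strategy = "otsu", threshold = 0.5) {
  .seal_from_series(.stack_series(stack, strategy, threshold))
}

#' Measure entrained bubbles in a post-collapse frame
#'
#' Bubbles are bright connected components enclosed by the dark region.
#' Components closer than the optical detection floor are merged into one
#' bubble (morphological closing with a disk of radius half the floor)
#' whose area is the combined area of the cluster; a (possibly merged)
#' bubble is counted when its spatial extent or equivalent diameter
#' reaches the floor. `A_total` is the dark area including bubble
#' interiors.
#'
#' @param final_mask logical matrix (`TRUE` = dark), e.g. from
#'   [binarize()] on the last frame.
#' @param pixel_size length per pixel (m).
#' @param floor minimum detectable bubble diameter (m), default 100 um.
#' @return An object of class `"bubble_set"`: data.frame `bubbles`
#'   (`id, x_px, y_px, area_m2, d_eq_m`), `A_total`, `A_bubbles`, `count`,
#'   `ratio`.
#' @export
measure_bubbles <- function(final_mask, pixel_size = 10e-6, floor = 100e-6) {
  stopifnot(is.matrix(final_mask), is.logical(final_mask))
  px <- pixel_size
  img <- EBImage::Image(final_mask * 1)
  filled <- EBImage::fillHull(img) > 0.5
  A_total <- sum(filled) * px^2
  bubble_mask <- filled & !final_mask
  empty <- structure(list(
    bubbles = data.frame(id = integer(0), x_px = numeric(0),
                         y_px = numeric(0), area_m2 = numeric(0),
                         d_eq_m = numeric(0)),
    A_total = A_total, A_bubbles = 0, count = 0L, ratio = 0),
    class = "bubble_set")
  if (!any(bubble_mask)) return(empty)
  r <- max(1L, round(floor / (2 * px)))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(bubble_mask * 1), brush) > 0.5
  labels <- EBImage::bwlabel(EBImage::Image(closed * 1))
  lab <- as.integer(labels)
  dim(lab) <- dim(final_mask)
  rows <- list()
  for (k in seq_len(max(lab))) {
    sel <- lab == k & bubble_mask
    npx <- sum(sel)
    if (npx == 0L) next
    idx <- which(sel, arr.ind = TRUE)
    extent <- sqrt(diff(range(idx[, 1]))^2 + diff(range(idx[, 2]))^2) + 1
    d_eq <- 2 * sqrt(npx / pi) * px
    if (extent * px >= floor || d_eq >= floor)
      rows[[length(rows) + 1L]] <- data.frame(
        id = k, x_px = mean(idx[, 2]), y_px = mean(idx[, 1]),
        area_m2 = npx * px^2, d_eq_m = d_eq)
  }
  if (!length(rows)) return(empty)
  bubbles <- do.call(rbind, rows)
  bubbles$id <- seq_len(nrow(bubbles))
  A_bub <- sum(bubbles$area_m2)
  structure(list(bubbles = bubbles, A_total = A_total, A_bubbles = A_bub,
                 count = nrow(bubbles),
                 ratio = if (A_total > 0) A_bub / A_total else 0),
            class = "bubble_set")
}

#' @export
print.bubble_set <- function(x, ...) {
  cat(sprintf(
    "<bubble_set> %d bubble%s, A_bubbles/A_total = %.3g (A_total %.3g mm^2)\n",
    x$count, if (x$count == 1) "" else "s", x$ratio, 1e6 * x$A_total))
  invisible(x)
}

#' Export per-stack cavity kinematics as CSV
#'
#' @param series a [cavity_area_series()] result.
#' @param path output CSV path; columns `t_s`, `H_c_m`, `A_m2`.
#' @export
write_area_series_csv <- function(series, path) {
  stopifnot(inherits(series, "cavity_area_series"))
  write.csv(data.frame(t_s = series$t, H_c_m = series$H_c,
                       A_m2 = series$A),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a bubble report as CSV
#'
#' @param bubbles a [measure_bubbles()] result.
#' @param path output CSV path; columns `id`, `x_px`, `y_px`, `area_m2`,
#'   `d_eq_m`.
#' @export
write_bubble_csv <- function(bubbles, path) {
  stopifnot(inherits(bubbles, "bubble_set"))
  write.csv(bubbles$bubbles, path, row.names = FALSE)
  invisible(path)
}

#' Write a frame stack as a PNG sequence with a metadata sidecar
#'
#' @param stack a [frame_stack()].
#' @param dir output directory (created if missing); frames are written
#'   as `frame_0001.png, ...` plus a `sidecar.yaml` holding `dt`,
#'   `pixel_size`, `origin` and `axis`.
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames))
    png::writePNG(pmin(pmax(stack$frames[[i]], 0), 1),
                  file.path(dir, sprintf("frame_%04d.png", i)))
  yaml::write_yaml(list(dt = stack$dt, pixel_size = stack$pixel_size,
                        origin = as.integer(stack$origin),
                        axis = as.numeric(stack$axis),
                        n_frames = length(stack$frames)),
                   file.path(dir, "sidecar.yaml"))
  invisible(dir)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param dir directory holding `frame_*.png` and `sidecar.yaml`.
#' @return A [frame_stack()].
#' @export
read_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "sidecar.yaml"))
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  frames <- lapply(files, function(f) {
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  frame_stack(frames, dt = meta$dt, pixel_size = meta$pixel_size,
              origin = meta$origin, axis = meta$axis)
}
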
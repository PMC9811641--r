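# Seeded generator of ground-truthed synthetic experiments and rendered
# shadowgraph stacks. The renderer draws a bright background, a dark
# capillary-bridge disk (vertically cropped by the sensor, as in the real
# field of view), a parabolic cavity opening from the impact point, an
# incoming jet column, seal events (pinch gaps, an overarching dome) and
# post-collapse entrained bubbles, and returns the as-rendered truth next
# to the frames.

# evaluate expr under a fixed RNG seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.default_sim_config <- function() {
  list(
    materials = NULL,          # NULL = all bundled materials
    U_range = c(8, 69.5),      # m/s, the study's jet-speed window
    D_range = c(50e-6, 120e-6),# m, the study's jet-diameter window
    D_cb = 6e-3, H_wall = 1e-3,
    width = 768L, height = 328L,
    pixel_size = 10e-6, dt = 1 / 50000,
    bg = 0.88, fg = 0.12,      # background / liquid gray levels
    n_pre = 2L, n_post = 5L, max_frames = 250L,
    L_min = 3e-4,              # smallest rendered cavity depth (m)
    n_expand_min = 8L,         # frames the expansion must span
    t_col_min = 1.6e-4,        # shortest rendered collapse (s)
    L_frac_max = 0.75,         # cap on L_max as a fraction of D_cb
    s_col = 600,               # collapse-time slope vs A_max (s m^-2)
    floor = 100e-6)            # optical detection floor (m)
}

#' Sample a seeded synthetic impact experiment
#'
#' Draws a material from the bundled table, a jet with
#' `U_0 ~ U[8, 69.5]` m/s and `D_0 ~ U[50, 120]` um, and the default
#' confinement (6 mm bridge, 1 mm wall separation), then derives the
#' ground truth: the seal regime from [predict_seal()], the cavity speed
#' from [cavity_velocity_model()], the cavity depth from the traversal
#' model (clipped to the renderable range), and the regime's planned
#' pinch positions and bubble content.
#'
#' @param seed integer seed; identical seeds give identical experiments.
#' @param config named list overriding entries of the default generator
#'   configuration (see the package vignette).
#' @return An object of class `"synthetic_experiment"`.
#' @export
sample_experiment <- function(seed, config = list()) {
  cfg <- modifyList(.default_sim_config(), config)
  tab <- material_table()
  if (!is.null(cfg$materials)) {
    tab <- tab[tab$name %in% cfg$materials, , drop = FALSE]
    if (nrow(tab) == 0L) stop("config error: no materials to draw from")
  }
  .with_seed(seed, {
    nm <- tab$name[sample.int(nrow(tab), 1L)]
    target <- as_material(nm)
    jet <- suppressWarnings(jet_spec(
      U_0 = runif(1, cfg$U_range[1], cfg$U_range[2]),
      D_0 = runif(1, cfg$D_range[1], cfg$D_range[2])))
    geom <- bridge_geometry(D_cb = cfg$D_cb, H_wall = cfg$H_wall)
    dims <- dimensionless_set(jet, target, geom)
    assess <- suppressWarnings(assess_traversal(jet, target, geom))
    U_c <- cavity_velocity_model(jet, target)
    # rendered depth: model prediction, floored so the expansion spans
    # enough frames for front-velocity metrology, capped by the bridge
    L_max <- min(max(assess$H_max, cfg$L_min,
                     cfg$n_expand_min * U_c * cfg$dt),
                 cfg$L_frac_max * cfg$D_cb)
    regime <- predict_seal(dims$We, dims$Oh_cb, target$material_class,
                           material_name = target$name)$regime
    t_e <- L_max / U_c
    A_plan <- (4 / 3) * sqrt(jet$D_0) * L_max^1.5
    t_col <- max(cfg$s_col * A_plan, cfg$t_col_min)
    # keep the event inside the frame budget
    t_budget <- (cfg$max_frames - cfg$n_pre - cfg$n_post - 7L) * cfg$dt
    if (t_e + t_col > t_budget) t_col <- max(t_budget - t_e, 10 * cfg$dt)
    x_p <- switch(regime,
      deep_seal = runif(1, 0.45, 0.75) * L_max,
      shallow_seal = runif(1, 0.12, 0.28) * L_max,
      numeric(0))
    n_b <- switch(regime,
      deep_seal = sample(2:6, 1L),
      shallow_seal = sample(4:8, 1L),
      surface_seal = 1L,
      0L)
    ratio_plan <- switch(regime,
      deep_seal = runif(1, 0.25, 0.55),
      shallow_seal = runif(1, 0.40, 0.60),
      0)
    structure(list(
      seed = seed, material = target, jet = jet, geometry = geom,
      dims = dims, config = cfg,
      truth = list(regime = regime, U_c = U_c, L_max = L_max, t_e = t_e,
                   t_col = t_col, x_p = x_p, n_bubbles = n_b,
                   ratio_plan = ratio_plan, decision = assess$decision)),
      class = "synthetic_experiment")
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("<synthetic_experiment> seed %d: %s, U_0 = %.3g m/s, D_0 = %.3g um\n",
              x$seed, x$material$name, x$jet$U_0, 1e6 * x$jet$D_0))
  cat(sprintf("  truth: %s, U_c = %.3g m/s, L_max = %.3g mm, %d bubble(s)\n",
              x$truth$regime, x$truth$U_c, 1e3 * x$truth$L_max,
              x$truth$n_bubbles))
  invisible(x)
}

# place n non-overlapping bubbles (row, col, r_px) inside the visible disk;
# shrinks radii when random packing fails, so the achieved area can fall
# short of the requested one (the rendered truth records what was drawn)
.place_bubbles <- function(n, area_target_px, nr, nc, r0, cc, rad_px,
                           min_r = 8, max_r = 70, gap = 14) {
  if (n == 0L) return(data.frame(row = numeric(0), col = numeric(0),
                                 r = numeric(0)))
  w <- runif(n, 0.6, 1.4)
  r <- sqrt((area_target_px * w / sum(w)) / pi)
  r <- pmin(pmax(r, min_r), max_r)
  for (round in 1:9) {
    pos <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (a in 1:300) {
        rr <- runif(1, r[i] + 3, nr - r[i] - 2)
        jj <- runif(1, cc - rad_px + r[i] + 12, cc + rad_px - r[i] - 12)
        if (sqrt((rr - r0)^2 + (jj - cc)^2) > rad_px - r[i] - 12) next
        if (i > 1) {
          d <- sqrt((pos[1:(i - 1), 1] - rr)^2 + (pos[1:(i - 1), 2] - jj)^2)
          if (any(d < r[1:(i - 1)] + r[i] + gap)) next
        }
        pos[i, ] <- c(rr, jj); placed <- TRUE; break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(data.frame(row = pos[, 1], col = pos[, 2], r = r))
    r <- pmax(r * 0.85, min_r)
  }
  stop("could not place bubbles; requested area too large for the bridge")
}

#' Render a synthetic experiment as a shadowgraph stack
#'
#' Draws the frame sequence for the experiment's truth kinematics at the
#' default 50k frames per second and 10 um per pixel: linear front growth
#' at the truth `U_c`, parabolic profile clipped one pixel inside the
#' local bridge chord, self-similar retraction over the planned collapse
#' time, the regime's seal event (interior pinch gap; or an overarching
#' dome closing the mouth during expansion for surface seal), and final
#' post-collapse frames with the entrained bubbles. The returned truth is
#' *as rendered* (pixel-exact areas, counts and times).
#'
#' @param exp a [sample_experiment()] object.
#' @param config named list overriding the experiment's render settings
#'   (`n_frames` forces the stack length; 0 gives an empty stack).
#' @return list of class `"rendered_experiment"` with `stack` (a
#'   [frame_stack()]) and `truth` (regime, `U_c`, `L_max`, `A_max`,
#'   `t_col`, `A_total`, `A_bubbles`, `ratio`, `count`, `bubbles`,
#'   `A_series`).
#' @export
render_stack <- function(exp, config = list()) {
  stopifnot(inherits(exp, "synthetic_experiment"))
  cfg <- modifyList(exp$config, config)
  tr <- exp$truth
  if (tr$L_max > exp$geometry$D_cb && tr$decision != "traverse")
    stop("rendering error: cavity exceeds the bridge for an embedding impact")
  nr <- cfg$height; nc <- cfg$width
  px <- cfg$pixel_size; dt <- cfg$dt
  r0 <- as.integer(round(nr / 2)); cc <- as.integer(round(nc / 2))
  rad_px <- (exp$geometry$D_cb / 2) / px
  c0 <- as.integer(round(cc - rad_px))
  cols <- seq_len(nc); rows <- seq_len(nr)
  in_disk_col <- abs(cols - cc) <= rad_px
  chord <- ifelse(in_disk_col, sqrt(pmax(rad_px^2 - (cols - cc)^2, 0)), 0)
  base0 <- matrix(cfg$bg, nr, nc)
  for (j in which(in_disk_col)) {
    h <- chord[j]
    if (h >= 0.5) base0[max(1, ceiling(r0 - h)):min(nr, floor(r0 + h)), j] <-
        cfg$fg
  }
  disk_px <- sum(base0 == cfg$fg)

  n_act <- ceiling((tr$t_e + tr$t_col) / dt) + 4L  # incl. closure frames
  n_frames <- if (!is.null(cfg$n_frames)) cfg$n_frames
              else min(cfg$n_pre + n_act + cfg$n_post, cfg$max_frames)
  if (n_frames == 0L)
    return(structure(list(
      stack = frame_stack(list(), dt = dt, pixel_size = px,
                          origin = c(r0, c0)),
      truth = tr), class = "rendered_experiment"))

  jw <- max(1L, round(exp$jet$D_0 / 2 / px))
  L_px <- tr$L_max / px
  # planned seal features in pixel columns
  gap_cols <- if (length(tr$x_p)) {
    jp <- c0 + round(tr$x_p / px)
    unlist(lapply(jp, function(j) (j - 3L):(j + 3L)))
  } else integer(0)
  dome_cols <- c0 + 0:5
  t_dome <- 0.6 * tr$t_e
  t_gap <- tr$t_e + 0.3 * tr$t_col

  # post-collapse bubbles (drawn in the final frames)
  bub <- .with_seed(exp$seed + 7654321L, {
    if (tr$regime %in% c("deep_seal", "shallow_seal"))
      .place_bubbles(tr$n_bubbles, tr$ratio_plan * disk_px,
                     nr, nc, r0, cc, rad_px)
    else data.frame(row = numeric(0), col = numeric(0), r = numeric(0))
  })

  frames <- vector("list", n_frames)
  A_series <- numeric(n_frames)
  front_px <- numeric(n_frames)
  t_seq <- (seq_len(n_frames) - 1L) * dt
  i_act0 <- cfg$n_pre + 1L
  closed_at <- NA_integer_
  surface_hold <- NULL
  bubble_area_px <- numeric(nrow(bub))
  # bubbles appear only after a short fully-closed interlude, so the
  # event and its aftermath are separated by empty-cavity frames
  t_bub <- tr$t_e + tr$t_col + 2.5 * dt

  for (i in seq_len(n_frames)) {
    t <- t_seq[i] - t_seq[min(i_act0, n_frames)]
    m <- base0
    active <- i >= i_act0 && (tr$regime == "surface_seal" ||
                              is.na(closed_at))
    if (active && tr$regime != "surface_seal" && t > tr$t_e + tr$t_col)
      active <- FALSE
    if (active && t >= 0) {
      lam <- if (t <= tr$t_e) 1
             else if (tr$regime == "surface_seal") 1
             else max(0, 1 - (t - tr$t_e) / tr$t_col)
      f_px <- min(tr$U_c * min(t, tr$t_e) / px, L_px)
      jmax <- c0 + floor(f_px)
      h_vec <- integer(0)
      if (jmax > c0 && lam > 0) {
        jj <- (c0 + 1L):jmax
        x_m <- (jj - c0) * px
        R_m <- lam * inertial_profile(x_m, min(t, tr$t_e), exp$jet, tr$U_c)
        # cap the half-width so every cavity column keeps at least one
        # dark wall pixel inside the bridge chord
        h <- pmin(round(R_m / px), floor(chord[jj]) - 1)
        if (tr$regime == "surface_seal" && t >= t_dome) {
          # keep the sealed cavity enclosed: its height may not exceed the
          # bridge chord a few columns to the left, or the bright interior
          # would leak around the dome to the background
          h <- pmin(h, floor(chord[pmax(jj - 6L, 1L)]) - 1)
        }
        h[h < 0] <- 0L
        drop_cols <- logical(length(jj))
        if (length(gap_cols) && t >= t_gap) drop_cols <- jj %in% gap_cols
        if (tr$regime == "surface_seal" && t >= t_dome)
          drop_cols <- drop_cols | jj %in% dome_cols
        for (kk in seq_along(jj)) {
          if (h[kk] >= 1L && !drop_cols[kk])
            m[(r0 - h[kk]):(r0 + h[kk]), jj[kk]] <- cfg$bg
        }
        h_vec <- ifelse(drop_cols | h < 1L, 0L, 2L * h + 1L)
        A_series[i] <- sum(h_vec) * px^2
        present <- h_vec > 0L
        front_px[i] <- if (any(present)) max(which(present)) else 0
      }
      if (A_series[i] == 0 && t > tr$t_e && is.na(closed_at) &&
          tr$regime != "surface_seal")
        closed_at <- i
      # incoming jet during expansion
      if (t <= tr$t_e && c0 > 2L)
        m[(r0 - jw):(r0 + jw), 1:(c0 - 1L)] <- cfg$fg
      if (tr$regime == "surface_seal" && t > tr$t_e) {
        if (is.null(surface_hold)) surface_hold <- m
        m <- surface_hold
        if (i > 1L && A_series[i] == 0) {
          A_series[i] <- A_series[i - 1L]
          front_px[i] <- front_px[i - 1L]
        }
      }
    }
    if (!active && i >= i_act0 && t >= t_bub &&
        tr$regime != "surface_seal") {
      # post-collapse: restored bridge plus entrained bubbles
      if (nrow(bub)) for (b in seq_len(nrow(bub))) {
        rr <- max(1L, floor(bub$row[b] - bub$r[b])):
              min(nr, ceiling(bub$row[b] + bub$r[b]))
        jj <- max(1L, floor(bub$col[b] - bub$r[b])):
              min(nc, ceiling(bub$col[b] + bub$r[b]))
        d2 <- outer((rr - bub$row[b])^2, (jj - bub$col[b])^2, "+")
        sel <- d2 <= bub$r[b]^2
        sub <- m[rr, jj]
        sub[sel] <- cfg$bg
        m[rr, jj] <- sub
        bubble_area_px[b] <- sum(sel)
      }
    }
    frames[[i]] <- m
  }

  i_Amax <- which.max(A_series)
  later <- which(A_series == 0 & seq_len(n_frames) > i_Amax &
                   seq_len(n_frames) >= i_act0)
  t_col_rendered <- if (length(later) && A_series[i_Amax] > 0 &&
                        tr$regime != "surface_seal")
    t_seq[min(later)] - t_seq[i_Amax] else NA_real_
  if (tr$regime == "surface_seal") {
    # the sealed cavity itself is the single entrained bubble
    count <- 1L
    A_bub_px <- A_series[n_frames] / px^2
    bubbles_df <- data.frame(row = r0, col = c0 + front_px[n_frames] / 2,
                             r = NA_real_, area_px = A_bub_px)
  } else {
    count <- nrow(bub)
    A_bub_px <- sum(bubble_area_px)
    bubbles_df <- if (count) cbind(bub, area_px = bubble_area_px)
                  else data.frame(row = numeric(0), col = numeric(0),
                                  r = numeric(0), area_px = numeric(0))
  }
  truth <- list(
    regime = tr$regime, U_c = tr$U_c,
    L_max = max(front_px) * px,
    A_max = max(A_series), A_series = A_series,
    t_col = t_col_rendered,
    x_p = tr$x_p,
    A_total = disk_px * px^2,
    A_bubbles = A_bub_px * px^2,
    ratio = if (disk_px > 0) A_bub_px / disk_px else 0,
    count = count, bubbles = bubbles_df,
    decision = tr$decision)
  structure(list(
    stack = frame_stack(frames, dt = dt, pixel_size = px,
                        origin = c(r0, c0)),
    truth = truth), class = "rendered_experiment")
}

#' Add seeded Gaussian pixel noise to a stack
#'
#' Adds clipped additive Gaussian noise with standard deviation `sigma`
#' gray levels (on the 0-255 scale) to every frame; `sigma = 0` returns
#' the stack unchanged.
#'
#' @param stack a [frame_stack()].
#' @param sigma noise standard deviation in gray levels (0-255 scale),
#'   non-negative.
#' @param seed integer seed making the noise reproducible.
#' @return A [frame_stack()] with noisy frames clipped to `[0, 1]`.
#' @export
inject_noise <- function(stack, sigma, seed = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(stack)
  .with_seed(seed, {
    stack$frames <- lapply(stack$frames, function(f) {
      pmin(pmax(f + matrix(rnorm(length(f), 0, sigma / 255),
                           nrow(f), ncol(f)), 0), 1)
    })
    stack
  })
}
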
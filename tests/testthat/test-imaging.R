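# Shadowgraph metrology on frames with code-built ground truth.

test_that("binarization segments dark regions deterministically", {
  expect_error(binarize(NULL), "empty frame")
  # uniform bright frame: no dark region under a fixed threshold
  expect_equal(sum(binarize(matrix(0.9, 50, 50), "fixed", 0.5)), 0)
  # rendered disk: otsu recovers its area within 1%
  fr <- disk_frame(radius = 40)
  mask <- binarize(fr)
  expect_equal(sum(mask), pi * 40^2, tolerance = 0.01)
  # identical input, identical output
  expect_identical(binarize(fr), binarize(fr))
  # complement strategy on the inverted image gives the complementary mask
  m1 <- binarize(fr, "fixed", 0.5, dark = TRUE)
  m2 <- binarize(1 - fr, "fixed", 0.5, dark = FALSE)
  expect_identical(m1, m2)
})

test_that("cavity profiles are recovered within one pixel", {
  sc <- slab_cavity_frame(front_px = 150, a = 4)
  mask <- binarize(sc$frame, "fixed", 0.5)
  prof <- extract_cavity_profile(mask, c(sc$r0, sc$c0), pixel_size = 10e-6)
  # front within one pixel of the last rendered column
  drawn_front <- max(which(sc$h_true > 0)) - sc$c0
  expect_lt(abs(attr(prof, "front_m") / 10e-6 - drawn_front), 1.5)
  # every axial bin within one pixel of the rendered half-width
  got_px <- prof$R_m / 10e-6
  cols <- sc$c0 + seq_along(got_px) - 1L  # profile starts at the origin column
  want_px <- sc$h_true[cols] + 0.5        # centre pixel widens the run by one
  keep <- sc$h_true[cols] > 0
  expect_true(all(abs(got_px[keep] - want_px[keep]) <= 1))
  # a pre-impact frame yields an empty profile, not an error
  blank <- matrix(0.9, 200, 300); blank[, 40:260] <- 0.1
  p0 <- extract_cavity_profile(binarize(blank, "fixed", 0.5), c(100, 40))
  expect_equal(nrow(p0), 0)
  expect_equal(attr(p0, "front_m"), 0)
})

test_that("front velocity fits recover rendered speeds", {
  # u_px = 10 px/frame at 10 um px and 20 us dt -> 5 m/s
  st <- slab_stack(n_frames = 12, u_px = 10)
  fit <- fit_front_velocity(st, strategy = "fixed")
  expect_equal(fit$U_c, 5, tolerance = 0.02)
  # stationary cavity: zero velocity
  still <- frame_stack(replicate(6, slab_cavity_frame(front_px = 80)$frame,
                                 simplify = FALSE),
                       origin = c(100, 40))
  expect_equal(fit_front_velocity(still, strategy = "fixed")$U_c, 0)
  # with seeded pixel noise (sigma = 5 gray levels) still within 5%
  noisy <- inject_noise(slab_stack(n_frames = 12, u_px = 10), 5, seed = 99)
  expect_equal(fit_front_velocity(noisy, strategy = "fixed")$U_c, 5,
               tolerance = 0.05)
  # too few usable frames
  short <- frame_stack(list(slab_cavity_frame(front_px = 10)$frame),
                       origin = c(100, 40))
  expect_error(fit_front_velocity(short, strategy = "fixed"),
               "insufficient")
})

test_that("area series locate the maximum and the collapse", {
  # expansion for 6 frames, then shrink to closure at frame 10
  fronts <- c(0, 30, 60, 90, 120, 150, 100, 60, 25, 0, 0)
  frames <- lapply(fronts, function(f)
    slab_cavity_frame(front_px = f)$frame)
  st <- frame_stack(frames, origin = c(100, 40))
  ar <- cavity_area_series(st, strategy = "fixed")
  expect_equal(which.max(ar$A), 6)
  expect_equal(ar$A_max, max(ar$A))
  expect_false(ar$open_ended)
  # collapse time: frames 6 -> 10 at dt = 2e-5
  expect_equal(ar$t_col, 4 * 2e-5, tolerance = 1e-9)
  # rendered area matches the drawn pixel count exactly
  drawn <- sum(2 * slab_cavity_frame(front_px = 150)$h_true + 1)
  expect_equal(ar$A_max, drawn * (10e-6)^2, tolerance = 0.02)
  # a never-closing stack is flagged open-ended
  st_open <- slab_stack(n_frames = 8, u_px = 10)
  ar_open <- cavity_area_series(st_open, strategy = "fixed")
  expect_true(ar_open$open_ended)
  expect_true(is.na(ar_open$t_col))
})

test_that("bubbles are counted, merged and floored per the cluster rule", {
  px <- 10e-6
  blank_mask <- matrix(FALSE, 120, 160)
  b0 <- measure_bubbles(blank_mask, px)
  expect_equal(b0$count, 0L); expect_equal(b0$ratio, 0)
  # three 150 um bubbles (r = 7.5 px) inside a dark disk: all counted,
  # areas exact to the rendered pixel count
  fr <- disk_frame(nr = 200, nc = 200, center = c(100, 100), radius = 80)
  centers <- list(c(70, 80), c(130, 80), c(100, 135))
  drawn_px <- integer(3)
  for (k in 1:3) {
    d2 <- outer((1:200 - centers[[k]][1])^2, (1:200 - centers[[k]][2])^2,
                "+")
    sel <- d2 <= 7.5^2
    fr[sel] <- 0.9
    drawn_px[k] <- sum(sel)
  }
  bs <- measure_bubbles(binarize(fr, "fixed", 0.5), px)
  expect_equal(bs$count, 3L)
  expect_equal(sort(bs$bubbles$area_m2), sort(drawn_px) * px^2,
               tolerance = 1e-9)
  expect_lte(bs$A_bubbles, bs$A_total)
  # two 60 um bubbles separated by a 30 um gap merge into one counted
  # bubble with the combined area
  fr2 <- disk_frame(nr = 200, nc = 200, center = c(100, 100), radius = 80)
  tot <- 0
  for (ccol in c(90, 99)) {  # 3 px centre gap between 3 px radii
    d2 <- outer((1:200 - 100)^2, (1:200 - ccol)^2, "+")
    sel <- d2 <= 3^2
    fr2[sel] <- 0.9
    tot <- tot + sum(sel)
  }
  bs2 <- measure_bubbles(binarize(fr2, "fixed", 0.5), px)
  expect_equal(bs2$count, 1L)
  expect_equal(bs2$bubbles$area_m2, tot * px^2, tolerance = 1e-9)
  # a lone 60 um bubble is below the optical floor and dropped
  fr3 <- disk_frame(nr = 200, nc = 200, center = c(100, 100), radius = 80)
  d2 <- outer((1:200 - 100)^2, (1:200 - 100)^2, "+")
  fr3[d2 <= 3^2] <- 0.9
  expect_equal(measure_bubbles(binarize(fr3, "fixed", 0.5), px)$count, 0L)
})

test_that("measurements are idempotent and scale with the metadata", {
  st <- slab_stack(n_frames = 10, u_px = 12)
  a1 <- cavity_area_series(st, strategy = "fixed")
  a2 <- cavity_area_series(st, strategy = "fixed")
  expect_identical(a1, a2)
  # doubling the pixel size scales areas by 4 and velocities by 2
  st2 <- st; st2$pixel_size <- 2 * st$pixel_size
  expect_equal(cavity_area_series(st2, strategy = "fixed")$A_max,
               4 * a1$A_max)
  expect_equal(fit_front_velocity(st2, strategy = "fixed")$U_c,
               2 * fit_front_velocity(st, strategy = "fixed")$U_c)
  # halving dt doubles the fitted velocity
  st3 <- st; st3$dt <- st$dt / 2
  expect_equal(fit_front_velocity(st3, strategy = "fixed")$U_c,
               2 * fit_front_velocity(st, strategy = "fixed")$U_c)
})

test_that("pinch events are located at interior gaps", {
  # draw a cavity with a 4-column interior gap at x = 60 px
  frames <- lapply(c(80, 100, 120, 120, 120), function(f) {
    sc <- slab_cavity_frame(front_px = f)
    m <- sc$frame
    if (f == 120) m[, sc$c0 + 58:62] <- 0.1  # re-close the bridge there
    m
  })
  st <- frame_stack(frames, origin = c(100, 40))
  ev <- detect_pinch_events(st, strategy = "fixed")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$x_p / 10e-6, 59, tolerance = 0.05)
})

test_that("stacks round-trip through PNG + sidecar files", {
  st <- slab_stack(n_frames = 4, u_px = 15)
  dir <- tempfile("stack")
  write_stack(st, dir)
  back <- read_stack(dir)
  expect_equal(length(back$frames), 4L)
  expect_equal(back$dt, st$dt)
  expect_equal(back$pixel_size, st$pixel_size)
  expect_equal(back$origin, st$origin)
  # PNG quantizes to 8 bits; frames agree to within one gray level
  expect_lt(max(abs(back$frames[[2]] - st$frames[[2]])), 1 / 255)
})

test_that("analysis results export as tidy CSV", {
  st <- slab_stack(n_frames = 6, u_px = 10)
  f1 <- tempfile(fileext = ".csv")
  write_area_series_csv(cavity_area_series(st, strategy = "fixed"), f1)
  df <- read.csv(f1)
  expect_identical(names(df), c("t_s", "H_c_m", "A_m2"))
  expect_equal(nrow(df), 6L)
  fr <- disk_frame(nr = 200, nc = 200, center = c(100, 100), radius = 80)
  d2 <- outer((1:200 - 100)^2, (1:200 - 100)^2, "+")
  fr[d2 <= 8^2] <- 0.9
  f2 <- tempfile(fileext = ".csv")
  write_bubble_csv(measure_bubbles(binarize(fr, "fixed", 0.5), 10e-6), f2)
  db <- read.csv(f2)
  expect_identical(names(db), c("id", "x_px", "y_px", "area_m2", "d_eq_m"))
  expect_equal(nrow(db), 1L)
})
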
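# Shared fixtures: reference materials, jets, and small rendered scenes
# built in code.

water_mat <- function() as_material("water")
glycerol_mat <- function() as_material("glycerol_78")

ref_jet <- function(U_0 = 20, D_0 = 100e-6, ...) {
  suppressWarnings(jet_spec(U_0 = U_0, D_0 = D_0, ...))
}

# a frame with a filled dark disk on a bright background
disk_frame <- function(nr = 120, nc = 160, center = c(60, 80), radius = 40,
                       bg = 0.9, fg = 0.1) {
  m <- matrix(bg, nr, nc)
  d2 <- outer((seq_len(nr) - center[1])^2, (seq_len(nc) - center[2])^2, "+")
  m[d2 <= radius^2] <- fg
  m
}

# a rectangular dark bridge slab with a parabolic cavity of known
# half-width R(x) = sqrt(a * (front_px - x)) drawn from the left edge;
# returns the frame plus the ground-truth half-widths per column
slab_cavity_frame <- function(nr = 200, nc = 300, r0 = 100, c0 = 40,
                              slab_cols = 40:260, front_px = 150,
                              a = 4, bg = 0.9, fg = 0.1) {
  m <- matrix(bg, nr, nc)
  m[, slab_cols] <- fg
  h_true <- integer(nc)
  if (front_px >= 1) {
    for (x in 1:front_px) {
      j <- c0 + x
      h <- round(sqrt(a * (front_px - x)))
      if (h >= 1) {
        m[(r0 - h):(r0 + h), j] <- bg
        h_true[j] <- h
      }
    }
  }
  list(frame = m, h_true = h_true, r0 = r0, c0 = c0, front_px = front_px)
}

# stack of slab frames with a front advancing at u_px pixels per frame
slab_stack <- function(n_frames = 12, u_px = 10, dt = 2e-5,
                       pixel_size = 10e-6, ...) {
  frames <- lapply(seq_len(n_frames), function(i) {
    slab_cavity_frame(front_px = round(u_px * (i - 1)), ...)$frame
  })
  ref <- slab_cavity_frame(...)
  frame_stack(frames, dt = dt, pixel_size = pixel_size,
              origin = c(ref$r0, ref$c0))
}
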
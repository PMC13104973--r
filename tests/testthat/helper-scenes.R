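# Small scene builders shared across test files.

# A rectangular logical mask inside an h x w frame.
block_mask <- function(h, w, rows, cols) {
  m <- matrix(FALSE, h, w)
  m[rows, cols] <- TRUE
  m
}

# A ratio_movie with the given percent-scale frames and no flagged pixels.
make_ratio_movie <- function(frames) {
  structure(list(data = frames,
                 background_flag = array(FALSE, dim = dim(frames)),
                 ratio_floor = 0),
            class = "ratio_movie")
}

# Static scene: elliptical cell plus two stress fibers, no ruffles.
static_fiber_scene <- function(noise_sd, seed = 3, n_frames = 60) {
  scene <- scene_spec(n_frames = n_frames, noise_sd = noise_sd, seed = seed)
  fibers <- static_structure_spec(r0 = c(25, 35), c0 = c(20, 25),
                                  r1 = c(40, 30), c1 = c(45, 40),
                                  width = c(2, 2), intensity = c(100, 80))
  generate_ruffle_movie(scene, ruffle_spec(), fibers)
}

# Protrusion scene: rectangular cell growing to the right.
protrusion_masks <- function(h = 80, w = 80) {
  base <- block_mask(h, w, 20:60, 20:45)
  full <- base
  full[20:60, 46:70] <- TRUE
  list(base = base, full = full)
}

# Nearest-detection distances from each ground-truth centre.
match_distances <- function(spots, gt) {
  vapply(seq_len(nrow(gt)), function(i) {
    if (nrow(spots) == 0) return(Inf)
    min(sqrt((spots$z - gt$z[i])^2 + (spots$y - gt$y[i])^2 +
               (spots$x - gt$x[i])^2))
  }, numeric(1))
}
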
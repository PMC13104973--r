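# Synthetic fluorescence scenes with exact planted ground truth. Each
# generator renders the noiseless scene first, records the truth, then adds
# noise, so the truth is never contaminated by the noise model. All
# randomness is driven by the spec's seed and generators are pure functions
# of their specs.

#' Scene specification for a ruffling movie
#'
#' Describes the static part of a live-cell actin movie: an elliptical cell
#' body on a dark background, with additive Gaussian readout noise and
#' optional Poisson shot noise.
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames.
#' @param cell_center `(row, col)` centre of the cell ellipse.
#' @param cell_axes `(row, col)` semi-axes in pixels; the ellipse must lie
#'   fully inside the frame.
#' @param cell_intensity,background_intensity intensities in arbitrary units;
#'   `cell_intensity` must exceed `background_intensity`.
#' @param noise_sd standard deviation of additive Gaussian noise (AU).
#' @param shot_noise if `TRUE`, pixel values are Poisson-resampled from their
#'   expected counts before Gaussian noise is added.
#' @param seed integer seed; identical specs yield bit-identical scenes.
#' @return A validated list of class `scene_spec`.
#' @export
scene_spec <- function(height = 64, width = 64, n_frames = 100,
                       frame_interval = 2,
                       cell_center = c((height + 1) / 2, (width + 1) / 2),
                       cell_axes = c(0.34 * height, 0.38 * width),
                       cell_intensity = 200, background_intensity = 10,
                       noise_sd = 2, shot_noise = FALSE, seed = 1L) {
  stopifnot(height >= 1, width >= 1, n_frames >= 1, frame_interval > 0)
  if (background_intensity < 0 || cell_intensity <= background_intensity)
    stop("need cell_intensity > background_intensity >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (cell_center[1] - cell_axes[1] < 1 || cell_center[1] + cell_axes[1] > height ||
      cell_center[2] - cell_axes[2] < 1 || cell_center[2] + cell_axes[2] > width)
    stop("cell ellipse must lie fully inside the frame")
  structure(list(height = height, width = width, n_frames = n_frames,
                 frame_interval = frame_interval, cell_center = cell_center,
                 cell_axes = cell_axes, cell_intensity = cell_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, shot_noise = shot_noise,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Ruffle event specification
#'
#' Each event is a transient bright cap at the cell edge: it appears at
#' `onset_frame`, persists for `duration_frames`, occupies a fixed fraction
#' of the cell area and drifts along the cell edge, emulating the fast
#' spatial motion that distinguishes membrane ruffles from static
#' stress fibers.
#'
#' @param edge_angle radians; position of the cap on the cell edge.
#' @param area_fraction fraction of the cell area covered while active
#'   (0 < f < 0.5).
#' @param onset_frame first active frame (1-based).
#' @param duration_frames number of active frames.
#' @param amplitude intensity added on top of the cell body (AU), > 0.
#' @param drift_px_per_frame tangential drift speed of the cap.
#' @return A data frame of class `ruffle_spec`, one row per event.
#' @export
ruffle_spec <- function(edge_angle = numeric(), area_fraction = numeric(),
                        onset_frame = integer(), duration_frames = integer(),
                        amplitude = numeric(), drift_px_per_frame = 0) {
  n_ev <- length(edge_angle)
  drift_px_per_frame <- rep_len(as.numeric(drift_px_per_frame), n_ev)
  ev <- data.frame(edge_angle = as.numeric(edge_angle),
                   area_fraction = as.numeric(area_fraction),
                   onset_frame = as.integer(onset_frame),
                   duration_frames = as.integer(duration_frames),
                   amplitude = as.numeric(amplitude),
                   drift_px_per_frame = as.numeric(drift_px_per_frame))
  if (nrow(ev) > 0) {
    stopifnot(all(ev$area_fraction > 0), all(ev$area_fraction < 0.5),
              all(ev$onset_frame >= 1), all(ev$duration_frames >= 1),
              all(ev$amplitude > 0))
  }
  class(ev) <- c("ruffle_spec", class(ev))
  ev
}

#' Static stress-fiber specification
#'
#' Straight bright line segments inside the cell, identical in every frame.
#' They emulate the actin-high static structures that contaminate naive
#' intensity thresholding.
#'
#' @param r0,c0,r1,c1 segment endpoints (row, col), inside the cell ellipse.
#' @param width fiber width in pixels (>= 1).
#' @param intensity added intensity (AU).
#' @return A data frame of class `static_structure_spec`.
#' @export
static_structure_spec <- function(r0 = numeric(), c0 = numeric(),
                                  r1 = numeric(), c1 = numeric(),
                                  width = 2, intensity = 100) {
  fb <- data.frame(r0 = as.numeric(r0), c0 = as.numeric(c0),
                   r1 = as.numeric(r1), c1 = as.numeric(c1),
                   width = as.numeric(width), intensity = as.numeric(intensity))
  if (nrow(fb) > 0) stopifnot(all(fb$width >= 1))
  class(fb) <- c("static_structure_spec", class(fb))
  fb
}

ellipse_mask <- function(height, width, center, axes) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((rr - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
}

# Solve, by bisection on the pixel grid, the cap radius whose intersection
# with the cell ellipse covers `target_px` pixels. Exact to the pixel-count
# resolution of the grid, unlike the analytic half-disk area.
cap_mask_for_area <- function(d2, cell, target_px) {
  lo <- 0.3
  hi <- sqrt(max(d2))
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    n <- sum(d2 <= mid^2 & cell)
    if (n < target_px) lo <- mid else hi <- mid
  }
  d2 <= hi^2 & cell
}

#' Generate a ruffling movie with planted ground truth
#'
#' Renders the cell body, static fibers and transient drifting ruffle caps,
#' records the exact per-frame ruffle and cell masks, then applies noise.
#'
#' @param scene a [scene_spec()].
#' @param ruffles a [ruffle_spec()]; empty for a static scene.
#' @param statics optional [static_structure_spec()].
#' @return A list with `movie` (a [bamp_movie()]) and `truth`, the latter
#'   holding per-frame logical `ruffle_masks` and `cell_masks` (computed on
#'   the noiseless scene), the cell area and per-frame planted area
#'   fractions.
#' @export
generate_ruffle_movie <- function(scene, ruffles = ruffle_spec(),
                                  statics = NULL) {
  stopifnot(inherits(scene, "scene_spec"))
  h <- scene$height; w <- scene$width; T <- scene$n_frames
  if (nrow(ruffles) > 0 &&
      any(ruffles$onset_frame + ruffles$duration_frames - 1L > T))
    stop("ruffle events extend past the last frame")
  cell <- ellipse_mask(h, w, scene$cell_center, scene$cell_axes)
  cell_area <- sum(cell)
  base <- scene$background_intensity +
    (scene$cell_intensity - scene$background_intensity) * cell
  if (!is.null(statics) && nrow(statics) > 0) {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside <- function(r, c) {
      ((r - scene$cell_center[1]) / scene$cell_axes[1])^2 +
        ((c - scene$cell_center[2]) / scene$cell_axes[2])^2 <= 1
    }
    for (i in seq_len(nrow(statics))) {
      f <- statics[i, ]
      if (!inside(f$r0, f$c0) || !inside(f$r1, f$c1))
        stop("fiber endpoints must lie inside the cell ellipse")
      # distance from each pixel to the segment
      vx <- f$r1 - f$r0; vy <- f$c1 - f$c0
      len2 <- vx^2 + vy^2
      tt <- if (len2 == 0) 0 else
        pmin(1, pmax(0, ((rr - f$r0) * vx + (cc - f$c0) * vy) / len2))
      dist2 <- (rr - (f$r0 + tt * vx))^2 + (cc - (f$c0 + tt * vy))^2
      fiber <- dist2 <= (f$width / 2)^2 & cell
      base <- base + f$intensity * fiber
    }
  }
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  rho <- mean(scene$cell_axes)
  movie <- array(0, dim = c(T, h, w))
  ruffle_masks <- array(FALSE, dim = c(T, h, w))
  cell_masks <- array(rep(cell, each = T), dim = c(T, h, w))
  for (t in seq_len(T)) {
    amp_map <- matrix(0, h, w)
    frame_mask <- matrix(FALSE, h, w)
    if (nrow(ruffles) > 0) {
      active <- which(t >= ruffles$onset_frame &
                        t < ruffles$onset_frame + ruffles$duration_frames)
      if (sum(ruffles$area_fraction[active]) > 0.5)
        stop("overlapping ruffle events exceed half the cell area in frame ", t)
      for (e in active) {
        ev <- ruffles[e, ]
        theta <- ev$edge_angle +
          (t - ev$onset_frame) * ev$drift_px_per_frame / rho
        p <- c(scene$cell_center[1] + scene$cell_axes[1] * sin(theta),
               scene$cell_center[2] + scene$cell_axes[2] * cos(theta))
        d2 <- (rr - p[1])^2 + (cc - p[2])^2
        m <- cap_mask_for_area(d2, cell, round(ev$area_fraction * cell_area))
        frame_mask <- frame_mask | m
        amp_map <- pmax(amp_map, ev$amplitude * m)
      }
    }
    ruffle_masks[t, , ] <- frame_mask
    movie[t, , ] <- base + amp_map
  }
  per_frame_fraction <- apply(ruffle_masks, 1, sum) / cell_area
  movie <- with_seed(scene$seed, {
    if (scene$shot_noise) movie[] <- rpois(length(movie), lambda = movie)
    if (scene$noise_sd > 0)
      movie <- movie + rnorm(length(movie), sd = scene$noise_sd)
    pmax(movie, 0)
  })
  list(movie = bamp_movie(movie, frame_interval = scene$frame_interval),
       truth = list(ruffle_masks = ruffle_masks, cell_masks = cell_masks,
                    cell_area = cell_area,
                    per_frame_fraction = per_frame_fraction,
                    mean_fraction = mean(per_frame_fraction)))
}

#' Build a ruffle event schedule with a prescribed time-averaged area fraction
#'
#' Plants `n_events` sequential drifting caps inside the frame range where a
#' ±`half_window` rolling-median window is fully contained, so the planted
#' events remain transient with respect to the baseline window. The per-event
#' active area fraction is scaled so the ruffle area averaged over the whole
#' movie equals `target_fraction`.
#'
#' @param target_fraction desired time-averaged ruffle area / cell area.
#' @param n_frames movie length in frames.
#' @param half_window rolling-median half window the analysis will use.
#' @param n_events,duration_frames number and length of events.
#' @param amplitude,drift_px_per_frame passed through to [ruffle_spec()].
#' @return A [ruffle_spec()].
#' @export
ruffle_events_for_fraction <- function(target_fraction, n_frames,
                                       half_window = 25, n_events = 4,
                                       duration_frames = 12,
                                       amplitude = 200,
                                       drift_px_per_frame = 1.5) {
  active_frames <- n_events * duration_frames
  f_active <- target_fraction * n_frames / active_frames
  if (f_active >= 0.5)
    stop("target fraction too large for the event schedule")
  first <- half_window + 1L
  last <- n_frames - half_window - duration_frames
  if (last < first)
    stop("movie too short for the requested schedule")
  onsets <- round(seq(first, last, length.out = n_events))
  ruffle_spec(edge_angle = seq(0, 2 * pi, length.out = n_events + 1)[seq_len(n_events)],
              area_fraction = rep(f_active, n_events),
              onset_frame = onsets,
              duration_frames = rep(duration_frames, n_events),
              amplitude = rep(amplitude, n_events),
              drift_px_per_frame = rep(drift_px_per_frame, n_events))
}

#' Protrusion scene specification
#'
#' Describes a two-channel optogenetic-style movie: a cell whose footprint
#' grows from `base_mask` (T0) to `full_mask` (T1), imaged in a membrane
#' marker channel and a reporter channel whose intensity is a region-wise
#' multiple of the membrane signal.
#'
#' @param base_mask,full_mask logical matrices; `base_mask` must be a subset
#'   of `full_mask`.
#' @param n_frames number of frames in the rendered movie.
#' @param growth_schedule optional integer matrix (same shape) giving, for
#'   each added pixel, the frame at which it appears; `NA` elsewhere. By
#'   default added pixels appear in order of distance from the base mask,
#'   spread evenly over frames `2..n_frames`.
#' @param membrane_intensity membrane channel intensity on the cell (AU).
#' @param reporter_ratio_protrusive,reporter_ratio_body true reporter over
#'   membrane ratios in the protrusive region (`full & !base`) and the cell
#'   body (`base`).
#' @param noise_sd additive Gaussian noise (AU), applied to both channels.
#' @param seed integer seed.
#' @return A validated list of class `protrusion_scene_spec`.
#' @export
protrusion_scene_spec <- function(base_mask, full_mask, n_frames = 20,
                                  growth_schedule = NULL,
                                  membrane_intensity = 100,
                                  reporter_ratio_protrusive = 1.5,
                                  reporter_ratio_body = 1,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(is.logical(base_mask), is.logical(full_mask),
            all(dim(base_mask) == dim(full_mask)), n_frames >= 2)
  if (any(base_mask & !full_mask))
    stop("`base_mask` must be a subset of `full_mask`")
  if (reporter_ratio_protrusive <= 0 || reporter_ratio_body <= 0)
    stop("reporter ratios must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(base_mask = base_mask, full_mask = full_mask,
                 n_frames = as.integer(n_frames),
                 growth_schedule = growth_schedule,
                 membrane_intensity = membrane_intensity,
                 reporter_ratio_protrusive = reporter_ratio_protrusive,
                 reporter_ratio_body = reporter_ratio_body,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "protrusion_scene_spec")
}

#' Generate a two-channel protrusion movie
#'
#' @param spec a [protrusion_scene_spec()].
#' @return A list with `reporter` and `membrane` (both [bamp_movie()]) and
#'   `truth` holding the T0/T1 masks, the protrusive partition and the true
#'   planted ratios.
#' @export
generate_protrusion_movie <- function(spec) {
  stopifnot(inherits(spec, "protrusion_scene_spec"))
  base <- spec$base_mask
  full <- spec$full_mask
  added <- full & !base
  T <- spec$n_frames
  d <- dim(base)
  appear <- spec$growth_schedule
  if (is.null(appear)) {
    appear <- matrix(NA_integer_, d[1], d[2])
    if (any(added)) {
      dist <- EBImage::distmap(EBImage::Image((!base) * 1))
      dist <- array(as.numeric(dist), dim = d)
      rk <- rank(dist[added], ties.method = "first")
      appear[added] <- 1L + as.integer(ceiling(rk / sum(added) * (T - 1L)))
    }
  }
  ratio_map <- matrix(0, d[1], d[2])
  ratio_map[base] <- spec$reporter_ratio_body
  ratio_map[added] <- spec$reporter_ratio_protrusive
  membrane <- array(0, dim = c(T, d[1], d[2]))
  reporter <- array(0, dim = c(T, d[1], d[2]))
  for (t in seq_len(T)) {
    mask_t <- base | (added & !is.na(appear) & appear <= t)
    membrane[t, , ] <- spec$membrane_intensity * mask_t
    reporter[t, , ] <- spec$membrane_intensity * mask_t * ratio_map
  }
  out <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      membrane <- membrane + rnorm(length(membrane), sd = spec$noise_sd)
      reporter <- reporter + rnorm(length(reporter), sd = spec$noise_sd)
    }
    list(membrane = pmax(membrane, 0), reporter = pmax(reporter, 0))
  })
  list(reporter = bamp_movie(out$reporter),
       membrane = bamp_movie(out$membrane),
       truth = list(mask_t0 = base, mask_t1 = full, protrusive = added,
                    non_protrusive = base,
                    ratio_protrusive = spec$reporter_ratio_protrusive,
                    ratio_body = spec$reporter_ratio_body))
}

#' Spot volume scene specification
#'
#' An ellipsoidal cell (actin channel) plus isotropic Gaussian point sources
#' (spot channel) at known centres inside and outside the cell, emulating a
#' proximity-ligation z-stack.
#'
#' @param shape `(Z, Y, X)` volume size in voxels.
#' @param voxel_spacing voxel spacing in micrometres `(z, y, x)`.
#' @param cell_center,cell_axes ellipsoid centre and semi-axes in voxels.
#' @param cell_intensity,background_intensity actin channel intensities (AU).
#' @param spots_inside,spots_outside data frames with columns
#'   `z, y, x, sigma, amplitude`; inside centres must lie within the
#'   ellipsoid and outside centres beyond it.
#' @param min_separation minimum pairwise centre distance in voxels.
#' @param noise_sd additive Gaussian noise (AU) on both channels.
#' @param seed integer seed.
#' @return A validated list of class `spot_scene_spec`.
#' @export
spot_scene_spec <- function(shape = c(64, 64, 64), voxel_spacing = c(1, 1, 1),
                            cell_center = (shape + 1) / 2,
                            cell_axes = c(0.34, 0.40, 0.40) * shape,
                            cell_intensity = 200, background_intensity = 10,
                            spots_inside = NULL, spots_outside = NULL,
                            min_separation = 10, noise_sd = 10, seed = 1L) {
  empty <- data.frame(z = numeric(), y = numeric(), x = numeric(),
                      sigma = numeric(), amplitude = numeric())
  if (is.null(spots_inside)) spots_inside <- empty
  if (is.null(spots_outside)) spots_outside <- empty
  ell <- function(p) sum(((p - cell_center) / cell_axes)^2)
  for (i in seq_len(nrow(spots_inside)))
    if (ell(as.numeric(spots_inside[i, c("z", "y", "x")])) > 1)
      stop("an inside spot centre lies outside the cell ellipsoid")
  for (i in seq_len(nrow(spots_outside)))
    if (ell(as.numeric(spots_outside[i, c("z", "y", "x")])) <= 1)
      stop("an outside spot centre lies inside the cell ellipsoid")
  all_c <- rbind(spots_inside[, c("z", "y", "x")],
                 spots_outside[, c("z", "y", "x")])
  if (nrow(all_c) > 1) {
    dm <- as.matrix(dist(all_c))
    diag(dm) <- Inf
    if (min(dm) < min_separation)
      stop("planted spot centres violate the minimum separation")
  }
  stopifnot(all(shape >= 1), all(voxel_spacing > 0), noise_sd >= 0)
  structure(list(shape = as.integer(shape), voxel_spacing = voxel_spacing,
                 cell_center = cell_center, cell_axes = cell_axes,
                 cell_intensity = cell_intensity,
                 background_intensity = background_intensity,
                 spots_inside = spots_inside, spots_outside = spots_outside,
                 min_separation = min_separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "spot_scene_spec")
}

ellipsoid_mask <- function(shape, center, axes) {
  z <- ((seq_len(shape[1]) - center[1]) / axes[1])^2
  y <- ((seq_len(shape[2]) - center[2]) / axes[2])^2
  x <- ((seq_len(shape[3]) - center[3]) / axes[3])^2
  outer(outer(z, y, `+`), x, `+`) <= 1
}

add_gaussian_spot <- function(vol, center, sigma, amplitude) {
  d <- dim(vol)
  r <- ceiling(4 * sigma)
  zi <- max(1, floor(center[1] - r)):min(d[1], ceiling(center[1] + r))
  yi <- max(1, floor(center[2] - r)):min(d[2], ceiling(center[2] + r))
  xi <- max(1, floor(center[3] - r)):min(d[3], ceiling(center[3] + r))
  gz <- exp(-(zi - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(yi - center[2])^2 / (2 * sigma^2))
  gx <- exp(-(xi - center[3])^2 / (2 * sigma^2))
  vol[zi, yi, xi] <- vol[zi, yi, xi] +
    amplitude * outer(outer(gz, gy, `*`), gx, `*`)
  vol
}

#' Generate a two-channel spot volume
#'
#' @param spec a [spot_scene_spec()].
#' @return A list with `actin` and `spots` (both [bamp_volume()]) and
#'   `truth` holding the inside/outside centre tables and the cell
#'   ellipsoid mask.
#' @export
generate_spot_volume <- function(spec) {
  stopifnot(inherits(spec, "spot_scene_spec"))
  cell <- ellipsoid_mask(spec$shape, spec$cell_center, spec$cell_axes)
  actin <- spec$background_intensity +
    (spec$cell_intensity - spec$background_intensity) * cell
  actin <- array(actin, dim = spec$shape)
  spots <- array(spec$background_intensity, dim = spec$shape)
  all_spots <- rbind(spec$spots_inside, spec$spots_outside)
  for (i in seq_len(nrow(all_spots))) {
    s <- all_spots[i, ]
    spots <- add_gaussian_spot(spots, c(s$z, s$y, s$x), s$sigma, s$amplitude)
  }
  out <- with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      actin <- actin + rnorm(length(actin), sd = spec$noise_sd)
      spots <- spots + rnorm(length(spots), sd = spec$noise_sd)
    }
    list(actin = pmax(actin, 0), spots = pmax(spots, 0))
  })
  list(actin = bamp_volume(out$actin, spec$voxel_spacing),
       spots = bamp_volume(out$spots, spec$voxel_spacing),
       truth = list(spots_inside = spec$spots_inside,
                    spots_outside = spec$spots_outside,
                    cell_mask = cell))
}

#' Sample a random, valid spot scene
#'
#' Plants `n_inside` spots well inside the cell ellipsoid and `n_outside`
#' spots in the surrounding background, with uniform random scales and the
#' spec's minimum pairwise separation, by seeded rejection sampling.
#'
#' @param seed integer seed (drives both placement and rendering noise).
#' @param n_inside,n_outside numbers of planted spots.
#' @param sigma_range range of planted Gaussian scales (voxels).
#' @param amplitude peak amplitude (AU).
#' @param noise_sd additive Gaussian noise sd (AU).
#' @param shape volume size.
#' @param min_separation minimum pairwise centre distance (voxels).
#' @return A [spot_scene_spec()].
#' @export
random_spot_scene <- function(seed, n_inside = 5, n_outside = 2,
                              sigma_range = c(3, 5), amplitude = 100,
                              noise_sd = 10, shape = c(64, 64, 64),
                              min_separation = 12) {
  center <- (shape + 1) / 2
  axes <- c(0.34, 0.40, 0.40) * shape
  with_seed(seed, {
    pts <- matrix(numeric(0), 0, 3)
    ell <- function(p) sum(((p - center) / axes)^2)
    draw <- function(inside) {
      for (try in 1:5000) {
        p <- runif(3, 6, shape - 5)
        e <- ell(p)
        ok_pos <- if (inside) e < 0.6 else e > 1.4
        ok_sep <- nrow(pts) == 0 ||
          min(sqrt(rowSums((pts - matrix(p, nrow(pts), 3, byrow = TRUE))^2))) >=
            min_separation
        if (ok_pos && ok_sep) return(p)
      }
      stop("could not place spots with the requested separation")
    }
    for (i in seq_len(n_inside)) pts <- rbind(pts, draw(TRUE))
    for (i in seq_len(n_outside)) pts <- rbind(pts, draw(FALSE))
    sig <- runif(n_inside + n_outside, sigma_range[1], sigma_range[2])
    inside_df <- data.frame(z = pts[seq_len(n_inside), 1],
                            y = pts[seq_len(n_inside), 2],
                            x = pts[seq_len(n_inside), 3],
                            sigma = sig[seq_len(n_inside)],
                            amplitude = amplitude)
    outside_df <- if (n_outside > 0)
      data.frame(z = pts[n_inside + seq_len(n_outside), 1],
                 y = pts[n_inside + seq_len(n_outside), 2],
                 x = pts[n_inside + seq_len(n_outside), 3],
                 sigma = sig[n_inside + seq_len(n_outside)],
                 amplitude = amplitude)
    else NULL
    spot_scene_spec(shape = shape, cell_center = center, cell_axes = axes,
                    spots_inside = inside_df, spots_outside = outside_df,
                    min_separation = min_separation, noise_sd = noise_sd,
                    seed = seed)
  })
}

#' Nuclei field specification for the EdU assay
#'
#' Non-overlapping circular nuclei; all appear in the DAPI channel, a fixed
#' subset in the EdU channel. Positivity is assigned to the first
#' `floor(n * fraction + 0.5)` nuclei in seeded shuffle order, so the planted
#' positive count is exact.
#'
#' @param height,width field size in pixels.
#' @param n_nuclei number of nuclei.
#' @param positive_fraction fraction of EdU-positive nuclei in `[0, 1]`.
#' @param radius_mean,radius_sd nucleus radius distribution (pixels).
#' @param dapi_intensity,edu_intensity,background intensities (AU).
#' @param noise_sd additive Gaussian noise sd (AU).
#' @param seed integer seed.
#' @return A validated list of class `nuclei_scene_spec`.
#' @export
nuclei_scene_spec <- function(height = 256, width = 256, n_nuclei = 20,
                              positive_fraction = 0.4, radius_mean = 8,
                              radius_sd = 1, dapi_intensity = 100,
                              edu_intensity = 100, background = 5,
                              noise_sd = 2, seed = 1L) {
  stopifnot(height >= 1, width >= 1, n_nuclei >= 1,
            positive_fraction >= 0, positive_fraction <= 1,
            radius_mean > 0, radius_sd >= 0, noise_sd >= 0)
  structure(list(height = height, width = width, n_nuclei = n_nuclei,
                 positive_fraction = positive_fraction,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 dapi_intensity = dapi_intensity,
                 edu_intensity = edu_intensity, background = background,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "nuclei_scene_spec")
}

#' Generate paired EdU/DAPI images
#'
#' @param spec a [nuclei_scene_spec()].
#' @return A list with `edu` and `dapi` image matrices and `truth` holding
#'   the nucleus table (centre, radius, EdU label), the noiseless channel
#'   masks and the exact positive-pixel fraction.
#' @export
generate_nuclei_images <- function(spec) {
  stopifnot(inherits(spec, "nuclei_scene_spec"))
  h <- spec$height; w <- spec$width; n <- spec$n_nuclei
  with_seed(spec$seed, {
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0
    while (nrow(centers) < n) {
      tries <- tries + 1
      if (tries > 500 * n)
        stop("cannot place ", n, " non-overlapping nuclei in a ",
             h, " x ", w, " field")
      r <- max(2, rnorm(1, spec$radius_mean, spec$radius_sd))
      if (r + 2 >= min(h, w) / 2) next
      p <- c(runif(1, r + 2, h - r - 1), runif(1, r + 2, w - r - 1))
      if (nrow(centers) > 0) {
        dd <- sqrt(rowSums((centers - matrix(p, nrow(centers), 2,
                                             byrow = TRUE))^2))
        if (min(dd - radii) < r + 2) next
      }
      centers <- rbind(centers, p)
      radii <- c(radii, r)
    }
    k <- floor(n * spec$positive_fraction + 0.5)
    ord <- sample(n)
    positive <- logical(n)
    positive[ord[seq_len(k)]] <- TRUE
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    dapi_mask <- matrix(FALSE, h, w)
    edu_mask <- matrix(FALSE, h, w)
    for (i in seq_len(n)) {
      disk <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2
      dapi_mask <- dapi_mask | disk
      if (positive[i]) edu_mask <- edu_mask | disk
    }
    dapi <- spec$background + spec$dapi_intensity * dapi_mask
    edu <- spec$background + spec$edu_intensity * edu_mask
    truth <- list(nuclei = data.frame(row = centers[, 1], col = centers[, 2],
                                      radius = radii, positive = positive),
                  dapi_mask = dapi_mask, edu_mask = edu_mask,
                  positive_count = k,
                  positive_pixel_fraction = sum(edu_mask) / sum(dapi_mask))
    if (spec$noise_sd > 0) {
      dapi <- pmax(dapi + rnorm(length(dapi), sd = spec$noise_sd), 0)
      edu <- pmax(edu + rnorm(length(edu), sd = spec$noise_sd), 0)
    }
    list(edu = edu, dapi = dapi, truth = truth)
  })
}
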
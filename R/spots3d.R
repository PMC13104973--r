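# 3D proximity-ligation spot detection: isotropize, percentile-normalize to
# [0,1], difference-of-Gaussian detection, actin-derived cell-mask gating,
# and compartment spot densities.

#' Parameters of the 3D spot detector
#'
#' @param min_sigma,max_sigma Gaussian scale band of the detector (voxels).
#' @param threshold minimum normalized difference-of-Gaussian response.
#' @param p_low,p_high percentiles mapped to 0 and 1 by
#'   [percentile_normalize()].
#' @param sigma_ratio geometric step of the scale ladder.
#' @param overlap detections whose spheres (radius `sigma * sqrt(3)`)
#'   overlap by more than this fraction are resolved by keeping the higher
#'   response.
#' @return A list of class `spot_params`.
#' @export
spot_params <- function(min_sigma = 3, max_sigma = 6, threshold = 0.01,
                        p_low = 2, p_high = 99.8, sigma_ratio = 1.6,
                        overlap = 0.5) {
  stopifnot(min_sigma > 0, max_sigma > min_sigma, p_low >= 0,
            p_high > p_low, p_high <= 100, sigma_ratio > 1,
            overlap > 0, overlap <= 1)
  structure(list(min_sigma = min_sigma, max_sigma = max_sigma,
                 threshold = threshold, p_low = p_low, p_high = p_high,
                 sigma_ratio = sigma_ratio, overlap = overlap),
            class = "spot_params")
}

#' Resample a volume to isotropic voxels
#'
#' Linear interpolation so all three spacings equal the smallest input
#' spacing; each axis gets `round(n * spacing / target)` samples.
#'
#' @param v a [bamp_volume()].
#' @return A [bamp_volume()] with equal spacings.
#' @export
isotropize <- function(v) {
  stopifnot(inherits(v, "bamp_volume"))
  target <- min(v$voxel_spacing)
  if (target <= 0) stop("voxel spacing must be positive")
  new_dim <- pmax(1L, as.integer(round(dim(v$data) * v$voxel_spacing / target)))
  if (all(new_dim == dim(v$data)))
    return(bamp_volume(v$data, rep(target, 3)))
  bamp_volume(resample_volume_linear(v$data, new_dim), rep(target, 3))
}

#' Percentile normalization to the unit interval
#'
#' Maps the `p_low` and `p_high` percentiles of the input to 0 and 1 and
#' clips; a constant input (degenerate percentiles) is rejected.
#'
#' @param v a [bamp_volume()] or numeric array.
#' @param params a [spot_params()].
#' @return Same container as the input, normalized to `[0, 1]`.
#' @export
percentile_normalize <- function(v, params = spot_params()) {
  a <- as_volume_array(v)
  q <- quantile(a, probs = c(params$p_low, params$p_high) / 100,
                names = FALSE, type = 7)
  if (q[2] <= q[1])
    stop("degenerate percentiles (constant volume?); cannot normalize")
  out <- pmin(pmax((a - q[1]) / (q[2] - q[1]), 0), 1)
  out <- array(out, dim = dim(a))
  if (inherits(v, "bamp_volume")) bamp_volume(out, v$voxel_spacing) else out
}

dog_sigma_ladder <- function(params) {
  k <- as.integer(log(params$max_sigma / params$min_sigma) /
                    log(params$sigma_ratio) + 1)
  params$min_sigma * params$sigma_ratio^(0:(k + 0L))
}

# Fractional overlap of two spheres relative to the smaller one.
sphere_overlap_fraction <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  rmin <- min(r1, r2)
  if (d <= abs(r1 - r2)) return(1)
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2 + 6 * r1 * r2) / (12 * d)
  lens / ((4 / 3) * pi * rmin^3)
}

prune_overlapping_spots <- function(spots, overlap) {
  if (nrow(spots) < 2) return(spots)
  ord <- order(-spots$response)
  spots <- spots[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots) - 1)) {
    if (!keep[i]) next
    for (j in (i + 1):nrow(spots)) {
      if (!keep[j]) next
      d <- sqrt(sum((spots[i, c("z", "y", "x")] -
                       spots[j, c("z", "y", "x")])^2))
      f <- sphere_overlap_fraction(spots$scale[i] * sqrt(3),
                                   spots$scale[j] * sqrt(3), d)
      if (f > overlap) keep[j] <- FALSE
    }
  }
  out <- spots[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Difference-of-Gaussian spot detection in a normalized volume
#'
#' Smooths the volume along a geometric scale ladder from `min_sigma`
#' onwards, forms scale-normalized difference-of-Gaussian images
#' (`(G_i - G_{i+1}) / (sigma_ratio - 1)`), and reports local maxima of the
#' 4D scale stack above `threshold`. Overlapping detections are resolved by
#' sphere overlap, keeping the higher response.
#'
#' @param v a [bamp_volume()] or array, normalized to `[0, 1]`.
#' @param params a [spot_params()].
#' @return A data frame of class `spot_list` with columns
#'   `z, y, x` (1-based voxel indices), `scale` (sigma of the detecting
#'   layer) and `response`.
#' @export
detect_spots_dog <- function(v, params = spot_params()) {
  a <- as_volume_array(v)
  sigmas <- dog_sigma_ladder(params)
  n_layers <- length(sigmas) - 1L
  d <- dim(a)
  stack <- array(0, dim = c(d, n_layers))
  g_prev <- gauss_smooth(a, sigmas[1])
  for (i in seq_len(n_layers)) {
    g_next <- gauss_smooth(a, sigmas[i + 1])
    stack[, , , i] <- (g_prev - g_next) / (params$sigma_ratio - 1)
    g_prev <- g_next
  }
  mx <- cpp_local_maxima4(stack, params$threshold)
  spots <- data.frame(z = mx[, 1], y = mx[, 2], x = mx[, 3],
                      scale = sigmas[mx[, 4]], response = mx[, 5])
  spots <- prune_overlapping_spots(spots, params$overlap)
  class(spots) <- c("spot_list", class(spots))
  spots
}

#' Binary cell mask from the actin channel
#'
#' 3-class Otsu thresholding keeps the brightest voxels (above the upper of
#' the two thresholds); the mask is then postprocessed, in order, by keeping
#' the largest spatial component, binary closing (ball radius 3), hole
#' filling, and binary erosion (ball radius 1). The order is part of the
#' contract: permuting it changes the result.
#'
#' @param actin a [bamp_volume()] or array (ideally isotropic).
#' @return A list of class `cell_mask3d` with the logical `mask`.
#' @export
cell_mask_from_actin <- function(actin) {
  a <- as_volume_array(actin)
  thr <- otsu_two_thresholds(a)
  mask <- a > thr[2]
  if (!any(mask))
    stop("3-class Otsu thresholding produced an empty mask")
  lab <- cpp_label3(mask, 26L)
  sizes <- tabulate(lab[lab > 0])
  mask <- array(lab == which.max(sizes), dim = dim(a))
  off3 <- ball_offsets(3)
  mask <- cpp_morph3(cpp_morph3(mask, off3, TRUE), off3, FALSE)  # closing
  mask <- cpp_fill_holes3(mask)
  mask <- cpp_morph3(mask, ball_offsets(1), FALSE)               # erosion
  structure(list(mask = mask), class = "cell_mask3d")
}

#' Remove spot detections outside the cell volume
#'
#' Retains spots whose rounded centre voxel lies inside the mask.
#'
#' @param spots a `spot_list`.
#' @param mask a `cell_mask3d` (or logical array) in the same voxel grid.
#' @return The filtered `spot_list`.
#' @export
filter_spots <- function(spots, mask) {
  m <- if (inherits(mask, "cell_mask3d")) mask$mask else mask
  if (nrow(spots) == 0) return(spots)
  d <- dim(m)
  idx <- cbind(pmin(pmax(round(spots$z), 1), d[1]),
               pmin(pmax(round(spots$y), 1), d[2]),
               pmin(pmax(round(spots$x), 1), d[3]))
  out <- spots[m[idx], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spot density of a cellular compartment
#'
#' Number of spots inside a compartment divided by the compartment's area
#' (2D, pixels) or volume (3D, voxels). Compartment outlines (e.g. the
#' lamella boundary) are user-supplied.
#'
#' @param n_spots spot count inside the compartment.
#' @param area compartment area/volume, > 0.
#' @param compartment_name label carried through to the result.
#' @return A list of class `density_result`.
#' @export
compartment_density <- function(n_spots, area, compartment_name = "") {
  stopifnot(n_spots >= 0)
  if (!is.numeric(area) || area <= 0) stop("compartment area must be > 0")
  structure(list(compartment_name = compartment_name,
                 n_spots = n_spots, area = area,
                 density = n_spots / area),
            class = "density_result")
}

#' Full 3D spot pipeline on a two-channel acquisition
#'
#' Isotropizes both channels, percentile-normalizes the spot channel,
#' detects spots, derives the cell mask from the actin channel and filters
#' detections to the cell volume.
#'
#' @param spot_channel,actin_channel [bamp_volume()] objects sharing a grid.
#' @param params a [spot_params()].
#' @return A list with `spots` (in-mask detections), `spots_all` (before
#'   mask gating), `mask` (a `cell_mask3d`) and the isotropized normalized
#'   volume.
#' @export
spot_pipeline <- function(spot_channel, actin_channel,
                          params = spot_params()) {
  spot_iso <- isotropize(spot_channel)
  actin_iso <- isotropize(actin_channel)
  normalized <- percentile_normalize(spot_iso, params)
  spots_all <- detect_spots_dog(normalized, params)
  mask <- cell_mask_from_actin(actin_iso)
  list(spots = filter_spots(spots_all, mask), spots_all = spots_all,
       mask = mask, normalized = normalized)
}
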
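# Simplified 3D cell segmentation: gamma correction, median filtering,
# isotropization, percentile normalization and downsampling, followed by
# per-slice Otsu thresholding in the three orthoviews and a majority-vote
# consensus. The published consensus machinery (gradient-flow label
# aggregation, label diffusion, guided filtering) is deliberately replaced
# by the vote + nearest-neighbour upsampling, which keeps the module
# self-contained; see the methods vignette.

#' Parameters of the 3D segmentation pipeline
#'
#' @param gamma gamma-correction exponent applied to min-max rescaled
#'   intensities.
#' @param median_size cubic median-filter neighbourhood edge length in
#'   voxels (odd).
#' @param downsample_factor isotropic downsampling factor in `(0, 1]`.
#' @param min_norm_intensity normalized-intensity floor intersected with the
#'   per-slice Otsu masks.
#' @param consensus_votes how many of the three orthoviews must mark a voxel.
#' @param p_low,p_high percentiles of the normalization step.
#' @return A list of class `seg3d_params`.
#' @export
seg3d_params <- function(gamma = 0.8, median_size = 3,
                         downsample_factor = 1 / 4,
                         min_norm_intensity = 0.2, consensus_votes = 2,
                         p_low = 2, p_high = 99.8) {
  stopifnot(gamma > 0, median_size >= 1, median_size %% 2 == 1,
            downsample_factor > 0, downsample_factor <= 1,
            min_norm_intensity >= 0, min_norm_intensity <= 1,
            consensus_votes %in% 1:3)
  structure(list(gamma = gamma, median_size = as.integer(median_size),
                 downsample_factor = downsample_factor,
                 min_norm_intensity = min_norm_intensity,
                 consensus_votes = as.integer(consensus_votes),
                 p_low = p_low, p_high = p_high),
            class = "seg3d_params")
}

#' Preprocess a volume for segmentation
#'
#' In order: gamma correction (on intensities min-max rescaled to `[0, 1]`,
#' so the exponent is well defined for arbitrary intensity ranges), cubic
#' median filtering, isotropization, percentile normalization to `[0, 1]`,
#' and isotropic downsampling. The order is pinned by a regression test.
#'
#' @param v a [bamp_volume()].
#' @param params a [seg3d_params()].
#' @return A [bamp_volume()] on the downsampled isotropic grid, in `[0, 1]`.
#' @export
preprocess_volume <- function(v, params = seg3d_params()) {
  stopifnot(inherits(v, "bamp_volume"))
  a <- v$data
  rng <- range(a)
  if (diff(rng) <= 0) stop("constant volume cannot be normalized")
  a <- ((a - rng[1]) / (rng[2] - rng[1]))^params$gamma
  a <- cpp_median_filter3(a, (params$median_size - 1L) %/% 2L)
  iso <- isotropize(bamp_volume(a, v$voxel_spacing))
  norm <- percentile_normalize(iso, spot_params(p_low = params$p_low,
                                                p_high = params$p_high))
  new_dim <- pmax(1L, as.integer(round(dim(norm$data) *
                                         params$downsample_factor)))
  out <- resample_volume_linear(norm$data, new_dim)
  bamp_volume(pmin(pmax(out, 0), 1),
              norm$voxel_spacing / params$downsample_factor)
}

#' Per-slice Otsu segmentation in the three orthoviews
#'
#' Each 2D slice of the x-y, x-z and y-z orthoviews is thresholded by Otsu
#' and intersected with the `min_norm_intensity` floor. A slice with no
#' intensity contrast is segmented by the floor alone.
#'
#' @param v a [bamp_volume()] or array normalized to `[0, 1]`.
#' @param params a [seg3d_params()].
#' @return A list of three logical volumes (`xy`, `xz`, `yz`), all on the
#'   input grid.
#' @export
orthoview_otsu <- function(v, params = seg3d_params()) {
  a <- as_volume_array(v)
  d <- dim(a)
  slice_mask <- function(sl) {
    if (diff(range(sl)) <= 1e-12) return(sl >= params$min_norm_intensity)
    (sl > otsu_threshold(sl)) & (sl >= params$min_norm_intensity)
  }
  xy <- array(FALSE, d); xz <- array(FALSE, d); yz <- array(FALSE, d)
  for (z in seq_len(d[1])) xy[z, , ] <- slice_mask(a[z, , ])
  for (y in seq_len(d[2])) xz[, y, ] <- slice_mask(a[, y, ])
  for (x in seq_len(d[3])) yz[, , x] <- slice_mask(a[, , x])
  list(xy = xy, xz = xz, yz = yz)
}

#' Majority-vote consensus of the orthoview segmentations
#'
#' A voxel is kept if at least `consensus_votes` of the three views mark it;
#' the largest connected component of the vote mask is retained.
#'
#' @param views list of three logical volumes from [orthoview_otsu()].
#' @param params a [seg3d_params()].
#' @return A list of class `cell_mask3d`.
#' @export
consensus_combine <- function(views, params = seg3d_params()) {
  stopifnot(length(views) == 3,
            all(dim(views[[1]]) == dim(views[[2]])),
            all(dim(views[[1]]) == dim(views[[3]])))
  votes <- views[[1]] + views[[2]] + views[[3]]
  mask <- array(votes >= params$consensus_votes, dim = dim(views[[1]]))
  if (!any(mask)) stop("empty consensus segmentation")
  lab <- cpp_label3(mask, 26L)
  sizes <- tabulate(lab[lab > 0])
  structure(list(mask = array(lab == which.max(sizes), dim = dim(mask))),
            class = "cell_mask3d")
}

#' Full simplified 3D cell segmentation
#'
#' Preprocessing, orthoview Otsu, consensus, and nearest-neighbour
#' upsampling of the mask back to the input grid.
#'
#' @param v a [bamp_volume()].
#' @param params a [seg3d_params()].
#' @return A list with `mask` (a `cell_mask3d` on the original grid) and
#'   `mask_downsampled` (on the processing grid).
#' @export
segment_cell_3d <- function(v, params = seg3d_params()) {
  pre <- preprocess_volume(v, params)
  views <- orthoview_otsu(pre, params)
  consensus <- consensus_combine(views, params)
  up <- resample_mask_nn(consensus$mask, dim(v$data))
  list(mask = structure(list(mask = up), class = "cell_mask3d"),
       mask_downsampled = consensus)
}
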
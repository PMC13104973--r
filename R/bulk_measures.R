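# Scalar image readouts: EdU proliferation pixel ratio, integrated density
# on sum projections, and western-blot relative densitometry.

#' EdU/DAPI proliferation rate
#'
#' The ratio of EdU-positive pixels over DAPI-positive pixels, expressed as
#' a percentage. Thresholds must be held fixed across samples being
#' compared; [suggest_channel_threshold()] proposes one.
#'
#' @param edu,dapi 2D image matrices of equal shape (AU).
#' @param threshold_edu,threshold_dapi positive-pixel thresholds (AU), > 0.
#' @return Proliferation rate in percent.
#' @export
proliferation_rate <- function(edu, dapi, threshold_edu, threshold_dapi) {
  stopifnot(is.matrix(edu), is.matrix(dapi), all(dim(edu) == dim(dapi)),
            threshold_edu > 0, threshold_dapi > 0)
  n_dapi <- sum(dapi >= threshold_dapi)
  if (n_dapi == 0) stop("no DAPI-positive pixels at this threshold")
  100 * sum(edu >= threshold_edu) / n_dapi
}

#' Otsu-based threshold suggestion for a channel
#'
#' @param img 2D image matrix.
#' @return A threshold on the image's intensity scale.
#' @export
suggest_channel_threshold <- function(img) {
  otsu_threshold(img)
}

#' Integrated density inside a region of interest on a sum projection
#'
#' Sums the stack over its first axis (z or t) and then sums the projected
#' values inside the ROI: the total fluorescence of the outlined cell.
#'
#' @param stack a [bamp_volume()], [bamp_movie()] or 3D array (slices along
#'   the first axis); a 2D matrix is treated as a single slice.
#' @param roi_mask logical matrix matching the slice shape, nonempty.
#' @return Integrated density (AU * px).
#' @export
integrated_density <- function(stack, roi_mask) {
  a <- if (inherits(stack, "bamp_volume")) stack$data
       else if (inherits(stack, "bamp_movie")) stack$data
       else stack
  if (is.matrix(a)) a <- array(a, dim = c(1, dim(a)))
  stopifnot(length(dim(a)) == 3L, is.logical(roi_mask),
            all(dim(a)[2:3] == dim(roi_mask)))
  if (!any(roi_mask)) stop("empty ROI")
  proj <- apply(a, c(2, 3), sum)
  sum(proj[roi_mask])
}

#' Relative band density of a western-blot lane
#'
#' Normalizes a band density to the solvent-control band and to the loading
#' control: `(band / control_band) / (loading / control_loading)`.
#'
#' @param sample,solvent_control lists or one-row data frames with
#'   `band_density` and `loading_density` entries (all > 0).
#' @return Dimensionless relative density.
#' @export
relative_density <- function(sample, solvent_control) {
  vals <- c(sample$band_density, sample$loading_density,
            solvent_control$band_density, solvent_control$loading_density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all band and loading densities must be positive")
  (sample$band_density / solvent_control$band_density) /
    (sample$loading_density / solvent_control$loading_density)
}

#' Band density from a lane intensity profile
#'
#' Integrates a 1D lane profile over a band window after subtracting the
#' straight-line baseline through the window endpoints (the ImageJ "Gels"
#' convention); a negative integral is clipped to zero.
#'
#' @param profile numeric vector of lane intensities.
#' @param band_window integer `(start, end)` indices into the profile,
#'   `start < end`.
#' @return Band density (AU * px).
#' @export
lane_profile_density <- function(profile, band_window) {
  stopifnot(is.numeric(profile), length(band_window) == 2)
  s <- as.integer(band_window[1]); e <- as.integer(band_window[2])
  if (s < 1 || e > length(profile) || e <= s)
    stop("degenerate band window")
  idx <- s:e
  baseline <- profile[s] + (profile[e] - profile[s]) * (idx - s) / (e - s)
  resid <- profile[idx] - baseline
  # trapezoidal integral over unit-spaced samples
  max(0, sum((resid[-1] + resid[-length(resid)]) / 2))
}

#' Relative densitometry for a lane table
#'
#' Applies [relative_density()] to every lane of a measurement table against
#' a named solvent-control lane.
#'
#' @param lanes data frame with columns `condition_label`, `band_density`,
#'   `loading_density`.
#' @param control_label `condition_label` of the solvent control.
#' @return The input with a `relative_density` column appended.
#' @export
densitometry_table <- function(lanes, control_label) {
  stopifnot(all(c("condition_label", "band_density", "loading_density") %in%
                  names(lanes)))
  ctrl <- lanes[lanes$condition_label == control_label, , drop = FALSE]
  if (nrow(ctrl) != 1)
    stop("exactly one lane must match the control label")
  lanes$relative_density <- vapply(seq_len(nrow(lanes)), function(i)
    relative_density(lanes[i, ], ctrl), numeric(1))
  lanes
}
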
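# Lightweight S3 containers shared by all pipelines. Axis conventions are
# fixed package-wide: movies are T x Y x X, volumes are Z x Y x X, masks are
# logical arrays of the same shape, voxel/pixel coordinates are 1-based in R.

#' Time-lapse fluorescence movie
#'
#' A single-channel movie stored as a `T x Y x X` array of nonnegative
#' intensities (arbitrary units) together with its frame interval.
#'
#' @param data numeric 3D array, frames along the first dimension.
#' @param frame_interval time between frames in seconds.
#' @param pixel_size optional pixel size in micrometres (metadata only).
#' @return An object of class `bamp_movie`.
#' @export
bamp_movie <- function(data, frame_interval = 2, pixel_size = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a T x Y x X array")
  if (dim(data)[1] < 1L) stop("movie must contain at least one frame")
  if (!all(is.finite(data))) stop("movie intensities must be finite")
  if (min(data) < 0) stop("movie intensities must be nonnegative")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("`frame_interval` must be a positive number of seconds")
  structure(
    list(data = data, frame_interval = frame_interval, pixel_size = pixel_size),
    class = "bamp_movie"
  )
}

#' @export
print.bamp_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bamp_movie> %d frames of %d x %d px, dt = %gs\n",
              d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' Fluorescence volume
#'
#' A 3D image stored as a `Z x Y x X` array with voxel spacing in micrometres
#' `(z, y, x)`.
#'
#' @param data numeric 3D array.
#' @param voxel_spacing numeric length-3 vector of positive spacings (um).
#' @return An object of class `bamp_volume`.
#' @export
bamp_volume <- function(data, voxel_spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a Z x Y x X array")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be three positive numbers (z, y, x)")
  structure(list(data = data, voxel_spacing = voxel_spacing),
            class = "bamp_volume")
}

#' @export
print.bamp_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bamp_volume> %d x %d x %d voxels, spacing (%g, %g, %g) um\n",
              d[1], d[2], d[3],
              x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  invisible(x)
}

#' Per-frame mask stack
#'
#' Logical masks aligned to a movie, labelled by their role in the analysis.
#'
#' @param masks logical `T x Y x X` array.
#' @param role one of `"cell"`, `"ruffle"`, `"protrusive"`, `"non_protrusive"`.
#' @return An object of class `bamp_mask_stack`.
#' @export
mask_stack <- function(masks, role = c("cell", "ruffle", "protrusive",
                                       "non_protrusive")) {
  role <- match.arg(role)
  if (!is.array(masks) || length(dim(masks)) != 3L || !is.logical(masks))
    stop("`masks` must be a logical T x Y x X array")
  structure(list(masks = masks, role = role), class = "bamp_mask_stack")
}

#' @export
print.bamp_mask_stack <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<bamp_mask_stack role=%s> %d frames of %d x %d px (%d fg px)\n",
              x$role, d[1], d[2], d[3], sum(x$masks)))
  invisible(x)
}

as_movie_array <- function(x) {
  if (inherits(x, "bamp_movie")) x$data else x
}

as_volume_array <- function(x) {
  if (inherits(x, "bamp_volume")) x$data else x
}
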
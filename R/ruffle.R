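# Ruffling-rate quantification. Ruffles move fast relative to stress fibers,
# so a pixelwise rolling temporal median isolates the static (low-frequency)
# actin signal; the raw/median ratio on a percentage scale highlights
# transient structures, which are then segmented with a multi-scale locally
# adaptive threshold and scored as a percentage of the cell area.

#' Parameters of the ruffling-rate pipeline
#'
#' @param half_window_frames half width of the rolling median window in
#'   frames; the default 25 corresponds to +/-50 s at a 2 s frame interval.
#' @param ratio_floor baseline intensities below this value are treated as
#'   background and excluded from the ratio. `NULL` (default) sets it at run
#'   time to 10% of the movie's median foreground intensity (foreground by
#'   global Otsu).
#' @param scale_sigmas increasing Gaussian scales (pixels) of the multi-scale
#'   segmentation.
#' @param min_ratio minimum percent-ratio a pixel must reach to qualify as a
#'   ruffle candidate (percent scale; 100 = no temporal change).
#' @param tile_px tile size of the locally adaptive (per-tile Otsu) threshold.
#' @param min_object_px connected components smaller than this are discarded.
#' @param restrict_to_cell intersect ruffle masks with the cell mask before
#'   scoring.
#' @return A list of class `ruffle_params`.
#' @export
ruffle_params <- function(half_window_frames = 25, ratio_floor = NULL,
                          scale_sigmas = c(1, 2, 4), min_ratio = 120,
                          tile_px = 32, min_object_px = 8,
                          restrict_to_cell = TRUE) {
  stopifnot(half_window_frames >= 1, all(diff(scale_sigmas) > 0),
            min_object_px >= 0, tile_px >= 4, min_ratio >= 0)
  structure(list(half_window_frames = as.integer(half_window_frames),
                 ratio_floor = ratio_floor, scale_sigmas = scale_sigmas,
                 min_ratio = min_ratio, tile_px = as.integer(tile_px),
                 min_object_px = as.integer(min_object_px),
                 restrict_to_cell = isTRUE(restrict_to_cell)),
            class = "ruffle_params")
}

#' Rolling temporal-median baseline
#'
#' Per pixel and frame, the median intensity over the window
#' `[t - h, t + h]` intersected with the movie, i.e. the window truncates at
#' the movie ends rather than reflecting, so the baseline stays an order
#' statistic of observed data.
#'
#' @param movie a [bamp_movie()] (or T x Y x X array).
#' @param params a [ruffle_params()]; only `half_window_frames` is used.
#' @return A [bamp_movie()] of identical shape holding the baseline.
#' @export
temporal_baseline <- function(movie, params = ruffle_params()) {
  a <- as_movie_array(movie)
  if (is.null(dim(a)) || length(dim(a)) != 3L) stop("movie must be T x Y x X")
  if (dim(a)[1] < 1L) stop("movie has no frames")
  out <- cpp_rolling_median_t(a, params$half_window_frames)
  if (inherits(movie, "bamp_movie"))
    bamp_movie(out, movie$frame_interval, movie$pixel_size)
  else out
}

#' Percent-ratio normalization against the temporal baseline
#'
#' The raw movie divided by its low-frequency baseline, on a percentage
#' scale (100 = unchanged). Pixels whose baseline falls below `ratio_floor`
#' are flagged as background and carry value 0; this guards the division
#' against near-zero background baselines.
#'
#' @param movie,baseline matching [bamp_movie()] objects or arrays.
#' @param params a [ruffle_params()].
#' @return A list of class `ratio_movie` with `data` (percent scale),
#'   `background_flag` and the `ratio_floor` used.
#' @export
ratio_normalize <- function(movie, baseline, params = ruffle_params()) {
  raw <- as_movie_array(movie)
  base <- as_movie_array(baseline)
  if (!all(dim(raw) == dim(base)))
    stop("movie and baseline must have identical shape")
  floor_val <- params$ratio_floor
  if (is.null(floor_val)) {
    thr <- otsu_threshold(raw)
    fg <- raw[raw > thr]
    floor_val <- if (length(fg) > 0) 0.1 * median(fg) else 0.1 * median(raw)
  }
  flag <- base < floor_val
  ratio <- array(0, dim = dim(raw))
  ratio[!flag] <- 100 * raw[!flag] / base[!flag]
  structure(list(data = ratio, background_flag = flag,
                 ratio_floor = floor_val),
            class = "ratio_movie")
}

# Per-tile Otsu threshold map: each tile gets its own Otsu threshold; tiles
# without appreciable contrast get +Inf (nothing passes locally and the
# global `min_ratio` floor governs instead).
local_tile_thresholds <- function(img, tile_px, min_contrast = 1e-8) {
  d <- dim(img)
  thr <- matrix(Inf, d[1], d[2])
  rs <- unique(c(seq(1, d[1], by = tile_px), d[1] + 1L))
  cs <- unique(c(seq(1, d[2], by = tile_px), d[2] + 1L))
  for (i in seq_len(length(rs) - 1L)) {
    for (j in seq_len(length(cs) - 1L)) {
      ri <- rs[i]:(rs[i + 1L] - 1L)
      ci <- cs[j]:(cs[j + 1L] - 1L)
      vals <- img[ri, ci]
      if (diff(range(vals)) <= min_contrast) next
      thr[ri, ci] <- otsu_threshold(vals)
    }
  }
  thr
}

#' Multi-scale locally adaptive ruffle segmentation
#'
#' At each Gaussian scale the percent-ratio frame is smoothed and thresholded
#' by a per-tile Otsu threshold; a pixel is a ruffle candidate at a scale if
#' the smoothed ratio exceeds both the local threshold and the global
#' `min_ratio` floor. Candidates are united across scales and the union is
#' then restricted to pixels whose own (unsmoothed) ratio also exceeds the
#' floor, which trims the blur halo the coarser scales would otherwise add.
#' Background-flagged pixels are removed and components below
#' `min_object_px` discarded.
#'
#' @param ratio a `ratio_movie` from [ratio_normalize()].
#' @param params a [ruffle_params()].
#' @return A [mask_stack()] with role `"ruffle"`.
#' @export
segment_ruffles <- function(ratio, params = ruffle_params()) {
  stopifnot(inherits(ratio, "ratio_movie"))
  d <- dim(ratio$data)
  masks <- array(FALSE, dim = d)
  for (t in seq_len(d[1])) {
    frame <- ratio$data[t, , ]
    m <- matrix(FALSE, d[2], d[3])
    for (s in params$scale_sigmas) {
      sm <- gauss_smooth(frame, s)
      thr <- local_tile_thresholds(sm, params$tile_px)
      m <- m | (sm >= pmax(thr, params$min_ratio))
    }
    m <- m & frame >= params$min_ratio
    m <- m & !ratio$background_flag[t, , ]
    masks[t, , ] <- filter_small_2d(m, params$min_object_px)
  }
  mask_stack(masks, "ruffle")
}

#' Per-frame cell segmentation in the raw actin movie
#'
#' Each frame is temporally smoothed with its neighbours, spatially smoothed,
#' and thresholded by global Otsu; frames whose foreground/background
#' contrast is too low (no cell at the chosen threshold) yield an empty mask
#' with a warning. Masks are hole-filled and size-filtered.
#'
#' @param movie a [bamp_movie()] or array.
#' @param params a [ruffle_params()].
#' @param min_contrast minimum foreground/background mean intensity ratio for
#'   a frame to be considered to contain a cell.
#' @return A [mask_stack()] with role `"cell"`.
#' @export
segment_cells <- function(movie, params = ruffle_params(), min_contrast = 2) {
  a <- as_movie_array(movie)
  d <- dim(a)
  masks <- array(FALSE, dim = d)
  empty_frames <- integer(0)
  for (t in seq_len(d[1])) {
    idx <- max(1, t - 1):min(d[1], t + 1)
    frame <- apply(a[idx, , , drop = FALSE], c(2, 3), mean)
    frame <- gauss_smooth(frame, 1)
    thr <- otsu_threshold(frame)
    m <- frame > thr
    fg <- mean(frame[m])
    bg <- mean(frame[!m])
    if (!any(m) || all(m) || !is.finite(fg) || !is.finite(bg) ||
        bg <= 0 || fg / bg < min_contrast) {
      empty_frames <- c(empty_frames, t)
      next
    }
    m <- fill_holes_2d(m)
    masks[t, , ] <- filter_small_2d(m, params$min_object_px)
  }
  if (length(empty_frames) > 0)
    warning("no cell foreground found in frame(s) ",
            paste(empty_frames, collapse = ", "))
  mask_stack(masks, "cell")
}

#' Ruffling rate of a movie
#'
#' Relates the ruffle area to the cell area per frame
#' (`100 * |ruffle ∩ cell| / |cell|`) and averages the per-frame percentage
#' over time. Frames with an empty cell mask are excluded from the mean and
#' reported.
#'
#' @param ruffles a [mask_stack()] with role `"ruffle"`.
#' @param cells a [mask_stack()] with role `"cell"`.
#' @param params a [ruffle_params()].
#' @return A list of class `ruffle_rate_result` with `per_frame_percent`
#'   (NA for excluded frames), `mean_rate_percent`, `excluded_frames` and
#'   `params_used`.
#' @export
ruffling_rate <- function(ruffles, cells, params = ruffle_params()) {
  stopifnot(inherits(ruffles, "bamp_mask_stack"),
            inherits(cells, "bamp_mask_stack"),
            all(dim(ruffles$masks) == dim(cells$masks)))
  T <- dim(ruffles$masks)[1]
  per_frame <- rep(NA_real_, T)
  for (t in seq_len(T)) {
    cell_t <- cells$masks[t, , ]
    n_cell <- sum(cell_t)
    if (n_cell == 0) next
    r <- ruffles$masks[t, , ]
    if (params$restrict_to_cell) r <- r & cell_t
    per_frame[t] <- 100 * sum(r) / n_cell
  }
  excluded <- which(is.na(per_frame))
  if (length(excluded) == T)
    stop("all frames have empty cell masks; cannot compute a ruffling rate")
  structure(list(per_frame_percent = per_frame,
                 mean_rate_percent = mean(per_frame, na.rm = TRUE),
                 excluded_frames = excluded,
                 params_used = params),
            class = "ruffle_rate_result")
}

#' @export
print.ruffle_rate_result <- function(x, ...) {
  cat(sprintf("<ruffle_rate_result> mean rate %.2f%% over %d scored frames\n",
              x$mean_rate_percent,
              sum(!is.na(x$per_frame_percent))))
  invisible(x)
}

#' Full ruffling-rate pipeline on one movie
#'
#' Baseline, ratio, ruffle and cell segmentation, and scoring in one call.
#'
#' @inheritParams temporal_baseline
#' @return A `ruffle_rate_result` with the intermediate masks attached as
#'   attributes `ruffle_masks` and `cell_masks`.
#' @export
ruffle_rate_pipeline <- function(movie, params = ruffle_params()) {
  baseline <- temporal_baseline(movie, params)
  ratio <- ratio_normalize(movie, baseline, params)
  ruffles <- segment_ruffles(ratio, params)
  cells <- segment_cells(movie, params)
  res <- ruffling_rate(ruffles, cells, params)
  attr(res, "ruffle_masks") <- ruffles
  attr(res, "cell_masks") <- cells
  res
}
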
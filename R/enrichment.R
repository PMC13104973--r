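# Subcellular enrichment of a membrane-bound reporter in protrusions.
# The reporter channel is normalized by a uniform membrane marker to cancel
# membrane-fold geometry, the cell footprint is segmented at a user-tuned
# threshold at T0 and T1, and the mean normalized intensity is compared
# between pixels gained between T0 and T1 (protrusive) and pixels present at
# both (non-protrusive).

#' Parameters of the enrichment computation
#'
#' The three user-defined quantities of the procedure: the segmentation
#' threshold (manually tuned to separate individual cells), the first
#' activation frame T0 and the user-assessed maximal-protrusion frame T1.
#'
#' @param seg_threshold intensity threshold (AU) applied to the segmentation
#'   channel; required, > 0.
#' @param t0_frame,t1_frame 1-based frame indices, `t0_frame < t1_frame`.
#' @param membrane_floor pixels whose membrane signal falls below this are
#'   excluded from the normalized movie.
#' @param min_object_px size filter applied to segmentation masks.
#' @param stat_frames which frames the class means are taken over: `"t1"`
#'   (default; T1 is where the protrusive class is defined) or `"t0_to_t1"`
#'   (average over the activation window).
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(seg_threshold, t0_frame, t1_frame,
                              membrane_floor = 0, min_object_px = 8,
                              stat_frames = c("t1", "t0_to_t1")) {
  stopifnot(seg_threshold > 0, t0_frame >= 1, t1_frame > t0_frame,
            membrane_floor >= 0)
  stat_frames <- match.arg(stat_frames)
  structure(list(seg_threshold = seg_threshold,
                 t0_frame = as.integer(t0_frame),
                 t1_frame = as.integer(t1_frame),
                 membrane_floor = membrane_floor,
                 min_object_px = as.integer(min_object_px),
                 stat_frames = stat_frames),
            class = "enrichment_params")
}

#' Normalize a reporter movie by the membrane marker channel
#'
#' Frame-by-frame division of the reporter by the membrane channel. Pixels
#' with membrane signal below `membrane_floor` are excluded (value 0,
#' flagged).
#'
#' @param reporter,membrane matching [bamp_movie()] objects or arrays.
#' @param params an [enrichment_params()].
#' @return A list of class `normalized_movie` with `data` and
#'   `excluded_flag`.
#' @export
normalize_by_membrane <- function(reporter, membrane, params) {
  rep_a <- as_movie_array(reporter)
  mem_a <- as_movie_array(membrane)
  if (!all(dim(rep_a) == dim(mem_a)))
    stop("reporter and membrane movies must have identical shape")
  flag <- mem_a < params$membrane_floor | mem_a <= 0
  out <- array(0, dim = dim(rep_a))
  out[!flag] <- rep_a[!flag] / mem_a[!flag]
  structure(list(data = out, excluded_flag = flag),
            class = "normalized_movie")
}

#' Threshold segmentation of a single frame
#'
#' Foreground = pixels at or above the tuned threshold, hole-filled and
#' size-filtered. An empty result is returned as an empty mask with a
#' warning.
#'
#' @param frame 2D numeric matrix.
#' @param params an [enrichment_params()].
#' @return Logical matrix.
#' @export
segment_cell_frame <- function(frame, params) {
  stopifnot(is.matrix(frame))
  m <- frame >= params$seg_threshold
  if (!any(m)) {
    warning("no pixel reaches the segmentation threshold; empty mask")
    return(m)
  }
  if (all(m)) return(m)
  m <- fill_holes_2d(m)
  filter_small_2d(m, params$min_object_px)
}

#' Protrusive / non-protrusive pixel partition
#'
#' Protrusive pixels belong to the cell at T1 but not at T0; pixels present
#' at both are non-protrusive. Pixels present only at T0 (retraction) belong
#' to neither class.
#'
#' @param mask_t0,mask_t1 logical matrices of equal shape.
#' @return A list of class `protrusion_partition` with `mask_t0`, `mask_t1`,
#'   `protrusive`, `non_protrusive`.
#' @export
partition_protrusions <- function(mask_t0, mask_t1) {
  stopifnot(is.logical(mask_t0), is.logical(mask_t1),
            all(dim(mask_t0) == dim(mask_t1)))
  part <- structure(list(mask_t0 = mask_t0, mask_t1 = mask_t1,
                         protrusive = mask_t1 & !mask_t0,
                         non_protrusive = mask_t0 & mask_t1),
                    class = "protrusion_partition")
  stopifnot(!any(part$protrusive & part$non_protrusive),
            !any(part$protrusive & !mask_t1),
            !any(part$non_protrusive & !mask_t1))
  part
}

#' Mean normalized intensity inside and outside protrusions
#'
#' Means are taken over non-excluded pixels of the normalized movie at the
#' frame(s) selected by `params$stat_frames`, restricted to each partition
#' class.
#'
#' @param normalized a `normalized_movie` from [normalize_by_membrane()].
#' @param partition a `protrusion_partition`.
#' @param params an [enrichment_params()].
#' @return A list of class `enrichment_result` with `mean_protrusive`,
#'   `mean_non_protrusive`, `enrichment_ratio` and usable pixel counts.
#' @export
enrichment_stats <- function(normalized, partition, params) {
  stopifnot(inherits(normalized, "normalized_movie"),
            inherits(partition, "protrusion_partition"))
  frames <- if (params$stat_frames == "t1") params$t1_frame
            else params$t0_frame:params$t1_frame
  class_mean <- function(class_mask) {
    vals <- numeric(0)
    for (t in frames) {
      ok <- class_mask & !normalized$excluded_flag[t, , ]
      vals <- c(vals, normalized$data[t, , ][ok])
    }
    list(mean = if (length(vals) > 0) mean(vals) else NA_real_,
         n = length(vals))
  }
  pro <- class_mean(partition$protrusive)
  non <- class_mean(partition$non_protrusive)
  if (pro$n == 0)
    warning("no usable protrusive pixels; protrusive mean undefined")
  if (non$n == 0)
    warning("no usable non-protrusive pixels; non-protrusive mean undefined")
  ratio <- if (!is.na(pro$mean) && !is.na(non$mean) &&
               pro$mean > 0 && non$mean > 0) pro$mean / non$mean
           else NA_real_
  structure(list(mean_protrusive = pro$mean,
                 mean_non_protrusive = non$mean,
                 enrichment_ratio = ratio,
                 n_px_protrusive = pro$n,
                 n_px_non_protrusive = non$n,
                 params_used = params),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(paste0("<enrichment_result> protrusive %.3f (n=%d), ",
                     "non-protrusive %.3f (n=%d), ratio %.3f\n"),
              x$mean_protrusive, x$n_px_protrusive,
              x$mean_non_protrusive, x$n_px_non_protrusive,
              x$enrichment_ratio))
  invisible(x)
}

#' Suggest the maximal-protrusion frame T1
#'
#' Convenience helper: suggests T1 as the frame whose segmented footprint
#' gains the most area over the T0 mask. T1 remains a user decision in the
#' procedure; this merely proposes a candidate.
#'
#' @param membrane a [bamp_movie()] or array (segmentation channel).
#' @param params an [enrichment_params()]; its `t1_frame` is ignored.
#' @return Integer frame index.
#' @export
suggest_t1 <- function(membrane, params) {
  a <- as_movie_array(membrane)
  mask_t0 <- segment_cell_frame(a[params$t0_frame, , ], params)
  gains <- vapply(seq_len(dim(a)[1]), function(t) {
    if (t <= params$t0_frame) return(-Inf)
    sum(segment_cell_frame(a[t, , ], params) & !mask_t0)
  }, numeric(1))
  which.max(gains)
}

#' Full enrichment pipeline on a two-channel acquisition
#'
#' Normalizes the reporter by the membrane marker, segments the cell at T0
#' and T1 on the membrane channel (the channel that defines cell extent;
#' `seg_channel = "normalized"` switches to the normalized movie), partitions
#' the footprint and computes the class means.
#'
#' @param reporter,membrane matching movies.
#' @param params an [enrichment_params()].
#' @param seg_channel `"membrane"` (default) or `"normalized"`.
#' @return An `enrichment_result` with the partition attached as attribute
#'   `partition`.
#' @export
enrichment_pipeline <- function(reporter, membrane, params,
                                seg_channel = c("membrane", "normalized")) {
  seg_channel <- match.arg(seg_channel)
  normalized <- normalize_by_membrane(reporter, membrane, params)
  seg_src <- if (seg_channel == "membrane") as_movie_array(membrane)
             else normalized$data
  part <- partition_protrusions(
    segment_cell_frame(seg_src[params$t0_frame, , ], params),
    segment_cell_frame(seg_src[params$t1_frame, , ], params))
  res <- enrichment_stats(normalized, part, params)
  attr(res, "partition") <- part
  res
}
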
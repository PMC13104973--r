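# Readers/writers and the stage-runner surface. Conventions: movies are
# multi-page grayscale TIFFs (one page per frame, T x Y x X in memory),
# volumes one page per z-slice; intensities are stored as 16-bit counts
# (1 AU = 1 count, clamped to [0, 65535]) and promoted to floating point
# unchanged on read; per-file JSON sidecars (<file>.json) carry frame
# interval / voxel spacing; configs are YAML; tables are CSV; run manifests
# are JSON.

MAX_TIFF_COUNT <- 65535

read_tiff_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("TIFF file ", path, " contains no pages")
  for (p in pages)
    if (length(dim(p)) > 2)
      stop("RGB/multi-channel TIFF not supported; provide one grayscale ",
           "file per channel: ", path)
  pages
}

pages_to_array <- function(pages) {
  d <- dim(pages[[1]])
  out <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) {
    if (!all(dim(pages[[i]]) == d)) stop("TIFF pages differ in size")
    out[i, , ] <- as.numeric(pages[[i]])
  }
  out
}

write_tiff_stack <- function(a, path) {
  if (min(a) < 0 || max(a) > MAX_TIFF_COUNT)
    a <- pmin(pmax(a, 0), MAX_TIFF_COUNT)
  pages <- lapply(seq_len(dim(a)[1]),
                  function(i) round(a[i, , ]) / MAX_TIFF_COUNT)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else NULL
}

#' Read a movie from a multi-page grayscale TIFF
#'
#' Integer sample values are promoted to floating point unchanged. The frame
#' interval is taken from the argument if given, else from the JSON sidecar
#' written by [write_movie()].
#'
#' @param path TIFF file path.
#' @param frame_interval seconds between frames; overrides the sidecar.
#' @param pixel_size optional pixel size (um).
#' @return A [bamp_movie()].
#' @export
read_movie <- function(path, frame_interval = NULL, pixel_size = NULL) {
  a <- pages_to_array(read_tiff_pages(path))
  side <- read_sidecar(path)
  if (is.null(frame_interval)) frame_interval <- side$frame_interval
  if (is.null(frame_interval))
    stop("frame interval unknown: pass `frame_interval` or provide the ",
         "JSON sidecar ", sidecar_path(path))
  if (is.null(pixel_size)) pixel_size <- side$pixel_size
  bamp_movie(a, frame_interval, pixel_size)
}

#' Write a movie as a multi-page 16-bit grayscale TIFF
#'
#' Values are rounded to integer counts (clamped to `[0, 65535]`); a JSON
#' sidecar records the frame interval.
#'
#' @param movie a [bamp_movie()].
#' @param path destination TIFF path.
#' @return The path, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "bamp_movie"))
  write_tiff_stack(movie$data, path)
  jsonlite::write_json(list(axes = "TYX",
                            frame_interval = movie$frame_interval,
                            pixel_size = movie$pixel_size),
                       sidecar_path(path), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a volume from a multi-page grayscale TIFF
#'
#' @param path TIFF file path (one page per z-slice).
#' @param voxel_spacing `(z, y, x)` spacing in um; overrides the sidecar.
#'   Required if no sidecar exists.
#' @return A [bamp_volume()].
#' @export
read_volume <- function(path, voxel_spacing = NULL) {
  a <- pages_to_array(read_tiff_pages(path))
  side <- read_sidecar(path)
  if (is.null(voxel_spacing)) voxel_spacing <- unlist(side$voxel_spacing)
  if (is.null(voxel_spacing))
    stop("voxel spacing unknown: pass `voxel_spacing` or provide the ",
         "JSON sidecar ", sidecar_path(path))
  bamp_volume(a, voxel_spacing)
}

#' Write a volume as a multi-page 16-bit grayscale TIFF
#'
#' @param volume a [bamp_volume()].
#' @param path destination TIFF path.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "bamp_volume"))
  write_tiff_stack(volume$data, path)
  jsonlite::write_json(list(axes = "ZYX",
                            voxel_spacing = volume$voxel_spacing),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Write a logical mask (2D or 3D) as a TIFF
#' @param mask logical matrix or array (slices along the first axis).
#' @param path destination path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  a <- if (is.matrix(mask)) array(mask, dim = c(1, dim(mask))) else mask
  write_tiff_stack(a * MAX_TIFF_COUNT, path)
  invisible(path)
}

#' Read a TIFF mask back as a logical array
#' @param path TIFF path written by [write_mask()].
#' @param drop if `TRUE` (default) a single-page mask is returned as a matrix.
#' @return Logical matrix or array.
#' @export
read_mask <- function(path, drop = TRUE) {
  a <- pages_to_array(read_tiff_pages(path)) > MAX_TIFF_COUNT / 2
  if (drop && dim(a)[1] == 1L) a <- a[1, , ]
  a
}

#' Load a YAML configuration
#' @param path YAML file.
#' @return A named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Write stage outputs and a run manifest
#'
#' Writes each table as CSV (columns in the order given), each mask as TIFF,
#' and a JSON manifest recording the resolved configuration, package version
#' and seed, so a rerun with the same config and seed reproduces the files.
#'
#' @param tables named list of data frames.
#' @param masks named list of logical masks (may be empty).
#' @param config resolved parameter list to serialize.
#' @param out_dir output directory (created if needed).
#' @param seed the seed governing the run (recorded in the manifest).
#' @return Invisibly, the manifest path.
#' @export
write_results <- function(tables = list(), masks = list(), config = list(),
                          out_dir, seed = NA_integer_) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
  }
  for (nm in names(masks)) {
    f <- file.path(out_dir, paste0(nm, ".tif"))
    write_mask(masks[[nm]], f)
    files <- c(files, f)
  }
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(package = "bampq",
         version = as.character(packageVersion("bampq")),
         seed = seed, config = config,
         files = basename(files)),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

as_movie_input <- function(x, ...) {
  if (is.character(x)) read_movie(x, ...) else x
}

as_volume_input <- function(x, ...) {
  if (is.character(x)) read_volume(x, ...) else x
}

#' Run the ruffling-rate stage
#'
#' @param movie a [bamp_movie()] or TIFF path.
#' @param params a [ruffle_params()].
#' @param out_dir optional output directory for the per-frame table, the
#'   one-row summary, optional mask TIFFs and the manifest.
#' @param write_masks also write ruffle/cell mask TIFFs.
#' @param seed recorded in the manifest.
#' @return The `ruffle_rate_result`.
#' @export
run_ruffle_rate <- function(movie, params = ruffle_params(), out_dir = NULL,
                            write_masks = FALSE, seed = NA_integer_) {
  movie <- as_movie_input(movie)
  res <- ruffle_rate_pipeline(movie, params)
  if (!is.null(out_dir)) {
    ruffles <- attr(res, "ruffle_masks")$masks
    cells <- attr(res, "cell_masks")$masks
    T <- dim(ruffles)[1]
    per_frame <- data.frame(
      frame = seq_len(T),
      ruffle_px = vapply(seq_len(T), function(t)
        sum(ruffles[t, , ] & cells[t, , ]), numeric(1)),
      cell_px = vapply(seq_len(T), function(t) sum(cells[t, , ]), numeric(1)),
      percent = res$per_frame_percent)
    tables <- list(per_frame = per_frame,
                   summary = data.frame(
                     mean_rate_percent = res$mean_rate_percent,
                     n_frames_scored = sum(!is.na(res$per_frame_percent)),
                     n_frames_excluded = length(res$excluded_frames)))
    masks <- if (write_masks)
      list(ruffle_masks = ruffles, cell_masks = cells) else list()
    write_results(tables, masks, unclass(params), out_dir, seed)
  }
  res
}

#' Run the enrichment stage
#'
#' @param reporter,membrane movies or TIFF paths.
#' @param params an [enrichment_params()].
#' @param out_dir optional output directory.
#' @param seed recorded in the manifest.
#' @return The `enrichment_result`.
#' @export
run_enrichment <- function(reporter, membrane, params, out_dir = NULL,
                           seed = NA_integer_) {
  reporter <- as_movie_input(reporter)
  membrane <- as_movie_input(membrane)
  res <- enrichment_pipeline(reporter, membrane, params)
  if (!is.null(out_dir)) {
    part <- attr(res, "partition")
    tables <- list(enrichment = data.frame(
      mean_protrusive = res$mean_protrusive,
      mean_non_protrusive = res$mean_non_protrusive,
      enrichment_ratio = res$enrichment_ratio,
      n_px_protrusive = res$n_px_protrusive,
      n_px_non_protrusive = res$n_px_non_protrusive))
    masks <- list(protrusive = part$protrusive,
                  non_protrusive = part$non_protrusive)
    write_results(tables, masks, unclass(params), out_dir, seed)
  }
  res
}

#' Run the 3D spot-detection stage
#'
#' @param spot_channel,actin_channel volumes or TIFF paths.
#' @param params a [spot_params()].
#' @param out_dir optional output directory (spots CSV with an `in_mask`
#'   column, mask TIFF, manifest).
#' @param seed recorded in the manifest.
#' @return The [spot_pipeline()] result list.
#' @export
run_spots <- function(spot_channel, actin_channel, params = spot_params(),
                      out_dir = NULL, seed = NA_integer_) {
  spot_channel <- as_volume_input(spot_channel)
  actin_channel <- as_volume_input(actin_channel)
  res <- spot_pipeline(spot_channel, actin_channel, params)
  if (!is.null(out_dir)) {
    all_spots <- res$spots_all
    in_mask <- rep(FALSE, nrow(all_spots))
    if (nrow(all_spots) > 0 && nrow(res$spots) > 0) {
      key <- function(s) paste(round(s$z, 6), round(s$y, 6), round(s$x, 6))
      in_mask <- key(all_spots) %in% key(res$spots)
    }
    spots_tab <- cbind(as.data.frame(all_spots), in_mask = in_mask)
    write_results(list(spots = spots_tab),
                  list(cell_mask = res$mask$mask),
                  unclass(params), out_dir, seed)
  }
  res
}

#' Run the 3D segmentation stage
#'
#' @param volume a [bamp_volume()] or TIFF path.
#' @param params a [seg3d_params()].
#' @param out_dir optional output directory (mask TIFF at the original
#'   resolution plus a QC table with component count and volume).
#' @param seed recorded in the manifest.
#' @return The [segment_cell_3d()] result list.
#' @export
run_segment3d <- function(volume, params = seg3d_params(), out_dir = NULL,
                          seed = NA_integer_) {
  volume <- as_volume_input(volume)
  res <- segment_cell_3d(volume, params)
  if (!is.null(out_dir)) {
    lab <- cpp_label3(res$mask$mask, 26L)
    qc <- data.frame(n_components = max(lab),
                     mask_voxels = sum(res$mask$mask),
                     total_voxels = length(res$mask$mask))
    write_results(list(segmentation_qc = qc),
                  list(cell_mask = res$mask$mask),
                  unclass(params), out_dir, seed)
  }
  res
}

#' Run the EdU proliferation stage
#'
#' @param edu,dapi image matrices (or single-page TIFF paths).
#' @param threshold_edu,threshold_dapi shared thresholds (AU).
#' @param out_dir optional output directory.
#' @param seed recorded in the manifest.
#' @return Proliferation rate in percent.
#' @export
run_edu <- function(edu, dapi, threshold_edu, threshold_dapi,
                    out_dir = NULL, seed = NA_integer_) {
  if (is.character(edu)) edu <- pages_to_array(read_tiff_pages(edu))[1, , ]
  if (is.character(dapi)) dapi <- pages_to_array(read_tiff_pages(dapi))[1, , ]
  rate <- proliferation_rate(edu, dapi, threshold_edu, threshold_dapi)
  if (!is.null(out_dir))
    write_results(list(proliferation = data.frame(
      edu_positive_px = sum(edu >= threshold_edu),
      dapi_positive_px = sum(dapi >= threshold_dapi),
      rate_percent = rate)),
      config = list(threshold_edu = threshold_edu,
                    threshold_dapi = threshold_dapi),
      out_dir = out_dir, seed = seed)
  rate
}

#' Run the densitometry stage
#'
#' @param lanes data frame or CSV path with `condition_label`,
#'   `band_density`, `loading_density` columns.
#' @param control_label solvent-control lane label.
#' @param out_dir optional output directory.
#' @param seed recorded in the manifest.
#' @return The lane table with relative densities.
#' @export
run_densitometry <- function(lanes, control_label, out_dir = NULL,
                             seed = NA_integer_) {
  if (is.character(lanes)) lanes <- read.csv(lanes)
  out <- densitometry_table(lanes, control_label)
  if (!is.null(out_dir))
    write_results(list(relative_density = out),
                  config = list(control_label = control_label),
                  out_dir = out_dir, seed = seed)
  out
}
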
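# Plain-text and TIFF interchange: coordinate CSVs, metric CSVs, ROI and
# sidecar JSON, multipage 16-bit TIFF frame stacks.

#' Read and write cone coordinate CSVs
#'
#' The interchange format is a CSV with header `id,x_um,y_um`.
#'
#' @param coords Coordinates (matrix or data frame, um).
#' @param path File path.
#' @return `read_coords()` returns a data frame `id`, `x_um`, `y_um`.
#' @export
write_coords <- function(coords, path) {
  df <- if (is.data.frame(coords) && all(c("id", "x_um", "y_um") %in% names(coords))) {
    coords[, c("id", "x_um", "y_um")]
  } else {
    xy_df(as_xy(coords))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coords
#' @export
read_coords <- function(path) {
  df <- read.csv(path)
  if (!all(c("id", "x_um", "y_um") %in% names(df))) {
    stop("coordinate CSV must have header id,x_um,y_um", call. = FALSE)
  }
  df[, c("id", "x_um", "y_um")]
}

#' Write and read a frame stack as multipage 16-bit TIFF plus JSON sidecar
#'
#' Intensities are mapped linearly onto the 16-bit range; the mapping and
#' the acquisition metadata (`scale_um_per_px`, `n_frames`, `seed`,
#' rendering config) go to a JSON sidecar so the stack round-trips to
#' within 16-bit quantization.
#'
#' @param stack A `frame_stack`.
#' @param path TIFF path; the sidecar is written next to it as
#'   `<path>.json` unless `sidecar` is given.
#' @param sidecar Optional sidecar JSON path.
#' @return `read_frame_stack()` returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path, sidecar = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  lo <- min(vapply(stack$frames, min, numeric(1)))
  hi <- max(vapply(stack$frames, max, numeric(1)))
  if (hi <= lo) hi <- lo + 1
  norm <- lapply(stack$frames, function(f) (f - lo) / (hi - lo))
  tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  meta <- list(scale_um_per_px = stack$scale_um_per_px,
               n_frames = stack$n_frames, seed = stack$seed,
               intensity_min = lo, intensity_max = hi,
               field_size = stack$field_size,
               config = unclass(stack$config))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(f) {
    meta$intensity_min + f * (meta$intensity_max - meta$intensity_min)
  })
  structure(list(frames = frames, scale_um_per_px = meta$scale_um_per_px,
                 n_frames = length(frames),
                 motion_log = NULL, field_size = meta$field_size,
                 config = meta$config, seed = meta$seed),
            class = "frame_stack")
}

#' Write and read per-ROI metric tables
#'
#' One row per (ROI, grader, modality) with columns `roi_id`, `modality`,
#' `grader`, `bound_density`, `nnd_um`, `icd_um`, `n_bound`, `n_total`.
#' For reporting, density is rounded to whole cones/mm^2 and spacings to
#' 0.01 um (matching the precision the metrics are conventionally quoted
#' at); in-memory values stay at full precision.
#'
#' @param metrics Data frame of metric rows (e.g. from
#'   `as.data.frame()` on [mosaic_metrics()] results, or
#'   [run_study()]`$metrics`).
#' @param path File path.
#' @export
write_metrics_csv <- function(metrics, path) {
  cols <- c("roi_id", "modality", "grader", "bound_density", "nnd_um",
            "icd_um", "n_bound", "n_total")
  if (!all(cols %in% names(metrics))) {
    stop("metrics table is missing required columns", call. = FALSE)
  }
  out <- metrics[, cols]
  out$bound_density <- round(out$bound_density)
  out$nnd_um <- round(out$nnd_um, 2)
  out$icd_um <- round(out$icd_um, 2)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' ROI JSON interchange
#'
#' @param r An [roi()].
#' @param path File path.
#' @export
write_roi_json <- function(r, path) {
  stopifnot(inherits(r, "roi"))
  jsonlite::write_json(list(origin_um = r$origin, size_um = r$size,
                            eccentricity_deg = r$eccentricity_deg,
                            meridian = r$meridian),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi(origin = j$origin_um, size = j$size_um,
      eccentricity_deg = if (is.null(j$eccentricity_deg)) NA_real_ else j$eccentricity_deg,
      meridian = if (is.null(j$meridian)) NA_character_ else j$meridian)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

# study_result -> files: metrics CSV, Bland-Altman point CSV, agreement
# JSON, run manifest JSON
write_study_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_metrics_csv(res$metrics, file.path(outdir, "metrics.csv"))

  pts <- do.call(rbind, lapply(names(res$interdevice), function(nm) {
    p <- res$interdevice[[nm]]$bland_altman$points
    data.frame(metric = nm, mean = p$mean, diff = p$diff)
  }))
  write.csv(pts, file.path(outdir, "bland_altman_points.csv"),
            row.names = FALSE, quote = FALSE)

  drop_points <- function(x) {
    if (is.list(x)) {
      x$points <- NULL
      x <- lapply(x, drop_points)
    }
    x
  }
  agreement <- strip_classes(drop_points(
    list(intergrader = res$intergrader, interdevice = res$interdevice)))
  jsonlite::write_json(agreement, file.path(outdir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  manifest <- strip_classes(list(
    package = "conemosaic",
    version = as.character(utils::packageVersion("conemosaic")),
    seed = res$config$seed,
    n_participants = res$config$n_participants,
    n_analyzable = sum(res$participants$analyzable),
    n_rois = res$n_rois,
    config = res$config))
  manifest$config$graders <- lapply(res$config$graders, unclass)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
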
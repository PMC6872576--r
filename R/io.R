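# 16-bit multi-page TIFF I/O. Photon counts are stored as count / 65535 so
# integer counts below 65535 round-trip exactly.
TIFF_SCALE <- 65535

write_stack_tiff <- function(arr, path) {
  pages <- lapply(seq_len(dim(arr)[3L]), function(k) {
    m <- arr[, , k] / TIFF_SCALE
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * TIFF_SCALE)
  arr
}

#' Write a simulated time-lapse to disk
#'
#' Writes one multi-page 16-bit TIFF per channel
#' (`<prefix>_actin_probe.tif`, `<prefix>_calcium.tif`), a sidecar YAML with
#' frame times, pixel size and stimulus time, and the ground-truth event
#' table as `<prefix>_events.csv` (columns event_time_s, origin_x_um,
#' origin_y_um, direction_deg, lifetime_s).
#'
#' @param stack A `timelapse`.
#' @param prefix Output path prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_timelapse <- function(stack, prefix) {
  stopifnot(inherits(stack, "timelapse"))
  paths <- c(
    actin_probe = paste0(prefix, "_actin_probe.tif"),
    calcium = paste0(prefix, "_calcium.tif"),
    sidecar = paste0(prefix, "_stack.yaml"),
    events = paste0(prefix, "_events.csv")
  )
  write_stack_tiff(stack$channels$actin_probe, paths[["actin_probe"]])
  write_stack_tiff(stack$channels$calcium, paths[["calcium"]])
  yaml::write_yaml(
    list(frame_times_s = as.numeric(stack$frame_times_s),
         pixel_size_um = stack$pixel_size_um,
         stimulus_time_s = stack$stimulus_time_s,
         intensity_scale = TIFF_SCALE,
         channels = names(stack$channels)),
    paths[["sidecar"]])
  utils::write.csv(stack$ground_truth$events, paths[["events"]],
                   row.names = FALSE)
  invisible(paths)
}

#' Read a time-lapse written by [write_timelapse()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `timelapse` (without simulation ground truth beyond the event
#'   table; `geometry` is `NULL` so quantification requires explicit masks).
#' @export
read_timelapse <- function(prefix) {
  side <- yaml::read_yaml(paste0(prefix, "_stack.yaml"))
  events_path <- paste0(prefix, "_events.csv")
  events <- if (file.exists(events_path)) {
    utils::read.csv(events_path)
  } else NULL
  import_timelapse(
    actin_tif = paste0(prefix, "_actin_probe.tif"),
    calcium_tif = paste0(prefix, "_calcium.tif"),
    frame_times_s = as.numeric(side$frame_times_s),
    pixel_size_um = side$pixel_size_um,
    stimulus_time_s = side$stimulus_time_s,
    events = events)
}

#' Import a two-channel time-lapse from multi-page TIFFs
#'
#' Entry point for real acquisitions: one multi-page TIFF per channel plus
#' the acquisition metadata.
#'
#' @param actin_tif,calcium_tif Paths to multi-page TIFF stacks (the calcium
#'   channel may be `NULL`).
#' @param frame_times_s Frame times in seconds (strictly increasing), or a
#'   single frame interval from which times are derived.
#' @param pixel_size_um Pixel size, micrometres.
#' @param stimulus_time_s Stimulus time, seconds.
#' @param events Optional ground-truth event table.
#' @return A `timelapse` with `geometry = NULL`.
#' @export
import_timelapse <- function(actin_tif, calcium_tif = NULL, frame_times_s,
                             pixel_size_um, stimulus_time_s = 0,
                             events = NULL) {
  actin <- read_stack_tiff(actin_tif)
  channels <- list(actin_probe = actin)
  if (!is.null(calcium_tif)) channels$calcium <- read_stack_tiff(calcium_tif)
  n <- dim(actin)[3L]
  if (length(frame_times_s) == 1L) {
    frame_times_s <- (seq_len(n) - 1L) * frame_times_s
  }
  if (length(frame_times_s) != n) {
    stop_param("`frame_times_s` length does not match the stack")
  }
  structure(
    list(frame_times_s = frame_times_s, channels = channels,
         pixel_size_um = pixel_size_um, geometry = NULL,
         stimulus_time_s = stimulus_time_s, configs = NULL,
         ground_truth = list(events = events, mass_um = NULL,
                             calcium_true = NULL)),
    class = "timelapse")
}

#' Read a binary ROI mask from TIFF or PNG
#'
#' Any pixel above half the maximum value is `TRUE`.
#'
#' @param path Path to a grayscale TIFF or PNG.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > max(img) / 2
}

#' Write traces to CSV
#'
#' Long format with columns `time_s`, `value`, `kind`, `cell_id`.
#'
#' @param traces A named list of [naa_trace()] objects (names become
#'   `cell_id`), or a single trace.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "naa_trace")) traces <- list(trace = traces)
  ids <- names(traces)
  if (is.null(ids)) ids <- as.character(seq_along(traces))
  df <- do.call(rbind, lapply(seq_along(traces), function(i) {
    d <- as.data.frame(traces[[i]])
    d$cell_id <- ids[i]
    d
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read traces written by [write_traces_csv()]
#'
#' @param path CSV path.
#' @return Named list of [naa_trace()] objects, one per `cell_id`.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$cell_id), function(d) {
    naa_trace(d$time_s, d$value, kind = d$kind[1L])
  })
  out
}

#' Write cell scores to JSON
#'
#' @param scores List of `cell_score` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_scores_json <- function(scores, path) {
  entries <- lapply(scores, function(s) {
    stopifnot(inherits(s, "cell_score"))
    list(cell_id = s$cell_id, positive = s$positive,
         peak_raw_heterogeneity = s$peak_raw_heterogeneity,
         baseline_mean = s$baseline_mean, baseline_sd = s$baseline_sd)
  })
  jsonlite::write_json(
    list(cells = entries, percent_positive = percent_positive(scores)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write chromatin statistics to CSV
#'
#' Columns `image_id`, `nucleus_area_px`, `het_area_px`, `fraction`.
#'
#' @param stats Named list of `chromatin_stats` (names become `image_id`).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_chromatin_csv <- function(stats, path) {
  if (inherits(stats, "chromatin_stats")) stats <- list(image = stats)
  ids <- names(stats)
  if (is.null(ids)) ids <- as.character(seq_along(stats))
  df <- data.frame(
    image_id = ids,
    nucleus_area_px = vapply(stats, function(s) s$nucleus_area_px, 0),
    het_area_px = vapply(stats, function(s) s$heterochromatin_area_px, 0),
    fraction = vapply(stats, function(s) s$fraction, 0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a grayscale image or binary mask
#'
#' Writes a numeric matrix (clipped to `[0, 1]`) or logical mask to TIFF or
#' PNG depending on the extension.
#'
#' @param image Numeric or logical matrix.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return Invisibly, the path.
#' @export
write_image <- function(image, path) {
  m <- if (is.logical(image)) image * 1 else pmin(pmax(image, 0), 1)
  m <- matrix(m, nrow(image), ncol(image))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a grayscale image
#'
#' @param path TIFF or PNG path.
#' @return Numeric matrix on the stored 0-1 scale.
#' @export
read_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}
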
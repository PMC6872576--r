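default_scoring <- function() list(k = 5, threshold = 0.5, sustain_frames = 2L)
default_population <- function() list(n_cells = 6L, responder_fraction = 1.0,
                                      pixel_size_um = 0.15,
                                      image_shape = c(72L, 72L))
default_segmentation <- function() list(min_nucleolus_px = 150L)

build_section <- function(ctor, given, section) {
  given <- as.list(given)
  ok <- names(formals(ctor))
  bad <- setdiff(names(given), ok)
  if (length(bad)) {
    stop_param(sprintf("unknown key(s) in config section '%s': %s",
                       section, paste(bad, collapse = ", ")))
  }
  do.call(ctor, given)
}

merge_defaults <- function(defaults, given, section) {
  given <- as.list(given)
  bad <- setdiff(names(given), names(defaults))
  if (length(bad)) {
    stop_param(sprintf("unknown key(s) in config section '%s': %s",
                       section, paste(bad, collapse = ", ")))
  }
  utils::modifyList(defaults, given)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with optional sections `geometry`, `kinetics`,
#' `imaging`, `calcium`, `scoring`, `population`, `segmentation` and a
#' top-level `seed`. Missing values are filled with the package defaults
#' (10 um nucleus, 1.5 um/s growth, 20 s mean nucleation interval, 16 s
#' onset latency, 50 s persistence, 3 s frame interval); unknown keys are
#' rejected with a descriptive error. An empty file yields the all-default
#' configuration.
#'
#' @param path Path to a YAML file.
#' @return Object of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_param(sprintf("config file '%s' not found", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_param("config must be a YAML mapping")
  known <- c("geometry", "kinetics", "imaging", "calcium", "scoring",
             "population", "segmentation", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_param(sprintf("unknown top-level config key(s): %s",
                       paste(bad, collapse = ", ")))
  }
  cfg <- structure(
    list(
      geometry = build_section(nucleus_geometry, raw$geometry, "geometry"),
      kinetics = build_section(kinetics_config, raw$kinetics, "kinetics"),
      imaging = build_section(imaging_config, raw$imaging, "imaging"),
      calcium = build_section(calcium_model, raw$calcium, "calcium"),
      scoring = merge_defaults(default_scoring(), raw$scoring, "scoring"),
      population = merge_defaults(default_population(), raw$population,
                                  "population"),
      segmentation = merge_defaults(default_segmentation(), raw$segmentation,
                                    "segmentation"),
      seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
    ),
    class = "run_config")
  cfg
}

#' Default pipeline configuration
#' @param seed Integer seed stored in the config.
#' @return A `run_config` with all package defaults.
#' @export
default_config <- function(seed = 1L) {
  structure(
    list(geometry = nucleus_geometry(), kinetics = kinetics_config(),
         imaging = imaging_config(), calcium = calcium_model(),
         scoring = default_scoring(), population = default_population(),
         segmentation = default_segmentation(), seed = as.integer(seed)),
    class = "run_config")
}

#' Save a configuration back to YAML
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.integer(v)) as.integer(v) else v)
  }
  yaml::write_yaml(
    list(geometry = strip(config$geometry),
         kinetics = strip(config$kinetics),
         imaging = strip(config$imaging),
         calcium = strip(config$calcium),
         scoring = config$scoring,
         population = config$population,
         segmentation = config$segmentation,
         seed = config$seed),
    path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed", x$seed, "\n")
  print(x$geometry); print(x$kinetics); print(x$imaging); print(x$calcium)
  invisible(x)
}

#' Run the full simulate-quantify-lag-score pipeline
#'
#' Simulates one default cell (stack written as per-channel TIFFs), extracts
#' the heterogeneity and calcium traces (CSV), estimates the calcium-to-NAA
#' lag (JSON), simulates and scores a cell population (JSON), and writes a
#' manifest tying the outputs to the configuration.
#'
#' @param config A `run_config` (see [load_config()], [default_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Object of class `run_manifest`: configuration MD5, package
#'   version, named output paths, timestamps.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- Sys.time()
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_path)

  log_stage <- function(...) message("[nactin] ", sprintf(...))

  log_stage("simulate: single cell, seed %d", config$seed)
  tl <- simulate_timelapse(config$geometry, config$kinetics, config$imaging,
                           config$calcium, seed = config$seed)
  stack_paths <- write_timelapse(tl, file.path(out_dir, "cell"))

  log_stage("quantify: heterogeneity + calcium traces")
  mask <- nucleus_mask(config$geometry)
  het <- heterogeneity_trace(tl, mask)
  ca_nuc <- roi_mean_trace(tl, mask)
  ca_cyto <- roi_mean_trace(tl, !mask)
  traces_path <- file.path(out_dir, "traces.csv")
  write_traces_csv(list(heterogeneity = het, calcium_nucleus = ca_nuc,
                        calcium_cytoplasm = ca_cyto), traces_path)

  log_stage("lag: onset threshold %.2f", config$scoring$threshold)
  lag <- estimate_lag(ca_nuc, het, threshold = config$scoring$threshold,
                      sustain_frames = config$scoring$sustain_frames)
  lag_path <- file.path(out_dir, "lag.json")
  jsonlite::write_json(
    list(lag_s = lag$lag_s, naa_onset_s = lag$naa_onset_s,
         calcium_onset_s = lag$calcium_onset_s, reason = lag$reason),
    lag_path, auto_unbox = TRUE, digits = NA, na = "null")

  log_stage("score: %d cells, responder fraction %.2f",
            config$population$n_cells, config$population$responder_fraction)
  pop_geom <- nucleus_geometry(
    diameter_um = config$geometry$diameter_um,
    pixel_size_um = config$population$pixel_size_um,
    image_shape = config$population$image_shape)
  pop <- simulate_population(
    config$population$n_cells, config$population$responder_fraction,
    geometry = pop_geom, kinetics = config$kinetics,
    imaging = config$imaging, calcium = config$calcium,
    seed = config$seed + 1L)
  scores <- score_population(pop, k = config$scoring$k)
  scores_path <- file.path(out_dir, "scores.json")
  write_scores_json(scores, scores_path)

  outputs <- c(actin_stack = unname(stack_paths[["actin_probe"]]),
               calcium_stack = unname(stack_paths[["calcium"]]),
               traces_csv = traces_path,
               lag_json = lag_path,
               scores_json = scores_path)
  manifest <- structure(
    list(config_md5 = unname(tools::md5sum(cfg_path)),
         package_version = as.character(utils::packageVersion("nactin")),
         config_path = cfg_path,
         outputs = outputs,
         started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
         finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("done: %d outputs in %s", length(outputs), out_dir)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> package", x$package_version, "config", x$config_md5, "\n")
  for (nm in names(x$outputs)) cat(sprintf("  %s: %s\n", nm, x$outputs[[nm]]))
  invisible(x)
}
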
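#' Simulate a two-channel nuclear time-lapse
#'
#' Generates an actin-probe channel and a calcium-sensor channel on a shared
#' time base. Filaments nucleate by a Poisson process starting a fixed
#' latency after the stimulus, elongate at constant speed inside the nuclear
#' disc, and disappear after exponential lifetimes; frames are rendered with
#' additive filament signal, Gaussian PSF and optional Poisson shot noise.
#' The calcium channel is spatially uniform per compartment (transient value
#' inside the nucleus, cytoplasmic value elsewhere) with the same noise
#' model. Ground truth (event table, per-frame filament mass, noise-free
#' calcium traces) is retained for validation.
#'
#' @param geometry A [nucleus_geometry()].
#' @param kinetics A [kinetics_config()].
#' @param imaging An [imaging_config()].
#' @param calcium A [calcium_model()].
#' @param seed Integer seed; the full stack is bit-reproducible.
#' @return Object of class `timelapse`: `frame_times_s`, `channels` (named
#'   list of row x col x frame arrays for `actin_probe` and `calcium`),
#'   `pixel_size_um`, `geometry`, `stimulus_time_s`, and `ground_truth`
#'   (`events` data frame with columns event_time_s, origin_x_um,
#'   origin_y_um, direction_deg, lifetime_s; `mass_um` per-frame total alive
#'   filament length; `calcium_true` noise-free compartment traces).
#' @examples
#' tl <- simulate_timelapse(seed = 1)
#' tl
#' @export
simulate_timelapse <- function(geometry = nucleus_geometry(),
                               kinetics = kinetics_config(),
                               imaging = imaging_config(),
                               calcium = calcium_model(),
                               seed) {
  stopifnot(inherits(geometry, "nucleus_geometry"),
            inherits(kinetics, "kinetics_config"),
            inherits(imaging, "imaging_config"),
            inherits(calcium, "calcium_model"))
  n_frames <- floor(imaging$duration_s / imaging$frame_interval_s) + 1L
  frame_times <- (seq_len(n_frames) - 1L) * imaging$frame_interval_s

  seeds <- derive_seeds(seed, 2L + 2L * n_frames)
  event_times <- sample_nucleation_times(imaging$duration_s, kinetics,
                                         imaging$stimulus_time_s,
                                         seed = seeds[1L])
  n_ev <- length(event_times)
  filaments <- with_seed(seeds[2L], {
    lapply(seq_len(n_ev), function(i) {
      pose <- sample_filament_pose(kinetics, geometry)
      lifetime <- stats::rexp(1, rate = 1 / kinetics$persistence_s)
      new_filament(event_times[i], pose$origin, pose$direction,
                   lifetime_s = max(lifetime, .Machine$double.eps), geometry)
    })
  })
  events <- data.frame(
    event_time_s = event_times,
    origin_x_um = vapply(filaments, function(f) f$origin[1L], 0),
    origin_y_um = vapply(filaments, function(f) f$origin[2L], 0),
    direction_deg = vapply(filaments, function(f)
      atan2(f$direction[2L], f$direction[1L]) * 180 / pi, 0),
    lifetime_s = vapply(filaments, function(f) f$lifetime_s, 0)
  )

  mask <- nucleus_mask(geometry)
  shp <- geometry$image_shape
  actin <- array(0, c(shp[1L], shp[2L], n_frames))
  ca <- array(0, c(shp[1L], shp[2L], n_frames))
  mass <- numeric(n_frames)

  ca_cyto <- simulate_calcium_trace(calcium, frame_times,
                                    imaging$stimulus_time_s, "cytoplasm")
  ca_nuc <- simulate_calcium_trace(calcium, frame_times,
                                   imaging$stimulus_time_s, "nucleus")

  # step filaments frame-to-frame; newborns advanced from their birth time
  state <- vector("list", n_ev)
  started <- rep(FALSE, n_ev)
  prev_t <- frame_times[1L]
  for (k in seq_len(n_frames)) {
    t_k <- frame_times[k]
    dt <- t_k - prev_t
    for (i in seq_len(n_ev)) {
      if (started[i]) {
        if (state[[i]]$alive) {
          state[[i]] <- advance_filament(state[[i]], dt, kinetics, geometry)
        }
      } else if (event_times[i] <= t_k) {
        f <- filaments[[i]]
        f <- advance_filament(f, t_k - f$birth_time_s, kinetics, geometry)
        state[[i]] <- f
        started[i] <- TRUE
      }
    }
    alive <- Filter(function(f) f$alive, state[started])
    mass[k] <- sum(vapply(alive, function(f) f$length_um, 0))
    actin[, , k] <- render_frame(alive, geometry, imaging,
                                 seed = seeds[2L + k])
    ca_exp <- matrix(ca_cyto$values[k], shp[1L], shp[2L])
    ca_exp[mask] <- ca_nuc$values[k]
    ca[, , k] <- if (imaging$noise == "poisson") {
      with_seed(seeds[2L + n_frames + k],
                matrix(stats::rpois(length(ca_exp), ca_exp), shp[1L], shp[2L]))
    } else ca_exp
    prev_t <- t_k
  }

  structure(
    list(frame_times_s = frame_times,
         channels = list(actin_probe = actin, calcium = ca),
         pixel_size_um = geometry$pixel_size_um,
         geometry = geometry,
         stimulus_time_s = imaging$stimulus_time_s,
         configs = list(kinetics = kinetics, imaging = imaging,
                        calcium = calcium),
         ground_truth = list(events = events, mass_um = mass,
                             calcium_true = list(cytoplasm = ca_cyto,
                                                 nucleus = ca_nuc))),
    class = "timelapse"
  )
}

#' @export
print.timelapse <- function(x, ...) {
  cat(sprintf(
    "<timelapse> %d frames (%.1f-%.1f s), channels: %s, %d x %d px (%.3f um/px), %d nucleation events\n",
    length(x$frame_times_s), min(x$frame_times_s), max(x$frame_times_s),
    paste(names(x$channels), collapse = ", "),
    dim(x$channels[[1L]])[1L], dim(x$channels[[1L]])[2L], x$pixel_size_um,
    nrow(x$ground_truth$events)))
  invisible(x)
}

#' Simulate a field of cells for positive-cell scoring
#'
#' Each cell is an independent time-lapse. Responders (drawn Bernoulli with
#' probability `responder_fraction`) use the supplied kinetics;
#' non-responders have nucleation disabled, so their actin channel stays
#' flat up to shot noise. Per-cell stacks default to a coarser pixel grid
#' than single-cell runs to keep population studies light.
#'
#' @param n_cells Number of cells (>= 1).
#' @param responder_fraction Probability a cell responds, in `[0, 1]`.
#' @param geometry,kinetics,imaging,calcium Configs shared by all cells.
#' @param seed Integer seed.
#' @return Object of class `cell_population`: list with `cells` (list of
#'   `timelapse`) and `responder` (logical ground-truth flags).
#' @export
simulate_population <- function(n_cells, responder_fraction,
                                geometry = nucleus_geometry(
                                  pixel_size_um = 0.15,
                                  image_shape = c(72L, 72L)),
                                kinetics = kinetics_config(),
                                imaging = imaging_config(),
                                calcium = calcium_model(),
                                seed) {
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1) {
    stop_param("`n_cells` must be >= 1")
  }
  if (!is.numeric(responder_fraction) || responder_fraction < 0 ||
      responder_fraction > 1) {
    stop_param("`responder_fraction` must lie in [0, 1]")
  }
  n_cells <- as.integer(n_cells)
  seeds <- derive_seeds(seed, n_cells + 1L)
  responder <- with_seed(seeds[1L],
                         stats::runif(n_cells) < responder_fraction)
  kin_off <- kinetics
  kin_off$nucleation_mean_interval_s <- Inf
  cells <- lapply(seq_len(n_cells), function(i) {
    simulate_timelapse(geometry,
                       if (responder[i]) kinetics else kin_off,
                       imaging, calcium, seed = seeds[i + 1L])
  })
  structure(list(cells = cells, responder = responder),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cells, %d ground-truth responders\n",
              length(x$cells), sum(x$responder)))
  invisible(x)
}
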
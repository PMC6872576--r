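#' Nucleus geometry
#'
#' Describes the circular nucleus used throughout the simulator: its physical
#' diameter, the pixel grid it is rasterized on, and its position in the
#' image. Physical coordinates are micrometres with the origin at the centre
#' of the top-left pixel; pixel (i, j) (0-based, row-major) has its centre at
#' (x = j * pixel_size, y = i * pixel_size).
#'
#' @param diameter_um Nucleus diameter in micrometres (default 10, a typical
#'   fibroblast nucleus).
#' @param pixel_size_um Physical size of one pixel in micrometres.
#' @param image_shape Integer vector `c(rows, cols)` of the pixel grid.
#' @param center_um Centre of the nucleus in micrometres `c(x, y)`; defaults
#'   to the image centre.
#' @return An object of class `nucleus_geometry`.
#' @examples
#' geom <- nucleus_geometry()
#' sum(nucleus_mask(geom)) * geom$pixel_size_um^2  # rasterized area, um^2
#' @export
nucleus_geometry <- function(diameter_um = 10,
                             pixel_size_um = 0.1,
                             image_shape = c(120L, 120L),
                             center_um = NULL) {
  check_scalar_pos(diameter_um, "diameter_um")
  check_scalar_pos(pixel_size_um, "pixel_size_um")
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 1L)) {
    stop_param("`image_shape` must be two positive integers (rows, cols)")
  }
  if (is.null(center_um)) {
    # image centre in physical coordinates
    center_um <- c((image_shape[2L] - 1) / 2, (image_shape[1L] - 1) / 2) *
      pixel_size_um
  }
  if (length(center_um) != 2L || any(!is.finite(center_um))) {
    stop_param("`center_um` must be a finite length-2 vector (x, y)")
  }
  r <- diameter_um / 2
  extent <- c((image_shape[2L] - 1), (image_shape[1L] - 1)) * pixel_size_um
  if (center_um[1L] - r < 0 || center_um[1L] + r > extent[1L] ||
      center_um[2L] - r < 0 || center_um[2L] + r > extent[2L]) {
    stop_param("nucleus disc does not fit inside the image bounds")
  }
  structure(
    list(diameter_um = diameter_um, pixel_size_um = pixel_size_um,
         image_shape = image_shape, center_um = as.numeric(center_um)),
    class = "nucleus_geometry"
  )
}

#' @export
print.nucleus_geometry <- function(x, ...) {
  cat(sprintf(
    "<nucleus_geometry> diameter %.2f um, %.3f um/px, image %d x %d px, centre (%.2f, %.2f) um\n",
    x$diameter_um, x$pixel_size_um, x$image_shape[1L], x$image_shape[2L],
    x$center_um[1L], x$center_um[2L]))
  invisible(x)
}

#' Rasterize the nucleus disc
#'
#' Binary mask of pixels whose centre lies inside the nucleus disc
#' (centre-in-disc membership).
#'
#' @param geometry A [nucleus_geometry()].
#' @return Logical matrix of dimension `image_shape`.
#' @export
nucleus_mask <- function(geometry) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  px <- geometry$pixel_size_um
  xs <- (seq_len(geometry$image_shape[2L]) - 1) * px  # columns -> x
  ys <- (seq_len(geometry$image_shape[1L]) - 1) * px  # rows -> y
  dx2 <- outer(rep(1, length(ys)), (xs - geometry$center_um[1L])^2)
  dy2 <- outer((ys - geometry$center_um[2L])^2, rep(1, length(xs)))
  (dx2 + dy2) <= (geometry$diameter_um / 2)^2
}

#' Filament kinetics configuration
#'
#' Parameters of the stochastic nucleation/elongation model: nucleation is a
#' homogeneous Poisson process (exponential inter-arrival times) that starts
#' a fixed latency after the stimulus; filaments elongate at constant speed
#' and disappear after an exponentially distributed lifetime.
#'
#' Defaults are the measured kinetics of calcium-induced nuclear actin
#' assembly: elongation at 1.5 um/s, mean inter-arrival 20 s, polymerization
#' starting about 16 s after stimulation and persisting for about 50 s.
#'
#' @param growth_rate_um_s Elongation speed, um/s.
#' @param nucleation_mean_interval_s Mean inter-arrival time of nucleation
#'   events, seconds. `Inf` disables nucleation.
#' @param onset_latency_s Deterministic delay between the stimulus and the
#'   start of the nucleation process, seconds.
#' @param persistence_s Mean filament lifetime (exponential), seconds.
#' @param origin_mode `"uniform_interior"` nucleates filaments uniformly in
#'   the nuclear disc; `"inm_anchored"` nucleates on the nuclear boundary
#'   with inward-pointing directions (filaments growing from the inner
#'   nuclear membrane).
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(growth_rate_um_s = 1.5,
                            nucleation_mean_interval_s = 20,
                            onset_latency_s = 16,
                            persistence_s = 50,
                            origin_mode = c("uniform_interior", "inm_anchored")) {
  check_scalar_pos(growth_rate_um_s, "growth_rate_um_s")
  if (!is.numeric(nucleation_mean_interval_s) ||
      length(nucleation_mean_interval_s) != 1L ||
      is.na(nucleation_mean_interval_s) || nucleation_mean_interval_s <= 0) {
    stop_param("`nucleation_mean_interval_s` must be a single positive number (Inf allowed)")
  }
  check_scalar_nonneg(onset_latency_s, "onset_latency_s")
  check_scalar_pos(persistence_s, "persistence_s")
  origin_mode <- match.arg(origin_mode)
  structure(
    list(growth_rate_um_s = growth_rate_um_s,
         nucleation_mean_interval_s = nucleation_mean_interval_s,
         onset_latency_s = onset_latency_s,
         persistence_s = persistence_s,
         origin_mode = origin_mode),
    class = "kinetics_config"
  )
}

#' @export
print.kinetics_config <- function(x, ...) {
  cat(sprintf(
    "<kinetics_config> growth %.2f um/s, mean interval %s s, latency %.1f s, persistence %.1f s, origins: %s\n",
    x$growth_rate_um_s, format(x$nucleation_mean_interval_s),
    x$onset_latency_s, x$persistence_s, x$origin_mode))
  invisible(x)
}

#' Imaging configuration
#'
#' Acquisition and rendering parameters for simulated time-lapses. Frames
#' are taken every `frame_interval_s` seconds (acquisition in the source
#' experiments was every 2-4 s). The expected actin-channel image is a
#' uniform background inside the nucleus plus additive filament signal
#' convolved with a Gaussian point-spread function; with `noise = "poisson"`
#' every pixel is an independent Poisson draw of its expectation (shot
#' noise), which dominates the unstimulated signal.
#'
#' @param frame_interval_s Time between frames, seconds.
#' @param duration_s Total acquisition length, seconds.
#' @param stimulus_time_s Time of drug addition, seconds from acquisition
#'   start. The default leaves 10 pre-stimulus baseline frames.
#' @param background_mean_photons Expected photon count per nucleus pixel
#'   before any filament forms.
#' @param filament_gain_photons_per_um Expected photons contributed per
#'   micrometre of filament length.
#' @param psf_sigma_um Standard deviation of the isotropic Gaussian PSF.
#' @param noise `"poisson"` for shot noise, `"none"` for the noise-free
#'   expectation.
#' @param conserve_total Logical; if `TRUE`, background inside the nucleus is
#'   lowered uniformly so that total expected intensity is unchanged by
#'   filament formation (probe redistribution instead of additive signal).
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(frame_interval_s = 3,
                           duration_s = 150,
                           stimulus_time_s = 30,
                           background_mean_photons = 100,
                           filament_gain_photons_per_um = 1000,
                           psf_sigma_um = 0.2,
                           noise = c("poisson", "none"),
                           conserve_total = FALSE) {
  check_scalar_pos(frame_interval_s, "frame_interval_s")
  check_scalar_pos(duration_s, "duration_s")
  if (duration_s <= frame_interval_s) {
    stop_param("`duration_s` must exceed `frame_interval_s`")
  }
  check_scalar_nonneg(stimulus_time_s, "stimulus_time_s")
  check_scalar_nonneg(background_mean_photons, "background_mean_photons")
  check_scalar_nonneg(filament_gain_photons_per_um, "filament_gain_photons_per_um")
  check_scalar_nonneg(psf_sigma_um, "psf_sigma_um")
  noise <- match.arg(noise)
  structure(
    list(frame_interval_s = frame_interval_s, duration_s = duration_s,
         stimulus_time_s = stimulus_time_s,
         background_mean_photons = background_mean_photons,
         filament_gain_photons_per_um = filament_gain_photons_per_um,
         psf_sigma_um = psf_sigma_um, noise = noise,
         conserve_total = isTRUE(conserve_total)),
    class = "imaging_config"
  )
}

#' @export
print.imaging_config <- function(x, ...) {
  cat(sprintf(
    "<imaging_config> %.1f s interval, %.0f s duration, stimulus %.0f s, bg %.0f photons, gain %.0f photons/um, PSF %.2f um, noise: %s\n",
    x$frame_interval_s, x$duration_s, x$stimulus_time_s,
    x$background_mean_photons, x$filament_gain_photons_per_um,
    x$psf_sigma_um, x$noise))
  invisible(x)
}

#' Phenomenological calcium transient model
#'
#' A difference-of-exponentials transient,
#' `baseline + A * (exp(-t/tau_decay) - exp(-t/tau_rise))` rescaled so that
#' its peak equals `amplitude`, starting at the stimulus. The nuclear
#' compartment lags the cytoplasmic one by `nuclear_delay_s`, reflecting
#' diffusion of calcium into the nucleus.
#'
#' @param baseline Resting fluorescence (photons per pixel).
#' @param amplitude Peak elevation above baseline.
#' @param rise_tau_s Rise time constant, seconds.
#' @param decay_tau_s Decay time constant, seconds; must exceed `rise_tau_s`.
#' @param nuclear_delay_s Delay of the nuclear transient relative to the
#'   cytoplasmic one, seconds.
#' @return An object of class `calcium_model`.
#' @export
calcium_model <- function(baseline = 50,
                          amplitude = 150,
                          rise_tau_s = 2,
                          decay_tau_s = 15,
                          nuclear_delay_s = 1) {
  check_scalar_nonneg(baseline, "baseline")
  check_scalar_nonneg(amplitude, "amplitude")
  check_scalar_pos(rise_tau_s, "rise_tau_s")
  check_scalar_pos(decay_tau_s, "decay_tau_s")
  check_scalar_nonneg(nuclear_delay_s, "nuclear_delay_s")
  if (rise_tau_s >= decay_tau_s) {
    stop_param("`rise_tau_s` must be smaller than `decay_tau_s` (degenerate transient shape)")
  }
  structure(
    list(baseline = baseline, amplitude = amplitude,
         rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
         nuclear_delay_s = nuclear_delay_s),
    class = "calcium_model"
  )
}

#' @export
print.calcium_model <- function(x, ...) {
  cat(sprintf(
    "<calcium_model> baseline %.0f, amplitude %.0f, rise %.1f s, decay %.1f s, nuclear delay %.1f s\n",
    x$baseline, x$amplitude, x$rise_tau_s, x$decay_tau_s, x$nuclear_delay_s))
  invisible(x)
}
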
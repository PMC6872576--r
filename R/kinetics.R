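#' Sample filament nucleation times
#'
#' Nucleation events form a homogeneous Poisson process that starts
#' `onset_latency_s` after the stimulus; inter-arrival times are i.i.d.
#' exponential with the configured mean. Events are returned up to
#' `duration_s`.
#'
#' @param duration_s Length of the observation window, seconds.
#' @param kinetics A [kinetics_config()].
#' @param stimulus_time_s Stimulus time, seconds.
#' @param seed Integer seed; the draw is reproducible.
#' @return Numeric vector of event times (seconds), possibly empty.
#' @examples
#' t <- sample_nucleation_times(200, kinetics_config(), stimulus_time_s = 0, seed = 1)
#' diff(t)  # exponential inter-arrivals, mean 20 s
#' @export
sample_nucleation_times <- function(duration_s, kinetics, stimulus_time_s = 0,
                                    seed) {
  stopifnot(inherits(kinetics, "kinetics_config"))
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_nonneg(stimulus_time_s, "stimulus_time_s")
  tau <- kinetics$nucleation_mean_interval_s
  if (!is.finite(tau)) return(numeric(0))
  start <- stimulus_time_s + kinetics$onset_latency_s
  if (start >= duration_s) return(numeric(0))
  with_seed(seed, {
    # draw in blocks until the window is covered
    times <- numeric(0)
    t_cur <- start
    repeat {
      n_draw <- max(16L, ceiling((duration_s - t_cur) / tau * 1.5))
      gaps <- stats::rexp(n_draw, rate = 1 / tau)
      new_times <- t_cur + cumsum(gaps)
      times <- c(times, new_times)
      t_cur <- times[length(times)]
      if (t_cur > duration_s) break
    }
    times[times <= duration_s]
  })
}

# Maximum filament length along a ray before the tip leaves the nucleus disc.
# Solves |origin + L * dir - center|^2 = r^2 for the positive root.
ray_clamp_length <- function(origin, direction, geometry) {
  oc <- origin - geometry$center_um
  r <- geometry$diameter_um / 2
  b <- sum(oc * direction)
  c0 <- sum(oc * oc) - r^2
  disc <- b^2 - c0
  if (disc < 0) return(0)  # origin outside the disc (shouldn't happen)
  max(0, -b + sqrt(disc))
}

#' Create a filament
#'
#' A filament is a straight segment growing from `origin` along `direction`.
#' Its tip is clamped at the nuclear boundary and it disappears (instantly,
#' no shrink phase) once its age exceeds `lifetime_s`.
#'
#' @param birth_time_s Nucleation time, seconds.
#' @param origin Length-2 numeric, micrometres.
#' @param direction Length-2 numeric; normalized internally.
#' @param lifetime_s Lifetime from nucleation to disappearance, seconds.
#' @param geometry A [nucleus_geometry()]; the origin must lie in the disc.
#' @return Object of class `filament` with fields `birth_time_s`, `origin`,
#'   `direction`, `length_um`, `age_s`, `lifetime_s`, `max_length_um`,
#'   `alive`.
#' @export
new_filament <- function(birth_time_s, origin, direction, lifetime_s,
                         geometry) {
  stopifnot(inherits(geometry, "nucleus_geometry"))
  origin <- as.numeric(origin); direction <- as.numeric(direction)
  if (length(origin) != 2L || length(direction) != 2L) {
    stop_param("`origin` and `direction` must have length 2")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop_param("`direction` must be non-zero")
  direction <- direction / nrm
  check_scalar_pos(lifetime_s, "lifetime_s")
  if (sum((origin - geometry$center_um)^2) > (geometry$diameter_um / 2)^2 + 1e-9) {
    stop_param("filament origin lies outside the nucleus disc")
  }
  structure(
    list(birth_time_s = birth_time_s, origin = origin, direction = direction,
         length_um = 0, age_s = 0, lifetime_s = lifetime_s,
         max_length_um = ray_clamp_length(origin, direction, geometry),
         alive = TRUE),
    class = "filament"
  )
}

#' Advance a filament in time
#'
#' Elongates the filament by `growth_rate * dt`, clamping the tip at the
#' nuclear boundary, and marks it dead once its age exceeds its lifetime.
#'
#' @param filament A `filament` (see [new_filament()]).
#' @param dt_s Time step, seconds (non-negative).
#' @param kinetics A [kinetics_config()].
#' @param geometry A [nucleus_geometry()].
#' @return The updated filament.
#' @export
advance_filament <- function(filament, dt_s, kinetics, geometry) {
  stopifnot(inherits(filament, "filament"), inherits(kinetics, "kinetics_config"))
  if (!is.numeric(dt_s) || length(dt_s) != 1L || is.na(dt_s) || dt_s < 0) {
    stop_param("`dt_s` must be a single non-negative number")
  }
  if (!filament$alive) stop_param("cannot advance a dead filament")
  if (dt_s == 0) return(filament)
  filament$age_s <- filament$age_s + dt_s
  filament$length_um <- min(filament$length_um + kinetics$growth_rate_um_s * dt_s,
                            filament$max_length_um)
  if (filament$age_s >= filament$lifetime_s) filament$alive <- FALSE
  filament
}

#' @export
print.filament <- function(x, ...) {
  cat(sprintf(
    "<filament> born %.1f s, origin (%.2f, %.2f) um, length %.2f um (max %.2f), age %.1f / %.1f s, %s\n",
    x$birth_time_s, x$origin[1L], x$origin[2L], x$length_um, x$max_length_um,
    x$age_s, x$lifetime_s, if (x$alive) "alive" else "gone"))
  invisible(x)
}

# Sample an origin and direction according to the configured origin mode.
# uniform_interior: uniform over the disc, direction uniform on the circle.
# inm_anchored: origin on the boundary, direction uniform over the
# inward-pointing half-plane.
sample_filament_pose <- function(kinetics, geometry) {
  r <- geometry$diameter_um / 2
  if (kinetics$origin_mode == "uniform_interior") {
    rho <- r * sqrt(stats::runif(1))
    phi <- stats::runif(1, 0, 2 * pi)
    origin <- geometry$center_um + rho * c(cos(phi), sin(phi))
    theta <- stats::runif(1, 0, 2 * pi)
    direction <- c(cos(theta), sin(theta))
  } else {
    phi <- stats::runif(1, 0, 2 * pi)
    origin <- geometry$center_um + r * c(cos(phi), sin(phi))
    inward <- -c(cos(phi), sin(phi))
    # uniform over the half-plane of directions with positive inward component
    theta <- stats::runif(1, -pi / 2, pi / 2)
    ca <- cos(theta); sa <- sin(theta)
    direction <- c(ca * inward[1L] - sa * inward[2L],
                   sa * inward[1L] + ca * inward[2L])
  }
  list(origin = origin, direction = direction)
}

#' Sample filament lifetimes
#'
#' Draws lifetimes from the persistence distribution used by the simulator:
#' exponential with mean `persistence_s`.
#'
#' @param n Number of lifetimes.
#' @param kinetics A [kinetics_config()].
#' @param seed Integer seed.
#' @return Numeric vector of lifetimes in seconds.
#' @export
sample_filament_lifetimes <- function(n, kinetics, seed) {
  stopifnot(inherits(kinetics, "kinetics_config"))
  if (!is.numeric(n) || n < 1) stop_param("`n` must be >= 1")
  with_seed(seed, stats::rexp(as.integer(n), rate = 1 / kinetics$persistence_s))
}
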
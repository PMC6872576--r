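# Unit-peak difference-of-exponentials transient shape evaluated at time u
# after onset (u may be a vector; negative values give 0).
transient_shape <- function(u, rise_tau, decay_tau) {
  peak_u <- rise_tau * decay_tau / (decay_tau - rise_tau) * log(decay_tau / rise_tau)
  peak <- exp(-peak_u / decay_tau) - exp(-peak_u / rise_tau)
  s <- ifelse(u <= 0, 0, exp(-u / decay_tau) - exp(-u / rise_tau))
  s / peak
}

#' Simulate a calcium-sensor trace
#'
#' Evaluates the phenomenological transient at the frame times: constant
#' baseline before the stimulus, then a difference-of-exponentials pulse
#' scaled to peak at `baseline + amplitude`, returning to baseline
#' asymptotically. The nuclear compartment is delayed by `nuclear_delay_s`
#' relative to the cytoplasmic one.
#'
#' @param model A [calcium_model()].
#' @param frame_times_s Increasing numeric frame times, seconds.
#' @param stimulus_time_s Stimulus time, seconds.
#' @param compartment `"cytoplasm"` or `"nucleus"`.
#' @return A [naa_trace()] of kind `"calcium"`.
#' @export
simulate_calcium_trace <- function(model, frame_times_s, stimulus_time_s,
                                   compartment = c("cytoplasm", "nucleus")) {
  stopifnot(inherits(model, "calcium_model"))
  compartment <- match.arg(compartment)
  if (any(diff(frame_times_s) <= 0)) {
    stop_param("`frame_times_s` must be strictly increasing")
  }
  onset <- stimulus_time_s +
    if (compartment == "nucleus") model$nuclear_delay_s else 0
  vals <- model$baseline + model$amplitude *
    transient_shape(frame_times_s - onset, model$rise_tau_s, model$decay_tau_s)
  naa_trace(frame_times_s, vals, kind = "calcium")
}

#' Analytical peak time of the calcium transient
#'
#' Time after onset at which the difference-of-exponentials transient peaks:
#' `tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @param model A [calcium_model()].
#' @return Peak time in seconds after transient onset.
#' @export
calcium_peak_time <- function(model) {
  stopifnot(inherits(model, "calcium_model"))
  with(model, rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s) *
         log(decay_tau_s / rise_tau_s))
}
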
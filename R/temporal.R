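#' Detect the onset of a normalized trace
#'
#' Onset is the first time the trace crosses `threshold` and stays at or
#' above it for `sustain_frames` consecutive frames; the crossing time is
#' linearly interpolated between the bracketing frames. A trace that never
#' crosses (or a degenerate flat trace) yields an absent onset rather than
#' an error.
#'
#' @param norm_trace A `normalized_trace` from [normalize_by_range()].
#' @param threshold Crossing level in `[0, 1]`, default 0.5 (half-max).
#' @param sustain_frames Frames the trace must stay above threshold.
#' @return Object of class `onset_result`: `onset_time_s` (`NA` if absent),
#'   `threshold`, `interpolated`.
#' @export
detect_onset <- function(norm_trace, threshold = 0.5, sustain_frames = 2L) {
  stopifnot(inherits(norm_trace, "naa_trace"))
  if (threshold < 0 || threshold > 1) stop_param("`threshold` must lie in [0, 1]")
  sustain_frames <- max(1L, as.integer(sustain_frames))
  res <- function(t, interp) structure(
    list(onset_time_s = t, threshold = threshold, interpolated = interp),
    class = "onset_result")
  if (is_degenerate(norm_trace)) return(res(NA_real_, FALSE))
  v <- norm_trace$values; tt <- norm_trace$times_s; n <- length(v)
  above <- v >= threshold
  for (i in which(above)) {
    if (i + sustain_frames - 1L > n) break
    if (all(above[i:(i + sustain_frames - 1L)])) {
      if (i == 1L) return(res(tt[1L], FALSE))
      # linear interpolation between frame i-1 (below) and i (at/above)
      t0 <- tt[i - 1L]; t1 <- tt[i]; v0 <- v[i - 1L]; v1 <- v[i]
      tc <- if (v1 == v0) t1 else t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
      return(res(tc, TRUE))
    }
  }
  res(NA_real_, FALSE)
}

#' @export
print.onset_result <- function(x, ...) {
  if (is.na(x$onset_time_s)) {
    cat(sprintf("<onset_result> absent (threshold %.2f)\n", x$threshold))
  } else {
    cat(sprintf("<onset_result> %.2f s (threshold %.2f%s)\n", x$onset_time_s,
                x$threshold, if (x$interpolated) ", interpolated" else ""))
  }
  invisible(x)
}

#' Lag between calcium elevation and nuclear actin assembly
#'
#' `lag = onset(NAA) - onset(calcium)`; a positive lag means nuclear actin
#' assembly follows the calcium elevation. Traces are range-normalized
#' before onset detection; raw or already-normalized traces are both
#' accepted.
#'
#' @param calcium_trace,naa_trace Traces on the same time base.
#' @param threshold Onset threshold passed to [detect_onset()].
#' @param sustain_frames Passed to [detect_onset()].
#' @return Object of class `lag_result`: `lag_s` (`NA` if either onset is
#'   absent, with `reason`), `naa_onset_s`, `calcium_onset_s`.
#' @export
estimate_lag <- function(calcium_trace, naa_trace, threshold = 0.5,
                         sustain_frames = 2L) {
  stopifnot(inherits(calcium_trace, "naa_trace"),
            inherits(naa_trace, "naa_trace"))
  if (!isTRUE(all.equal(calcium_trace$times_s, naa_trace$times_s))) {
    stop_param("traces must share a time base")
  }
  norm <- function(tr) if (inherits(tr, "normalized_trace")) tr else
    normalize_by_range(tr)
  on_ca <- detect_onset(norm(calcium_trace), threshold, sustain_frames)
  on_naa <- detect_onset(norm(naa_trace), threshold, sustain_frames)
  reason <- NULL
  if (is.na(on_ca$onset_time_s)) reason <- c(reason, "no calcium onset")
  if (is.na(on_naa$onset_time_s)) reason <- c(reason, "no NAA onset")
  structure(
    list(lag_s = on_naa$onset_time_s - on_ca$onset_time_s,
         naa_onset_s = on_naa$onset_time_s,
         calcium_onset_s = on_ca$onset_time_s,
         reason = if (length(reason)) paste(reason, collapse = "; ") else NA_character_),
    class = "lag_result"
  )
}

#' @export
print.lag_result <- function(x, ...) {
  if (is.na(x$lag_s)) {
    cat(sprintf("<lag_result> absent (%s)\n", x$reason))
  } else {
    cat(sprintf("<lag_result> lag %.2f s (NAA %.2f s, calcium %.2f s)\n",
                x$lag_s, x$naa_onset_s, x$calcium_onset_s))
  }
  invisible(x)
}

#' Validate heterogeneity as a proxy for filament mass
#'
#' Spearman rank correlation between the ground-truth total filament length
#' per frame and the measured heterogeneity per frame — the check that the
#' spatial intensity variance tracks the degree of nuclear F-actin
#' formation.
#'
#' @param mass_um Numeric per-frame total filament length (ground truth), or
#'   a `timelapse` whose ground truth is used.
#' @param het_trace A heterogeneity [naa_trace()] of the same length.
#' @return Object of class `proxy_validation`: `spearman_rho` (`NA` when a
#'   series is constant, with `defined = FALSE`), `n_frames`.
#' @export
validate_heterogeneity_proxy <- function(mass_um, het_trace) {
  if (inherits(mass_um, "timelapse")) mass_um <- mass_um$ground_truth$mass_um
  stopifnot(inherits(het_trace, "naa_trace"))
  if (length(mass_um) != length(het_trace$values)) {
    stop_param("filament-mass series and trace must have equal length")
  }
  defined <- stats::sd(mass_um) > 0 && stats::sd(het_trace$values) > 0
  rho <- if (defined) {
    stats::cor(mass_um, het_trace$values, method = "spearman")
  } else NA_real_
  structure(list(spearman_rho = rho, defined = defined,
                 n_frames = length(mass_um)),
            class = "proxy_validation")
}

#' @export
print.proxy_validation <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<proxy_validation> Spearman rho = %.3f over %d frames\n",
                x$spearman_rho, x$n_frames))
  } else {
    cat("<proxy_validation> undefined (constant series)\n")
  }
  invisible(x)
}
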
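#' Time-indexed scalar trace
#'
#' Container for a per-frame scalar series: the spatial-heterogeneity
#' readout of the actin probe, or a mean calcium-sensor intensity.
#'
#' @param times_s Strictly increasing numeric times, seconds.
#' @param values Numeric values, one per time point.
#' @param kind `"heterogeneity"` or `"calcium"`.
#' @return Object of class `naa_trace`.
#' @export
naa_trace <- function(times_s, values, kind = c("heterogeneity", "calcium")) {
  kind <- match.arg(kind)
  times_s <- as.numeric(times_s); values <- as.numeric(values)
  if (length(times_s) != length(values) || length(times_s) == 0L) {
    stop_param("`times_s` and `values` must be non-empty and equal length")
  }
  if (any(diff(times_s) <= 0)) stop_param("`times_s` must be strictly increasing")
  structure(list(times_s = times_s, values = values, kind = kind),
            class = "naa_trace")
}

#' @export
print.naa_trace <- function(x, ...) {
  cat(sprintf("<naa_trace:%s> %d points, t in [%.1f, %.1f] s, values in [%.3g, %.3g]%s\n",
              x$kind, length(x$values), min(x$times_s), max(x$times_s),
              min(x$values), max(x$values),
              if (isTRUE(attr(x, "degenerate"))) " [degenerate]" else ""))
  invisible(x)
}

#' @export
plot.naa_trace <- function(x, ...) {
  plot(x$times_s, x$values, type = "l", xlab = "time (s)",
       ylab = x$kind, ...)
  invisible(x)
}

#' @export
as.data.frame.naa_trace <- function(x, ...) {
  data.frame(time_s = x$times_s, value = x$values, kind = x$kind)
}

#' Min-max normalize a trace by its changing range
#'
#' Rescales a trace to `[0, 1]` via `(v - min) / (max - min)`. A flat trace
#' (zero range) maps to all zeros and is flagged degenerate via the
#' `degenerate` attribute instead of raising: flat traces are the expected
#' output of non-responding cells.
#'
#' @param trace A [naa_trace()].
#' @return A `naa_trace` additionally classed `normalized_trace`, with
#'   attribute `degenerate` set to `TRUE` for a zero-range input.
#' @export
normalize_by_range <- function(trace) {
  stopifnot(inherits(trace, "naa_trace"))
  rng <- range(trace$values)
  degenerate <- (rng[2L] - rng[1L]) == 0
  vals <- if (degenerate) rep(0, length(trace$values)) else
    (trace$values - rng[1L]) / (rng[2L] - rng[1L])
  out <- naa_trace(trace$times_s, vals, trace$kind)
  class(out) <- c("normalized_trace", class(out))
  attr(out, "degenerate") <- degenerate
  out
}

#' Is a normalized trace degenerate (flat input)?
#' @param trace A `normalized_trace`.
#' @return Logical.
#' @export
is_degenerate <- function(trace) isTRUE(attr(trace, "degenerate"))
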
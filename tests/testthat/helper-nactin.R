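# Shared fixtures: small geometries and short acquisitions keep unit tests
# fast; acceptance checks use the package defaults.

small_geometry <- function() {
  nucleus_geometry(diameter_um = 4, pixel_size_um = 0.1,
                   image_shape = c(60L, 60L))
}

short_imaging <- function(...) {
  imaging_config(duration_s = 60, stimulus_time_s = 12, ...)
}

# Independent two-pass variance oracle (explicit loops, no vectorized
# shortcuts shared with the implementation).
variance_oracle <- function(values) {
  n <- length(values)
  s <- 0
  for (v in values) s <- s + v
  m <- s / n
  ss <- 0
  for (v in values) ss <- ss + (v - m)^2
  ss / n
}

# Exponential MLE of the mean from a sample (closed form: sample mean).
exp_mle_mean <- function(x) sum(x) / length(x)
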
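# Run code under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic entry points take an explicit seed; no function relies on
# (or perturbs) global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_param <- function(...) stop(..., call. = FALSE)

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_param(sprintf("`%s` must be a single positive number", name))
  }
  invisible(x)
}

check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_param(sprintf("`%s` must be a single non-negative number", name))
  }
  invisible(x)
}

# Gaussian blur with the kernel capped at the image size, so small images
# (and tests on tiny fixtures) do not exceed EBImage's brush limits.
gaussian_blur <- function(x, sigma) {
  radius <- 2 * ceiling(3 * sigma) + 1
  cap <- min(dim(x))
  if (cap %% 2 == 0) cap <- cap - 1
  EBImage::gblur(x, sigma = sigma, radius = min(radius, cap))
}
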
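test_that("spatial heterogeneity is the population variance over the ROI", {
  # constant image
  expect_equal(spatial_heterogeneity(matrix(5, 4, 4), matrix(TRUE, 4, 4)), 0)

  # hand-computed: {0, 0, 10, 10} -> mean 5, variance 25 (divide by N)
  img <- matrix(c(0, 0, 10, 10), 2, 2)
  expect_equal(spatial_heterogeneity(img, matrix(TRUE, 2, 2)), 25.0)

  # masked subset only
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(spatial_heterogeneity(img, mask), 0)

  # Poisson background: variance ~= mean
  set.seed(1)
  pimg <- matrix(rpois(120^2, 100), 120, 120)
  expect_equal(spatial_heterogeneity(pimg, matrix(TRUE, 120, 120)), 100,
               tolerance = 0.05)

  expect_error(spatial_heterogeneity(img, matrix(FALSE, 2, 2)), "TRUE pixel")
})

test_that("spatial heterogeneity matches the two-pass oracle on random images", {
  set.seed(7)
  for (i in 1:100) {
    img <- matrix(runif(400, 0, 1000), 20, 20)
    mask <- matrix(runif(400) < 0.7, 20, 20)
    if (!any(mask)) mask[1] <- TRUE
    expect_equal(spatial_heterogeneity(img, mask), variance_oracle(img[mask]),
                 tolerance = 1e-9)
  }
})

test_that("heterogeneity trace has one value per frame and peaks with filament mass", {
  geom <- small_geometry()
  tl <- simulate_timelapse(geom, imaging = short_imaging(noise = "none"),
                           seed = 4)
  het <- heterogeneity_trace(tl)
  expect_length(het$values, length(tl$frame_times_s))
  skip_if(all(tl$ground_truth$mass_um == 0))
  expect_equal(which.max(het$values), which.max(tl$ground_truth$mass_um))
  expect_error(heterogeneity_trace(tl, channel = "nope"), "not present")
})

test_that("range normalization maps to [0,1] and flags flat traces", {
  tr <- naa_trace(c(0, 3, 6, 9), c(2, 2, 8, 4))
  nt <- normalize_by_range(tr)
  expect_equal(nt$values, c(0, 0, 1, 1 / 3))
  expect_false(is_degenerate(nt))

  flat <- normalize_by_range(naa_trace(c(0, 3, 6), c(5, 5, 5)))
  expect_true(is_degenerate(flat))
  expect_equal(flat$values, c(0, 0, 0))

  # idempotent on non-degenerate normalized traces
  expect_equal(normalize_by_range(nt)$values, nt$values)

  # contract: min 0, max 1
  set.seed(2)
  for (i in 1:20) {
    v <- rnorm(10)
    nt <- normalize_by_range(naa_trace(1:10, v))
    expect_equal(range(nt$values), c(0, 1))
  }
})

test_that("ROI mean trace recovers the calcium transient per compartment", {
  geom <- small_geometry()
  m <- calcium_model(nuclear_delay_s = 6)
  imaging <- short_imaging()
  tl <- simulate_timelapse(geom, kinetics_config(), imaging, m, seed = 6)
  mask <- nucleus_mask(geom)

  # constant-frame sanity: noise-free nuclear trace equals the model values
  tl0 <- simulate_timelapse(geom, kinetics_config(), short_imaging(noise = "none"),
                            m, seed = 6)
  nuc0 <- roi_mean_trace(tl0, mask)
  expect_equal(nuc0$values, tl0$ground_truth$calcium_true$nucleus$values,
               tolerance = 1e-12)

  # noisy recovery: RMS error below 3 * sqrt(peak / Npix)
  nuc <- roi_mean_trace(tl, mask)
  truth <- tl$ground_truth$calcium_true$nucleus$values
  rms <- sqrt(mean((nuc$values - truth)^2))
  expect_lt(rms, 3 * sqrt(max(truth) / sum(mask)))

  # disjoint masks preserve the configured nuclear delay
  cyto <- roi_mean_trace(tl, !mask)
  lag <- estimate_lag(cyto, nuc)
  expect_equal(lag$lag_s, m$nuclear_delay_s, tolerance = imaging$frame_interval_s)
})

test_that("cell scoring separates responders from flat traces", {
  # flat trace -> negative
  flat <- naa_trace(seq(0, 60, 3), rep(100, 21))
  expect_false(score_cell(flat, stimulus_time_s = 12)$positive)

  # needs >= 3 baseline frames
  expect_error(score_cell(flat, stimulus_time_s = 3), "3 pre-stimulus")

  # a clear post-stimulus excursion -> positive
  v <- c(rep(100, 5), rep(100, 3), 160, 180, 150, rep(100, 10))
  jit <- c(-1, 1, -1, 1, 0, rep(0, 16))
  tr <- naa_trace(seq(0, 60, 3), v + jit)
  sc <- score_cell(tr, stimulus_time_s = 14)
  expect_true(sc$positive)
  expect_equal(sc$peak_raw_heterogeneity, 180)
  expect_gte(sc$baseline_sd, 0)
})

test_that("percent positive is the positive count over the total", {
  mk <- function(p) structure(list(cell_id = NA, positive = p,
                                   peak_raw_heterogeneity = 0,
                                   baseline_mean = 0, baseline_sd = 0),
                              class = "cell_score")
  scores <- c(lapply(1:3, function(i) mk(TRUE)),
              lapply(1:27, function(i) mk(FALSE)))
  expect_equal(percent_positive(scores), 10.0)
  expect_equal(percent_positive(lapply(1:5, function(i) mk(TRUE))), 100)
  # conservation: positives + negatives = total
  pos <- sum(vapply(scores, function(s) s$positive, NA))
  expect_equal(pos + sum(!vapply(scores, function(s) s$positive, NA)),
               length(scores))
  expect_error(percent_positive(list()), "non-empty")
})
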
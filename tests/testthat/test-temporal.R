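test_that("onset detection interpolates the sustained threshold crossing", {
  nt <- normalize_by_range(naa_trace(c(0, 3, 6, 9), c(0, 0, 1, 1)))
  res <- detect_onset(nt, threshold = 0.5)
  expect_equal(res$onset_time_s, 4.5)  # midpoint of the 3-6 s bracket
  expect_true(res$interpolated)

  # never crossing -> absent
  low <- normalize_by_range(naa_trace(1:5, c(0, 0.1, 0.2, 0.3, 1)))
  expect_true(is.na(detect_onset(low, threshold = 0.9,
                                 sustain_frames = 3)$onset_time_s))

  # degenerate trace -> absent, not an error
  flat <- normalize_by_range(naa_trace(1:4, rep(2, 4)))
  expect_true(is.na(detect_onset(flat)$onset_time_s))

  # threshold 0 -> onset at the first frame
  res0 <- detect_onset(normalize_by_range(naa_trace(c(2, 5, 8), c(0, 1, 0.2))),
                       threshold = 0)
  expect_equal(res0$onset_time_s, 2)

  # sustained requirement: a one-frame blip is not an onset
  blip <- normalize_by_range(naa_trace(seq(0, 18, 3),
                                       c(0, 0, 1, 0, 0, 0.8, 0.9)))
  res_b <- detect_onset(blip, threshold = 0.5, sustain_frames = 2)
  expect_gt(res_b$onset_time_s, 9)
})

test_that("onset is monotone non-decreasing in the threshold", {
  set.seed(5)
  for (i in 1:20) {
    v <- cumsum(abs(rnorm(15)))
    nt <- normalize_by_range(naa_trace(seq(0, by = 3, length.out = 15), v))
    onsets <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th)
      detect_onset(nt, threshold = th, sustain_frames = 1L)$onset_time_s, 0)
    expect_true(all(diff(onsets) >= -1e-12))
  }
})

test_that("lag estimation is exactly shift-equivariant", {
  times <- seq(0, 150, 3)
  m <- calcium_model()
  base <- simulate_calcium_trace(m, times, 30, "cytoplasm")

  # identical traces -> lag 0
  expect_equal(estimate_lag(base, base)$lag_s, 0)

  # pure shift by k frames -> lag k * interval, exactly
  for (k in c(1L, 4L, 7L)) {
    shifted <- naa_trace(times, c(rep(base$values[1L], k),
                                  base$values[seq_len(length(times) - k)]))
    expect_equal(estimate_lag(base, shifted)$lag_s, k * 3)
  }

  # shifting the calcium trace instead flips the sign
  sh <- naa_trace(times, c(rep(base$values[1L], 4),
                           base$values[seq_len(length(times) - 4)]))
  expect_equal(estimate_lag(sh, base)$lag_s, -12)

  # missing onset reported with a reason
  flat <- naa_trace(times, rep(1, length(times)))
  res <- estimate_lag(base, flat)
  expect_true(is.na(res$lag_s))
  expect_match(res$reason, "NAA")
})

test_that("heterogeneity is a faithful proxy for filament mass", {
  geom <- small_geometry()
  kin <- kinetics_config()
  imaging <- imaging_config(duration_s = 21, frame_interval_s = 3,
                            stimulus_time_s = 1, noise = "none")

  # deterministic nested growth: a single filament elongating frame by frame
  # -> Spearman rho exactly 1 (monotone additive rendering)
  frames <- seq(0, 21, 3)
  f <- new_filament(0, geom$center_um - c(1, 0), c(1, 0.2), 1e6, geom)
  mass <- numeric(length(frames))
  het <- numeric(length(frames))
  for (k in seq_along(frames)) {
    if (k > 1) f <- advance_filament(f, 0.2, kin, geom)  # +0.3 um per frame
    mass[k] <- f$length_um
    img <- render_frame(list(f), geom, imaging)
    het[k] <- spatial_heterogeneity(img, nucleus_mask(geom))
  }
  pv <- validate_heterogeneity_proxy(mass, naa_trace(frames, het))
  expect_true(pv$defined)
  expect_equal(pv$spearman_rho, 1.0)

  # zero-filament simulation -> flagged undefined
  tl0 <- simulate_timelapse(geom,
                            kinetics_config(nucleation_mean_interval_s = Inf),
                            short_imaging(noise = "none"), seed = 1)
  pv0 <- validate_heterogeneity_proxy(tl0, heterogeneity_trace(tl0))
  expect_false(pv0$defined)
  expect_true(is.na(pv0$spearman_rho))
})
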
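test_that("nucleation is a Poisson process with the configured mean", {
  kin <- kinetics_config()
  # determinism contract
  expect_identical(
    sample_nucleation_times(300, kin, stimulus_time_s = 10, seed = 7),
    sample_nucleation_times(300, kin, stimulus_time_s = 10, seed = 7))

  # events start only after stimulus + latency
  t <- sample_nucleation_times(300, kin, stimulus_time_s = 10, seed = 7)
  expect_true(all(t >= 10 + kin$onset_latency_s))
  expect_true(all(t <= 300))

  # expected count T / tau over the open window (average over replicates)
  window <- 200
  counts <- vapply(1:400, function(s)
    length(sample_nucleation_times(window, kin, stimulus_time_s = 0, seed = s)),
    0)
  expected <- (window - kin$onset_latency_s) / kin$nucleation_mean_interval_s
  expect_equal(mean(counts), expected, tolerance = 0.05)

  # MLE of the exponential mean from >= 1e4 inter-arrivals
  long <- sample_nucleation_times(3.5e5, kin, stimulus_time_s = 0, seed = 11)
  gaps <- diff(long)
  expect_gte(length(gaps), 1e4)
  expect_equal(exp_mle_mean(gaps), 20, tolerance = 0.02)

  # infinite mean interval disables nucleation
  kin_off <- kinetics_config(nucleation_mean_interval_s = Inf)
  expect_length(sample_nucleation_times(300, kin_off, 0, seed = 1), 0)

  expect_error(kinetics_config(nucleation_mean_interval_s = -1), "positive")
})

test_that("inter-arrival times pass a KS test against the exponential law", {
  kin <- kinetics_config()
  t <- sample_nucleation_times(3.5e5, kin, stimulus_time_s = 0, seed = 3)
  gaps <- diff(t)
  expect_gte(length(gaps), 1e4)
  ks <- stats::ks.test(gaps, "pexp", rate = 1 / kin$nucleation_mean_interval_s)
  expect_gt(ks$p.value, 0.01)
})

test_that("filament elongation follows rate x time with boundary clamping", {
  geom <- nucleus_geometry()  # 10 um disc
  kin <- kinetics_config()
  center <- geom$center_um
  f <- new_filament(0, center, c(1, 0), lifetime_s = 1e6, geometry = geom)

  # rate x time
  f2 <- advance_filament(f, 2, kin, geom)
  expect_equal(f2$length_um, 3.0)

  # dt = 0 is the identity
  expect_identical(advance_filament(f, 0, kin, geom), f)

  # clamp at the disc radius from the centre, any direction
  for (th in c(0, 1, 2.5, 4.4)) {
    g <- new_filament(0, center, c(cos(th), sin(th)), 1e6, geom)
    g <- advance_filament(g, 100, kin, geom)
    expect_equal(g$length_um, 5.0)
    # tip stays inside the disc (point-in-disc along the ray)
    tip <- g$origin + g$length_um * g$direction
    expect_lte(sum((tip - center)^2), (geom$diameter_um / 2)^2 + 1e-9)
  }

  expect_error(advance_filament(f, -1, kin, geom), "non-negative")
})

test_that("filaments die once their age exceeds their lifetime", {
  geom <- nucleus_geometry()
  kin <- kinetics_config()
  f <- new_filament(0, geom$center_um, c(0, 1), lifetime_s = 5, geometry = geom)
  f <- advance_filament(f, 4.9, kin, geom)
  expect_true(f$alive)
  f <- advance_filament(f, 0.2, kin, geom)
  expect_false(f$alive)
  expect_error(advance_filament(f, 1, kin, geom), "dead")
})

test_that("filament tips never leave the nucleus disc over full histories", {
  geom <- small_geometry()
  kin <- kinetics_config()
  r2 <- (geom$diameter_um / 2)^2
  for (s in 1:20) {
    tl <- simulate_timelapse(geom, kin, short_imaging(noise = "none"),
                             seed = s)
    ev <- tl$ground_truth$events
    for (i in seq_len(nrow(ev))) {
      th <- ev$direction_deg[i] * pi / 180
      f <- new_filament(ev$event_time_s[i],
                        c(ev$origin_x_um[i], ev$origin_y_um[i]),
                        c(cos(th), sin(th)), ev$lifetime_s[i], geom)
      while (f$alive) {
        f <- advance_filament(f, 1, kin, geom)
        tip <- f$origin + f$length_um * f$direction
        expect_lte(sum((tip - geom$center_um)^2), r2 + 1e-9)
      }
    }
  }
})

test_that("inm_anchored mode nucleates on the boundary pointing inward", {
  geom <- nucleus_geometry()
  kin <- kinetics_config(origin_mode = "inm_anchored")
  imaging <- short_imaging(noise = "none")
  tl <- simulate_timelapse(geom, kin, imaging, seed = 5)
  ev <- tl$ground_truth$events
  skip_if(nrow(ev) == 0)
  r <- geom$diameter_um / 2
  for (i in seq_len(nrow(ev))) {
    o <- c(ev$origin_x_um[i], ev$origin_y_um[i])
    expect_equal(sqrt(sum((o - geom$center_um)^2)), r, tolerance = 1e-9)
    th <- ev$direction_deg[i] * pi / 180
    inward <- (geom$center_um - o) / r
    expect_gt(sum(c(cos(th), sin(th)) * inward), 0)
  }
})
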
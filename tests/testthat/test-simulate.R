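test_that("frame count and channel layout follow the acquisition config", {
  geom <- small_geometry()
  imaging <- imaging_config(duration_s = 90, frame_interval_s = 3,
                            stimulus_time_s = 12, noise = "none")
  tl <- simulate_timelapse(geom, kinetics_config(), imaging, seed = 1)
  expect_length(tl$frame_times_s, 31L)  # floor(90/3) + 1
  expect_named(tl$channels, c("actin_probe", "calcium"))
  expect_equal(dim(tl$channels$actin_probe), c(60L, 60L, 31L))
  expect_equal(dim(tl$channels$calcium), c(60L, 60L, 31L))
  expect_true(all(tl$channels$actin_probe >= 0))
})

test_that("no nucleation events gives a flat heterogeneity trace up to noise", {
  geom <- small_geometry()
  kin <- kinetics_config(nucleation_mean_interval_s = Inf)
  tl <- simulate_timelapse(geom, kin, short_imaging(noise = "none"), seed = 1)
  expect_equal(nrow(tl$ground_truth$events), 0L)
  het <- heterogeneity_trace(tl)
  expect_true(all(het$values == 0))  # noise-free uniform frames
})

test_that("simulated stacks are bit-identical under identical seeds", {
  geom <- small_geometry()
  a <- simulate_timelapse(geom, imaging = short_imaging(), seed = 42)
  b <- simulate_timelapse(geom, imaging = short_imaging(), seed = 42)
  expect_identical(a$channels, b$channels)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  c <- simulate_timelapse(geom, imaging = short_imaging(), seed = 43)
  expect_false(identical(a$channels$actin_probe, c$channels$actin_probe))
})

test_that("ground-truth filament mass matches an independent reconstruction", {
  geom <- small_geometry()
  kin <- kinetics_config()
  tl <- simulate_timelapse(geom, kin, short_imaging(noise = "none"), seed = 8)
  ev <- tl$ground_truth$events
  # reconstruct per-frame total length analytically from the event table
  mass <- vapply(tl$frame_times_s, function(t) {
    tot <- 0
    for (i in seq_len(nrow(ev))) {
      age <- t - ev$event_time_s[i]
      if (age >= 0 && age < ev$lifetime_s[i]) {
        th <- ev$direction_deg[i] * pi / 180
        f <- new_filament(ev$event_time_s[i],
                          c(ev$origin_x_um[i], ev$origin_y_um[i]),
                          c(cos(th), sin(th)), ev$lifetime_s[i], geom)
        tot <- tot + min(kin$growth_rate_um_s * age, f$max_length_um)
      }
    }
    tot
  }, 0)
  expect_equal(tl$ground_truth$mass_um, mass, tolerance = 1e-9)
})

test_that("population responder flags follow the binomial law", {
  geom <- small_geometry()
  imaging <- short_imaging()
  # fraction 0: all flat actin channels (no events anywhere)
  pop0 <- simulate_population(8, 0, geometry = geom, imaging = imaging,
                              seed = 1)
  expect_false(any(pop0$responder))
  expect_true(all(vapply(pop0$cells, function(c)
    nrow(c$ground_truth$events) == 0L, NA)))

  # fraction 1 with duration >> mean interval: every cell has >= 1 event
  img_long <- imaging_config(duration_s = 150, stimulus_time_s = 10)
  pop1 <- simulate_population(6, 1, geometry = geom, imaging = img_long,
                              seed = 2)
  expect_true(all(pop1$responder))
  expect_true(all(vapply(pop1$cells, function(c)
    nrow(c$ground_truth$events) >= 1L, NA)))

  # fraction 0.5, n = 200: responder count inside the central 99% interval
  # (flags only; cheap config so the stacks stay small)
  tiny <- nucleus_geometry(diameter_um = 2, pixel_size_um = 0.2,
                           image_shape = c(14L, 14L))
  pop <- simulate_population(200, 0.5, geometry = tiny,
                             imaging = short_imaging(), seed = 3)
  n_resp <- sum(pop$responder)
  expect_gte(n_resp, qbinom(0.005, 200, 0.5))
  expect_lte(n_resp, qbinom(0.995, 200, 0.5))

  expect_error(simulate_population(0, 0.5, seed = 1), "n_cells")
  expect_error(simulate_population(10, 1.5, seed = 1), "responder_fraction")
})
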
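test_that("a zero-amplitude evoked field stays exactly at baseline", {
  cfg <- sim_config(height = 8, width = 8, duration = 15, noise_sigma = 0)
  kern <- evoked_kernel_params(peak_fraction = 0, undershoot_fraction = 0)
  truth <- simulate_evoked_field(cfg, kern, stimulus_onsets = 5)
  frac <- haem_fractional(truth)
  expect_identical(unique(as.vector(frac$hbt)), 1)
})

test_that("the evoked kernel peaks at the configured amplitude and time", {
  cfg <- sim_config(height = 8, width = 8, duration = 20, noise_sigma = 0)
  kern <- evoked_kernel_params(time_to_peak = 3, peak_fraction = 0.05)
  truth <- simulate_evoked_field(cfg, kern, stimulus_onsets = 5)
  frac <- haem_fractional(truth)
  times <- frame_times(dim(frac$hbt)[3], cfg$frame_rate)
  inside <- attr(truth, "active_region")
  px <- which(inside)[1]
  trace <- frac$hbt[cbind(arrayInd(px, dim(inside)))[1],
                    arrayInd(px, dim(inside))[2], ]
  expect_equal(max(trace), 1.05, tolerance = 1e-10)
  expect_equal(times[which.max(trace)], 5 + 3)
  # outside the region: flat baseline
  outside_px <- which(!inside)[1]
  oc <- arrayInd(outside_px, dim(inside))
  expect_identical(unique(frac$hbt[oc[1], oc[2], ]), 1)
})

test_that("triphasic mode makes HbR cross baseline at least twice", {
  cfg <- sim_config(height = 4, width = 4, duration = 25, noise_sigma = 0)
  kern <- evoked_kernel_params(hbr_mode = "triphasic",
                               triphasic_bump_fraction = 0.02)
  truth <- simulate_evoked_field(cfg, kern,
                                 active_region = matrix(TRUE, 4, 4),
                                 stimulus_onsets = 5)
  hbr <- haem_fractional(truth)$hbr[1, 1, ]
  crossings <- sum(diff(sign(hbr - 1)) != 0 & abs(diff(hbr)) > 1e-12)
  expect_gte(crossings, 2)
  expect_gt(max(hbr), 1)    # early bump above baseline
  expect_lt(min(hbr), 1)    # washout below baseline
})

test_that("overlapping stimulus windows are rejected", {
  cfg <- sim_config(height = 4, width = 4, duration = 20)
  expect_error(simulate_evoked_field(cfg, evoked_kernel_params(),
                                     stimulus_onsets = c(5, 6)),
               "overlap")
})

test_that("CSD arrival delay follows distance / speed arithmetic", {
  # 3 mm/min, two pixels 1 mm apart -> profiles shifted by 20 s
  cfg <- sim_config(height = 1, width = 21, pixel_pitch_um = 100,
                    frame_rate = 5, duration = 150, noise_sigma = 0)
  cs <- csd_params(origin = c(1, 1), speed = 3)
  f <- haem_fractional(simulate_csd_field(cfg, cs))
  t_min_near <- which.min(f$hbt[1, 1, ])   # at the origin
  t_min_far <- which.min(f$hbt[1, 11, ])   # 10 px = 1 mm away
  expect_equal((t_min_far - t_min_near) / cfg$frame_rate, 20,
               tolerance = 0.5)
})

test_that("infinite-speed limit gives a synchronous field", {
  cfg <- sim_config(height = 6, width = 6, frame_rate = 2, duration = 100,
                    noise_sigma = 0)
  f <- haem_fractional(simulate_csd_field(cfg, csd_params(speed = 1e9)))
  per_pixel <- matrix(f$hbt, 36, dim(f$hbt)[3])
  expect_lt(max(apply(per_pixel, 2, function(x) diff(range(x)))), 1e-9)
})

test_that("a short undershoot decay recovers the late-window mean to baseline", {
  cfg <- sim_config(height = 2, width = 2, frame_rate = 1, duration = 900,
                    noise_sigma = 0)
  f <- haem_fractional(simulate_csd_field(
    cfg, csd_params(speed = 1e6, undershoot_decay_tau = 40)))
  late <- f$hbt[1, 1, 600:900]
  expect_equal(mean(late), 1.0, tolerance = 1e-3)
})

test_that("rendering with zero concentration change and no noise returns I0", {
  cfg <- sim_config(height = 4, width = 4, duration = 4, noise_sigma = 0)
  zero <- haem_field(array(0, c(4, 4, 20)), array(0, c(4, 4, 20)),
                     mode = "absolute", frame_rate = 5)
  stack <- render_reflectance(zero, test_spectra(), cfg, i0 = 0.5)
  expect_identical(unique(as.vector(stack$data)), 0.5)
})

test_that("render then attenuation reproduces the Beer-Lambert delta-OD", {
  sp <- test_spectra()
  cfg <- sim_config(height = 6, width = 6, duration = 16, noise_sigma = 0)
  truth <- simulate_evoked_field(cfg, evoked_kernel_params(),
                                 stimulus_onsets = 6)
  stack <- render_reflectance(truth, sp, cfg, saturation_dependent = FALSE)
  at <- compute_attenuation(stack, c(0, 4))
  E <- extinction_at(sp, cfg$wavelengths_nm)
  L <- pathlength_at(sp, cfg$wavelengths_nm, 0.7)[, 1]
  for (w in c(1, 3)) {
    expected <- L[w] * (E[w, "eps_hbo"] * truth$hbo * 1e-6 +
                          E[w, "eps_hbr"] * truth$hbr * 1e-6)
    expect_lt(max(abs(at$values[, , w, ] - expected)), 1e-10)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- sim_config(height = 8, width = 8, duration = 10, noise_sigma = 0.01,
                    seed = 11L)
  truth <- simulate_evoked_field(cfg, evoked_kernel_params(),
                                 stimulus_onsets = 5)
  s1 <- render_reflectance(truth, test_spectra(), cfg)
  s2 <- render_reflectance(truth, test_spectra(), cfg)
  expect_identical(s1$data, s2$data)

  e1 <- simulate_electrode(3, neural_sim_params(n_channels = 2,
                                                sampling_rate = 10000),
                           stimulus_onsets = 1, seed = 5)
  e2 <- simulate_electrode(3, neural_sim_params(n_channels = 2,
                                                sampling_rate = 10000),
                           stimulus_onsets = 1, seed = 5)
  expect_identical(e1$recording$traces, e2$recording$traces)
  expect_identical(e1$events, e2$events)
})

test_that("electrode event counts follow the configured Poisson rates", {
  p <- neural_sim_params(n_channels = 16, sampling_rate = 10000,
                         baseline_rate = 10, evoked_gain = 2)
  sim <- simulate_electrode(30, p, stimulus_onsets = c(10, 20),
                            stimulus_duration = 2, seed = 9)
  ev <- sim$events
  in_stim <- (ev$time_s >= 10 & ev$time_s < 12) |
    (ev$time_s >= 20 & ev$time_s < 22)
  # 16 channels x 2 windows x 2 s x 20/s = 1280 expected evoked events
  n_stim <- sum(in_stim)
  expect_lt(abs(n_stim - 1280) / sqrt(1280), 4)
  # baseline: 16 x 26 s x 10/s = 4160
  n_base <- sum(!in_stim)
  expect_lt(abs(n_base - 4160) / sqrt(4160), 4)
})

test_that("unit evoked gain leaves stimulus windows at the baseline rate", {
  p <- neural_sim_params(n_channels = 16, sampling_rate = 10000,
                         baseline_rate = 10, evoked_gain = 1)
  sim <- simulate_electrode(40, p, stimulus_onsets = seq(5, 35, by = 10),
                            stimulus_duration = 2, seed = 13)
  ev <- sim$events
  in_stim <- Reduce(`|`, lapply(seq(5, 35, by = 10),
                                function(on) ev$time_s >= on & ev$time_s < on + 2))
  n_stim <- sum(in_stim)      # expected 16 ch x 8 s x 10/s = 1280
  expect_lt(abs(n_stim - 1280) / sqrt(1280), 4)
})
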
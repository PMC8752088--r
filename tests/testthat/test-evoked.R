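test_that("trial_set enforces sorted, non-overlapping trials", {
  ts <- trial_set(c(30, 10, 50), pre_window = 4, post_window = 10)
  expect_equal(ts$onsets, c(10, 30, 50))
  expect_error(trial_set(c(10, 15), pre_window = 4, post_window = 10),
               "overlap")
})

test_that("identical trials average to any single trial with zero SEM", {
  kern <- evoked_kernel_params(undershoot_fraction = 0)
  ser <- noisy_roi_series(kern, onsets = c(10, 50, 90),
                          duration = 110, noise_sd = 0)
  avg <- trial_average(ser, trial_set(c(10, 50, 90), post_window = 15))
  hbt <- dplyr::filter(avg, component == "hbt")
  expect_lt(max(hbt$sem), 1e-9)
  expect_equal(max(hbt$mean), 1.05, tolerance = 1e-9)
})

test_that("SEM shrinks as 1/sqrt(n) and the mean converges to the kernel", {
  kern <- evoked_kernel_params()
  mean_sem <- function(n) {
    onsets <- seq(10, by = 20, length.out = n)
    ser <- noisy_roi_series(kern, onsets, duration = max(onsets) + 18,
                            noise_sd = 0.01, seed = 2)
    avg <- trial_average(ser, trial_set(onsets, post_window = 15))
    mean(dplyr::filter(avg, component == "hbt")$sem)
  }
  s4 <- mean_sem(4)
  s16 <- mean_sem(16)
  expect_equal(s4 / s16, 2, tolerance = 0.25)
})

test_that("a single trial returns itself with absent SEM", {
  ser <- noisy_roi_series(evoked_kernel_params(), onsets = 10,
                          duration = 30, noise_sd = 0)
  avg <- trial_average(ser, trial_set(10, post_window = 15))
  expect_true(all(is.na(avg$sem)))
  expect_equal(max(dplyr::filter(avg, component == "hbt")$mean), 1.05,
               tolerance = 1e-9)
})

test_that("trials extending beyond the recording are rejected by name", {
  ser <- noisy_roi_series(evoked_kernel_params(), onsets = 10,
                          duration = 20, noise_sd = 0)
  expect_error(trial_average(ser, trial_set(c(10), post_window = 15)),
               "trial 1")
})

test_that("summarise_evoked reads a hand-built triangular pulse exactly", {
  t <- seq(-4, 15, by = 0.2)
  tri <- 1 + 0.05 * pmax(0, 1 - abs(t - 2) / 2)   # peaks 1.05 at t = 2
  avg <- tibble::tibble(time_rel_s = t, component = "hbt", mean = tri)
  s <- summarise_evoked(avg, stim_duration = 2, post = 10)
  expect_equal(s$peak, 0.05)
  expect_equal(s$time_to_peak_s, 2)
  # linear rise from 0 at t=0 to peak at t=2: 10%->90% spans 1.6 s
  expect_equal(s$rise_time_s, 1.6, tolerance = 1e-9)
  # triangle area: base 4 s, height 0.05
  expect_equal(s$auc, 0.1, tolerance = 1e-9)
})

test_that("a flat trace summarises to zero with absent times", {
  avg <- tibble::tibble(time_rel_s = seq(-4, 15, 0.2), component = "hbt",
                        mean = 1)
  s <- summarise_evoked(avg, stim_duration = 2)
  expect_equal(s$peak, 0)
  expect_true(is.na(s$time_to_peak_s))
  expect_equal(s$auc, 0)
})

test_that("evoked metrics recover the simulator's configured parameters", {
  kern <- evoked_kernel_params(time_to_peak = 3, peak_fraction = 0.08)
  onsets <- seq(10, by = 20, length.out = 30)
  # 0.002 is the ROI-mean noise the rendered imaging chain delivers at the
  # default 1% reflectance noise once ~300 ROI pixels are averaged
  ser <- noisy_roi_series(kern, onsets, duration = max(onsets) + 18,
                          noise_sd = 0.002, seed = 5)
  avg <- trial_average(ser, trial_set(onsets, post_window = 15))
  s <- summarise_evoked(avg, stim_duration = 2)
  hbt <- dplyr::filter(s, component == "hbt")
  expect_equal(hbt$peak, 0.08, tolerance = 0.05)
  expect_equal(hbt$time_to_peak_s, 3, tolerance = 0.05)
  # HbR peak is the signed (negative) washout extremum
  hbr <- dplyr::filter(s, component == "hbr")
  expect_lt(hbr$peak, 0)
})

test_that("the HbR classifier labels the simulator's modes correctly", {
  onsets <- seq(10, by = 20, length.out = 10)
  lab <- function(mode, bump, seed) {
    kern <- evoked_kernel_params(hbr_mode = mode,
                                 triphasic_bump_fraction = bump)
    ser <- noisy_roi_series(kern, onsets, duration = max(onsets) + 18,
                            noise_sd = 0.005, seed = seed)
    classify_hbr(trial_average(ser, trial_set(onsets, post_window = 15)))
  }
  tri <- vapply(1:10, function(s) lab("triphasic", 0.03, s), character(1))
  bi <- vapply(11:20, function(s) lab("biphasic", 0, s), character(1))
  expect_true(all(tri == "triphasic"))
  expect_true(all(bi == "biphasic"))
})

test_that("pure noise is read as flat in at least 95% of draws", {
  labs <- vapply(1:40, function(seed) {
    set.seed(seed)
    avg <- tibble::tibble(time_rel_s = seq(-4, 15, by = 0.2),
                          component = "hbr",
                          mean = 1 + rnorm(96, sd = 0.005))
    classify_hbr(avg)
  }, character(1))
  expect_gte(mean(labs == "flat"), 0.95)
})

test_that("gas challenge metrics follow rectangle and ramp arithmetic", {
  t <- seq(0, 100, by = 0.5)
  step <- ifelse(t >= 40 & t <= 60, 1.2, 1.0)
  ser <- tibble::tibble(time_s = t, hbt = step)
  r <- gas_challenge_response(ser, c(40, 60), c(0, 30))
  expect_equal(r$mean_change, 0.2)
  expect_equal(r$auc, 0.2 * 20, tolerance = 1e-9)

  flat <- tibble::tibble(time_s = t, hbt = 1)
  r0 <- gas_challenge_response(flat, c(40, 60), c(0, 30))
  expect_equal(r0$mean_change, 0)
  expect_equal(r0$auc, 0)

  # slow ramp 1.0 -> 1.3 over the window: integral 0.3 * 20 / 2
  ramp <- tibble::tibble(time_s = t,
                         hbt = 1 + 0.3 * pmax(0, pmin((t - 40) / 20, 1)))
  rr <- gas_challenge_response(ramp, c(40, 60), c(0, 30))
  expect_equal(rr$auc, 3, tolerance = 1e-6)
  expect_error(gas_challenge_response(ser, c(90, 120), c(0, 30)), "outside")
})

test_that("re-baselined mean traces sit at 1.0 over the pre-window", {
  onsets <- seq(10, by = 20, length.out = 20)
  ser <- noisy_roi_series(evoked_kernel_params(), onsets,
                          duration = max(onsets) + 18, noise_sd = 0.01,
                          seed = 8)
  avg <- trial_average(ser, trial_set(onsets, post_window = 15))
  pre <- dplyr::filter(avg, component == "hbt", time_rel_s < 0)
  se <- mean(pre$sem) / sqrt(nrow(pre))
  expect_lt(abs(mean(pre$mean) - 1), 3 * max(se, 1e-4))
})
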
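test_that("packaged optical tables satisfy their physical invariants", {
  sp <- test_spectra()
  expect_true(all(sp$extinction$eps_hbo > 0))
  expect_true(all(sp$extinction$eps_hbr > 0))
  expect_true(all(sp$pathlength$pathlength_cm > 0))
  expect_lte(min(sp$saturation_grid), 0.3)
  expect_gte(max(sp$saturation_grid), 1.0)
  # every instrument wavelength is covered exactly
  expect_true(all(c(494, 560, 575, 595) %in% sp$extinction$wavelength_nm))
  # red light travels further than green in tissue
  L <- pathlength_at(sp, c(560, 595), 0.7)
  expect_gt(L[2, 1], L[1, 1])
})

test_that("spectra TSV round trip preserves the tables", {
  sp <- test_spectra()
  dir <- withr::local_tempdir()
  write_spectra(sp, dir)
  sp2 <- read_spectra(file.path(dir, "extinction.tsv"),
                      file.path(dir, "pathlength.tsv"))
  expect_equal(sp2$extinction, sp$extinction)
  expect_equal(sp2$pathlength, sp$pathlength, tolerance = 1e-12)
})

test_that("attenuation is zero for frames equal to the baseline mean", {
  d <- array(0.4, c(3, 3, 2, 10))
  stack <- reflectance_stack(d, c(560, 575), frame_rate = 5)
  at <- compute_attenuation(stack, c(0, 1))
  expect_equal(max(abs(at$values)), 0)
})

test_that("attenuation recovers a hand-computed log ratio", {
  d <- array(0.4, c(3, 3, 2, 10))
  d[2, 2, 1, 6:10] <- 0.4 * exp(-0.1)
  stack <- reflectance_stack(d, c(560, 575), frame_rate = 5)
  at <- compute_attenuation(stack, c(0, 0.8))   # frames 1-5
  expect_equal(at$values[2, 2, 1, 7], 0.1, tolerance = 1e-12)
  expect_equal(at$values[2, 2, 2, 7], 0)
  expect_equal(at$values[1, 1, 1, 7], 0)
})

test_that("attenuation rejects bad inputs with informative errors", {
  d <- array(0.4, c(2, 2, 2, 6))
  stack <- reflectance_stack(d, c(560, 575), frame_rate = 1)
  expect_error(compute_attenuation(stack, c(0, 0.5)), "2 frames")
  expect_error(compute_attenuation(stack, c(0, 100)), "within the recording")
  d2 <- d; d2[1, 1, 1, 3] <- 0
  stack2 <- reflectance_stack(d2, c(560, 575), frame_rate = 1)
  expect_error(compute_attenuation(stack2, c(0, 2)), "frame 3")
})

test_that("zero attenuation unmixes to the exact baseline state", {
  sp <- test_spectra()
  at <- make_atten(array(0, c(2, 2, 4, 5)), c(494, 560, 575, 595))
  h <- unmix(at, sp, baseline_state(), mode = "absolute")
  expect_equal(max(abs(h$hbo)), 0)
  expect_equal(max(abs(h$hbr)), 0)
  hf <- haem_fractional(h)
  expect_identical(unique(as.vector(hf$hbt)), 1)
  expect_identical(unique(as.vector(hf$hbo)), 1)
  expect_identical(unique(as.vector(hf$hbr)), 1)
})

test_that("unmix inverts the forward Beer-Lambert model at the instrument wavelengths", {
  sp <- test_spectra()
  true_hbo <- c(3.7, -1.2, 0, 8)
  true_hbr <- c(-1.1, 0.4, 0, -3)
  da <- sapply(seq_along(true_hbo), function(i)
    forward_da(sp, true_hbo[i], true_hbr[i]))
  at <- make_atten(aperm(array(da, c(4, 1, 1, length(true_hbo))),
                         c(2, 3, 1, 4)),
                   c(494, 560, 575, 595))
  h <- unmix(at, sp, mode = "absolute")
  expect_equal(as.vector(h$hbo), true_hbo, tolerance = 1e-8)
  expect_equal(as.vector(h$hbr), true_hbr, tolerance = 1e-8)
})

test_that("unmixing is linear: doubling attenuation doubles concentrations", {
  sp <- test_spectra()
  da <- forward_da(sp, 2.5, -0.8)
  at1 <- make_atten(array(da, c(1, 1, 4, 1)), c(494, 560, 575, 595))
  at2 <- make_atten(array(2 * da, c(1, 1, 4, 1)), c(494, 560, 575, 595))
  h1 <- unmix(at1, sp, mode = "absolute")
  h2 <- unmix(at2, sp, mode = "absolute")
  expect_equal(2 * h1$hbo, h2$hbo, tolerance = 1e-12)
  expect_equal(2 * h1$hbr, h2$hbr, tolerance = 1e-12)
})

test_that("HbT = HbO + HbR at every sample (conservation)", {
  sp <- test_spectra()
  set.seed(42)
  at <- make_atten(array(rnorm(4 * 4 * 4 * 20, sd = 0.01), c(4, 4, 4, 20)),
                   c(494, 560, 575, 595))
  h <- unmix(at, sp, mode = "absolute")
  rel <- max(abs(h$hbt - (h$hbo + h$hbr))) / max(abs(h$hbt))
  expect_lte(rel, 1e-12)
})

test_that("a rank-deficient wavelength set is rejected with a condition report", {
  sp <- test_spectra()
  at <- make_atten(array(0.01, c(1, 1, 2, 1)), c(500, 500))
  expect_error(unmix(at, sp), "condition number")
})

test_that("concentration noise covariance matches the least-squares prediction", {
  sp <- test_spectra()
  wl <- c(494, 560, 575, 595)
  E <- extinction_at(sp, wl)
  L <- pathlength_at(sp, wl, 0.7)[, 1]
  X <- L * E
  sigma <- 1e-3
  pred_cov <- solve(crossprod(X)) * sigma^2     # in M^2
  n <- 2e4
  set.seed(7)
  da <- matrix(rnorm(4 * n, sd = sigma), 4, n)
  at <- make_atten(aperm(array(da, c(4, 1, 1, n)), c(2, 3, 1, 4)), wl)
  h <- unmix(at, sp, mode = "absolute")
  emp_cov <- stats::cov(cbind(as.vector(h$hbo), as.vector(h$hbr))) * 1e-12
  expect_equal(emp_cov[1, 1], pred_cov[1, 1], tolerance = 0.05)
  expect_equal(emp_cov[2, 2], pred_cov[2, 2], tolerance = 0.05)
  expect_equal(emp_cov[1, 2], pred_cov[1, 2], tolerance = 0.10)
})

test_that("fractional output is invariant to the assumed baseline concentration", {
  # when ground truth is expressed fractionally, rescaling c_hbt0 rescales
  # the recovered deltas by the same factor and cancels in the ratio
  sp <- test_spectra()
  for (c0 in c(80, 100, 120)) {
    b <- baseline_state(c_hbt0 = c0)
    cfg <- sim_config(height = 4, width = 4, duration = 10, noise_sigma = 0)
    kern <- evoked_kernel_params(peak_fraction = 0.05)
    truth <- simulate_evoked_field(cfg, kern,
                                   active_region = matrix(TRUE, 4, 4),
                                   stimulus_onsets = 2)
    # re-express the truth at this baseline: same fractional change
    truth$hbo <- truth$hbo * c0 / 100
    truth$hbr <- truth$hbr * c0 / 100
    truth$hbt <- truth$hbt * c0 / 100
    truth$baseline <- b
    stack <- render_reflectance(truth, sp, cfg, baseline = b,
                                saturation_dependent = FALSE)
    h <- unmix(compute_attenuation(stack, c(0, 1)), sp, b)
    expect_equal(max(h$hbt), 1.05, tolerance = 1e-6)
  }
})

test_that("PLSA with a saturation-flat pathlength table equals single-pass unmixing", {
  spf <- flat_spectra()
  set.seed(3)
  at <- make_atten(array(rnorm(2 * 2 * 4 * 6, sd = 0.01), c(2, 2, 4, 6)),
                   c(494, 560, 575, 595))
  h0 <- unmix(at, spf, mode = "absolute")
  h1 <- plsa_refine(at, spf, mode = "absolute")
  expect_equal(h1$hbo, h0$hbo, tolerance = 1e-12)
  expect_true(attr(h1, "plsa")$converged)
})

test_that("PLSA with infinite tolerance returns the first iterate", {
  sp <- test_spectra()
  set.seed(4)
  at <- make_atten(array(rnorm(2 * 2 * 4 * 6, sd = 0.05), c(2, 2, 4, 6)),
                   c(494, 560, 575, 595))
  h0 <- unmix(at, sp, mode = "absolute")
  h1 <- plsa_refine(at, sp, tol = Inf, mode = "absolute")
  expect_equal(h1$hbo, h0$hbo)
  expect_equal(attr(h1, "plsa")$iterations, 1)
})

test_that("PLSA corrects the pathlength mismatch during a desaturation episode", {
  # saturation drops 0.70 -> ~0.55 during a simulated CSD; the true
  # pathlengths follow it, so single-pass unmixing at S0 is biased and the
  # refinement recovers the truth
  sp <- test_spectra()
  cfg <- sim_config(height = 4, width = 4, frame_rate = 1, duration = 120,
                    noise_sigma = 0)
  cs <- csd_params(speed = 1e5, dip_fraction = 0.55, washout_ratio = 0.88)
  truth <- simulate_csd_field(cfg, cs, t_insert = 10)
  sat_true <- (70 + truth$hbo) / (100 + truth$hbt)
  expect_lt(min(sat_true), 0.57)     # episode really desaturates
  expect_gt(min(70 + truth$hbo), 0)  # stays physical
  stack <- render_reflectance(truth, sp, cfg, saturation_dependent = TRUE)
  at <- compute_attenuation(stack, c(0, 4))
  h_single <- unmix(at, sp, mode = "absolute")
  h_plsa <- plsa_refine(at, sp, tol = 1e-7, mode = "absolute")
  scale <- max(abs(truth$hbt))
  err_single <- max(abs(h_single$hbt - truth$hbt)) / scale
  err_plsa <- max(abs(h_plsa$hbt - truth$hbt)) / scale
  expect_lt(err_plsa, 0.02)
  expect_gt(err_single / err_plsa, 5)
  expect_true(attr(h_plsa, "plsa")$converged)
})
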
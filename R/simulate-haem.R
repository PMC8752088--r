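#' Simulation configuration
#'
#' Geometry, timing and noise settings shared by the forward simulators.
#' Defaults are a desk-scale imaging session: 64 x 64 pixels at 50 um pitch
#' (a ~3.2 mm cortical field), 5 Hz full-spectral frame rate, the four
#' instrument wavelengths, and 1% multiplicative reflectance noise.
#'
#' @param height,width grid size in pixels.
#' @param pixel_pitch_um physical pixel size (um).
#' @param frame_rate imaging frame rate (Hz).
#' @param duration recording length (s).
#' @param wavelengths_nm illumination wavelengths (nm).
#' @param noise_sigma multiplicative reflectance noise SD (fraction).
#' @param seed integer seed fixing every stochastic draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(height = 64, width = 64, pixel_pitch_um = 50,
                       frame_rate = 5, duration = 30,
                       wavelengths_nm = c(494, 560, 575, 595),
                       noise_sigma = 0.01, seed = 1L) {
  vals <- c(height, width, pixel_pitch_um, frame_rate, duration)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all sim_config dimensions, rates and durations must be positive")
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  structure(list(height = height, width = width,
                 pixel_pitch_um = pixel_pitch_um, frame_rate = frame_rate,
                 duration = duration,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "sim_config")
}

#' Evoked haemodynamic kernel parameters
#'
#' Parameterises the stimulus-evoked response: a gamma-variate rise
#' (convolved with the stimulus boxcar, then renormalised so the peak lands
#' exactly at `time_to_peak` after `onset_delay` with fractional amplitude
#' `peak_fraction`), followed by a delayed undershoot. HbO carries
#' `washout_ratio` times the HbT change so HbR falls during the response
#' (washout); in triphasic mode HbR additionally shows an early positive
#' bump of fractional size `triphasic_bump_fraction` before the washout.
#'
#' @param onset_delay s between stimulus onset and response start.
#' @param time_to_peak s from onset to the HbT peak.
#' @param peak_fraction fractional HbT at peak (e.g. 0.05 = +5%).
#' @param undershoot_fraction fractional depth of the post-stimulus
#'   undershoot.
#' @param stimulus_duration s (2 or 16 in the standard protocols).
#' @param hbr_mode `"biphasic"` or `"triphasic"`.
#' @param triphasic_bump_fraction fractional HbR amplitude of the initial
#'   positive deflection (triphasic mode only; must then be > 0).
#' @param washout_ratio dHbO / dHbT (> 1 makes dHbR negative).
#' @param shape gamma-variate shape parameter.
#' @return An `evoked_kernel_params` list.
#' @export
evoked_kernel_params <- function(onset_delay = 0, time_to_peak = 3,
                                 peak_fraction = 0.05,
                                 undershoot_fraction = 0.01,
                                 stimulus_duration = 2,
                                 hbr_mode = c("biphasic", "triphasic"),
                                 triphasic_bump_fraction = 0,
                                 washout_ratio = 1.25, shape = 3) {
  hbr_mode <- match.arg(hbr_mode)
  if (time_to_peak <= 0) abort("time_to_peak must be > 0")
  if (hbr_mode == "triphasic" && triphasic_bump_fraction <= 0)
    abort("triphasic mode requires triphasic_bump_fraction > 0")
  structure(list(onset_delay = onset_delay, time_to_peak = time_to_peak,
                 peak_fraction = peak_fraction,
                 undershoot_fraction = undershoot_fraction,
                 stimulus_duration = stimulus_duration, hbr_mode = hbr_mode,
                 triphasic_bump_fraction = triphasic_bump_fraction,
                 washout_ratio = washout_ratio, shape = shape),
            class = "evoked_kernel_params")
}

# Gamma-variate bump: unit peak at t = peak_time, zero for t <= delay.
gamma_bump <- function(t, peak_time, shape, delay = 0) {
  tt <- pmax(t - delay, 0) / (peak_time - delay)
  ifelse(tt > 0, tt^shape * exp(shape * (1 - tt)), 0)
}

# Evoked HbT kernel sampled at times t (s, relative to stimulus onset):
# gamma-variate convolved with the stimulus boxcar, time- and
# amplitude-normalised so max = 1 exactly at onset_delay + time_to_peak.
evoked_kernel <- function(t, kernel) {
  k <- kernel
  dt <- 0.01
  tg <- seq(0, (k$time_to_peak + k$stimulus_duration) * 6, by = dt)
  g <- gamma_bump(tg, k$time_to_peak, k$shape)
  nbox <- max(1, round(k$stimulus_duration / dt))
  conv <- stats::filter(c(g, numeric(nbox)), rep(1, nbox), sides = 1)
  conv <- as.numeric(conv)[seq_along(tg)]
  conv[is.na(conv)] <- 0
  i_max <- which.max(conv)
  scale_t <- k$time_to_peak / tg[i_max]
  # query on the rescaled time axis
  tq <- (t - k$onset_delay) / scale_t
  y <- approx(tg, conv / conv[i_max], xout = pmax(tq, 0), yleft = 0,
              rule = 2)$y
  y[t < k$onset_delay] <- 0
  y
}

# Post-stimulus undershoot kernel: gamma bump starting only after the main
# response (zero at and before the HbT peak, so the peak value is exact).
undershoot_kernel <- function(t, kernel) {
  k <- kernel
  delay <- k$onset_delay + k$time_to_peak + k$stimulus_duration
  # sharper than the main kernel so the undershoot resolves within a trial
  gamma_bump(t, peak_time = delay + 4, shape = 2 * k$shape, delay = delay)
}

#' Circular binary mask
#'
#' @param height,width grid size (or pass a [sim_config()] as `height`).
#' @param center `c(row, col)`; defaults to the grid centre.
#' @param radius_px radius in pixels.
#' @return Logical matrix.
#' @export
disc_mask <- function(height, width = NULL, center = NULL, radius_px = 10) {
  if (inherits(height, "sim_config")) {
    width <- height$width
    height <- height$height
  }
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius_px^2
}

#' Simulate a stimulus-evoked haemodynamic field
#'
#' Inside `active_region`, fractional HbT follows the evoked kernel summed
#' over stimulus onsets; outside, the field stays at baseline. The absolute
#' decomposition is `dHbO = washout_ratio * dHbT`,
#' `dHbR = dHbT - dHbO` (negative: washout), with an optional early positive
#' HbR bump (compensated in HbO so HbT is untouched) in triphasic mode.
#'
#' @param cfg a [sim_config()].
#' @param kernel an [evoked_kernel_params()].
#' @param active_region logical matrix `[height, width]`; default a centred
#'   disc of radius 1/5 the grid height.
#' @param stimulus_onsets onset times (s); windows
#'   `[onset, onset + stimulus_duration]` must not overlap.
#' @return A [haem_field()] in absolute mode (ground truth).
#' @export
simulate_evoked_field <- function(cfg, kernel = evoked_kernel_params(),
                                  active_region = NULL,
                                  stimulus_onsets = 5) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(active_region))
    active_region <- disc_mask(cfg, radius_px = cfg$height / 5)
  if (!all(dim(active_region) == c(cfg$height, cfg$width)))
    abort("active_region must match the simulation grid")
  stimulus_onsets <- sort(stimulus_onsets)
  if (length(stimulus_onsets) > 1 &&
      any(diff(stimulus_onsets) < kernel$stimulus_duration))
    abort("stimulus windows overlap")
  b <- baseline_state()
  nt <- round(cfg$duration * cfg$frame_rate)
  times <- frame_times(nt, cfg$frame_rate)

  resp <- numeric(nt)     # fractional HbT deviation
  bump <- numeric(nt)     # fractional HbR early bump (triphasic)
  for (on in stimulus_onsets) {
    resp <- resp + kernel$peak_fraction * evoked_kernel(times - on, kernel) -
      kernel$undershoot_fraction * undershoot_kernel(times - on, kernel)
    if (kernel$hbr_mode == "triphasic") {
      bump_k <- evoked_kernel_params(
        onset_delay = kernel$onset_delay,
        time_to_peak = max(0.4 * kernel$time_to_peak, 0.3),
        stimulus_duration = min(kernel$stimulus_duration, 1),
        shape = kernel$shape)
      bump <- bump + kernel$triphasic_bump_fraction *
        evoked_kernel(times - on, bump_k)
    }
  }

  dhbt_uM <- b$c_hbt0 * resp                 # time profile, uM
  dhbo_uM <- kernel$washout_ratio * dhbt_uM
  dhbr_uM <- dhbt_uM - dhbo_uM
  dbump_uM <- b$c_hbr0 * bump
  dhbr_uM <- dhbr_uM + dbump_uM
  dhbo_uM <- dhbo_uM - dbump_uM              # HbT unchanged by the bump

  mask <- as.numeric(active_region)
  hbo <- array(outer(mask, dhbo_uM), c(cfg$height, cfg$width, nt))
  hbr <- array(outer(mask, dhbr_uM), c(cfg$height, cfg$width, nt))
  h <- haem_field(hbo, hbr, mode = "absolute", frame_rate = cfg$frame_rate,
                  baseline = b, pixel_pitch_um = cfg$pixel_pitch_um,
                  stim_onsets = stimulus_onsets)
  attr(h, "active_region") <- active_region
  h
}

#' Spreading-depression wave parameters
#'
#' Temporal profile of fractional HbT at one location after the wave
#' arrives: a constriction dip to `dip_fraction`, a rebound overshoot to
#' `rebound_fraction`, then a prolonged undershoot at `undershoot_fraction`
#' decaying back to baseline with time constant `undershoot_decay_tau`.
#' The wave propagates radially from `origin` at `speed` (mm/min).
#'
#' @param origin `c(row, col)` pixel of the insertion site; `NULL` = grid
#'   centre.
#' @param speed propagation speed, mm/min (> 0).
#' @param dip_fraction minimum fractional HbT (< 1).
#' @param rebound_fraction rebound maximum fractional HbT.
#' @param undershoot_fraction sustained undershoot level (fractional HbT).
#' @param undershoot_decay_tau s; decay of the undershoot toward 1.0.
#' @param dip_time,dip_width,rebound_time,rebound_width,undershoot_onset
#'   shape timings (s after local wave arrival).
#' @param washout_ratio dHbO / dHbT split, as in the evoked model.
#' @return A `csd_params` list.
#' @export
csd_params <- function(origin = NULL, speed = 3, dip_fraction = 0.6,
                       rebound_fraction = 1.10, undershoot_fraction = 0.95,
                       undershoot_decay_tau = 300, dip_time = 30,
                       dip_width = 12, rebound_time = 90, rebound_width = 25,
                       undershoot_onset = 150, washout_ratio = 1.1) {
  if (speed <= 0) abort("speed must be > 0 (mm/min)")
  if (dip_fraction >= 1) abort("dip_fraction must be < 1 (a constriction)")
  structure(list(origin = origin, speed = speed, dip_fraction = dip_fraction,
                 rebound_fraction = rebound_fraction,
                 undershoot_fraction = undershoot_fraction,
                 undershoot_decay_tau = undershoot_decay_tau,
                 dip_time = dip_time, dip_width = dip_width,
                 rebound_time = rebound_time, rebound_width = rebound_width,
                 undershoot_onset = undershoot_onset,
                 washout_ratio = washout_ratio),
            class = "csd_params")
}

# CSD temporal profile at local time tau (s after wave arrival), fractional.
csd_profile <- function(tau, p) {
  dev <- -(1 - p$dip_fraction) *
    exp(-(tau - p$dip_time)^2 / (2 * p$dip_width^2)) +
    (p$rebound_fraction - 1) *
    exp(-(tau - p$rebound_time)^2 / (2 * p$rebound_width^2)) +
    (p$undershoot_fraction - 1) *
    stats::plogis((tau - p$undershoot_onset) / 20) *
    exp(-pmax(tau - p$undershoot_onset, 0) / p$undershoot_decay_tau)
  1 + ifelse(tau > 0, dev, 0)
}

#' Simulate a spreading-depression haemodynamic field
#'
#' Each pixel at distance `d` (mm) from the origin experiences the
#' dip-rebound-undershoot profile delayed by `d / speed` after the insertion
#' time.
#'
#' @param cfg a [sim_config()] (`duration` should extend well past the
#'   undershoot window of interest).
#' @param csd a [csd_params()].
#' @param t_insert electrode insertion time (s).
#' @return A [haem_field()] in absolute mode; attribute `csd_truth` carries
#'   the generating parameters and `t_insert`.
#' @export
simulate_csd_field <- function(cfg, csd = csd_params(), t_insert = 0) {
  stopifnot(inherits(cfg, "sim_config"), inherits(csd, "csd_params"))
  origin <- csd$origin %||% c((cfg$height + 1) / 2, (cfg$width + 1) / 2)
  if (origin[1] < 1 || origin[1] > cfg$height ||
      origin[2] < 1 || origin[2] > cfg$width)
    abort("CSD origin must lie within the grid")
  b <- baseline_state()
  nt <- round(cfg$duration * cfg$frame_rate)
  times <- frame_times(nt, cfg$frame_rate)
  rows <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  cols <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  dist_mm <- sqrt((rows - origin[1])^2 + (cols - origin[2])^2) *
    cfg$pixel_pitch_um / 1000
  delay_s <- dist_mm / csd$speed * 60

  frac <- array(1, c(cfg$height, cfg$width, nt))
  for (t in seq_len(nt)) {
    tau <- times[t] - t_insert - delay_s
    frac[, , t] <- csd_profile(tau, csd)
  }
  dhbt <- (frac - 1) * b$c_hbt0
  dhbo <- csd$washout_ratio * dhbt
  dhbr <- dhbt - dhbo
  h <- haem_field(dhbo, dhbr, mode = "absolute", frame_rate = cfg$frame_rate,
                  baseline = b, pixel_pitch_um = cfg$pixel_pitch_um)
  attr(h, "csd_truth") <- list(params = csd, t_insert = t_insert,
                               origin = origin)
  h
}
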
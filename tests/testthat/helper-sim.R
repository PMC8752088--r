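# Shared fixtures, built in code. The packaged optical tables are loaded
# once per test run.
.nv_cache <- new.env()

test_spectra <- function() {
  if (is.null(.nv_cache$spectra)) .nv_cache$spectra <- default_spectra()
  .nv_cache$spectra
}

# spectra whose pathlength table is constant in saturation (the fixed point
# of the path-length scaling iteration)
flat_spectra <- function() {
  sp <- test_spectra()
  pl <- sp$pathlength
  pl0 <- dplyr::left_join(
    pl[, c("wavelength_nm", "saturation")],
    dplyr::summarise(dplyr::group_by(pl, .data$wavelength_nm),
                     pathlength_cm = mean(.data$pathlength_cm)),
    by = "wavelength_nm")
  spectra_tables(sp$extinction, pl0)
}

# assemble an attenuation_series directly from an array of delta-OD values
make_atten <- function(values, wavelengths_nm, frame_rate = 5,
                       baseline_window = c(0, 1), pixel_pitch_um = 50) {
  structure(
    list(values = values, wavelengths_nm = wavelengths_nm,
         frame_rate = frame_rate, baseline_window = baseline_window,
         pixel_pitch_um = pixel_pitch_um, stim_onsets = numeric()),
    class = "attenuation_series")
}

# forward Beer-Lambert delta-OD for given concentration changes (uM) at
# fixed saturation -- independent of the unmix() code path
forward_da <- function(spectra, dhbo_uM, dhbr_uM, saturation = 0.7) {
  E <- extinction_at(spectra, c(494, 560, 575, 595))
  L <- pathlength_at(spectra, c(494, 560, 575, 595), saturation)[, 1]
  L * (E[, "eps_hbo"] * dhbo_uM * 1e-6 + E[, "eps_hbr"] * dhbr_uM * 1e-6)
}

# ROI-level fractional evoked series with iid Gaussian noise, bypassing the
# imaging chain (for trial-metric tests)
noisy_roi_series <- function(kernel, onsets, duration, frame_rate = 5,
                             noise_sd = 0.005, seed = 1) {
  cfg <- sim_config(height = 1, width = 1, frame_rate = frame_rate,
                    duration = duration, noise_sigma = 0, seed = seed)
  truth <- simulate_evoked_field(cfg, kernel,
                                 active_region = matrix(TRUE, 1, 1),
                                 stimulus_onsets = onsets)
  ser <- haem_grid_mean(haem_fractional(truth))
  set.seed(seed)
  for (cmp in c("hbt", "hbo", "hbr"))
    ser[[cmp]] <- ser[[cmp]] + rnorm(nrow(ser), sd = noise_sd)
  ser
}
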
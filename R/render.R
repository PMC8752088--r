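#' Render a reflectance stack from a ground-truth haemoglobin field
#'
#' Forward model of the imaging physics, the inverse of [unmix()]:
#' `I(lambda, t, px) = I0 * exp(-L(lambda, S) * (eps_hbo * dHbO + eps_hbr * dHbR))`
#' with optional multiplicative Gaussian noise `(1 + sigma * Z)`, seeded.
#' When `saturation_dependent` is `TRUE` the pathlength follows the true
#' instantaneous saturation `S = HbO / HbT` per pixel and frame (the regime
#' the path-length scaling refinement corrects for); when `FALSE` it is fixed
#' at the baseline saturation, making single-pass unmixing exact.
#'
#' @param truth a [haem_field()] in absolute mode (delta uM).
#' @param spectra a [spectra_tables()].
#' @param cfg a [sim_config()] supplying wavelengths, noise level and seed.
#' @param baseline a [baseline_state()].
#' @param i0 incident intensity (values must stay in \[0, 1\] for TIFF
#'   export).
#' @param saturation_dependent use the true per-sample saturation for the
#'   pathlength look-up.
#' @return A [reflectance_stack()].
#' @export
render_reflectance <- function(truth, spectra, cfg,
                               baseline = baseline_state(), i0 = 0.5,
                               saturation_dependent = TRUE) {
  stopifnot(inherits(truth, "haem_field"), inherits(spectra, "spectra_tables"),
            inherits(cfg, "sim_config"))
  if (truth$mode != "absolute")
    abort("truth must be in absolute concentration mode (delta uM)")
  wl <- cfg$wavelengths_nm
  E <- extinction_at(spectra, wl)
  d <- dim(truth$hbt)
  n <- prod(d)
  dhbo_M <- as.vector(truth$hbo) * 1e-6
  dhbr_M <- as.vector(truth$hbr) * 1e-6

  if (saturation_dependent) {
    sat <- (baseline$c_hbo0 * 1e-6 + dhbo_M) /
      pmax(baseline$c_hbt0 * 1e-6 + dhbo_M + dhbr_M, .Machine$double.eps)
    Lmat <- pathlength_at(spectra, wl, sat)           # [wl, sample]
  } else {
    Lmat <- matrix(pathlength_at(spectra, wl, baseline$s0)[, 1],
                   nrow = length(wl), ncol = n)
  }
  # attenuation per wavelength x sample
  da <- Lmat * (outer(E[, "eps_hbo"], dhbo_M) + outer(E[, "eps_hbr"], dhbr_M))
  intens <- i0 * exp(-da)
  if (cfg$noise_sigma > 0) {
    intens <- with_seed(cfg$seed, {
      intens * (1 + cfg$noise_sigma * rnorm(length(intens)))
    })
  }
  # [wl, row, col, time] -> [row, col, wl, time]
  stack_data <- aperm(array(intens, c(length(wl), d[1], d[2], d[3])),
                      c(2, 3, 1, 4))
  reflectance_stack(stack_data, wl, truth$frame_rate,
                    pixel_pitch_um = truth$pixel_pitch_um,
                    stim_onsets = truth$stim_onsets)
}
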
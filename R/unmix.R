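#' Spectral unmixing by the modified Beer-Lambert law
#'
#' Per pixel and time point, solves the linear system
#' `dA(lambda) = L(lambda, S) * (eps_hbo(lambda) * dHbO + eps_hbr(lambda) * dHbR)`
#' in the least-squares sense over the recorded wavelengths, where `L` is the
#' saturation-dependent effective pathlength. Returns the concentration
#' changes and their sum `dHbT = dHbO + dHbR`, either as delta-uM
#' (`mode = "absolute"`) or scaled by the component baselines
#' (`mode = "fractional"`, baseline = 1.0).
#'
#' With the default scalar saturation the design matrix is shared by every
#' sample and the inversion is a single matrix product; when `saturation` is
#' a per-sample array (as in the path-length scaling iteration) each sample
#' gets its own 2x2 normal-equation solve, vectorised.
#'
#' @param atten an `attenuation_series` from [compute_attenuation()].
#' @param spectra a [spectra_tables()] object covering the stack wavelengths.
#' @param baseline a [baseline_state()].
#' @param mode output scale, `"fractional"` (default) or `"absolute"`.
#' @param saturation scalar saturation for the pathlength look-up (default
#'   `baseline$s0`) or an array `[row, col, time]` of per-sample saturations.
#' @return A [haem_field()].
#' @export
unmix <- function(atten, spectra, baseline = baseline_state(),
                  mode = c("fractional", "absolute"), saturation = NULL) {
  stopifnot(inherits(atten, "attenuation_series"),
            inherits(spectra, "spectra_tables"))
  mode <- match.arg(mode)
  wl <- atten$wavelengths_nm
  if (length(wl) < 2)
    abort("at least 2 wavelengths are required to separate HbO and HbR")
  E <- extinction_at(spectra, wl)
  d <- dim(atten$values)
  n <- d[1] * d[2] * d[4]
  amat <- matrix(aperm(atten$values, c(3, 1, 2, 4)), nrow = d[3])

  if (is.null(saturation)) saturation <- baseline$s0

  if (length(saturation) == 1) {
    L <- pathlength_at(spectra, wl, saturation)[, 1]
    X <- L * E
    kap <- kappa(X, exact = TRUE)
    if (!is.finite(kap) || kap > 1e8)
      abort(sprintf(
        "wavelength set cannot separate HbO from HbR (design condition number %.3g)",
        kap))
    dc <- solve(crossprod(X), t(X) %*% amat) * 1e6   # M -> uM
    dhbo <- dc[1, ]
    dhbr <- dc[2, ]
  } else {
    if (!all(dim(saturation) == d[c(1, 2, 4)]))
      abort("per-sample saturation must be an array [row, col, time]")
    Lmat <- pathlength_at(spectra, wl, as.vector(saturation))
    a1 <- Lmat * E[, "eps_hbo"]
    a2 <- Lmat * E[, "eps_hbr"]
    s11 <- colSums(a1 * a1)
    s12 <- colSums(a1 * a2)
    s22 <- colSums(a2 * a2)
    b1 <- colSums(a1 * amat)
    b2 <- colSums(a2 * amat)
    det <- s11 * s22 - s12^2
    if (any(det <= .Machine$double.eps * s11 * s22))
      abort("wavelength set cannot separate HbO from HbR (singular design)")
    dhbo <- (s22 * b1 - s12 * b2) / det * 1e6
    dhbr <- (s11 * b2 - s12 * b1) / det * 1e6
  }

  h <- haem_field(
    hbo = array(dhbo, d[c(1, 2, 4)]),
    hbr = array(dhbr, d[c(1, 2, 4)]),
    mode = "absolute", frame_rate = atten$frame_rate, baseline = baseline,
    pixel_pitch_um = atten$pixel_pitch_um, stim_onsets = atten$stim_onsets)
  if (mode == "fractional") haem_fractional(h) else h
}

#' Path-length scaling refinement of the spectral inversion
#'
#' The single-pass inversion assumes the baseline oxygen saturation when
#' looking up pathlengths. When saturation actually moves (e.g. during a
#' spreading-depression episode) those pathlengths are wrong. This routine
#' iterates: unmix with pathlengths at the current per-sample saturation
#' estimate, update `S = HbO / (HbO + HbR)` from the recovered
#' concentrations, look the pathlengths up again — until the maximum
#' absolute change in fractional HbT between successive iterates falls below
#' `tol` or `max_iter` is reached. Saturation estimates leaving the
#' physiological range are clamped to `sat_limits` and counted.
#'
#' @inheritParams unmix
#' @param tol convergence tolerance on fractional HbT (default 1e-4).
#' @param max_iter maximum number of inversion passes (default 20).
#' @param sat_limits clamp range for the saturation estimate.
#' @return A [haem_field()] with attribute `plsa`: list of `iterations`,
#'   `converged`, `n_clamped`, `last_delta`.
#' @export
plsa_refine <- function(atten, spectra, baseline = baseline_state(),
                        tol = 1e-4, max_iter = 20,
                        mode = c("fractional", "absolute"),
                        sat_limits = c(0.05, 0.99)) {
  mode <- match.arg(mode)
  h <- unmix(atten, spectra, baseline, mode = "absolute")
  b <- baseline
  frac_prev <- (b$c_hbt0 + h$hbt) / b$c_hbt0
  it <- 1
  delta <- Inf
  n_clamped <- 0
  while (it < max_iter && delta > tol) {
    sat <- (b$c_hbo0 + h$hbo) / pmax(b$c_hbt0 + h$hbt, .Machine$double.eps)
    out_of_range <- sat < sat_limits[1] | sat > sat_limits[2]
    n_clamped <- sum(out_of_range)
    sat <- pmin(pmax(sat, sat_limits[1]), sat_limits[2])
    h <- unmix(atten, spectra, baseline, mode = "absolute", saturation = sat)
    h$saturation <- sat
    frac <- (b$c_hbt0 + h$hbt) / b$c_hbt0
    delta <- max(abs(frac - frac_prev))
    frac_prev <- frac
    it <- it + 1
  }
  converged <- delta <= tol
  if (!converged)
    warn(sprintf(
      "PLSA did not converge in %d iterations (last fractional-HbT change %.3g)",
      it, delta))
  out <- if (mode == "fractional") haem_fractional(h) else h
  attr(out, "plsa") <- list(iterations = it, converged = converged,
                            n_clamped = n_clamped, last_delta = delta)
  out
}
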
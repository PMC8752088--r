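#' Optical constants for haemoglobin spectroscopy
#'
#' A `spectra_tables` object bundles the two physics tables the spectral
#' inversion needs: molar extinction coefficients of oxy- and
#' deoxy-haemoglobin per wavelength (natural-log base, 1/(M*cm)), and the
#' effective optical pathlength per (wavelength, baseline oxygen saturation)
#' grid point (cm). Pathlengths are saturation-dependent because blood
#' absorption — and hence how deep photons travel before re-emission — changes
#' with the oxygenation of the tissue they traverse.
#'
#' @param extinction tibble with columns `wavelength_nm`, `eps_hbo`,
#'   `eps_hbr` (all positive).
#' @param pathlength tibble with columns `wavelength_nm`, `saturation`,
#'   `pathlength_cm` (positive; saturation grid must span at least
#'   \[0.3, 1.0\]).
#' @return An object of class `spectra_tables`.
#' @seealso [default_spectra()], [read_spectra()], [pathlength_at()]
#' @export
spectra_tables <- function(extinction, pathlength) {
  extinction <- tibble::as_tibble(extinction)
  pathlength <- tibble::as_tibble(pathlength)
  need_e <- c("wavelength_nm", "eps_hbo", "eps_hbr")
  need_p <- c("wavelength_nm", "saturation", "pathlength_cm")
  if (!all(need_e %in% names(extinction)))
    abort(paste("extinction table needs columns:", paste(need_e, collapse = ", ")))
  if (!all(need_p %in% names(pathlength)))
    abort(paste("pathlength table needs columns:", paste(need_p, collapse = ", ")))
  if (any(extinction$eps_hbo <= 0) || any(extinction$eps_hbr <= 0))
    abort("extinction coefficients must all be positive")
  if (any(pathlength$pathlength_cm <= 0))
    abort("pathlengths must all be positive")
  sat <- sort(unique(pathlength$saturation))
  if (min(sat) > 0.3 || max(sat) < 1.0)
    abort("pathlength saturation grid must span at least [0.3, 1.0]")
  structure(
    list(extinction = extinction, pathlength = pathlength,
         saturation_grid = sat),
    class = "spectra_tables"
  )
}

#' @export
print.spectra_tables <- function(x, ...) {
  wl <- range(x$extinction$wavelength_nm)
  cat("<spectra_tables>\n")
  cat("  extinction: ", nrow(x$extinction), " wavelengths, ",
      wl[1], "-", wl[2], " nm\n", sep = "")
  cat("  pathlength: saturation grid ",
      min(x$saturation_grid), "-", max(x$saturation_grid),
      " (", length(x$saturation_grid), " points)\n", sep = "")
  invisible(x)
}

#' Assumed baseline haemodynamic state
#'
#' The inversion expresses concentration changes relative to an assumed
#' resting state: total haemoglobin concentration `c_hbt0` (default 100 uM)
#' and oxygen saturation `s0` (default 0.70). Component baselines follow as
#' HbO0 = s0 * c_hbt0 and HbR0 = (1 - s0) * c_hbt0.
#'
#' @param c_hbt0 baseline total haemoglobin, uM (> 0).
#' @param s0 baseline oxygen saturation, fraction in (0, 1).
#' @return A `baseline_state` list with `c_hbt0`, `s0`, `c_hbo0`, `c_hbr0`.
#' @export
baseline_state <- function(c_hbt0 = 100, s0 = 0.70) {
  if (!is.numeric(c_hbt0) || length(c_hbt0) != 1 || c_hbt0 <= 0)
    abort("c_hbt0 must be a single positive number (uM)")
  if (!is.numeric(s0) || length(s0) != 1 || s0 <= 0 || s0 >= 1)
    abort("s0 must be a single number strictly between 0 and 1")
  structure(list(c_hbt0 = c_hbt0, s0 = s0,
                 c_hbo0 = s0 * c_hbt0, c_hbr0 = (1 - s0) * c_hbt0),
            class = "baseline_state")
}

#' Diffusion-approximation effective pathlength
#'
#' Two-parameter model for the mean photon pathlength of diffusely re-emitted
#' light over a semi-infinite scattering medium:
#' `L = 1 / (2 * sqrt(mua * (mua + musp)))`, with absorption
#' `mua = c_hbt0 * (S * eps_hbo + (1 - S) * eps_hbr)` set by the baseline
#' blood content at saturation `S`, and reduced scattering
#' `musp = musp_a * (lambda / 560)^(-musp_b)`. Gives a few hundred um of
#' path at green wavelengths rising towards the red, the behaviour
#' Monte-Carlo tissue models produce.
#'
#' @param wavelength_nm wavelengths (nm), must be present in `extinction`.
#' @param saturation oxygen saturation value(s) in (0, 1).
#' @param extinction extinction tibble (natural-log base).
#' @param c_hbt0 baseline total haemoglobin (uM).
#' @param musp_a reduced scattering at 560 nm (1/cm).
#' @param musp_b scattering power-law exponent.
#' @return Matrix of pathlengths (cm), wavelengths in rows, saturations in
#'   columns.
#' @export
diffusion_pathlength <- function(wavelength_nm, saturation, extinction,
                                 c_hbt0 = 100, musp_a = 17, musp_b = 1.2) {
  idx <- match(wavelength_nm, extinction$wavelength_nm)
  if (anyNA(idx))
    abort(paste("wavelengths absent from extinction table:",
                paste(wavelength_nm[is.na(idx)], collapse = ", ")))
  c_molar <- c_hbt0 * 1e-6
  musp <- musp_a * (wavelength_nm / 560)^(-musp_b)
  out <- outer(seq_along(idx), seq_along(saturation),
               function(i, j) {
                 s <- saturation[j]
                 mua <- c_molar * (s * extinction$eps_hbo[idx[i]] +
                                     (1 - s) * extinction$eps_hbr[idx[i]])
                 1 / (2 * sqrt(mua * (mua + musp[i])))
               })
  dimnames(out) <- list(wavelength_nm, saturation)
  out
}

#' Default packaged optical constants
#'
#' Loads the packaged extinction table (450-650 nm at 1 nm; see the file
#' header in `inst/extdata/extinction.tsv` for provenance) and computes the
#' default saturation-indexed pathlength grid from [diffusion_pathlength()].
#'
#' @param wavelengths_nm optionally restrict to these wavelengths (e.g. the
#'   four instrument wavelengths 494, 560, 575, 595 nm).
#' @param saturation_grid saturation grid for the pathlength table.
#' @inheritParams diffusion_pathlength
#' @return A [spectra_tables()] object.
#' @export
default_spectra <- function(wavelengths_nm = NULL,
                            saturation_grid = seq(0.05, 1.00, by = 0.01),
                            c_hbt0 = 100, musp_a = 17, musp_b = 1.2) {
  path <- system.file("extdata", "extinction.tsv", package = "neurovasc")
  ext <- tibble::as_tibble(read.delim(path, comment.char = "#"))
  if (!is.null(wavelengths_nm)) {
    keep <- match(wavelengths_nm, ext$wavelength_nm)
    if (anyNA(keep))
      abort("requested wavelengths not covered by the packaged table")
    ext <- ext[keep, ]
  }
  pl <- diffusion_pathlength(ext$wavelength_nm, saturation_grid, ext,
                             c_hbt0 = c_hbt0, musp_a = musp_a,
                             musp_b = musp_b)
  pathlength <- tibble::tibble(
    wavelength_nm = rep(ext$wavelength_nm, times = length(saturation_grid)),
    saturation = rep(saturation_grid, each = nrow(ext)),
    pathlength_cm = as.vector(pl)
  )
  spectra_tables(ext, pathlength)
}

#' Look up pathlengths at given saturations
#'
#' Exact match in wavelength (no interpolation across the wavelength grid;
#' a missing instrument wavelength is an error), linear interpolation in
#' saturation within the grid, clamped at the grid edges.
#'
#' @param spectra a [spectra_tables()] object.
#' @param wavelengths_nm wavelengths to look up.
#' @param saturation saturation value(s); recycled against wavelengths when
#'   one of the two has length 1, otherwise a matrix is returned for all
#'   combinations when `saturation` is a vector.
#' @return Matrix \[wavelength, saturation\] of pathlengths (cm).
#' @export
pathlength_at <- function(spectra, wavelengths_nm, saturation) {
  stopifnot(inherits(spectra, "spectra_tables"))
  pl <- spectra$pathlength
  sat_grid <- spectra$saturation_grid
  s_cl <- pmin(pmax(saturation, min(sat_grid)), max(sat_grid))
  out <- matrix(NA_real_, length(wavelengths_nm), length(saturation))
  for (i in seq_along(wavelengths_nm)) {
    rows <- pl$wavelength_nm == wavelengths_nm[i]
    if (!any(rows))
      abort(paste0("wavelength ", wavelengths_nm[i],
                   " nm not in the pathlength table (exact match required)"))
    sub <- pl[rows, ]
    out[i, ] <- approx(sub$saturation, sub$pathlength_cm, xout = s_cl,
                       rule = 2)$y
  }
  dimnames(out) <- list(wavelengths_nm, NULL)
  out
}

#' Extinction coefficients at given wavelengths
#' @inheritParams pathlength_at
#' @return Matrix with columns `eps_hbo`, `eps_hbr`, one row per wavelength.
#' @export
extinction_at <- function(spectra, wavelengths_nm) {
  stopifnot(inherits(spectra, "spectra_tables"))
  idx <- match(wavelengths_nm, spectra$extinction$wavelength_nm)
  if (anyNA(idx))
    abort(paste("wavelengths absent from extinction table:",
                paste(wavelengths_nm[is.na(idx)], collapse = ", ")))
  cbind(eps_hbo = spectra$extinction$eps_hbo[idx],
        eps_hbr = spectra$extinction$eps_hbr[idx])
}

#' Read optical-constant tables from TSV files
#'
#' @param extinction_path TSV with columns wavelength_nm, eps_hbo, eps_hbr.
#' @param pathlength_path TSV with columns wavelength_nm, saturation,
#'   pathlength_cm.
#' @return A [spectra_tables()] object.
#' @export
read_spectra <- function(extinction_path, pathlength_path) {
  spectra_tables(
    read.delim(extinction_path, comment.char = "#"),
    read.delim(pathlength_path, comment.char = "#")
  )
}

#' Write optical-constant tables as TSV files
#'
#' @param spectra a [spectra_tables()] object.
#' @param dir output directory; writes `extinction.tsv` and
#'   `pathlength.tsv`.
#' @return Invisibly, the two paths written.
#' @export
write_spectra <- function(spectra, dir) {
  stopifnot(inherits(spectra, "spectra_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "extinction.tsv")
  p2 <- file.path(dir, "pathlength.tsv")
  write.table(spectra$extinction, p1, sep = "\t", row.names = FALSE,
              quote = FALSE)
  write.table(spectra$pathlength, p2, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(c(p1, p2))
}
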
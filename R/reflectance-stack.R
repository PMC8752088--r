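#' Multi-wavelength reflectance image stack
#'
#' Raw input of the spectroscopy pipeline: one cortical image per wavelength
#' per time point. Stored as a 4-D array `[row, col, wavelength, time]`, with
#' acquisition metadata attached.
#'
#' @param data numeric 4-D array `[row, col, wavelength, time]` of detected
#'   intensities.
#' @param wavelengths_nm illumination wavelengths, one per array slice.
#' @param frame_rate imaging frame rate in Hz (full multi-wavelength frames
#'   per second).
#' @param pixel_pitch_um physical size of one pixel, um.
#' @param stim_onsets stimulus onset times in seconds, if any.
#' @return An object of class `reflectance_stack`.
#' @export
reflectance_stack <- function(data, wavelengths_nm, frame_rate,
                              pixel_pitch_um = NA_real_,
                              stim_onsets = numeric()) {
  if (length(dim(data)) != 4)
    abort("data must be a 4-D array [row, col, wavelength, time]")
  if (dim(data)[3] != length(wavelengths_nm))
    abort("third array dimension must match length(wavelengths_nm)")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    abort("frame_rate must be positive (Hz)")
  structure(
    list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
         frame_rate = frame_rate, pixel_pitch_um = pixel_pitch_um,
         stim_onsets = as.numeric(stim_onsets)),
    class = "reflectance_stack"
  )
}

#' @export
print.reflectance_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<reflectance_stack> ", d[1], "x", d[2], " px, ",
      d[3], " wavelengths (", paste(x$wavelengths_nm, collapse = ", "),
      " nm), ", d[4], " frames @ ", x$frame_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Frame times of a stack or field
#'
#' Frame `t` is timestamped `(t - 1) / frame_rate` seconds.
#' @param n_frames number of frames.
#' @param frame_rate Hz.
#' @return Numeric vector of times (s).
#' @export
frame_times <- function(n_frames, frame_rate) (seq_len(n_frames) - 1) / frame_rate

#' Write a reflectance stack as multi-frame TIFF with JSON sidecar
#'
#' Frames are ordered time-major, wavelength-minor (frame index
#' `(t - 1) * n_wavelengths + w`), recorded in the sidecar along with
#' wavelengths, frame rate, pixel pitch and stimulus onsets. Intensities are
#' stored as 32-bit float; values must lie in \[0, 1\].
#'
#' @param stack a [reflectance_stack()].
#' @param path output `.tif` path; the sidecar is written alongside as
#'   `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "reflectance_stack"))
  d <- dim(stack$data)
  frames <- vector("list", d[3] * d[4])
  k <- 1
  for (t in seq_len(d[4])) {
    for (w in seq_len(d[3])) {
      frames[[k]] <- stack$data[, , w, t]
      k <- k + 1
    }
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  sidecar <- list(
    format = "reflectance_stack",
    frame_order = "time-major, wavelength-minor",
    wavelengths_nm = stack$wavelengths_nm,
    frame_rate_hz = stack$frame_rate,
    pixel_pitch_um = stack$pixel_pitch_um,
    stim_onsets_s = stack$stim_onsets,
    optical_density = "natural log"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a reflectance stack written by [write_stack_tiff()]
#'
#' @param path `.tif` path with `<path>.json` sidecar alongside.
#' @return A [reflectance_stack()].
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  nw <- length(meta$wavelengths_nm)
  nt <- length(frames) / nw
  if (nt != round(nt))
    abort("frame count is not a multiple of the sidecar wavelength count")
  d <- dim(frames[[1]])
  data <- array(NA_real_, c(d[1], d[2], nw, nt))
  k <- 1
  for (t in seq_len(nt)) {
    for (w in seq_len(nw)) {
      data[, , w, t] <- frames[[k]]
      k <- k + 1
    }
  }
  reflectance_stack(data, meta$wavelengths_nm, meta$frame_rate_hz,
                    pixel_pitch_um = meta$pixel_pitch_um %||% NA_real_,
                    stim_onsets = meta$stim_onsets_s %||% numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
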
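#' Convert detected reflectance to optical-density attenuation
#'
#' Attenuation is the natural-log optical density of each frame relative to
#' the per-pixel, per-wavelength mean over a baseline window:
#' `dA(lambda, t, px) = -ln( I(lambda, t, px) / mean_baseline I(lambda, ., px) )`.
#' A frame identical to its baseline mean therefore has attenuation exactly
#' zero everywhere.
#'
#' @param stack a [reflectance_stack()] with strictly positive intensities.
#' @param baseline_window numeric `c(t_start, t_end)` in seconds; defaults to
#'   the 4 s preceding the first stimulus onset when the stack carries onsets.
#' @return An `attenuation_series`: list with `values` (array
#'   `[row, col, wavelength, time]`), `wavelengths_nm`, `frame_rate`,
#'   `baseline_window`, `pixel_pitch_um`, `stim_onsets`.
#' @export
compute_attenuation <- function(stack, baseline_window = NULL) {
  stopifnot(inherits(stack, "reflectance_stack"))
  d <- dim(stack$data)
  times <- frame_times(d[4], stack$frame_rate)
  if (is.null(baseline_window)) {
    if (length(stack$stim_onsets) == 0)
      abort("no baseline_window given and the stack has no stimulus onsets")
    baseline_window <- c(max(0, stack$stim_onsets[1] - 4), stack$stim_onsets[1])
  }
  if (baseline_window[1] < times[1] - 1e-9 ||
      baseline_window[2] > times[d[4]] + 1e-9)
    abort("baseline_window must lie within the recording")
  base_idx <- which(times >= baseline_window[1] - 1e-9 &
                      times <= baseline_window[2] + 1e-9)
  if (length(base_idx) < 2)
    abort("baseline window must cover at least 2 frames")
  bad <- stack$data <= 0
  if (any(bad)) {
    bad_t <- which(apply(bad, 4, any))
    abort(sprintf(
      "non-positive intensities: %d pixels affected, first at frame %d",
      sum(bad), bad_t[1]))
  }
  baseline <- apply(stack$data[, , , base_idx, drop = FALSE], c(1, 2, 3), mean)
  values <- -log(stack$data / as.vector(baseline))
  structure(
    list(values = values, wavelengths_nm = stack$wavelengths_nm,
         frame_rate = stack$frame_rate, baseline_window = baseline_window,
         pixel_pitch_um = stack$pixel_pitch_um,
         stim_onsets = stack$stim_onsets),
    class = "attenuation_series"
  )
}

#' @export
print.attenuation_series <- function(x, ...) {
  d <- dim(x$values)
  cat("<attenuation_series> ", d[1], "x", d[2], " px, ", d[3],
      " wavelengths, ", d[4], " frames; baseline [",
      x$baseline_window[1], ", ", x$baseline_window[2], "] s\n", sep = "")
  invisible(x)
}
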
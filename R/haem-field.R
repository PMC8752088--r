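#' Per-pixel haemoglobin concentration field
#'
#' Container for HbT/HbO/HbR image time series. Two modes:
#' `"absolute"` stores concentration *changes* from baseline in uM (so
#' `hbt = hbo + hbr` exactly); `"fractional"` stores each component divided
#' by its own baseline concentration (so baseline = 1.0, and HbO/HbR use
#' component baselines `s0 * c_hbt0` and `(1 - s0) * c_hbt0`).
#'
#' @param hbo,hbr,hbt numeric arrays `[row, col, time]`.
#' @param mode `"absolute"` (delta uM) or `"fractional"`.
#' @param frame_rate Hz.
#' @param baseline a [baseline_state()].
#' @param pixel_pitch_um pixel size, um.
#' @param saturation optional per-sample oxygen-saturation array
#'   `[row, col, time]` (ground truth or PLSA estimate).
#' @param stim_onsets stimulus onset times (s).
#' @return An object of class `haem_field`.
#' @export
haem_field <- function(hbo, hbr, hbt = NULL,
                       mode = c("absolute", "fractional"),
                       frame_rate = 1, baseline = baseline_state(),
                       pixel_pitch_um = NA_real_, saturation = NULL,
                       stim_onsets = numeric()) {
  mode <- match.arg(mode)
  if (is.null(hbt)) {
    if (mode != "absolute")
      abort("hbt can only be derived as hbo + hbr in absolute mode")
    hbt <- hbo + hbr
  }
  stopifnot(identical(dim(hbo), dim(hbr)), identical(dim(hbo), dim(hbt)))
  structure(
    list(hbo = hbo, hbr = hbr, hbt = hbt, mode = mode,
         frame_rate = frame_rate, baseline = baseline,
         pixel_pitch_um = pixel_pitch_um, saturation = saturation,
         stim_onsets = as.numeric(stim_onsets)),
    class = "haem_field"
  )
}

#' @export
print.haem_field <- function(x, ...) {
  d <- dim(x$hbt)
  cat("<haem_field> ", d[1], "x", d[2], " px, ", d[3], " frames @ ",
      x$frame_rate, " Hz, mode = ", x$mode, "\n", sep = "")
  invisible(x)
}

#' Convert a haem_field between absolute and fractional modes
#'
#' Fractional HbT is `(c_hbt0 + dHbT) / c_hbt0`, and likewise per component
#' with its own baseline; the inverse recovers the delta-uM values.
#'
#' @param h a [haem_field()].
#' @return A [haem_field()] in the requested mode (a no-op if already there).
#' @export
haem_fractional <- function(h) {
  stopifnot(inherits(h, "haem_field"))
  if (h$mode == "fractional") return(h)
  b <- h$baseline
  haem_field(hbo = (b$c_hbo0 + h$hbo) / b$c_hbo0,
             hbr = (b$c_hbr0 + h$hbr) / b$c_hbr0,
             hbt = (b$c_hbt0 + h$hbt) / b$c_hbt0,
             mode = "fractional", frame_rate = h$frame_rate,
             baseline = b, pixel_pitch_um = h$pixel_pitch_um,
             saturation = h$saturation, stim_onsets = h$stim_onsets)
}

#' @rdname haem_fractional
#' @export
haem_absolute <- function(h) {
  stopifnot(inherits(h, "haem_field"))
  if (h$mode == "absolute") return(h)
  b <- h$baseline
  haem_field(hbo = h$hbo * b$c_hbo0 - b$c_hbo0,
             hbr = h$hbr * b$c_hbr0 - b$c_hbr0,
             hbt = h$hbt * b$c_hbt0 - b$c_hbt0,
             mode = "absolute", frame_rate = h$frame_rate,
             baseline = b, pixel_pitch_um = h$pixel_pitch_um,
             saturation = h$saturation, stim_onsets = h$stim_onsets)
}

#' Tidy a haem_field into a long tibble
#'
#' @param x a [haem_field()].
#' @param ... unused.
#' @return Tibble with columns `row`, `col`, `time_s`, `component`, `value`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.haem_field <- function(x, ...) {
  d <- dim(x$hbt)
  times <- frame_times(d[3], x$frame_rate)
  grid <- tidyr::expand_grid(
    time_s = times, col = seq_len(d[2]), row = seq_len(d[1]))
  dplyr::bind_rows(
    dplyr::mutate(grid, component = "hbt",
                  value = as.vector(x$hbt)),
    dplyr::mutate(grid, component = "hbo",
                  value = as.vector(x$hbo)),
    dplyr::mutate(grid, component = "hbr",
                  value = as.vector(x$hbr))
  )[, c("row", "col", "time_s", "component", "value")]
}

#' Grid-mean ROI series over all pixels
#'
#' Convenience equal to [extract_timeseries()] with a full-grid mask.
#' @param h a [haem_field()].
#' @return Tibble `time_s`, `hbt`, `hbo`, `hbr`.
#' @export
haem_grid_mean <- function(h) {
  stopifnot(inherits(h, "haem_field"))
  tibble::tibble(
    time_s = frame_times(dim(h$hbt)[3], h$frame_rate),
    hbt = apply(h$hbt, 3, mean),
    hbo = apply(h$hbo, 3, mean),
    hbr = apply(h$hbr, 3, mean)
  )
}

#' Write an ROI-level haemoglobin series to CSV
#'
#' @param series tibble with columns `time_s`, `hbt`, `hbo`, `hbr`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_roi_series <- function(series, path) {
  utils::write.csv(series[, c("time_s", "hbt", "hbo", "hbr")], path,
                   row.names = FALSE)
  invisible(path)
}
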
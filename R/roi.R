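#' Stimulus activation map
#'
#' Per-pixel mean fractional HbT over the stimulus window minus the mean
#' over the baseline window: the spatial footprint of the evoked response.
#'
#' @param h a [haem_field()] (converted to fractional mode internally).
#' @param stim_window,baseline_window `c(t0, t1)` in seconds; must lie
#'   within the recording and not overlap.
#' @return An `activation_map`: matrix of per-pixel changes with attributes
#'   `stim_window`, `baseline_window`, `pixel_pitch_um`.
#' @export
activation_map <- function(h, stim_window, baseline_window) {
  stopifnot(inherits(h, "haem_field"))
  h <- haem_fractional(h)
  times <- frame_times(dim(h$hbt)[3], h$frame_rate)
  i_stim <- window_index(times, stim_window, "stim_window")
  i_base <- window_index(times, baseline_window, "baseline_window")
  if (length(intersect(i_stim, i_base)) > 0)
    abort("stim_window and baseline_window overlap")
  m <- apply(h$hbt[, , i_stim, drop = FALSE], c(1, 2), mean) -
    apply(h$hbt[, , i_base, drop = FALSE], c(1, 2), mean)
  structure(m, class = c("activation_map", "matrix"),
            stim_window = stim_window, baseline_window = baseline_window,
            pixel_pitch_um = h$pixel_pitch_um)
}

#' Session-averaged activation map over a trial set
#'
#' Computes one [activation_map()] per stimulation trial — stimulus and
#' baseline windows placed relative to each onset — and averages them,
#' reducing pixel noise by the square root of the trial count. This is the
#' map a whole stimulation session provides for ROI selection.
#'
#' @param h a pixel-level [haem_field()].
#' @param trials a [trial_set()].
#' @param stim_offsets `c(from, to)` s relative to onset for the stimulus
#'   window; default just after onset to stimulus end + 3 s (the response
#'   peak).
#' @param base_offsets `c(from, to)` s relative to onset for the baseline
#'   window; default the trial pre-window, ending just before onset.
#' @return An `activation_map` (the across-trial mean).
#' @export
trial_activation_map <- function(h, trials,
                                 stim_offsets = c(0.5, trials$stim_duration + 3),
                                 base_offsets = c(-trials$pre_window, -0.5)) {
  stopifnot(inherits(trials, "trial_set"))
  maps <- lapply(trials$onsets, function(on)
    activation_map(h, on + stim_offsets, on + base_offsets))
  out <- Reduce(`+`, lapply(maps, unclass)) / length(maps)
  structure(out, class = c("activation_map", "matrix"),
            stim_window = stim_offsets, baseline_window = base_offsets,
            pixel_pitch_um = h$pixel_pitch_um, n_trials = trials$n_trials)
}

#' Automated region of interest from an activation map
#'
#' Thresholds the map at its spatial mean plus `k_sd` spatial standard
#' deviations (default 1.5), then keeps the largest 8-connected component —
#' the area of cortex with the largest haemodynamic response.
#'
#' @param map an [activation_map()] (or plain numeric matrix).
#' @param k_sd threshold multiplier (default 1.5).
#' @return An `roi_mask`: logical matrix with attributes `k_sd`,
#'   `provenance = "auto"`.
#' @export
auto_roi <- function(map, k_sd = 1.5) {
  m <- unclass(map)
  if (!all(is.finite(m))) abort("activation map must be finite")
  thr <- mean(m) + k_sd * sd(m)
  above <- m > thr
  if (!any(above))
    abort("no pixels exceed the ROI threshold; lower k_sd or inspect the data")
  labels <- EBImage::bwlabel(above)
  counts <- tabulate(labels[labels > 0])
  mask <- labels == which.max(counts)
  structure(mask, class = c("roi_mask", "matrix"), k_sd = k_sd,
            provenance = "auto", threshold = thr)
}

#' Wrap a user-drawn binary raster as an ROI mask
#'
#' @param mask logical (or 0/1 numeric) matrix on the imaging pixel grid.
#' @return An `roi_mask` with `provenance = "user"`.
#' @export
user_roi <- function(mask) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!any(mask)) abort("user mask is empty")
  structure(mask, class = c("roi_mask", "matrix"), k_sd = NA_real_,
            provenance = "user")
}

#' Extract the ROI-mean haemoglobin time series
#'
#' Unweighted mean over mask pixels, per time point and component.
#'
#' @param h a pixel-level [haem_field()].
#' @param roi an `roi_mask` (or logical matrix) matching the grid.
#' @return Tibble with columns `time_s`, `hbt`, `hbo`, `hbr` in the mode of
#'   `h`.
#' @export
extract_timeseries <- function(h, roi) {
  stopifnot(inherits(h, "haem_field"))
  mask <- matrix(as.logical(roi), nrow(roi), ncol(roi))
  d <- dim(h$hbt)
  if (!all(dim(mask) == d[1:2]))
    abort("mask dimensions do not match the imaging grid")
  if (!any(mask)) abort("ROI mask is empty")
  idx <- which(mask)
  flat <- function(a) {
    m <- matrix(a, d[1] * d[2], d[3])
    colMeans(m[idx, , drop = FALSE])
  }
  tibble::tibble(time_s = frame_times(d[3], h$frame_rate),
                 hbt = flat(h$hbt), hbo = flat(h$hbo), hbr = flat(h$hbr))
}

#' Jaccard overlap between two masks
#'
#' @param a,b logical matrices of equal size.
#' @return Intersection over union (0 when both empty).
#' @export
jaccard <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Read / write binary masks as single-frame TIFF rasters
#'
#' @param mask an `roi_mask` or logical matrix.
#' @param path `.tif` path.
#' @return `write_mask`: invisibly `path`; `read_mask`: an `roi_mask` with
#'   `provenance = "user"`.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  user_roi(m > 0.5)
}
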
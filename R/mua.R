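#' Zero-phase high-pass filter of an electrode recording
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (zero phase), removing DC, drift and low-frequency field potentials so
#' only the spiking band remains.
#'
#' @param rec an [electrode_recording()].
#' @param cutoff high-pass corner frequency, Hz (default 500; must be below
#'   Nyquist).
#' @param order filter order (default 4).
#' @return An [electrode_recording()] of the filtered traces.
#' @export
highpass <- function(rec, cutoff = 500, order = 4) {
  stopifnot(inherits(rec, "electrode_recording"))
  nyq <- rec$sampling_rate / 2
  if (cutoff >= nyq)
    abort(sprintf("cutoff (%g Hz) must be below Nyquist (%g Hz)", cutoff, nyq))
  bf <- signal::butter(order, cutoff / nyq, type = "high")
  out <- apply(rec$traces, 2, function(x) signal::filtfilt(bf, x))
  electrode_recording(out, rec$sampling_rate, rec$spacing_um)
}

#' Bin supra-threshold multi-unit events
#'
#' Implements the standard multi-unit counting rule: a per-channel threshold
#' at the baseline mean plus `k` baseline SDs of the *filtered trace*
#' (default k = 1.5), events counted per `bin_width` bin (default 100 ms),
#' and counts expressed as fractional change from the mean baseline-bin
#' count. An event is an upward crossing of the threshold (a sample below
#' followed by a sample at/above it), so one spike contributes one count
#' regardless of its width; set `count = "samples"` for the alternative
#' supra-threshold-sample rule, and `rectify = TRUE` to also count
#' downward crossings of the mirrored threshold below the mean.
#'
#' @param rec a filtered [electrode_recording()] (see [highpass()]).
#' @param baseline_window `c(t0, t1)` s used for the mean/SD and for the
#'   baseline bin count; must cover at least 10 bins.
#' @param bin_width bin width in seconds (default 0.1).
#' @param k threshold multiplier (default 1.5).
#' @param count `"crossings"` (default) or `"samples"`.
#' @param rectify also count events on the negative side.
#' @return Tibble: `bin_start_s`, `channel`, `count`, `fractional`.
#'   Attributes: `thresholds` (per channel), `bin_width`, `baseline_window`,
#'   `baseline_mean_count` (per channel), `sampling_rate`.
#' @export
bin_threshold <- function(rec, baseline_window, bin_width = 0.1, k = 1.5,
                          count = c("crossings", "samples"),
                          rectify = FALSE) {
  stopifnot(inherits(rec, "electrode_recording"))
  count <- match.arg(count)
  fs <- rec$sampling_rate
  n <- nrow(rec$traces)
  times <- (seq_len(n) - 1) / fs
  i_base <- window_index(times, baseline_window, "baseline_window")
  if (diff(baseline_window) < 10 * bin_width)
    abort("baseline_window must cover at least 10 bins")

  n_bins <- floor(n / (bin_width * fs))
  bin_of <- pmin(floor(times / bin_width) + 1, n_bins)
  bin_start <- (seq_len(n_bins) - 1) * bin_width
  base_bins <- which(bin_start >= baseline_window[1] - 1e-9 &
                       bin_start + bin_width <= baseline_window[2] + 1e-9)

  nch <- ncol(rec$traces)
  counts <- matrix(0L, n_bins, nch)
  thresholds <- numeric(nch)
  for (ch in seq_len(nch)) {
    x <- rec$traces[, ch]
    mu <- mean(x[i_base])
    sdv <- sd(x[i_base])
    if (sdv == 0)
      abort(sprintf("channel %d has zero baseline SD (degenerate trace)", ch))
    thr <- mu + k * sdv
    thresholds[ch] <- thr
    if (count == "crossings") {
      ev <- which(x[-1] >= thr & x[-n] < thr) + 1
      if (rectify) {
        thr_lo <- mu - k * sdv
        ev <- sort(c(ev, which(x[-1] <= thr_lo & x[-n] > thr_lo) + 1))
      }
      tab <- tabulate(bin_of[ev], nbins = n_bins)
    } else {
      above <- x >= thr
      if (rectify) above <- above | x <= mu - k * sdv
      tab <- tabulate(bin_of[above], nbins = n_bins)
    }
    counts[, ch] <- tab
  }
  base_mean <- colMeans(counts[base_bins, , drop = FALSE])
  frac <- sweep(counts, 2, ifelse(base_mean > 0, base_mean, NA_real_), "/")

  out <- tibble::tibble(
    bin_start_s = rep(bin_start, times = nch),
    channel = rep(seq_len(nch), each = n_bins),
    count = as.integer(counts),
    fractional = as.vector(frac)
  )
  attr(out, "thresholds") <- thresholds
  attr(out, "bin_width") <- bin_width
  attr(out, "baseline_window") <- baseline_window
  attr(out, "baseline_mean_count") <- base_mean
  attr(out, "sampling_rate") <- fs
  out
}

#' Select a depth range of channels from a binned MUA table
#'
#' Returns the selected channel block in original order. Defaults mirror the
#' standard probe layout: 12 channels covering the cortical depth for
#' analysis; channels 4-8 for the heat-map export. Because fractional
#' normalisation is per channel, selection and normalisation commute.
#'
#' @param mua tibble from [bin_threshold()].
#' @param channels integer channel indices to keep.
#' @return The subset tibble (attributes subset accordingly).
#' @export
depth_select <- function(mua, channels) {
  all_ch <- sort(unique(mua$channel))
  if (!all(channels %in% all_ch))
    abort("channel indices out of range")
  out <- dplyr::filter(mua, .data$channel %in% channels)
  for (a in c("thresholds", "baseline_mean_count")) {
    v <- attr(mua, a)
    if (!is.null(v)) attr(out, a) <- v[channels]
  }
  for (a in c("bin_width", "baseline_window", "sampling_rate"))
    attr(out, a) <- attr(mua, a)
  out
}

#' Matrix (channel x bin) view of a binned MUA table
#'
#' @param mua tibble from [bin_threshold()].
#' @param value `"fractional"` or `"count"`.
#' @return Numeric matrix, channels in rows (named), bins in columns.
#' @export
mua_matrix <- function(mua, value = c("fractional", "count")) {
  value <- match.arg(value)
  wide <- tidyr::pivot_wider(mua[, c("bin_start_s", "channel", value)],
                             names_from = "bin_start_s",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$channel
  m
}

#' Write a binned MUA table to CSV
#' @param mua tibble from [bin_threshold()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_mua_csv <- function(mua, path) {
  utils::write.csv(mua[, c("bin_start_s", "channel", "count", "fractional")],
                   path, row.names = FALSE)
  invisible(path)
}
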
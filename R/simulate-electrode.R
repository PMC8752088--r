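#' Multichannel extracellular recording
#'
#' @param traces numeric matrix `[sample, channel]` of voltages (arbitrary
#'   units).
#' @param sampling_rate Hz (> 1 kHz).
#' @param spacing_um inter-channel spacing along the probe (um).
#' @return An `electrode_recording` object.
#' @export
electrode_recording <- function(traces, sampling_rate, spacing_um = 100) {
  traces <- as.matrix(traces)
  if (!is.numeric(sampling_rate) || sampling_rate <= 1000)
    abort("sampling_rate must exceed 1 kHz")
  structure(list(traces = traces, sampling_rate = sampling_rate,
                 spacing_um = spacing_um),
            class = "electrode_recording")
}

#' @export
print.electrode_recording <- function(x, ...) {
  cat("<electrode_recording> ", ncol(x$traces), " channels x ",
      nrow(x$traces), " samples @ ", x$sampling_rate, " Hz (",
      round(nrow(x$traces) / x$sampling_rate, 2), " s)\n", sep = "")
  invisible(x)
}

#' Neural simulation parameters
#'
#' Defaults describe a high signal-to-noise multi-unit recording: 10
#' events/s per channel at baseline with spike peaks 50x the noise SD. In
#' this regime the baseline-trace SD is dominated by spiking, so the
#' standard counting rule (threshold at 1.5 SD above the baseline mean of
#' the filtered trace) sits ~5 noise-SDs above the noise floor: level
#' crossings are then almost all spike-driven and counts scale with the
#' underlying event rate. At lower SNR the same rule counts mostly noise
#' crossings and fractional MUA no longer tracks rate.
#'
#' @param n_channels number of probe channels (default 16).
#' @param channel_spacing_um probe spacing (default 100 um).
#' @param sampling_rate Hz (default 25 kHz).
#' @param baseline_rate baseline event rate per channel (events/s).
#' @param evoked_gain multiplicative rate factor during stimulus windows
#'   (>= 0).
#' @param spike_amplitude_sd_ratio spike peak over noise SD.
#' @param spike_width_ms full width of the biphasic spike waveform (ms).
#' @return A `neural_sim_params` list.
#' @export
neural_sim_params <- function(n_channels = 16, channel_spacing_um = 100,
                              sampling_rate = 25000, baseline_rate = 10,
                              evoked_gain = 2,
                              spike_amplitude_sd_ratio = 50,
                              spike_width_ms = 1.2) {
  if (n_channels < 1) abort("n_channels must be >= 1")
  if (evoked_gain < 0) abort("evoked_gain must be >= 0")
  structure(list(n_channels = n_channels,
                 channel_spacing_um = channel_spacing_um,
                 sampling_rate = sampling_rate,
                 baseline_rate = baseline_rate, evoked_gain = evoked_gain,
                 spike_amplitude_sd_ratio = spike_amplitude_sd_ratio,
                 spike_width_ms = spike_width_ms),
            class = "neural_sim_params")
}

# Stereotyped biphasic spike: Gaussian-derivative pulse (one positive then
# one negative lobe, zero mean, little energy below the spiking band so the
# high-pass filter barely reshapes it), peak amplitude 1. width_ms is the
# full extent (~6 sigma).
spike_waveform <- function(sampling_rate, width_ms) {
  sigma <- width_ms / 1000 / 6
  tt <- seq(-3 * sigma, 3 * sigma, by = 1 / sampling_rate)
  w <- -tt * exp(-tt^2 / (2 * sigma^2))
  w / max(w)
}

#' Simulate a multichannel spike-bearing voltage recording
#'
#' Each channel carries unit-SD Gaussian background noise plus stereotyped
#' biphasic spikes at Poisson event times: rate `baseline_rate` outside
#' stimulus windows and `baseline_rate * evoked_gain` inside them. Ground
#' truth event times are returned alongside the traces.
#'
#' @param duration recording length (s).
#' @param params a [neural_sim_params()].
#' @param stimulus_onsets stimulus onset times (s).
#' @param stimulus_duration stimulus length (s).
#' @param seed integer; fixes all draws.
#' @return List with `recording` (an [electrode_recording()]) and `events`
#'   (tibble `channel`, `time_s`).
#' @export
simulate_electrode <- function(duration, params = neural_sim_params(),
                               stimulus_onsets = numeric(),
                               stimulus_duration = 2, seed = 1L) {
  stopifnot(inherits(params, "neural_sim_params"))
  fs <- params$sampling_rate
  if (fs < 4 / (params$spike_width_ms / 1000))
    abort("sampling_rate is below twice the spike bandwidth")
  n <- round(duration * fs)
  wave <- spike_waveform(fs, params$spike_width_ms) *
    params$spike_amplitude_sd_ratio
  nw <- length(wave)

  with_seed(seed, {
    traces <- matrix(rnorm(n * params$n_channels), n, params$n_channels)
    ev_ch <- list()
    for (ch in seq_len(params$n_channels)) {
      n_base <- rpois(1, params$baseline_rate * duration)
      t_ev <- runif(n_base, 0, duration)
      in_stim <- rep(FALSE, n_base)
      for (on in stimulus_onsets)
        in_stim <- in_stim | (t_ev >= on & t_ev < on + stimulus_duration)
      g <- params$evoked_gain
      if (g < 1) {
        keep <- !in_stim | runif(n_base) < g
        t_ev <- t_ev[keep]
      } else if (g > 1) {
        for (on in stimulus_onsets) {
          n_extra <- rpois(1, (g - 1) * params$baseline_rate *
                             stimulus_duration)
          t_ev <- c(t_ev, runif(n_extra, on,
                                min(on + stimulus_duration, duration)))
        }
      }
      t_ev <- sort(t_ev)
      for (te in t_ev) {
        i0 <- round(te * fs) + 1
        idx <- i0:min(i0 + nw - 1, n)
        traces[idx, ch] <- traces[idx, ch] + wave[seq_along(idx)]
      }
      ev_ch[[ch]] <- t_ev
    }
    events <- tibble::tibble(
      channel = rep(seq_along(ev_ch), lengths(ev_ch)),
      time_s = unlist(ev_ch)
    )
    list(recording = electrode_recording(traces, fs,
                                         params$channel_spacing_um),
         events = events)
  })
}

#' Write an electrode recording as flat binary + JSON sidecar
#'
#' Voltages are stored as little-endian float64, channel-major (all samples
#' of channel 1, then channel 2, ...), with metadata in `<path>.json`.
#'
#' @param rec an [electrode_recording()].
#' @param path output `.bin` path.
#' @return Invisibly, `path`.
#' @export
write_electrode_bin <- function(rec, path) {
  stopifnot(inherits(rec, "electrode_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$traces), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(format = "electrode_recording", dtype = "float64le",
         order = "channel-major", n_samples = nrow(rec$traces),
         n_channels = ncol(rec$traces), sampling_rate_hz = rec$sampling_rate,
         channel_spacing_um = rec$spacing_um),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an electrode recording written by [write_electrode_bin()]
#' @param path `.bin` path with `<path>.json` sidecar.
#' @return An [electrode_recording()].
#' @export
read_electrode_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = meta$n_samples * meta$n_channels,
               size = 8, endian = "little")
  electrode_recording(matrix(v, meta$n_samples, meta$n_channels),
                      meta$sampling_rate_hz, meta$channel_spacing_um)
}
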
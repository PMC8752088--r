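#' Trial structure of a stimulation experiment
#'
#' @param onsets stimulus onset times (s), sorted internally.
#' @param pre_window s of baseline before each onset (default 4).
#' @param post_window s analysed after each onset.
#' @param stim_duration stimulus length (s); the standard protocols use 2 s
#'   (30 trials) or 16 s (15 trials).
#' @return A `trial_set` list.
#' @export
trial_set <- function(onsets, pre_window = 4, post_window = NULL,
                      stim_duration = 2) {
  onsets <- sort(as.numeric(onsets))
  if (is.null(post_window)) post_window <- stim_duration + 13
  if (length(onsets) > 1 && any(diff(onsets) < pre_window + post_window - 1e-9))
    abort("trials overlap within their pre + post windows")
  structure(list(onsets = onsets, pre_window = pre_window,
                 post_window = post_window, stim_duration = stim_duration,
                 n_trials = length(onsets)),
            class = "trial_set")
}

#' Trial-average an ROI haemoglobin series
#'
#' Cuts the series into per-trial epochs `[onset - pre, onset + post]`,
#' re-baselines each epoch to its own pre-window mean (so every trial starts
#' at 1.0), and averages point-wise across trials with the SEM.
#'
#' @param series tibble with `time_s` plus component columns (`hbt`, `hbo`,
#'   `hbr`), fractional scale.
#' @param trials a [trial_set()].
#' @return Long tibble: `time_rel_s` (s relative to onset), `component`,
#'   `mean`, `sem` (`NA` for a single trial), `n_trials`.
#' @export
trial_average <- function(series, trials) {
  stopifnot(inherits(trials, "trial_set"))
  comps <- intersect(c("hbt", "hbo", "hbr"), names(series))
  if (length(comps) == 0) abort("series has no component columns")
  t <- series$time_s
  dt <- stats::median(diff(t))
  n_pre <- round(trials$pre_window / dt)
  n_post <- round(trials$post_window / dt)
  rel_idx <- seq(-n_pre, n_post)
  time_rel <- rel_idx * dt

  purrr::map_dfr(comps, function(cmp) {
    y <- series[[cmp]]
    epochs <- matrix(NA_real_, length(rel_idx), trials$n_trials)
    for (k in seq_len(trials$n_trials)) {
      on_idx <- which.min(abs(t - trials$onsets[k]))
      idx <- on_idx + rel_idx
      if (idx[1] < 1 || idx[length(idx)] > length(t))
        abort(sprintf("trial %d (onset %g s) extends beyond the recording",
                      k, trials$onsets[k]))
      ep <- y[idx]
      epochs[, k] <- ep / mean(ep[rel_idx < 0])
    }
    tibble::tibble(
      time_rel_s = time_rel, component = cmp,
      mean = rowMeans(epochs),
      sem = if (trials$n_trials > 1)
        apply(epochs, 1, sd) / sqrt(trials$n_trials) else NA_real_,
      n_trials = trials$n_trials
    )
  })
}

# trapezoid integral
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# linear-interpolated first crossing time of level on the way up to the peak
first_crossing <- function(t, y, level, before_idx) {
  seg <- seq_len(before_idx)
  hit <- which(y[seg] >= level)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1 || y[i] == y[i - 1]) return(t[i])
  t[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Summarise an evoked mean trial trace
#'
#' Per component: peak fractional deviation from baseline after onset
#' (maximum for HbT/HbO; for HbR the signed extremum of largest magnitude,
#' so triphasic traces report whichever phase dominates), time to peak, the
#' 10%-to-90% rise time of the peak deviation, and the trapezoid area under
#' the deviation over `[onset, onset + stim_duration + post]`.
#'
#' @param avg output of [trial_average()] (columns `time_rel_s`,
#'   `component`, `mean`).
#' @param stim_duration stimulus length (s).
#' @param onset onset time on the `time_rel_s` axis (default 0).
#' @param post s past stimulus offset included in the AUC window
#'   (default 10).
#' @param rise_fractions the two peak fractions defining rise time.
#' @return Tibble: `component`, `peak`, `time_to_peak_s`, `rise_time_s`,
#'   `auc`. A flat trace gives `peak = 0` with times `NA`.
#' @export
summarise_evoked <- function(avg, stim_duration, onset = 0, post = 10,
                             rise_fractions = c(0.1, 0.9)) {
  avg |>
    dplyr::group_by(.data$component) |>
    dplyr::group_modify(function(df, key) {
      t <- df$time_rel_s
      dev <- df$mean - 1
      after <- t >= onset - 1e-9
      ta <- t[after]
      da <- dev[after]
      if (max(abs(da)) == 0)
        return(tibble::tibble(peak = 0, time_to_peak_s = NA_real_,
                              rise_time_s = NA_real_, auc = 0))
      i_pk <- if (key$component %in% c("hbt", "hbo")) which.max(da)
      else which.max(abs(da))
      peak <- da[i_pk]
      sgn <- sign(peak)
      t10 <- first_crossing(ta, sgn * da, rise_fractions[1] * abs(peak), i_pk)
      t90 <- first_crossing(ta, sgn * da, rise_fractions[2] * abs(peak), i_pk)
      win <- ta <= onset + stim_duration + post + 1e-9
      tibble::tibble(peak = peak,
                     time_to_peak_s = ta[i_pk] - onset,
                     rise_time_s = t90 - t10,
                     auc = trapz(ta[win], da[win]))
    }) |>
    dplyr::ungroup()
}

#' Classify the shape of an HbR washout trace
#'
#' `"triphasic"` when a supra-noise positive deflection precedes the main
#' negative deflection (both exceeding `noise_k` times the SD of the
#' pre-onset trace, sustained for at least `min_run` consecutive samples so
#' isolated noise excursions do not count), `"biphasic"` when only the
#' negative deflection (with return toward baseline) is present, `"flat"`
#' otherwise.
#'
#' @param avg output of [trial_average()], or any tibble with `time_rel_s`
#'   and `mean`; rows with `component == "hbr"` are used when present.
#' @param onset onset time on the `time_rel_s` axis.
#' @param noise_k noise-floor multiplier on the pre-onset SD (default 2).
#' @param min_run minimum consecutive supra-floor samples for a deflection.
#' @return `"triphasic"`, `"biphasic"` or `"flat"`.
#' @export
classify_hbr <- function(avg, onset = 0, noise_k = 2, min_run = 3) {
  if ("component" %in% names(avg)) {
    avg <- dplyr::filter(avg, .data$component == "hbr")
    if (nrow(avg) == 0) abort("no hbr component in the trace")
  }
  t <- avg$time_rel_s
  dev <- avg$mean - 1
  pre <- dev[t < onset]
  floor <- max(noise_k * sd(pre), 1e-9)
  post <- t >= onset
  tp <- t[post]
  dp <- dev[post]
  # first index at which `cond` holds for >= min_run consecutive samples
  first_run <- function(cond) {
    r <- rle(cond)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= min_run)
    if (length(ok) == 0) NA_integer_ else ends[ok[1]] - r$lengths[ok[1]] + 1L
  }
  i_pos <- first_run(dp > floor)
  i_neg <- first_run(dp < -floor)
  if (!is.na(i_pos) && !is.na(i_neg) && tp[i_pos] < tp[i_neg])
    return("triphasic")
  if (!is.na(i_neg)) return("biphasic")
  "flat"
}

#' Vascular-reactivity response to a gas challenge
#'
#' Mean and trapezoid area of the fractional HbT deviation over the
#' challenge window, relative to the pre-challenge baseline mean (the
#' standard CO2-hypercapnia test of maximal dilation).
#'
#' @param series ROI tibble with `time_s` and `hbt` (fractional).
#' @param challenge_window,baseline_window `c(t0, t1)` s, inside the
#'   recording.
#' @return One-row tibble: `mean_change`, `auc`.
#' @export
gas_challenge_response <- function(series, challenge_window,
                                   baseline_window) {
  t <- series$time_s
  i_ch <- window_index(t, challenge_window, "challenge_window")
  i_ba <- window_index(t, baseline_window, "baseline_window")
  base <- mean(series$hbt[i_ba])
  dev <- series$hbt[i_ch] - base
  tibble::tibble(mean_change = mean(dev), auc = trapz(t[i_ch], dev))
}
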
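#' Pair trial-wise evoked neural and haemodynamic peaks
#'
#' For each trial, takes the peak fractional MUA (averaged over the selected
#' channels) within the stimulus window and the peak fractional HbT within
#' the stimulus + post window — the two axes of the neurovascular-coupling
#' scatter.
#'
#' @param mua tibble from [bin_threshold()] (same session as the imaging).
#' @param haem ROI tibble with `time_s` and fractional `hbt`.
#' @param trials a [trial_set()] shared by both modalities.
#' @param channels channels to average; default all channels present.
#' @param condition optional label (e.g. gas condition) stored per row.
#' @return Tibble: `trial_id`, `stim_duration`, `condition`,
#'   `peak_mua_fractional`, `peak_hbt_fractional` — one row per trial.
#' @export
build_pairs <- function(mua, haem, trials, channels = NULL,
                        condition = NA_character_) {
  stopifnot(inherits(trials, "trial_set"))
  if (!is.null(channels)) mua <- depth_select(mua, channels)
  bw <- attr(mua, "bin_width") %||% 0.1
  pooled <- mua |>
    dplyr::group_by(.data$bin_start_s) |>
    dplyr::summarise(fractional = mean(.data$fractional), .groups = "drop")
  mua_end <- max(pooled$bin_start_s) + bw
  haem_end <- max(haem$time_s)
  purrr::map_dfr(seq_len(trials$n_trials), function(k) {
    on <- trials$onsets[k]
    if (on + trials$stim_duration > mua_end + 1e-9)
      abort(sprintf("trial %d extends beyond the MUA recording", k))
    if (on + trials$post_window > haem_end + 1e-9)
      abort(sprintf("trial %d extends beyond the imaging recording", k))
    m_win <- pooled$bin_start_s + bw > on &
      pooled$bin_start_s < on + trials$stim_duration
    h_win <- haem$time_s >= on &
      haem$time_s <= on + trials$stim_duration + trials$post_window
    tibble::tibble(
      trial_id = k, stim_duration = trials$stim_duration,
      condition = condition,
      peak_mua_fractional = max(pooled$fractional[m_win]),
      peak_hbt_fractional = max(haem$hbt[h_win]))
  })
}

#' Fit the neurovascular-coupling line
#'
#' Ordinary least squares of trial-wise peak HbT on peak MUA,
#' `y = slope * x + intercept`, with R^2 the squared Pearson correlation —
#' the printed line-equation convention of coupling scatter plots. Clusters
#' (e.g. 2 s vs 16 s stimulations) are pooled by default; fit subsets for
#' per-cluster lines.
#'
#' @param table tibble from [build_pairs()] (or any tibble with columns
#'   `peak_mua_fractional`, `peak_hbt_fractional`); >= 3 rows with
#'   non-degenerate x variance.
#' @return A `coupling_fit` object wrapping the `lm`; see [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_line <- function(table) {
  need <- c("peak_mua_fractional", "peak_hbt_fractional")
  if (!all(need %in% names(table)))
    abort(paste("table needs columns:", paste(need, collapse = ", ")))
  tab <- dplyr::filter(table, is.finite(.data$peak_mua_fractional),
                       is.finite(.data$peak_hbt_fractional))
  if (nrow(tab) < 3) abort("at least 3 complete trials are required")
  if (stats::var(tab$peak_mua_fractional) == 0)
    abort("zero variance in peak MUA; cannot fit a line")
  model <- lm(peak_hbt_fractional ~ peak_mua_fractional, data = tab)
  structure(list(model = model, table = tab,
                 slope = coef(model)[[2]], intercept = coef(model)[[1]],
                 r_squared = summary(model)$r.squared,
                 n = nrow(tab)),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf("<coupling_fit> y = %.4gx %s %.4g, R² = %.4f (n = %d)\n",
              x$slope, if (x$intercept >= 0) "+" else "-",
              abs(x$intercept), x$r_squared, x$n))
  invisible(x)
}

#' Tidy the coupling fit coefficients
#' @param x a `coupling_fit`.
#' @param ... unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high` (95%).
#' @export
tidy.coupling_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  ci <- stats::confint(x$model)
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std.error = s[, 2], statistic = s[, 3], p.value = s[, 4],
                 conf.low = ci[, 1], conf.high = ci[, 2])
}

#' One-row summary of the coupling fit
#' @param x a `coupling_fit`.
#' @param ... unused.
#' @return Tibble: `slope`, `intercept`, `r.squared`, `sigma`, `n`.
#' @export
glance.coupling_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared,
                 sigma = summary(x$model)$sigma, n = x$n)
}
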
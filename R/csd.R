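#' Detect a spreading-depression episode in an ROI series
#'
#' A CSD is a sustained constriction after electrode insertion. Onset is the
#' first post-insertion time at which fractional HbT stays below
#' `1 - dip_threshold` for at least `sustain` seconds. The event is then
#' characterised by its minimum (the dip), the rebound maximum between dip
#' and the late window, the mean over the late undershoot reporting window
#' (default 625-1250 s after insertion), and the time to sustained recovery
#' into `1 +/- recovery_band` held for `recovery_sustain` seconds.
#'
#' @param series ROI tibble with `time_s` and fractional `hbt`.
#' @param t_insert electrode insertion time (s).
#' @param dip_threshold fractional depth defining a dip (default 0.05).
#' @param sustain s the dip must persist to count (default 2).
#' @param late_window `c(start, end)` s after insertion for the undershoot
#'   mean (default `c(625, 1250)`); truncated (and flagged) when the
#'   recording is shorter.
#' @param recovery_band half-width of the recovered band around 1.0.
#' @param recovery_sustain s the series must stay in the band.
#' @return `NULL` when no sustained dip exists; otherwise a one-row tibble
#'   (class `csd_event`): `t_onset`, `dip_value`, `dip_time`,
#'   `rebound_value`, `undershoot_mean`, `recovery_time` (`NA` when never
#'   recovered), `truncated`. Times are seconds from insertion.
#' @export
detect_csd <- function(series, t_insert = 0, dip_threshold = 0.05,
                       sustain = 2, late_window = c(625, 1250),
                       recovery_band = 0.02, recovery_sustain = 60) {
  t <- series$time_s
  x <- series$hbt
  post <- t >= t_insert
  tp <- t[post]
  xp <- x[post]
  if (length(tp) < 2) abort("recording does not extend past t_insert")
  dt <- stats::median(diff(tp))

  below <- xp < 1 - dip_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths * dt >= sustain - 1e-9)
  if (length(ok) == 0) return(NULL)
  i_on <- starts[ok[1]]

  i_dip <- which.min(xp)
  dip_value <- xp[i_dip]

  lw <- t_insert + late_window
  if (lw[1] >= tp[length(tp)]) {
    undershoot_mean <- NA_real_
    truncated <- TRUE
  } else {
    truncated <- lw[2] > tp[length(tp)] + dt / 2
    in_late <- tp >= lw[1] & tp <= lw[2]
    undershoot_mean <- mean(xp[in_late])
  }

  pre_late <- tp >= tp[i_dip] & tp <= min(lw[1], tp[length(tp)])
  rebound_value <- if (any(pre_late)) max(xp[pre_late]) else NA_real_

  recovery_time <- NA_real_
  n_sus <- max(1, round(recovery_sustain / dt))
  in_band <- abs(xp - 1) <= recovery_band
  for (i in seq(i_dip, length(tp) - n_sus + 1)) {
    if (all(in_band[i:(i + n_sus - 1)])) {
      recovery_time <- tp[i] - t_insert
      break
    }
  }

  out <- tibble::tibble(
    t_onset = tp[i_on] - t_insert, dip_value = dip_value,
    dip_time = tp[i_dip] - t_insert, rebound_value = rebound_value,
    undershoot_mean = undershoot_mean, recovery_time = recovery_time,
    truncated = truncated)
  class(out) <- c("csd_event", class(out))
  out
}

#' Wavefront propagation speed of a spreading-depression episode
#'
#' Per pixel, the arrival time is the first crossing of half that pixel's
#' dip amplitude (robust to amplitude variation across the field). Speed is
#' the inverse slope of the least-squares regression of arrival time on
#' Euclidean distance from the origin, in mm/min, with the regression R^2 as
#' fit quality.
#'
#' @param h pixel-level [haem_field()] (any mode; fractional used).
#' @param t_insert insertion time (s).
#' @param origin `c(row, col)` of the insertion site; default the
#'   earliest-arrival pixel.
#' @param dip_threshold minimum dip amplitude for a pixel to count.
#' @param min_arrivals minimum number of arriving pixels for a fit.
#' @return One-row tibble: `speed_mm_min` (`NA` when non-propagating or too
#'   few arrivals), `r_squared`, `n_arrivals`, `propagating`. Attribute
#'   `arrivals` holds the per-pixel arrival table.
#' @export
wavefront_speed <- function(h, t_insert = 0, origin = NULL,
                            dip_threshold = 0.05, min_arrivals = 10) {
  stopifnot(inherits(h, "haem_field"))
  if (is.na(h$pixel_pitch_um))
    abort("pixel pitch is required to express speed in mm/min")
  h <- haem_fractional(h)
  d <- dim(h$hbt)
  times <- frame_times(d[3], h$frame_rate)
  keep <- times >= t_insert
  tt <- times[keep]
  m <- matrix(h$hbt[, , keep], d[1] * d[2], sum(keep))

  amp <- 1 - apply(m, 1, min)
  arr <- rep(NA_real_, nrow(m))
  for (px in which(amp >= dip_threshold)) {
    lev <- 1 - amp[px] / 2
    i <- which(m[px, ] < lev)[1]
    if (is.na(i)) next
    if (i == 1) {
      arr[px] <- tt[1]
    } else {
      y0 <- m[px, i - 1]; y1 <- m[px, i]
      arr[px] <- tt[i - 1] + (y0 - lev) / (y0 - y1) * (tt[i] - tt[i - 1])
    }
  }
  got <- which(!is.na(arr))
  res <- tibble::tibble(speed_mm_min = NA_real_, r_squared = NA_real_,
                        n_arrivals = length(got), propagating = FALSE)
  if (length(got) < min_arrivals) {
    warn(sprintf("only %d pixels reached the dip criterion (< %d); no speed",
                 length(got), min_arrivals))
    return(res)
  }
  rows <- (got - 1) %% d[1] + 1
  cols <- (got - 1) %/% d[1] + 1
  if (is.null(origin)) {
    i0 <- got[which.min(arr[got])]
    origin <- c((i0 - 1) %% d[1] + 1, (i0 - 1) %/% d[1] + 1)
  }
  dist_mm <- sqrt((rows - origin[1])^2 + (cols - origin[2])^2) *
    h$pixel_pitch_um / 1000
  fit <- lm(arr[got] ~ dist_mm)
  slope <- coef(fit)[[2]]              # s per mm
  r2 <- summary(fit)$r.squared
  dt <- stats::median(diff(tt))
  res$r_squared <- r2
  attr(res, "arrivals") <- tibble::tibble(row = rows, col = cols,
                                          dist_mm = dist_mm,
                                          arrival_s = arr[got])
  if (slope <= 0 || slope * diff(range(dist_mm)) < dt) {
    res$propagating <- FALSE           # synchronous / non-propagating field
    return(res)
  }
  res$speed_mm_min <- 60 / slope
  res$propagating <- TRUE
  res
}
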
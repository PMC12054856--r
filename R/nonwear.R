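#' Non-wear detection configuration
#'
#' Sliding-window criterion on the raw signal: a window is non-wear if, for
#' at least `axes_required` of the three axes, the per-axis sample standard
#' deviation is less than `sd_threshold` mg OR the per-axis value range
#' (max - min) is less than `range_threshold` mg. Comparisons are strict.
#' Windows of `window_minutes` advance by `slide_minutes`; flagged windows
#' are unioned into maximal intervals.
#'
#' @param window_minutes Window length in minutes (default 60).
#' @param slide_minutes Slide step in minutes (default 15; must be <= window).
#' @param sd_threshold Per-axis SD threshold in mg (default 3).
#' @param range_threshold Per-axis range threshold in mg (default 50).
#' @param axes_required Number of axes that must satisfy the criterion
#'   (default 2 of 3).
#' @return An `nwt_config` list.
#' @export
nwt_config <- function(window_minutes = 60, slide_minutes = 15,
                       sd_threshold = 3, range_threshold = 50,
                       axes_required = 2) {
  if (slide_minutes > window_minutes) stop("slide must be <= window")
  if (sd_threshold <= 0 || range_threshold <= 0) stop("thresholds must be > 0")
  if (!axes_required %in% 1:3) stop("axes_required must be 1, 2 or 3")
  structure(list(window_minutes = window_minutes,
                 slide_minutes = slide_minutes,
                 sd_threshold = sd_threshold,
                 range_threshold = range_threshold,
                 axes_required = as.integer(axes_required)),
            class = "nwt_config")
}

#' Detect non-wear time on a raw trace
#'
#' Applies the sliding-window standard-deviation/range criterion (see
#' [nwt_config()]) to the raw-rate signal and returns the union of all
#' flagged windows as a merged [interval_set()]. A trace shorter than one
#' window yields an empty set with a warning.
#'
#' @param trace A [raw_trace()].
#' @param config An [nwt_config()].
#' @return An [interval_set()] of non-wear episodes.
#' @export
detect_nonwear <- function(trace, config = nwt_config()) {
  w <- as.integer(round(config$window_minutes * 60 * trace$sample_rate))
  slide <- as.integer(round(config$slide_minutes * 60 * trace$sample_rate))
  n <- nrow(trace$data)
  if (n < w) {
    warning("trace shorter than one non-wear window; returning empty set")
    return(interval_set())
  }
  starts <- seq.int(1L, n - w + 1L, by = slide)
  t0 <- as.numeric(trace$start_time)
  win_s <- win_e <- numeric(0)
  mg <- trace$data * 1000
  for (st in starts) {
    seg <- mg[st:(st + w - 1L), , drop = FALSE]
    ok <- 0L
    for (a in 1:3) {
      v <- seg[, a]
      if (stats::sd(v) < config$sd_threshold ||
          (max(v) - min(v)) < config$range_threshold) ok <- ok + 1L
    }
    if (ok >= config$axes_required) {
      win_s <- c(win_s, t0 + (st - 1L) / trace$sample_rate)
      win_e <- c(win_e, t0 + (st - 1L + w) / trace$sample_rate)
    }
  }
  if (!length(win_s)) return(interval_set())
  merge_intervals(win_s, win_e)
}

#' Non-wear minutes within a day window
#'
#' Counts the minutes of a day window whose midpoint falls inside a
#' non-wear interval (consistent with the package-wide minute-membership
#' rule). A day "contains non-wear" iff the count is positive.
#'
#' @param nwt An [interval_set()] of non-wear episodes.
#' @param day_window A day window from [split_noon_days()], or any list with
#'   `start` (`POSIXct`) and `idx` (minute indices).
#' @return Whole minutes of overlap.
#' @export
nwt_minutes_per_day <- function(nwt, day_window) {
  n <- length(day_window$idx)
  if (!n) return(0L)
  sum(rasterize(nwt, day_window$minute_start %||% day_window$start, n))
}
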
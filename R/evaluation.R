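#' Minute-level confusion metrics
#'
#' Accuracy, sensitivity (true-positive rate on in-bed minutes) and
#' specificity (true-negative rate on out-of-bed minutes) between a
#' predicted and a labelled binary track. Ratios with a zero denominator
#' are returned as `NA` (absent), never as 0.
#'
#' @param pred,labels Integer 0/1 vectors of equal length; 1 = in bed.
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
day_metrics <- function(pred, labels) {
  if (length(pred) != length(labels))
    stop("prediction and labels differ in length", call. = FALSE)
  pred <- as.integer(pred); labels <- as.integer(labels)
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  list(accuracy = (tp + tn) / length(pred),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Baseline accuracy of always predicting "out of bed"
#'
#' @param labels Integer 0/1 vector.
#' @return Fraction of minutes labelled out of bed.
#' @export
baseline_accuracy <- function(labels) {
  if (!length(labels)) stop("labels must be non-empty")
  mean(as.integer(labels) == 0L)
}

#' Flag implausible day-level predictions as outliers
#'
#' A 24 h day is an outlier iff its predicted TiB is strictly below 60 min
#' (under one hour) or strictly above 1380 min (over 23 hours) — days the
#' model labelled essentially all or nothing as in bed.
#'
#' @param reports Data.frame with a `predicted_tib` column (minutes per day).
#' @return The data.frame with a logical `outlier` column set.
#' @export
flag_outliers <- function(reports) {
  if (is.null(reports$predicted_tib)) stop("reports must carry predicted_tib")
  reports$outlier <- reports$predicted_tib < 60 | reports$predicted_tib > 1380
  reports
}

#' Between-subject summary of a day-level metric
#'
#' Two-stage averaging: first the mean over each subject's scored days, then
#' mean and SD across subjects (subject-level metrics, as opposed to pooling
#' all minutes).
#'
#' @param reports Data.frame with columns `subject` and the metric.
#' @param metric Name of the metric column.
#' @return List with `mean`, `sd` (`NA` for a single subject), `n_subjects`,
#'   and `per_subject` (named vector of per-subject means).
#' @export
subject_summary <- function(reports, metric = "accuracy") {
  v <- reports[[metric]]
  keep <- !is.na(v)
  if (!any(keep)) stop("no scored days")
  per <- tapply(v[keep], reports$subject[keep], mean)
  list(mean = mean(per),
       sd = if (length(per) > 1) stats::sd(per) else NA_real_,
       n_subjects = length(per),
       per_subject = per)
}

#' Mean daily TiB over fully recorded days
#'
#' Sums predicted in-bed minutes per noon-to-noon day, restricted to fully
#' recorded days (partial first/last days excluded, as these make daily
#' totals incomparable), and averages across those days.
#'
#' @param pred_intervals An [interval_set()] of predicted TiB episodes
#'   (e.g. from [track_to_intervals()]).
#' @param day_windows Day windows from [split_noon_days()].
#' @return List with `per_day` (minutes per full day) and `mean`
#'   (`NA` with a warning if there is no full day).
#' @export
daily_tib_summary <- function(pred_intervals, day_windows) {
  full <- Filter(function(w) w$full, day_windows)
  if (!length(full)) {
    warning("no fully recorded day; daily TiB undefined")
    return(list(per_day = numeric(0), mean = NA_real_))
  }
  per_day <- vapply(full, function(w)
    sum(rasterize(pred_intervals, w$start, 1440L)), 0)
  list(per_day = per_day, mean = mean(per_day))
}

#' Bland-Altman method comparison
#'
#' Paired comparison of two per-subject estimates: differences `x - y`
#' against pair means, with bias (mean difference) and 95% limits of
#' agreement `bias +/- 1.96 * sd(difference)`.
#'
#' @param x,y Paired numeric vectors (same subjects, same order).
#' @return List with `mean` (pair means), `difference`, `bias`, `loa`
#'   (lower/upper limits of agreement).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  d <- x - y
  bias <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  list(mean = (x + y) / 2, difference = d, bias = bias,
       loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s))
}

#' Build per-day reports for one subject's predictions
#'
#' Convenience assembly of the day-level evaluation: per noon-day predicted
#' TiB, confusion metrics against labels (when present), non-wear minutes,
#' full-day and outlier flags.
#'
#' @param pred Integer 0/1 predicted track for the whole series.
#' @param series The [minute_series()] that was predicted (supplies times
#'   and, optionally, labels).
#' @param nwt An [interval_set()] of non-wear episodes (may be empty).
#' @param subject Subject identifier stored in the report rows.
#' @return Data.frame, one row per day window: `subject`, `day_start`,
#'   `full_day`, `predicted_tib`, `labelled_tib`, `accuracy`, `sensitivity`,
#'   `specificity`, `nwt_minutes`, `outlier`.
#' @export
day_reports <- function(pred, series, nwt = interval_set(), subject = "S000") {
  wins <- split_noon_days(series)
  rows <- lapply(wins, function(w) {
    p <- pred[w$idx]
    lab <- if (!is.null(series$labels)) series$labels[w$idx]
    m <- if (!is.null(lab)) day_metrics(p, lab) else
      list(accuracy = NA_real_, sensitivity = NA_real_, specificity = NA_real_)
    data.frame(subject = subject, day_start = w$start, full_day = w$full,
               predicted_tib = sum(p == 1L),
               labelled_tib = if (!is.null(lab)) sum(lab == 1L) else NA_integer_,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity,
               nwt_minutes = nwt_minutes_per_day(nwt, w))
  })
  flag_outliers(do.call(rbind, rows))
}
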
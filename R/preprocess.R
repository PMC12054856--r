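#' Fit cohort-level normalization statistics
#'
#' Computes the per-axis mean and standard deviation of the per-minute
#' acceleration pooled over every minute of every subject in the cohort.
#' These statistics are the last deterministic preparation step before
#' augmentation and modelling; they must be fitted on training data only and
#' frozen for validation/test (the cross-validation harness enforces this
#' via the provenance string).
#'
#' @param cohort List of [minute_series()] (or bare n-by-3 matrices).
#' @param source Free-text provenance identifier stored with the stats.
#' @return A `normalization_stats` object: per-axis `mean` and `sd` (g),
#'   `n_minutes`, `source`.
#' @export
fit_normalizer <- function(cohort, source = "unnamed-cohort") {
  if (!length(cohort)) stop("cohort must be non-empty")
  vals <- do.call(rbind, lapply(cohort, function(s) {
    if (inherits(s, "minute_series")) {
      if (s$normalized) stop("cohort contains already-normalized series")
      s$values
    } else as.matrix(s)
  }))
  if (nrow(vals) < 2) stop("need at least 2 pooled minutes per axis")
  mu <- colMeans(vals)
  sdv <- apply(vals, 2, stats::sd)
  if (any(sdv <= 0))
    stop(sprintf("degenerate cohort: zero pooled variance on axis %s",
                 paste(c("x", "y", "z")[sdv <= 0], collapse = ",")),
         call. = FALSE)
  structure(list(mean = mu, sd = sdv, n_minutes = nrow(vals), source = source),
            class = "normalization_stats")
}

#' @export
print.normalization_stats <- function(x, ...) {
  cat(sprintf("<normalization_stats [%s]: %d minutes\n mean (%.4f, %.4f, %.4f) g, sd (%.4f, %.4f, %.4f) g>\n",
              x$source, x$n_minutes, x$mean[1], x$mean[2], x$mean[3],
              x$sd[1], x$sd[2], x$sd[3]))
  invisible(x)
}

# Provenance fingerprint of normalization stats; predictions refuse series
# normalized with different stats.
norm_stats_ref <- function(stats) {
  paste(c(stats$source, sprintf("%.12g", c(stats$mean, stats$sd))),
        collapse = "|")
}

#' Apply (or invert) cohort normalization
#'
#' `apply_normalizer` maps each axis to `(value - mean) / sd`; labels are
#' untouched and the `normalized` flag plus stats provenance are set.
#' Already-normalized input is refused (double-normalization guard).
#' `invert_normalizer` undoes the transformation exactly.
#'
#' @param series A [minute_series()].
#' @param stats A `normalization_stats` object from [fit_normalizer()].
#' @return A [minute_series()].
#' @export
apply_normalizer <- function(series, stats) {
  if (series$normalized)
    stop("series is already normalized (double-normalization guard)", call. = FALSE)
  v <- sweep(sweep(series$values, 2, stats$mean, "-"), 2, stats$sd, "/")
  minute_series(v, series$start_minute, labels = series$labels,
                normalized = TRUE, norm_ref = norm_stats_ref(stats))
}

#' @rdname apply_normalizer
#' @export
invert_normalizer <- function(series, stats) {
  if (!series$normalized) stop("series is not normalized", call. = FALSE)
  if (!identical(series$norm_ref, norm_stats_ref(stats)))
    stop("series was normalized with different statistics", call. = FALSE)
  v <- sweep(sweep(series$values, 2, stats$sd, "*"), 2, stats$mean, "+")
  minute_series(v, series$start_minute, labels = series$labels,
                normalized = FALSE)
}

#' Serialize normalization stats to JSON
#'
#' @param stats A `normalization_stats`.
#' @param path Output path.
#' @export
write_normalizer <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalizer
#' @export
read_normalizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
                 n_minutes = x$n_minutes, source = x$source),
            class = "normalization_stats")
}
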
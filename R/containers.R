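#' Raw tri-axial acceleration traces
#'
#' A `raw_trace` holds a uniformly sampled tri-axial acceleration signal in
#' gravitational units (g). Sample `i` (1-based) is taken at
#' `start_time + (i - 1) / sample_rate` seconds.
#'
#' @param data Numeric matrix with one row per sample and columns `x`, `y`,
#'   `z` (g). Axis convention used by the bundled simulator: `x`
#'   medio-lateral, `y` vertical-when-upright, `z` anterior-posterior.
#' @param start_time `POSIXct` timestamp of the first sample.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(data, start_time, sample_rate) {
  data <- as.matrix(data)
  if (ncol(data) != 3) stop("trace data must have 3 columns (x, y, z)")
  if (any(!is.finite(data))) stop("trace contains non-finite values")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  colnames(data) <- c("x", "y", "z")
  structure(list(data = data, start_time = as_utc(start_time),
                 sample_rate = sample_rate),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace: %d samples @ %g Hz from %s (%.2f h)>\n",
              nrow(x$data), x$sample_rate, format_iso(x$start_time),
              nrow(x$data) / x$sample_rate / 3600))
  invisible(x)
}

trace_end_time <- function(trace) {
  trace$start_time + nrow(trace$data) / trace$sample_rate
}

trace_offsets <- function(trace) {
  (seq_len(nrow(trace$data)) - 1) / trace$sample_rate
}

#' Per-minute aggregated series
#'
#' A `minute_series` is the model's native resolution: one tri-axial value per
#' minute (per-axis mean of the raw samples in that minute), optionally
#' z-normalized, optionally carrying a per-minute binary in-bed label track.
#'
#' @param values Numeric matrix, one row per minute, columns `x`, `y`, `z`.
#' @param start_minute `POSIXct`, start of the first minute (whole minute).
#' @param labels Optional integer vector (0/1) of per-minute in-bed labels.
#' @param normalized Logical flag; `TRUE` after [apply_normalizer()].
#' @param norm_ref Provenance string of the normalization stats used (internal).
#' @return An object of class `minute_series`.
#' @export
minute_series <- function(values, start_minute, labels = NULL,
                          normalized = FALSE, norm_ref = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 3) stop("minute values must have 3 columns")
  colnames(values) <- c("x", "y", "z")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values))
      stop("labels must have one entry per minute")
    if (any(!labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  }
  structure(list(values = values, start_minute = as_utc(start_minute),
                 labels = labels, normalized = isTRUE(normalized),
                 norm_ref = norm_ref),
            class = "minute_series")
}

#' @export
print.minute_series <- function(x, ...) {
  cat(sprintf("<minute_series: %d minutes from %s%s%s>\n",
              nrow(x$values), format_iso(x$start_minute),
              if (x$normalized) ", normalized" else "",
              if (!is.null(x$labels)) ", labelled" else ""))
  invisible(x)
}

n_minutes <- function(series) nrow(series$values)

minute_times <- function(series) {
  series$start_minute + (seq_len(n_minutes(series)) - 1) * 60
}
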
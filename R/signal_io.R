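#' Read and write raw acceleration traces
#'
#' Traces are stored as plain CSV with header
#' `timestamp_iso8601,x_g,y_g,z_g`. Comment lines starting with `#` are
#' tolerated. Reading validates that timestamps are strictly increasing and
#' uniformly spaced; the first offending row is named in the error.
#'
#' @param path File path.
#' @param trace A [raw_trace()].
#' @return `read_trace` returns a [raw_trace()]; `write_trace` returns `path`
#'   invisibly. Round-tripping preserves values to 1e-6 g.
#' @export
read_trace <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE,
                          colClasses = list(character = 1))
  need <- c("timestamp_iso8601", "x_g", "y_g", "z_g")
  if (!all(need %in% names(dt)))
    stop(sprintf("missing column(s): %s",
                 paste(setdiff(need, names(dt)), collapse = ", ")), call. = FALSE)
  t <- parse_iso(dt$timestamp_iso8601)
  if (length(t) < 2) {
    rate <- 1
  } else {
    d <- diff(as.numeric(t))
    bad <- which(d <= 0)
    if (length(bad))
      stop(sprintf("non-monotone timestamps at row %d", bad[1] + 1), call. = FALSE)
    rate <- 1 / stats::median(d)
    irregular <- which(abs(d - d[1]) > 1e-3)
    if (length(irregular))
      stop(sprintf("irregular sampling gap of %.3f s at row %d (expected %.3f s)",
                   d[irregular[1]], irregular[1] + 1, d[1]), call. = FALSE)
    rate <- 1 / d[1]
  }
  raw_trace(cbind(dt$x_g, dt$y_g, dt$z_g), t[1], rate)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  dt <- data.frame(
    timestamp_iso8601 = format_iso(trace$start_time + trace_offsets(trace)),
    x_g = round(trace$data[, 1], 6),
    y_g = round(trace$data[, 2], 6),
    z_g = round(trace$data[, 3], 6))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read and write interval sets
#'
#' CSV dialect: `start_iso8601,end_iso8601`, one interval per row.
#'
#' @param path File path.
#' @param x An [interval_set()].
#' @export
read_intervals <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  if (!nrow(dt)) return(interval_set())
  interval_set(parse_iso(dt$start_iso8601), parse_iso(dt$end_iso8601))
}

#' @rdname read_intervals
#' @export
write_intervals <- function(x, path) {
  data.table::fwrite(data.frame(start_iso8601 = format_iso(x$start),
                                end_iso8601 = format_iso(x$end)), path)
  invisible(path)
}

#' Read and write per-minute label tracks
#'
#' CSV dialect: `minute_start_iso8601,in_bed` with binary labels.
#'
#' @param path File path.
#' @param labels Integer 0/1 vector.
#' @param start `POSIXct` start of the first minute.
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1))
  list(start = parse_iso(dt$minute_start_iso8601[1]),
       labels = as.integer(dt$in_bed))
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, start, path) {
  data.table::fwrite(data.frame(
    minute_start_iso8601 = format_iso(start + (seq_along(labels) - 1) * 60),
    in_bed = as.integer(labels)), path)
  invisible(path)
}

#' Aggregate a raw trace to one data point per minute
#'
#' Each whole minute is summarised by the per-axis arithmetic mean of all
#' samples whose timestamp falls in `[minute, minute + 1)`. Partial leading
#' and trailing minutes are dropped, so the result is aligned to minute
#' boundaries.
#'
#' @param trace A [raw_trace()] spanning at least one full minute.
#' @return A [minute_series()] (unlabelled, unnormalized).
#' @export
to_minutes <- function(trace) {
  t0 <- as.numeric(trace$start_time)
  first_boundary <- ceiling(t0 / 60 - 1e-9) * 60
  end <- t0 + nrow(trace$data) / trace$sample_rate
  n_min <- floor((end - first_boundary) / 60 + 1e-9)
  if (n_min < 1) stop("trace spans less than one full minute", call. = FALSE)
  idx <- floor((t0 + trace_offsets(trace) - first_boundary) / 60 + 1e-9)
  keep <- idx >= 0 & idx < n_min
  sums <- rowsum(trace$data[keep, , drop = FALSE], idx[keep])
  counts <- tabulate(idx[keep] + 1L, nbins = n_min)
  vals <- sums / counts
  rownames(vals) <- NULL
  minute_series(vals, .POSIXct(first_boundary, tz = "UTC"))
}

#' Rasterize an interval set to a per-minute binary track
#'
#' Minute `m` is labelled 1 iff the midpoint of `[m, m + 1)` lies inside any
#' interval. [track_to_intervals()] is the inverse operation: it merges runs
#' of consecutive 1-minutes back into a minute-aligned interval set. The
#' round trip rasterize -> de-rasterize is idempotent; on minute-aligned
#' interval sets it is the identity.
#'
#' @param intervals An [interval_set()].
#' @param start `POSIXct` start of the first minute of the raster.
#' @param n_minutes Number of minutes to rasterize.
#' @return Integer 0/1 vector of length `n_minutes`.
#' @export
rasterize <- function(intervals, start, n_minutes) {
  if (n_minutes < 1) stop("n_minutes must be >= 1")
  mid <- as.numeric(as_utc(start)) + (seq_len(n_minutes) - 1) * 60 + 30
  if (!nrow(intervals)) return(integer(n_minutes))
  s <- as.numeric(intervals$start); e <- as.numeric(intervals$end)
  i <- findInterval(mid, s)
  as.integer(i > 0 & mid < e[pmax(i, 1L)])
}

#' @rdname rasterize
#' @param track Integer 0/1 vector of per-minute labels.
#' @export
track_to_intervals <- function(track, start) {
  track <- as.integer(track)
  if (!length(track) || !any(track == 1L)) return(interval_set())
  r <- rle(track)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths  # 0-based minute offsets
  on <- r$values == 1L
  t0 <- as.numeric(as_utc(start))
  interval_set(.POSIXct(t0 + begins[on] * 60, tz = "UTC"),
               .POSIXct(t0 + ends[on] * 60, tz = "UTC"))
}

#' Split a minute series into noon-to-noon day windows
#'
#' Days are anchored at local 12:00 (the convention for 24 h recordings in
#' population accelerometry protocols). A window is "full" iff all 1440
#' minutes are present; partial first/last windows are returned flagged
#' incomplete.
#'
#' @param series A [minute_series()].
#' @param anchor_hour Hour of day at which windows start (default 12).
#' @return A list of day windows, each a list with `start` (`POSIXct`),
#'   `idx` (integer indices into the series rows), and `full` (logical).
#' @export
split_noon_days <- function(series, anchor_hour = 12) {
  n <- n_minutes(series)
  if (!n) stop("empty minute series")
  t0 <- as.numeric(series$start_minute)
  day0 <- floor(t0 / 86400) * 86400
  anchor <- day0 + anchor_hour * 3600
  if (anchor > t0 + 1e-9) anchor <- anchor - 86400
  last <- t0 + (n - 1) * 60
  starts <- seq(anchor, last, by = 86400)
  lapply(starts, function(ws) {
    lo <- max(0, (ws - t0) / 60)
    hi <- min(n - 1, (ws + 86400 - 60 - t0) / 60)
    idx <- if (hi < lo) integer(0) else seq.int(floor(lo + 1e-9), floor(hi + 1e-9)) + 1L
    list(start = .POSIXct(ws, tz = "UTC"),
         minute_start = .POSIXct(t0 + (if (length(idx)) idx[1] - 1 else 0) * 60,
                                 tz = "UTC"),
         idx = idx, full = length(idx) == 1440L)
  })
}
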
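#' Ordered sets of half-open time intervals
#'
#' An `interval_set` is an ordered collection of non-overlapping half-open
#' intervals `[start, end)` used throughout the package for annotations,
#' predictions and non-wear episodes. Intervals may touch
#' (`end[i] == start[i+1]`) but never overlap.
#'
#' @param start,end `POSIXct` vectors of equal length; each `start` strictly
#'   before its `end`.
#' @return An object of class `interval_set`: a `data.frame` with `POSIXct`
#'   columns `start` and `end`, sorted by `start`.
#' @examples
#' s <- as.POSIXct("2024-01-06 23:00", tz = "UTC")
#' interval_set(s, s + 8 * 3600)
#' @export
interval_set <- function(start = as_utc(character()), end = as_utc(character())) {
  start <- as_utc(start); end <- as_utc(end)
  if (length(start) != length(end)) stop("start and end must have equal length")
  if (length(start)) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    if (any(end <= start)) stop("every interval must satisfy start < end")
    if (length(start) > 1 &&
        any(as.numeric(start[-1]) < as.numeric(end[-length(end)]) - 1e-9))
      stop("intervals must be non-overlapping")
  }
  structure(data.frame(start = start, end = end),
            class = c("interval_set", "data.frame"))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set: %d interval(s), total %.1f min>\n",
              nrow(x), interval_measure(x) / 60))
  if (nrow(x)) print(data.frame(start = x$start, end = x$end), ...)
  invisible(x)
}

is_interval_set <- function(x) inherits(x, "interval_set")

#' Total measure of an interval set
#'
#' @param x An [interval_set()].
#' @return Total covered time in seconds.
#' @export
interval_measure <- function(x) {
  if (!nrow(x)) return(0)
  sum(as.numeric(x$end) - as.numeric(x$start))
}

#' Intersection and union of interval sets
#'
#' Continuous-time set operations on half-open interval sets; the result is
#' again a valid, merged `interval_set`.
#'
#' @param a,b [interval_set()] objects.
#' @return An [interval_set()].
#' @export
interval_intersection <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(interval_set())
  ss <- c(); ee <- c()
  for (i in seq_len(nrow(a))) {
    lo <- pmax(as.numeric(a$start[i]), as.numeric(b$start))
    hi <- pmin(as.numeric(a$end[i]), as.numeric(b$end))
    keep <- lo < hi
    ss <- c(ss, lo[keep]); ee <- c(ee, hi[keep])
  }
  merge_intervals(ss, ee)
}

#' @rdname interval_intersection
#' @export
interval_union <- function(a, b) {
  merge_intervals(c(as.numeric(a$start), as.numeric(b$start)),
                  c(as.numeric(a$end), as.numeric(b$end)))
}

# Sort and merge overlapping/touching intervals given numeric epoch seconds.
merge_intervals <- function(start, end) {
  if (!length(start)) return(interval_set())
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1e-9) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  interval_set(.POSIXct(out_s, tz = "UTC"), .POSIXct(out_e, tz = "UTC"))
}

# Clip an interval set to [lo, hi) (POSIXct or numeric seconds).
clip_intervals <- function(x, lo, hi) {
  if (!nrow(x)) return(x)
  s <- pmax(as.numeric(x$start), as.numeric(lo))
  e <- pmin(as.numeric(x$end), as.numeric(hi))
  keep <- s < e
  if (!any(keep)) return(interval_set())
  interval_set(.POSIXct(s[keep], tz = "UTC"), .POSIXct(e[keep], tz = "UTC"))
}
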
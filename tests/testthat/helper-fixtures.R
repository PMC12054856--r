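# Shared fixture builders (all data generated in code; nothing on disk).

t_noon <- as.POSIXct("2024-01-06 12:00:00", tz = "UTC")

# constant-orientation trace
const_trace <- function(vec = c(0, 0, 1), n_sec = 120, rate = 1,
                        start = t_noon) {
  raw_trace(matrix(rep(vec, each = n_sec * rate), ncol = 3),
            start, rate)
}

# labelled minute series with given per-minute values
make_ms <- function(values, labels = NULL, start = t_noon,
                    normalized = FALSE, norm_ref = NULL) {
  minute_series(values, start, labels = labels, normalized = normalized,
                norm_ref = norm_ref)
}

iv <- function(start_str, end_str) {
  interval_set(as.POSIXct(start_str, tz = "UTC"),
               as.POSIXct(end_str, tz = "UTC"))
}

# Stationary epoch means: unit-sphere orientations (plus tilted extras),
# observed through a per-axis affine miscalibration a' = g * a + o.
miscal_epochs <- function(gain, offset, n_rep = 5, tilt = 0.05) {
  base <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                c(1, 1, 0) / sqrt(2), c(0, 1, 1) / sqrt(2))
  E <- do.call(rbind, replicate(n_rep, {
    v <- base + matrix(rnorm(length(base), 0, tilt), nrow(base))
    v / sqrt(rowSums(v^2))
  }, simplify = FALSE))
  sweep(sweep(E, 2, gain, "*"), 2, offset, "+")
}

# Brute-force non-wear oracle: enumerates every window, flags per-sample
# coverage, rebuilds intervals — an independent code path from the detector.
nonwear_oracle <- function(trace, config = nwt_config()) {
  w <- as.integer(round(config$window_minutes * 60 * trace$sample_rate))
  slide <- as.integer(round(config$slide_minutes * 60 * trace$sample_rate))
  n <- nrow(trace$data)
  if (n < w) return(interval_set())
  covered <- rep(FALSE, n)
  mg <- trace$data * 1000
  for (st in seq.int(1L, n - w + 1L, by = slide)) {
    idx <- st:(st + w - 1L)
    ok <- 0L
    for (a in 1:3) {
      v <- mg[idx, a]
      if (sd(v) < config$sd_threshold || diff(range(v)) < config$range_threshold)
        ok <- ok + 1L
    }
    if (ok >= config$axes_required) covered[idx] <- TRUE
  }
  if (!any(covered)) return(interval_set())
  r <- rle(covered)
  ends <- cumsum(r$lengths); begins <- ends - r$lengths
  t0 <- as.numeric(trace$start_time)
  interval_set(.POSIXct(t0 + begins[r$values] / trace$sample_rate, tz = "UTC"),
               .POSIXct(t0 + ends[r$values] / trace$sample_rate, tz = "UTC"))
}

# pooled accuracy of a model over a list of normalized labelled series
pooled_accuracy <- function(model, series_list) {
  hits <- 0L; tot <- 0L
  for (s in series_list) {
    p <- predict_lstm(model, s)
    hits <- hits + sum(p$track == s$labels)
    tot <- tot + length(s$labels)
  }
  hits / tot
}

# small separable cohort for model tests: in-bed minutes sit at a lying
# orientation, out-of-bed at an upright one, plus noise
separable_cohort <- function(n_subjects = 4, n_min = 240, seed = 99,
                             noise = 0.05) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    lab <- rep(c(0L, 1L), each = n_min / 2)
    v <- matrix(0, n_min, 3)
    v[lab == 0L, 2] <- 1   # upright: gravity on y
    v[lab == 1L, 3] <- 1   # lying: gravity on z
    v <- v + matrix(rnorm(3 * n_min, 0, noise), n_min, 3)
    make_ms(v, labels = lab)
  })
}

normalize_cohort <- function(cohort, source = "toy") {
  stats <- fit_normalizer(cohort, source = source)
  list(stats = stats,
       series = lapply(cohort, apply_normalizer, stats = stats))
}
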
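#' Configuration for the synthetic free-living signal generator
#'
#' Defines the study conditions the simulator emulates: multi-day hip-worn
#' recordings (starting at noon) with distinct in-bed, out-of-bed and
#' non-wear regimes, plus two imperfect "annotator" interval tracks derived
#' from the ground truth by boundary jitter.
#'
#' @param n_subjects Number of subjects.
#' @param days_per_subject Recording length per subject in 24 h days.
#' @param sample_rate Sampling rate in Hz (default 1; must be at least one
#'   sample per minute).
#' @param bed_time_mean,rise_time_mean Mean bed/rise clock times (`"HH:MM"`).
#' @param bed_time_sd,rise_time_sd Night-to-night SD of bed/rise times (min).
#' @param turn_rate In-bed posture turns per hour (Poisson).
#' @param activity_burst_rate Out-of-bed movement bursts per hour (Poisson).
#' @param posture_change_rate Out-of-bed quiet posture changes per hour.
#' @param activity_noise_sd Acceleration SD during bursts (g).
#' @param rest_noise_sd Baseline sensor/body noise SD while worn (g).
#' @param nonwear_prob_per_day Probability that a daytime window contains one
#'   non-wear episode (device left on a table: exactly constant signal).
#' @param nonwear_duration Length-2 range of non-wear episode durations (min).
#' @param nonwear_jitter_sd Optional sub-threshold noise SD (g) added during
#'   non-wear for robustness experiments; default 0 (perfectly flat).
#' @param miscalibration `NULL` for a perfectly calibrated device, or
#'   `list(gain =, offset =)` of per-axis affine miscalibration applied to
#'   the emitted signal (`a' = gain * a + offset`, offset in g).
#' @param annotator_jitter_sd SD of the Gaussian jitter (min) applied to
#'   interval boundaries to produce the two annotator tracks.
#' @param seed Base RNG seed; each subject uses a derived substream so
#'   subjects are mutually independent and individually reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 1, days_per_subject = 2, sample_rate = 1,
                       bed_time_mean = "23:00", bed_time_sd = 30,
                       rise_time_mean = "07:00", rise_time_sd = 30,
                       turn_rate = 2, activity_burst_rate = 6,
                       posture_change_rate = 4,
                       activity_noise_sd = 0.25, rest_noise_sd = 0.01,
                       nonwear_prob_per_day = 0.1,
                       nonwear_duration = c(60, 180), nonwear_jitter_sd = 0,
                       miscalibration = NULL,
                       annotator_jitter_sd = 5, seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              days_per_subject = as.integer(days_per_subject),
              sample_rate = sample_rate,
              bed_time_mean = clock_to_minutes(bed_time_mean),
              bed_time_sd = bed_time_sd,
              rise_time_mean = clock_to_minutes(rise_time_mean),
              rise_time_sd = rise_time_sd,
              turn_rate = turn_rate,
              activity_burst_rate = activity_burst_rate,
              posture_change_rate = posture_change_rate,
              activity_noise_sd = activity_noise_sd,
              rest_noise_sd = rest_noise_sd,
              nonwear_prob_per_day = nonwear_prob_per_day,
              nonwear_duration = nonwear_duration,
              nonwear_jitter_sd = nonwear_jitter_sd,
              miscalibration = miscalibration,
              annotator_jitter_sd = annotator_jitter_sd,
              seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  nonneg <- c("bed_time_sd", "rise_time_sd", "turn_rate", "activity_burst_rate",
              "posture_change_rate", "activity_noise_sd", "rest_noise_sd",
              "annotator_jitter_sd", "nonwear_jitter_sd")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0)
      stop(sprintf("sim_config: '%s' must be a non-negative scalar", f),
           call. = FALSE)
  }
  if (cfg$n_subjects < 1) stop("sim_config: n_subjects must be >= 1", call. = FALSE)
  if (cfg$days_per_subject < 1)
    stop("sim_config: days_per_subject must be >= 1 (zero-length day)", call. = FALSE)
  if (cfg$sample_rate < 1 / 60)
    stop("sim_config: sample_rate must give at least one sample per minute",
         call. = FALSE)
  stopifnot_scalar_prob(cfg$nonwear_prob_per_day, "nonwear_prob_per_day")
  if (length(cfg$nonwear_duration) != 2 || diff(cfg$nonwear_duration) < 0 ||
      any(cfg$nonwear_duration <= 0))
    stop("sim_config: nonwear_duration must be an increasing positive range",
         call. = FALSE)
  # in-bed interval must have positive length (crossing midnight is fine)
  tib <- (cfg$rise_time_mean + 1440 - cfg$bed_time_mean) %% 1440
  if (tib <= 0) stop("sim_config: bed/rise times give a zero-length night",
                     call. = FALSE)
  if (!is.null(cfg$miscalibration)) {
    m <- cfg$miscalibration
    if (!is.list(m) || length(m$gain) != 3 || length(m$offset) != 3)
      stop("sim_config: miscalibration must be list(gain = <3>, offset = <3>)",
           call. = FALSE)
  }
  invisible(cfg)
}

# Canonical lying (gravity along x or z) and upright (gravity along y)
# orientations for a right-hip device; each sampled segment gets a small
# random tilt so no two segments are exactly identical.
lying_bases <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(-1, 0, 0))

sample_orientation <- function(base, tilt_sd) {
  v <- base + stats::rnorm(3, 0, tilt_sd)
  v / sqrt(sum(v^2))
}

sample_lying <- function(tilt_sd = 0.08, avoid = NULL) {
  k <- sample.int(4, 1)
  if (!is.null(avoid) && k == avoid) k <- (k %% 4) + 1L
  list(k = k, v = sample_orientation(lying_bases[k, ], tilt_sd))
}

#' Simulate one subject's multi-day recording
#'
#' Generates a tri-axial trace with ground-truth in-bed intervals and
#' per-minute labels, optional non-wear episodes, optional per-axis affine
#' miscalibration, and two annotator tracks whose interval boundaries are
#' jittered versions of the truth (structure is never altered). In-bed
#' segments are a near-constant lying gravity vector with Poisson-timed
#' instantaneous turns; out-of-bed segments alternate quiet upright postures
#' with high-amplitude activity bursts; non-wear segments are exactly
#' constant. The recording starts at 12:00 noon.
#'
#' Deterministic for a fixed `(seed, subject_index)` pair: every subject
#' draws from its own derived RNG substream, so cohorts are reproducible and
#' subjects mutually independent.
#'
#' @param config A [sim_config()].
#' @param subject_index Non-negative integer identifying the subject.
#' @return A `sim_recording`: list with `trace` ([raw_trace()]),
#'   `truth_intervals`, `truth_labels` (per-minute 0/1), `nonwear_intervals`,
#'   `annotator_a`, `annotator_b` ([interval_set()]s),
#'   `applied_miscalibration`, and `subject_id`.
#' @export
simulate_subject <- function(config, subject_index = 0) {
  validate_sim_config(config)
  if (subject_index < 0) stop("subject_index must be >= 0")
  with_local_seed(derive_seed(config$seed, subject_index), {
    days <- config$days_per_subject
    rate <- config$sample_rate
    S <- days * 86400                       # recording length in seconds
    n <- as.integer(round(S * rate))
    t0 <- as_utc("2024-01-06 12:00:00")     # all recordings start at noon
    off <- (seq_len(n) - 1) / rate

    # --- bed/rise schedule (seconds from recording start at noon) ---------
    bed_off <- (config$bed_time_mean - 720) * 60   # 23:00 -> +39600 s
    rise_off <- (config$rise_time_mean + 720) * 60 # 07:00 next day -> +68400 s
    bed_s <- rise_s <- numeric(days)
    for (d in seq_len(days) - 1) {
      bed_s[d + 1] <- d * 86400 + bed_off + stats::rnorm(1, 0, config$bed_time_sd * 60)
      rise_s[d + 1] <- d * 86400 + rise_off + stats::rnorm(1, 0, config$rise_time_sd * 60)
    }
    bed_s <- pmax(pmin(bed_s, S - 120), 60)
    rise_s <- pmax(pmin(rise_s, S - 60), bed_s + 120)
    truth <- interval_set(t0 + bed_s, t0 + rise_s)

    # --- orientation change-points ----------------------------------------
    cp_t <- 0
    cp_v <- matrix(sample_orientation(c(0, 1, 0), 0.15), 1)
    for (d in seq_len(days)) {
      night <- c(bed_s[d], rise_s[d])
      cur <- sample_lying()
      cp_t <- c(cp_t, night[1]); cp_v <- rbind(cp_v, cur$v)
      n_turns <- stats::rpois(1, config$turn_rate * diff(night) / 3600)
      if (n_turns > 0) {
        for (tt in sort(stats::runif(n_turns, night[1], night[2]))) {
          cur <- sample_lying(avoid = cur$k)
          cp_t <- c(cp_t, tt); cp_v <- rbind(cp_v, cur$v)
        }
      }
      cp_t <- c(cp_t, night[2])
      cp_v <- rbind(cp_v, sample_orientation(c(0, 1, 0), 0.15))
    }
    # quiet posture changes while out of bed
    day_wins <- cbind(c(0, rise_s), c(bed_s, S))
    for (w in seq_len(nrow(day_wins))) {
      len <- day_wins[w, 2] - day_wins[w, 1]
      if (len <= 0) next
      n_pc <- stats::rpois(1, config$posture_change_rate * len / 3600)
      if (n_pc > 0) {
        for (tt in sort(stats::runif(n_pc, day_wins[w, 1], day_wins[w, 2]))) {
          cp_t <- c(cp_t, tt)
          cp_v <- rbind(cp_v, sample_orientation(c(0, 1, 0), 0.15))
        }
      }
    }
    o <- order(cp_t)
    cp_t <- cp_t[o]; cp_v <- cp_v[o, , drop = FALSE]
    sig <- cp_v[findInterval(off, cp_t), , drop = FALSE]

    # --- activity bursts (out of bed only) --------------------------------
    burst_s <- burst_e <- numeric(0)
    for (w in seq_len(nrow(day_wins))) {
      len <- day_wins[w, 2] - day_wins[w, 1]
      if (len <= 0) next
      n_b <- stats::rpois(1, config$activity_burst_rate * len / 3600)
      if (n_b > 0) {
        bs <- sort(stats::runif(n_b, day_wins[w, 1], day_wins[w, 2]))
        be <- pmin(bs + stats::runif(n_b, 60, 300), day_wins[w, 2])
        burst_s <- c(burst_s, bs); burst_e <- c(burst_e, be)
      }
    }
    in_burst <- rep(FALSE, n)
    if (length(burst_s)) {
      bi <- merge_intervals(burst_s + as.numeric(t0), burst_e + as.numeric(t0))
      bs <- as.numeric(bi$start) - as.numeric(t0)
      be <- as.numeric(bi$end) - as.numeric(t0)
      j <- findInterval(off, bs)
      in_burst <- j > 0 & off < be[pmax(j, 1L)]
    }

    # --- noise ------------------------------------------------------------
    if (config$rest_noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(3L * n, 0, config$rest_noise_sd), n, 3)
    nb <- sum(in_burst)
    if (nb > 0 && config$activity_noise_sd > 0)
      sig[in_burst, ] <- sig[in_burst, ] +
        matrix(stats::rnorm(3L * nb, 0, config$activity_noise_sd), nb, 3)

    # --- non-wear episodes (device flat on a table, exactly constant) -----
    nw_s <- nw_e <- numeric(0)
    for (w in seq_len(nrow(day_wins))) {
      if (stats::runif(1) >= config$nonwear_prob_per_day) next
      dur <- stats::runif(1, config$nonwear_duration[1], config$nonwear_duration[2]) * 60
      lo <- day_wins[w, 1] + 1800
      hi <- day_wins[w, 2] - 1800 - dur
      if (hi <= lo) next
      st <- stats::runif(1, lo, hi)
      nw_s <- c(nw_s, st); nw_e <- c(nw_e, st + dur)
    }
    if (length(nw_s)) {
      for (k in seq_along(nw_s)) {
        sel <- off >= nw_s[k] & off < nw_e[k]
        sig[sel, ] <- rep(c(0, 0, 1), each = sum(sel))
        if (config$nonwear_jitter_sd > 0)
          sig[sel, ] <- sig[sel, ] +
            matrix(stats::rnorm(3L * sum(sel), 0, config$nonwear_jitter_sd),
                   sum(sel), 3)
      }
      nonwear <- interval_set(t0 + nw_s, t0 + nw_e)
    } else nonwear <- interval_set()

    # --- miscalibration (per-axis affine a' = gain * a + offset) ----------
    if (!is.null(config$miscalibration)) {
      m <- config$miscalibration
      sig <- sweep(sweep(sig, 2, m$gain, "*"), 2, m$offset, "+")
      applied <- m
    } else applied <- list(gain = c(1, 1, 1), offset = c(0, 0, 0))

    # --- annotator tracks: boundary jitter only ---------------------------
    jitter_track <- function() {
      s <- as.numeric(truth$start) + stats::rnorm(days, 0, config$annotator_jitter_sd * 60)
      e <- as.numeric(truth$end) + stats::rnorm(days, 0, config$annotator_jitter_sd * 60)
      e <- pmax(e, s + 60)                 # keep every interval
      if (days > 1) for (k in 2:days) s[k] <- max(s[k], e[k - 1] + 1)
      e <- pmax(e, s + 60)
      interval_set(.POSIXct(s, tz = "UTC"), .POSIXct(e, tz = "UTC"))
    }
    ann_a <- jitter_track()
    ann_b <- jitter_track()

    labels <- rasterize(truth, t0, days * 1440L)

    structure(list(
      trace = raw_trace(sig, t0, rate),
      truth_intervals = truth,
      truth_labels = labels,
      nonwear_intervals = nonwear,
      annotator_a = ann_a,
      annotator_b = ann_b,
      applied_miscalibration = applied,
      subject_id = sprintf("S%03d", subject_index)),
      class = "sim_recording")
  })
}

#' @export
print.sim_recording <- function(x, ...) {
  cat(sprintf("<sim_recording %s: %.1f h trace, %d night(s), %d non-wear episode(s)>\n",
              x$subject_id, nrow(x$trace$data) / x$trace$sample_rate / 3600,
              nrow(x$truth_intervals), nrow(x$nonwear_intervals)))
  invisible(x)
}

#' Simulate a cohort
#'
#' One [simulate_subject()] call per subject (indices `0 .. n_subjects - 1`),
#' each on its own RNG substream, in stable order.
#'
#' @param config A [sim_config()].
#' @return List of `sim_recording` objects.
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$n_subjects) - 1L,
         function(i) simulate_subject(config, i))
}

#' Write a simulated recording to plain-text files
#'
#' Emits `trace.csv` (`timestamp_iso8601,x_g,y_g,z_g`), `labels.csv`
#' (`minute_start_iso8601,in_bed`), one interval CSV per track
#' (`truth|annotator_a|annotator_b|nonwear`), and a JSON sidecar with the
#' generating configuration and the applied miscalibration.
#'
#' @param rec A `sim_recording`.
#' @param dir Output directory (created if missing).
#' @param config Optional [sim_config()] stored in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trace(rec$trace, file.path(dir, "trace.csv"))
  write_labels(rec$truth_labels, rec$trace$start_time, file.path(dir, "labels.csv"))
  write_intervals(rec$truth_intervals, file.path(dir, "truth_intervals.csv"))
  write_intervals(rec$annotator_a, file.path(dir, "annotator_a.csv"))
  write_intervals(rec$annotator_b, file.path(dir, "annotator_b.csv"))
  write_intervals(rec$nonwear_intervals, file.path(dir, "nonwear_intervals.csv"))
  sidecar <- list(subject_id = rec$subject_id,
                  applied_miscalibration = rec$applied_miscalibration,
                  config = if (!is.null(config)) unclass(config))
  jsonlite::write_json(sidecar, file.path(dir, "recording.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
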
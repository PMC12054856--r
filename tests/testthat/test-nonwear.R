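test_that("constant, noisy, and 2-of-3 traces classify as expected", {
  cfg <- nwt_config()
  flat <- const_trace(c(0, 0, 1), n_sec = 2 * 3600)
  nw <- detect_nonwear(flat, cfg)
  expect_equal(interval_measure(nw), 2 * 3600)

  set.seed(40)
  noisy <- raw_trace(matrix(rnorm(3 * 2 * 3600, 0, 0.020), ncol = 3),
                     t_noon, 1)
  expect_equal(nrow(detect_nonwear(noisy, cfg)), 0)

  # two flat axes, one active axis: the 2-of-3 rule flags it
  two_flat <- raw_trace(cbind(0, 0, rnorm(2 * 3600, 0, 0.2)), t_noon, 1)
  expect_equal(interval_measure(detect_nonwear(two_flat, cfg)), 2 * 3600)

  # one flat axis only: not flagged
  one_flat <- raw_trace(cbind(0, rnorm(2 * 3600, 0, 0.2),
                              rnorm(2 * 3600, 0, 0.2)), t_noon, 1)
  expect_equal(nrow(detect_nonwear(one_flat, cfg)), 0)
})

test_that("short traces warn and detection matches the brute-force oracle", {
  expect_warning(nw <- detect_nonwear(const_trace(n_sec = 600)), "shorter")
  expect_equal(nrow(nw), 0)

  set.seed(41)
  for (k in 1:8) {
    n <- 6 * 3600
    base <- matrix(rnorm(3 * n, 0, 0.05), n, 3)
    # plant 0-2 flat episodes of random length
    for (ep in seq_len(sample(0:2, 1))) {
      len <- sample(1800:7200, 1)
      st <- sample(n - len, 1)
      base[st:(st + len - 1), ] <- rep(runif(3, -1, 1), each = len)
    }
    tr <- raw_trace(base, t_noon, 1)
    got <- detect_nonwear(tr)
    ora <- nonwear_oracle(tr)
    expect_identical(got$start, ora$start)
    expect_identical(got$end, ora$end)
  }
})

test_that("lowering the sd threshold never increases flagged time", {
  set.seed(42)
  n <- 6 * 3600
  base <- matrix(rnorm(3 * n, 0, 0.003), n, 3)   # borderline-quiet signal
  base[10000:20000, ] <- rep(c(0.1, 0.2, 0.97), each = 10001)
  tr <- raw_trace(base, t_noon, 1)
  flagged <- vapply(c(5, 3, 1, 0.5), function(th)
    interval_measure(detect_nonwear(tr, nwt_config(sd_threshold = th,
                                                   range_threshold = 1e-9))),
    0)
  expect_true(all(diff(flagged) <= 0))
})

test_that("sliding windows flag a superset of non-overlapping windows", {
  set.seed(45)
  n <- 6 * 3600
  base <- matrix(rnorm(3 * n, 0, 0.05), n, 3)
  base[5000:12000, ] <- rep(c(0, 0, 1), each = 7001)
  base[14000:17900, ] <- rep(c(1, 0, 0), each = 3901)
  tr <- raw_trace(base, t_noon, 1)
  slid <- detect_nonwear(tr, nwt_config(slide_minutes = 15))
  block <- detect_nonwear(tr, nwt_config(slide_minutes = 60))
  expect_equal(interval_measure(interval_intersection(slid, block)),
               interval_measure(block))   # block result contained in slid
})

test_that("per-day non-wear minutes agree with a minute-by-minute count", {
  ms <- make_ms(matrix(0, 1440, 3), start = t_noon)
  day <- split_noon_days(ms)[[1]]
  expect_equal(nwt_minutes_per_day(interval_set(), day), 0)
  nw <- iv("2024-01-07 02:00", "2024-01-07 03:00")
  expect_equal(nwt_minutes_per_day(nw, day), 60)

  set.seed(43)
  for (k in 1:20) {
    s <- t_noon + sort(round(runif(4, 0, 1435)) * 60 + round(runif(4, 0, 59)))
    nw <- tryCatch(interval_set(s[c(1, 3)], s[c(2, 4)] + 30),
                   error = function(e) NULL)
    if (is.null(nw)) next
    got <- nwt_minutes_per_day(nw, day)
    mids <- as.numeric(t_noon) + (0:1439) * 60 + 30
    brute <- sum(vapply(mids, function(m)
      any(m >= as.numeric(nw$start) & m < as.numeric(nw$end)), TRUE))
    expect_equal(got, brute)
  }
})

test_that("simulated flat non-wear episodes are fully detected", {
  cfg <- sim_config(seed = 44, days_per_subject = 2, nonwear_prob_per_day = 1,
                    nonwear_duration = c(90, 180))
  rec <- simulate_subject(cfg, 0)
  expect_gt(nrow(rec$nonwear_intervals), 0)
  det <- detect_nonwear(rec$trace)
  for (i in seq_len(nrow(rec$nonwear_intervals))) {
    ep <- rec$nonwear_intervals[i, ]
    hit <- interval_measure(interval_intersection(
      interval_set(ep$start, ep$end), det))
    expect_gt(hit, 0)   # every episode longer than the window is found
  }
})
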
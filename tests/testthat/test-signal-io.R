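test_that("trace CSV round-trips and validates its dialect", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("timestamp_iso8601,x_g,y_g,z_g",
               "2024-01-06T12:00:00.000,0.1,-0.2,0.97",
               "2024-01-06T12:00:01.000,0.11,-0.21,0.96",
               "2024-01-06T12:00:02.000,0.09,-0.19,0.98"), path)
  tr <- read_trace(path)
  expect_equal(nrow(tr$data), 3)
  expect_equal(tr$sample_rate, 1)
  expect_equal(tr$data[2, "y"], -0.21, ignore_attr = TRUE)

  set.seed(1)
  orig <- raw_trace(matrix(rnorm(300), ncol = 3), t_noon, 1)
  write_trace(orig, path)
  back <- read_trace(path)
  expect_equal(back$data, orig$data, tolerance = 2e-6)
  expect_equal(back$start_time, orig$start_time)

  writeLines(c("timestamp_iso8601,x_g,y_g,z_g",
               "2024-01-06T12:00:00.000,0,0,1",
               "2024-01-06T12:00:01.000,0,0,1",
               "2024-01-06T12:02:01.000,0,0,1"), path)
  expect_error(read_trace(path), "row 3")
  writeLines(c("timestamp_iso8601,x_g,y_g,z_g",
               "2024-01-06T12:00:01.000,0,0,1",
               "2024-01-06T12:00:00.000,0,0,1"), path)
  expect_error(read_trace(path), "non-monotone")
  writeLines("timestamp,x,y,z", path)
  expect_error(read_trace(path), "missing column")
})

test_that("per-minute aggregation takes the within-minute mean", {
  tr <- const_trace(c(0, 0, 1), n_sec = 120)
  ms <- to_minutes(tr)
  expect_equal(n_minutes(ms), 2)
  expect_equal(unname(ms$values), matrix(c(0, 0, 0, 0, 1, 1), 2))

  z <- rep(c(0.9, 1.1), 30)
  tr <- raw_trace(cbind(0, 0, z), t_noon, 1)
  expect_equal(unname(to_minutes(tr)$values[1, 3]), 1.0)

  day <- simulate_subject(sim_config(seed = 9, days_per_subject = 1), 0)
  expect_equal(n_minutes(to_minutes(day$trace)), 1440)

  # partial leading/trailing minutes are dropped
  tr <- const_trace(c(1, 0, 0), n_sec = 150, start = t_noon + 30)
  ms <- to_minutes(tr)
  expect_equal(n_minutes(ms), 2)
  expect_equal(ms$start_minute, t_noon + 60)
})

test_that("aggregation commutes with minute-aligned concatenation", {
  set.seed(8)
  d <- matrix(rnorm(540), ncol = 3)
  whole <- to_minutes(raw_trace(d, t_noon, 1))
  first <- to_minutes(raw_trace(d[1:120, ], t_noon, 1))
  second <- to_minutes(raw_trace(d[121:180, ], t_noon + 120, 1))
  expect_equal(rbind(first$values, second$values), whole$values)
})

test_that("rasterization follows the midpoint rule and round-trips", {
  night <- iv("2024-01-06 23:00", "2024-01-07 07:00")
  track <- rasterize(night, t_noon, 1440)
  expect_equal(sum(track), 480)
  expect_equal(rasterize(interval_set(), t_noon, 100), integer(100))

  back <- track_to_intervals(track, t_noon)
  expect_equal(back$start, night$start)
  expect_equal(back$end, night$end)

  # de-rasterize then re-rasterize is idempotent on arbitrary sets
  set.seed(42)
  for (k in 1:20) {
    s <- sort(runif(3, 0, 1200))
    ints <- interval_set(t_noon + c(s[1], s[3]) * 60,
                         t_noon + c(s[2], s[3] + 5 + runif(1, 0, 10)) * 60)
    r1 <- rasterize(ints, t_noon, 1440)
    snapped <- track_to_intervals(r1, t_noon)
    expect_identical(rasterize(snapped, t_noon, 1440), r1)
  }
})

test_that("noon-day splitting partitions the minute axis", {
  # 7-day recording starting 14:37 -> 6 full noon-to-noon windows
  start <- as.POSIXct("2024-01-06 14:37:00", tz = "UTC")
  n <- 7 * 1440
  ms <- make_ms(matrix(0, n, 3), start = start)
  wins <- split_noon_days(ms)
  expect_equal(sum(vapply(wins, function(w) w$full, TRUE)), 6)
  all_idx <- unlist(lapply(wins, function(w) w$idx))
  expect_identical(sort(all_idx), seq_len(n))         # partition
  expect_identical(anyDuplicated(all_idx), 0L)

  # exactly noon -> noon: one single full window
  ms <- make_ms(matrix(0, 1440, 3), start = t_noon)
  wins <- split_noon_days(ms)
  expect_length(wins, 1)
  expect_true(wins[[1]]$full)

  # 15:00 day 1 -> 10:00 day 4: three windows, only the middle one full
  start <- as.POSIXct("2024-01-06 15:00:00", tz = "UTC")
  n <- as.integer(difftime(as.POSIXct("2024-01-09 10:00:00", tz = "UTC"),
                           start, units = "mins"))
  wins <- split_noon_days(make_ms(matrix(0, n, 3), start = start))
  expect_length(wins, 3)
  expect_identical(vapply(wins, function(w) w$full, TRUE),
                   c(FALSE, TRUE, FALSE))
})
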
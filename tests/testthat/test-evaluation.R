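test_that("confusion metrics match hand arithmetic and edge conventions", {
  lab <- c(rep(1L, 480), rep(0L, 960))
  expect_equal(day_metrics(lab, lab),
               list(accuracy = 1, sensitivity = 1, specificity = 1))
  # TP=420 TN=900 FP=60 FN=60
  pred <- c(rep(1L, 420), rep(0L, 60), rep(0L, 900), rep(1L, 60))
  m <- day_metrics(pred, lab)
  expect_equal(m$accuracy, 1320 / 1440)
  expect_equal(m$sensitivity, 420 / 480)
  expect_equal(m$specificity, 900 / 960)
  # zero denominators yield absent, not zero
  expect_true(is.na(day_metrics(rep(0L, 10), rep(0L, 10))$sensitivity))
  expect_true(is.na(day_metrics(rep(1L, 10), rep(1L, 10))$specificity))
  expect_error(day_metrics(1:3 * 0L, 1:4 * 0L), "length")
})

test_that("accuracy decomposes exactly by prevalence", {
  set.seed(60)
  for (k in 1:50) {
    n <- sample(50:500, 1)
    lab <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- ifelse(runif(n) < 0.8, lab, 1L - lab)
    m <- day_metrics(pred, lab)
    prev <- mean(lab)
    if (is.na(m$sensitivity) || is.na(m$specificity)) next
    expect_equal(m$accuracy,
                 prev * m$sensitivity + (1 - prev) * m$specificity)
  }
})

test_that("the all-out-of-bed baseline is definitionally consistent", {
  lab <- rep(c(1L, 0L, 0L), 100)
  expect_equal(baseline_accuracy(lab), 2 / 3)
  expect_equal(baseline_accuracy(rep(0L, 5)), 1)
  set.seed(61)
  lab <- rbinom(300, 1, 0.3)
  expect_equal(baseline_accuracy(lab),
               day_metrics(rep(0L, 300), lab)$accuracy)
})

test_that("outlier flagging uses strict 60/1380-minute bounds", {
  reports <- data.frame(predicted_tib = c(30, 60, 59, 480, 1380, 1381, 1440))
  out <- flag_outliers(reports)
  expect_identical(out$outlier, c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("subject-level summaries use two-stage averaging", {
  reports <- data.frame(subject = c("a", "a", "b"),
                        accuracy = c(0.88, 0.92, 0.94))
  s <- subject_summary(reports, "accuracy")
  expect_equal(s$mean, mean(c(0.90, 0.94)))
  expect_equal(s$n_subjects, 2)
  one <- subject_summary(data.frame(subject = "a", accuracy = 0.9), "accuracy")
  expect_true(is.na(one$sd))

  set.seed(62)
  reports <- data.frame(subject = sample(letters[1:6], 60, replace = TRUE),
                        accuracy = runif(60, 0.7, 1))
  s <- subject_summary(reports, "accuracy")
  brute <- sapply(split(reports$accuracy, reports$subject), mean)
  expect_equal(s$mean, mean(brute))
  expect_equal(s$sd, sd(brute))
})

test_that("daily TiB totals use full days only and match brute force", {
  night <- function(d) iv(sprintf("2024-01-%02d 23:00", d),
                          sprintf("2024-01-%02d 07:00", d + 1))
  pred <- do.call(interval_union,
                  list(interval_union(night(6), night(7)), night(8)))
  ms <- make_ms(matrix(0, 3 * 1440, 3), start = t_noon)
  wins <- split_noon_days(ms)
  ds <- daily_tib_summary(pred, wins)
  expect_equal(ds$per_day, rep(480, 3))
  expect_equal(ds$mean, 480)

  # no full day -> absent with warning
  short <- split_noon_days(make_ms(matrix(0, 100, 3), start = t_noon + 3600))
  expect_warning(res <- daily_tib_summary(pred, short), "no fully recorded")
  expect_true(is.na(res$mean))

  set.seed(63)
  track <- rbinom(3 * 1440, 1, 0.3)
  ints <- track_to_intervals(track, t_noon)
  ds <- daily_tib_summary(ints, wins)
  brute <- sapply(0:2, function(d) sum(track[(d * 1440 + 1):((d + 1) * 1440)]))
  expect_equal(ds$per_day, brute)
})

test_that("Bland-Altman recovers known bias and limits", {
  ba <- bland_altman(c(600, 500), c(580, 510))
  expect_equal(ba$difference, c(20, -10))
  expect_equal(ba$bias, 5)
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(unname(same$loa), c(0, 0))

  set.seed(64)
  y <- runif(200, 400, 700)
  x <- y + 25 + rnorm(200, 0, 10)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 25, tolerance = 0.1)
  expect_lt(abs(unname(diff(ba$loa)) - 2 * 1.96 * 10), 6)
})

test_that("day reports assemble prediction, labels, non-wear and flags", {
  lab <- rasterize(iv("2024-01-06 23:00", "2024-01-07 07:00"), t_noon, 2880)
  ms <- make_ms(matrix(0, 2880, 3), labels = lab, start = t_noon)
  pred <- lab
  pred[1:30] <- 1L   # small disagreement on day 1
  nwt <- iv("2024-01-07 13:00", "2024-01-07 14:30")
  rep_df <- day_reports(pred, ms, nwt, subject = "X")
  expect_equal(nrow(rep_df), 2)
  expect_equal(rep_df$predicted_tib, c(510, 0))
  expect_equal(rep_df$labelled_tib, c(480, 0))
  expect_identical(rep_df$outlier, c(FALSE, TRUE))  # day 2: 0 min predicted
  expect_equal(rep_df$nwt_minutes, c(0, 90))
  expect_equal(rep_df$accuracy[1], 1410 / 1440)
})
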
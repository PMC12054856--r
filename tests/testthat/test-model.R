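small_cfg <- function(seed = 1, max_epochs = 15) {
  model_config(bidirectional = FALSE, n_layers = 1, cells_per_layer = 4,
               learning_rate = 3e-3, max_epochs = max_epochs,
               eval_every = 50, patience = 5, seed = seed)
}
small_aug <- aug_config(n_crops = 10, min_crop_minutes = 30)

test_that("parameter counts follow the architecture", {
  # 1 layer, H cells, uni: 4H(3+H+1) + H + 1
  for (H in c(1, 4, 32)) {
    expect_equal(lstm_n_params(model_config(FALSE, 1, H)),
                 4 * H * (3 + H + 1) + H + 1)
  }
  # bidirectional doubles the recurrent stack and the readout width
  H <- 8
  expect_equal(lstm_n_params(model_config(TRUE, 1, H)),
               2 * 4 * H * (3 + H + 1) + 2 * H + 1)
  # deeper layers consume the (possibly doubled) hidden width
  expect_equal(lstm_n_params(model_config(FALSE, 2, H)),
               4 * H * (3 + H + 1) + 4 * H * (H + H + 1) + H + 1)
  expect_equal(length(model_grid()), 48)
})

test_that("training separates an easy posture problem almost perfectly", {
  cohort <- separable_cohort(n_subjects = 5, n_min = 240)
  nc <- normalize_cohort(cohort)
  mod <- train_lstm(nc$series, small_cfg(seed = 1), small_aug)
  expect_gte(pooled_accuracy(mod, nc$series), 0.99)
})

test_that("degenerate or inconsistent training inputs are refused", {
  cohort <- separable_cohort(3, 120)
  nc <- normalize_cohort(cohort)
  zeroed <- lapply(nc$series, function(s) { s$labels[] <- 0L; s })
  expect_error(train_lstm(zeroed, small_cfg()), "degenerate labels")
  expect_error(train_lstm(nc$series[1], small_cfg()), "at least 2")
  expect_error(train_lstm(cohort, small_cfg()), "normalized")
  mixed <- nc$series
  mixed[[1]]$norm_ref <- "other"
  expect_error(train_lstm(mixed, small_cfg()), "different statistics")
})

test_that("fixed seeds reproduce the training trajectory exactly", {
  cohort <- separable_cohort(3, 120)
  nc <- normalize_cohort(cohort)
  m1 <- train_lstm(nc$series, small_cfg(seed = 5, max_epochs = 2), small_aug)
  m2 <- train_lstm(nc$series, small_cfg(seed = 5, max_epochs = 2), small_aug)
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$training_log, m2$training_log)
  m3 <- train_lstm(nc$series, small_cfg(seed = 6, max_epochs = 2), small_aug)
  expect_false(identical(m1$theta, m3$theta))
})

test_that("prediction preserves length and guards normalization provenance", {
  cohort <- separable_cohort(3, 120)
  nc <- normalize_cohort(cohort)
  mod <- train_lstm(nc$series, small_cfg(seed = 2, max_epochs = 1), small_aug)
  for (len in c(5, 240, 1440)) {
    s <- make_ms(matrix(rnorm(3 * len), len, 3), normalized = TRUE,
                 norm_ref = mod$norm_ref)
    p <- predict_lstm(mod, s)
    expect_length(p$prob, len)
    expect_length(p$track, len)
    expect_true(all(p$prob >= 0 & p$prob <= 1))
    expect_identical(p$track, as.integer(p$prob >= 0.5))
  }
  wrong <- make_ms(matrix(0, 10, 3), normalized = TRUE, norm_ref = "other")
  expect_error(predict_lstm(mod, wrong), "incompatible normalization")
  raw <- make_ms(matrix(0, 10, 3))
  expect_error(predict_lstm(mod, raw), "normalized")
})

test_that("trained models beat the always-out-of-bed baseline on held-out data", {
  cohort <- separable_cohort(n_subjects = 7, n_min = 240, seed = 101)
  stats <- fit_normalizer(cohort[1:5], "train")
  trn <- lapply(cohort[1:5], apply_normalizer, stats = stats)
  tst <- lapply(cohort[6:7], apply_normalizer, stats = stats)
  mod <- train_lstm(trn, small_cfg(seed = 3), small_aug)
  acc <- pooled_accuracy(mod, tst)
  base <- baseline_accuracy(unlist(lapply(tst, function(s) s$labels)))
  expect_gt(acc, base)
})

test_that("checkpoints round-trip through JSON exactly", {
  cohort <- separable_cohort(3, 120)
  nc <- normalize_cohort(cohort)
  mod <- train_lstm(nc$series, small_cfg(seed = 4, max_epochs = 1), small_aug)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(mod, path)
  back <- load_model(path)
  expect_identical(back$theta, mod$theta)
  expect_identical(back$norm_ref, mod$norm_ref)
  s <- nc$series[[1]]
  expect_identical(predict_lstm(back, s)$prob, predict_lstm(mod, s)$prob)
})

test_that("cross-validation partitions subjects and guards leakage", {
  fold <- tibhip:::make_folds(20, 10, seed = 1)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 2))
  expect_error(tibhip:::make_folds(5, 10), "fewer subjects")

  cohort <- separable_cohort(n_subjects = 6, n_min = 120, seed = 7)
  grid <- list(model_config(FALSE, 1, 2, max_epochs = 1, eval_every = 20),
               model_config(FALSE, 1, 4, max_epochs = 1, eval_every = 20))
  cv <- cross_validate(cohort, grid, aug_config(n_crops = 5), k = 3, seed = 2)
  expect_equal(nrow(cv), 2)
  expect_true(all(is.finite(cv$mean_accuracy)))
  expect_true(all(cv$mean_accuracy >= 0 & cv$mean_accuracy <= 1))
  # normalizer fitted freshly inside each fold
  expect_equal(length(unique(attr(cv, "norm_refs"))), 3)
  expect_error(cross_validate(cohort, grid, k = 10), "at least k=10")
})

test_that("model selection prefers sparsity within one standard error", {
  row <- function(bi, l, c, acc, se) data.frame(
    bidirectional = bi, n_layers = l, cells_per_layer = c,
    mean_accuracy = acc, se_accuracy = se,
    n_params = lstm_n_params(model_config(bi, l, c)))
  # single candidate
  tab <- row(TRUE, 4, 32, 0.95, 0.01)
  expect_equal(select_model(tab)$cells_per_layer, 32)
  # equal accuracy: the sparser 1x4 wins over 4x32
  tab <- rbind(row(FALSE, 1, 4, 0.94, 0.005), row(TRUE, 4, 32, 0.94, 0.005))
  sel <- select_model(tab)
  expect_equal(sel$n_layers, 1)
  expect_equal(sel$cells_per_layer, 4)
  expect_false(sel$bidirectional)
  # a clear winner outside the others' bands is chosen regardless of size
  tab <- rbind(row(FALSE, 1, 4, 0.80, 0.002), row(TRUE, 4, 32, 0.95, 0.002))
  sel <- select_model(tab)
  expect_equal(sel$cells_per_layer, 32)
  expect_true(sel$bidirectional)
})
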
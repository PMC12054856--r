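#' LSTM model configuration
#'
#' Architecture and training controls for the per-minute in-bed sequence
#' labeller. The hyperparameter search space used for model selection spans
#' 1/2/4 layers, 1--128 cells per layer, and uni- vs bi-directional
#' processing (see [model_grid()]).
#'
#' Training minimizes per-minute binary cross-entropy with Adam over a
#' stream of augmented crops (one crop per gradient step). Early stopping
#' monitors validation loss every `eval_every` steps and stops after
#' `patience` evaluations without improvement; one training pass ("epoch")
#' consumes `n_crops` crops per source sequence.
#'
#' @param bidirectional Process the series in both temporal directions.
#' @param n_layers Stacked LSTM layers (search space: 1, 2, 4).
#' @param cells_per_layer Hidden cells per layer and direction
#'   (search space: 1, 2, 4, 8, 16, 32, 64, 128).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param max_epochs Cap on training passes over the source sequences.
#' @param eval_every Gradient steps between validation evaluations.
#' @param patience Validation evaluations without improvement before stop.
#' @param min_delta Minimum validation-loss improvement (per-minute BCE)
#'   that counts as progress (default 5e-3; chance-level BCE is ~0.69, so
#'   smaller gains are negligible for a 0.5-thresholded labeller).
#' @param clip Global gradient-norm clip (0 disables).
#' @param validation_fraction Fraction of training subjects held out for the
#'   early-stopping criterion.
#' @param seed RNG seed controlling initialization, crop sampling and
#'   subject shuffling; fixed seed gives an identical training trajectory.
#' @return A `model_config` list.
#' @export
model_config <- function(bidirectional = TRUE, n_layers = 2,
                         cells_per_layer = 16, learning_rate = 1e-3,
                         max_epochs = 4, eval_every = 250, patience = 4,
                         min_delta = 5e-3, clip = 5,
                         validation_fraction = 0.2, seed = 1) {
  structure(list(bidirectional = isTRUE(bidirectional),
                 n_layers = as.integer(n_layers),
                 cells_per_layer = as.integer(cells_per_layer),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience),
                 min_delta = min_delta,
                 clip = clip,
                 validation_fraction = validation_fraction,
                 seed = seed),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config: %s LSTM, %d layer(s) x %d cell(s), %d parameters>\n",
              if (x$bidirectional) "bidirectional" else "unidirectional",
              x$n_layers, x$cells_per_layer, lstm_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a configuration
#'
#' @param config A [model_config()].
#' @return Integer parameter count.
#' @export
lstm_n_params <- function(config) {
  cpp_lstm_n_params(config$n_layers, config$cells_per_layer,
                    as.integer(config$bidirectional))
}

#' The hyperparameter search grid
#'
#' All combinations of layers (1, 2, 4), cells per layer (1, 2, 4, 8, 16,
#' 32, 64, 128) and directionality, as [model_config()]s sharing the given
#' training controls.
#'
#' @param layers,cells,bidirectional Grid axes.
#' @param ... Training controls forwarded to [model_config()].
#' @return List of `model_config` objects.
#' @export
model_grid <- function(layers = c(1, 2, 4), cells = c(1, 2, 4, 8, 16, 32, 64, 128),
                       bidirectional = c(FALSE, TRUE), ...) {
  g <- expand.grid(cells = cells, layers = layers, bidir = bidirectional)
  lapply(seq_len(nrow(g)), function(i)
    model_config(bidirectional = g$bidir[i], n_layers = g$layers[i],
                 cells_per_layer = g$cells[i], ...))
}

# Uniform(-1/sqrt(H), 1/sqrt(H)) init; forget-gate biases start at 1.
init_theta <- function(config) {
  L <- config$n_layers; H <- config$cells_per_layer
  ndir <- if (config$bidirectional) 2L else 1L
  P <- cpp_lstm_n_params(L, H, as.integer(config$bidirectional))
  k <- 1 / sqrt(H)
  theta <- stats::runif(P, -k, k)
  off <- 0
  for (l in seq_len(L)) {
    D <- if (l == 1) 3L else H * ndir
    for (d in seq_len(ndir)) {
      off <- off + 4 * H * D + 4 * H * H
      b <- numeric(4 * H)
      b[(H + 1):(2 * H)] <- 1          # forget gate bias
      theta[off + seq_len(4 * H)] <- b
      off <- off + 4 * H
    }
  }
  theta
}

check_training_samples <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 training subjects")
  refs <- vapply(samples, function(s) s$norm_ref %||% NA_character_, "")
  if (any(is.na(refs)) || any(!vapply(samples, function(s) s$normalized, TRUE)))
    stop("all training series must be normalized", call. = FALSE)
  if (length(unique(refs)) != 1)
    stop("training series normalized with different statistics", call. = FALSE)
  labs <- unlist(lapply(samples, function(s) s$labels))
  if (is.null(labs) || !length(labs)) stop("training series must carry labels")
  if (length(unique(labs)) < 2)
    stop("degenerate labels: only one class present in the training set",
         call. = FALSE)
  refs[1]
}

#' Train the LSTM sequence labeller
#'
#' Streams augmented crops (crop -> flip -> reverse -> noise per
#' [aug_config()]) from the normalized, labelled training sequences and
#' performs one Adam step per crop on the per-minute binary cross-entropy.
#' A subject-level validation split drives early stopping; the weights with
#' the best validation loss are returned. With a fixed `config$seed` the
#' whole trajectory is deterministic.
#'
#' @param samples List of labelled, normalized [minute_series()] — one per
#'   training subject (or per source sequence).
#' @param config A [model_config()].
#' @param augmentation An [aug_config()].
#' @param verbose Print progress.
#' @return A `trained_model`: `config`, `theta` (weights), `norm_ref`,
#'   `training_log` (data.frame of step/train/validation loss), `best_step`.
#' @export
train_lstm <- function(samples, config = model_config(),
                       augmentation = aug_config(), verbose = FALSE) {
  norm_ref <- check_training_samples(samples)
  L <- config$n_layers; H <- config$cells_per_layer
  bidir <- as.integer(config$bidirectional)
  with_local_seed(config$seed, {
    n_val <- max(1L, floor(config$validation_fraction * length(samples)))
    if (length(samples) - n_val < 1) n_val <- length(samples) - 1L
    val_idx <- sample(seq_along(samples), n_val)
    train <- samples[-val_idx]
    val <- samples[val_idx]

    theta <- init_theta(config)
    m <- numeric(length(theta)); v <- numeric(length(theta))
    best_theta <- theta; best_val <- Inf; best_step <- 0L
    bad_evals <- 0L; step <- 0L
    log_step <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
    run_train <- 0; run_n <- 0L
    stop_now <- FALSE

    val_loss <- function(th) {
      tot <- 0; nm <- 0L
      for (s in val) {
        p <- cpp_lstm_forward(th, s$values, L, H, bidir)
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        tot <- tot - sum(s$labels * log(p) + (1 - s$labels) * log(1 - p))
        nm <- nm + length(p)
      }
      tot / nm
    }

    for (epoch in seq_len(config$max_epochs)) {
      plan <- sample(rep(seq_along(train), each = augmentation$n_crops))
      for (src in plan) {
        a <- augment_one(train[[src]], augmentation)
        if (is.null(a)) next
        step <- step + 1L
        loss <- cpp_lstm_step(theta, m, v, step, a$values, a$labels,
                              L, H, bidir, config$learning_rate, config$clip)
        run_train <- run_train + loss; run_n <- run_n + 1L
        if (step %% config$eval_every == 0L) {
          vl <- val_loss(theta)
          log_step <- c(log_step, step)
          log_train <- c(log_train, run_train / run_n)
          log_val <- c(log_val, vl)
          if (verbose)
            message(sprintf("step %6d  train %.4f  val %.4f", step,
                            run_train / run_n, vl))
          run_train <- 0; run_n <- 0L
          if (vl < best_val - config$min_delta) {
            best_val <- vl; best_theta <- theta + 0; best_step <- step
            bad_evals <- 0L
          } else {
            bad_evals <- bad_evals + 1L
            if (bad_evals >= config$patience) { stop_now <- TRUE; break }
          }
        }
      }
      if (stop_now) break
    }
    if (best_step == 0L) { best_theta <- theta; best_val <- val_loss(theta) }

    structure(list(config = config, theta = best_theta, norm_ref = norm_ref,
                   training_log = data.frame(step = log_step,
                                             train_loss = log_train,
                                             val_loss = log_val),
                   best_step = best_step, best_val_loss = best_val),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model: %s, %d layer(s) x %d cell(s); best val loss %.4f @ step %d>\n",
              if (x$config$bidirectional) "biLSTM" else "LSTM",
              x$config$n_layers, x$config$cells_per_layer,
              x$best_val_loss, x$best_step))
  invisible(x)
}

#' Predict per-minute in-bed probabilities
#'
#' Runs the trained model over a normalized minute series. The series must
#' have been normalized with the same statistics as the training data
#' (checked via the stats provenance reference). The binary track thresholds
#' the probability at 0.5; no post-hoc smoothing is applied.
#'
#' @param model A `trained_model` from [train_lstm()].
#' @param series A normalized [minute_series()].
#' @return List with `prob` (numeric, one per minute) and `track`
#'   (integer 0/1, `prob >= 0.5`), both of the input length.
#' @export
predict_lstm <- function(model, series) {
  if (!inherits(series, "minute_series") || !series$normalized)
    stop("predict_lstm expects a normalized minute_series", call. = FALSE)
  if (!identical(series$norm_ref, model$norm_ref))
    stop("incompatible normalization: series was not normalized with the model's statistics",
         call. = FALSE)
  p <- cpp_lstm_forward(model$theta, series$values, model$config$n_layers,
                        model$config$cells_per_layer,
                        as.integer(model$config$bidirectional))
  list(prob = p, track = as.integer(p >= 0.5))
}

#' Save and load a trained model
#'
#' Checkpoints are plain JSON: the configuration, the flat weight vector
#' (encoded as 17-significant-digit strings so doubles round-trip
#' bit-exactly), and the normalization provenance reference.
#'
#' @param model A `trained_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  jsonlite::write_json(list(config = unclass(model$config),
                            theta = sprintf("%.17g", model$theta),
                            norm_ref = model$norm_ref,
                            best_step = model$best_step,
                            best_val_loss = model$best_val_loss),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, x$config[names(x$config) %in%
                                          names(formals(model_config))])
  structure(list(config = cfg, theta = as.numeric(x$theta),
                 norm_ref = x$norm_ref,
                 training_log = data.frame(),
                 best_step = x$best_step, best_val_loss = x$best_val_loss),
            class = "trained_model")
}

# Subject-level k-fold partition (internal; exported for testability).
make_folds <- function(n_subjects, k, seed = NULL) {
  if (n_subjects < k) stop("fewer subjects than folds", call. = FALSE)
  with_local_seed(seed, {
    fold <- rep(seq_len(k), length.out = n_subjects)
    sample(fold)
  })
}

#' Cross-validated hyperparameter search
#'
#' Subject-level k-fold cross-validation over a grid of architectures.
#' Folds partition subjects (never minutes), and both the normalization
#' statistics and the augmentation stream are fitted/drawn inside each
#' training fold only — the validation fold is normalized with the training
#' fold's frozen statistics (leakage guard: each fold's stats carry a
#' fold-specific provenance string).
#'
#' @param cohort List of subjects, each a list with `series` (an
#'   unnormalized, labelled [minute_series()]).
#' @param grid List of [model_config()]s (e.g. [model_grid()]).
#' @param augmentation An [aug_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment and per-fold training.
#' @param verbose Print per-cell progress.
#' @return A data.frame with one row per grid cell: architecture columns,
#'   `mean_accuracy`, `se_accuracy`, `n_params`; fold assignments and
#'   per-fold normalizer provenance in attributes `folds` / `norm_refs`.
#' @export
cross_validate <- function(cohort, grid, augmentation = aug_config(),
                           k = 10, seed = 1, verbose = FALSE) {
  if (length(cohort) < k)
    stop(sprintf("need at least k=%d subjects, got %d", k, length(cohort)),
         call. = FALSE)
  fold <- make_folds(length(cohort), k, seed)
  get_series <- function(s) if (inherits(s, "minute_series")) s else s$series
  acc <- matrix(NA_real_, length(grid), k)
  norm_refs <- character(k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f); va_idx <- which(fold == f)
    tr_series <- lapply(cohort[tr_idx], get_series)
    stats <- fit_normalizer(tr_series, source = sprintf("cv-fold-%d", f))
    norm_refs[f] <- norm_stats_ref(stats)
    tr_norm <- lapply(tr_series, apply_normalizer, stats = stats)
    va_norm <- lapply(cohort[va_idx], function(s)
      apply_normalizer(get_series(s), stats))
    for (gi in seq_along(grid)) {
      cfg <- grid[[gi]]
      cfg$seed <- derive_seed(seed, f * 1000L + gi)
      mod <- train_lstm(tr_norm, cfg, augmentation)
      hits <- 0L; tot <- 0L
      for (sv in va_norm) {
        pr <- predict_lstm(mod, sv)
        hits <- hits + sum(pr$track == sv$labels)
        tot <- tot + length(sv$labels)
      }
      acc[gi, f] <- hits / tot
      if (verbose)
        message(sprintf("fold %d cell %d: accuracy %.4f", f, gi, acc[gi, f]))
    }
  }
  out <- data.frame(
    bidirectional = vapply(grid, function(g) g$bidirectional, TRUE),
    n_layers = vapply(grid, function(g) g$n_layers, 1L),
    cells_per_layer = vapply(grid, function(g) g$cells_per_layer, 1L),
    mean_accuracy = rowMeans(acc),
    se_accuracy = apply(acc, 1, stats::sd) / sqrt(k),
    n_params = vapply(grid, lstm_n_params, 1L))
  attr(out, "folds") <- fold
  attr(out, "norm_refs") <- norm_refs
  attr(out, "fold_accuracy") <- acc
  out
}

#' Select the final model from cross-validation results
#'
#' Among all grid cells whose mean accuracy lies within one standard error
#' of the best cell's mean accuracy, returns the sparsest one (fewest
#' parameters); ties broken deterministically by (layers, cells,
#' directionality) order. This trades a statistically indistinguishable
#' amount of accuracy for sparsity.
#'
#' @param cv_results Data.frame from [cross_validate()] (columns
#'   `bidirectional`, `n_layers`, `cells_per_layer`, `mean_accuracy`,
#'   `se_accuracy`, `n_params`).
#' @return A [model_config()] for the selected cell.
#' @export
select_model <- function(cv_results) {
  if (!nrow(cv_results)) stop("empty cross-validation results")
  best <- which.max(cv_results$mean_accuracy)
  cutoff <- cv_results$mean_accuracy[best] - cv_results$se_accuracy[best]
  cand <- cv_results[cv_results$mean_accuracy >= cutoff, ]
  cand <- cand[order(cand$n_params, cand$n_layers, cand$cells_per_layer,
                     cand$bidirectional), ]
  model_config(bidirectional = cand$bidirectional[1],
               n_layers = cand$n_layers[1],
               cells_per_layer = cand$cells_per_layer[1])
}
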
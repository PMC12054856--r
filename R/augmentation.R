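#' Training-time augmentation configuration
#'
#' The four accelerometer-specific stochastic transformations applied to
#' training sequences, in the fixed order crop -> flip -> reverse -> noise:
#' * random cropping: `n_crops` sub-sequences per source sequence per
#'   training pass, lengths uniform between `min_crop_minutes` and the full
#'   series;
#' * upside-down flip (probability `flip_prob`): negates `flip_axes`,
#'   emulating a device worn upside down — by default the vertical and
#'   medio-lateral axes, the physically realizable 180-degree rotation about
#'   the anterior-posterior axis;
#' * time reversal (probability `reverse_prob`): values and labels reversed,
#'   emulating inverse turning behaviour;
#' * additive Gaussian noise (probability `noise_prob`, SD `noise_sd` in
#'   normalized units — augmentation runs after cohort normalization).
#'
#' @param n_crops Crops per source sequence per pass (default 100).
#' @param min_crop_minutes Minimum crop length in minutes (default 5).
#' @param flip_prob,reverse_prob,noise_prob Per-crop firing probabilities
#'   (defaults 0.5, 0.5, 0.1).
#' @param noise_sd Noise SD in normalized units (default 0.1).
#' @param flip_axes Character subset of `c("x","y","z")` to negate (default
#'   `c("x","y")`: medio-lateral + vertical).
#' @param seed Optional seed for bit-reproducible [augment_batch()] output.
#' @return An `aug_config` list.
#' @export
aug_config <- function(n_crops = 100, min_crop_minutes = 5,
                       flip_prob = 0.5, reverse_prob = 0.5,
                       noise_prob = 0.1, noise_sd = 0.1,
                       flip_axes = c("x", "y"), seed = NULL) {
  for (p in c("flip_prob", "reverse_prob", "noise_prob"))
    stopifnot_scalar_prob(get(p), p)
  if (min_crop_minutes < 1) stop("min_crop_minutes must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(flip_axes %in% c("x", "y", "z"))) stop("flip_axes must be in x/y/z")
  structure(list(n_crops = as.integer(n_crops),
                 min_crop_minutes = as.integer(min_crop_minutes),
                 flip_prob = flip_prob, reverse_prob = reverse_prob,
                 noise_prob = noise_prob, noise_sd = noise_sd,
                 flip_axes = flip_axes, seed = seed),
            class = "aug_config")
}

# A (values, labels) pair plus the record of applied operators.
as_aug_sample <- function(values, labels, ops = character(0)) {
  structure(list(values = values, labels = labels, ops = ops),
            class = "aug_sample")
}

as_sample <- function(x) {
  if (inherits(x, "aug_sample")) return(x)
  if (inherits(x, "minute_series")) {
    if (is.null(x$labels)) stop("sample has no labels")
    return(as_aug_sample(x$values, x$labels))
  }
  as_aug_sample(x$values, x$labels)
}

#' Random crop
#'
#' Draws a crop length uniformly in `[min_crop_minutes, T]` and a start
#' uniformly over the admissible positions; values and labels are cropped
#' identically. A series shorter than the minimum is skipped with a warning
#' (returns `NULL`).
#'
#' @param sample A labelled [minute_series()] or an `aug_sample`.
#' @param config An [aug_config()].
#' @return An `aug_sample`, or `NULL` if the series is too short.
#' @export
random_crop <- function(sample, config = aug_config()) {
  s <- as_sample(sample)
  T_ <- nrow(s$values)
  if (T_ < config$min_crop_minutes) {
    warning(sprintf("series of %d min shorter than min_crop_minutes=%d; skipped",
                    T_, config$min_crop_minutes))
    return(NULL)
  }
  L <- if (T_ == config$min_crop_minutes) T_ else
    sample.int(T_ - config$min_crop_minutes + 1L, 1L) + config$min_crop_minutes - 1L
  st <- if (T_ == L) 1L else sample.int(T_ - L + 1L, 1L)
  idx <- st:(st + L - 1L)
  as_aug_sample(s$values[idx, , drop = FALSE], s$labels[idx],
                c(s$ops, "crop"))
}

#' Upside-down flip
#'
#' Negates the configured axes; labels unchanged. An involution that
#' preserves each sample's vector magnitude exactly.
#'
#' @inheritParams random_crop
#' @export
aug_flip <- function(sample, config = aug_config()) {
  s <- as_sample(sample)
  j <- match(config$flip_axes, c("x", "y", "z"))
  s$values[, j] <- -s$values[, j, drop = FALSE]
  s$ops <- c(s$ops, "flip")
  s
}

#' Time reversal
#'
#' Reverses values and labels together; the total number of in-bed minutes
#' is unchanged. An involution.
#'
#' @inheritParams random_crop
#' @export
aug_reverse <- function(sample, config = aug_config()) {
  s <- as_sample(sample)
  idx <- rev(seq_len(nrow(s$values)))
  as_aug_sample(s$values[idx, , drop = FALSE], s$labels[idx],
                c(s$ops, "reverse"))
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. `N(0, noise_sd^2)` to every axis value; labels unchanged.
#'
#' @inheritParams random_crop
#' @export
aug_add_noise <- function(sample, config = aug_config()) {
  s <- as_sample(sample)
  if (config$noise_sd > 0) {
    n <- length(s$values)
    s$values <- s$values + matrix(stats::rnorm(n, 0, config$noise_sd),
                                  nrow(s$values), 3)
  }
  s$ops <- c(s$ops, "noise")
  s
}

# One augmented crop drawn from a source sample (internal, streaming use in
# the trainer); order fixed: crop -> flip -> reverse -> noise.
augment_one <- function(sample, config) {
  s <- random_crop(sample, config)
  if (is.null(s)) return(NULL)
  if (stats::runif(1) < config$flip_prob) s <- aug_flip(s, config)
  if (stats::runif(1) < config$reverse_prob) s <- aug_reverse(s, config)
  if (stats::runif(1) < config$noise_prob) s <- aug_add_noise(s, config)
  s
}

#' Augment a batch of training sequences
#'
#' For every source sample, draws `n_crops` random crops and, per crop
#' independently, flips with `flip_prob`, reverses with `reverse_prob` and
#' adds noise with `noise_prob` — always in the fixed order
#' crop -> flip -> reverse -> noise. Each output records which operators
#' fired in `$ops`. With `config$seed` set the output is bit-reproducible.
#'
#' @param samples List of labelled [minute_series()] or `aug_sample`s.
#' @param config An [aug_config()].
#' @return List of `aug_sample` objects
#'   (`length(samples) * n_crops` minus any skipped short series).
#' @export
augment_batch <- function(samples, config = aug_config()) {
  with_local_seed(config$seed, {
    out <- list()
    for (s in samples) {
      for (k in seq_len(config$n_crops)) {
        a <- augment_one(s, config)
        if (!is.null(a)) out[[length(out) + 1L]] <- a
      }
    }
    out
  })
}
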
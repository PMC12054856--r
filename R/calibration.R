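#' Find stationary epochs in a raw trace
#'
#' Scans the trace in consecutive non-overlapping windows and keeps those in
#' which the per-axis sample standard deviation is below the threshold on
#' all three axes — i.e. windows in which the device measures (close to)
#' pure gravity. Their per-axis means are the calibration observations: for
#' a well-calibrated device they lie on the unit sphere.
#'
#' @param trace A [raw_trace()].
#' @param window_s Window length in seconds (default 10).
#' @param sd_threshold_g Per-axis SD threshold in g (default 0.013).
#' @return Numeric matrix (one row per stationary epoch, columns x/y/z) of
#'   per-epoch mean acceleration; zero rows if none qualify.
#' @export
find_stationary_epochs <- function(trace, window_s = 10, sd_threshold_g = 0.013) {
  if (window_s < 1) stop("window_s must be >= 1")
  if (sd_threshold_g <= 0) stop("sd_threshold_g must be > 0")
  w <- as.integer(round(window_s * trace$sample_rate))
  n_win <- nrow(trace$data) %/% w
  if (n_win == 0 || w < 2)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  keep <- rep(TRUE, n_win)
  means <- matrix(0, n_win, 3, dimnames = list(NULL, c("x", "y", "z")))
  for (a in 1:3) {
    m <- matrix(trace$data[seq_len(n_win * w), a], w, n_win)
    mu <- colMeans(m)
    sdv <- sqrt(colSums((m - rep(mu, each = w))^2) / (w - 1))
    means[, a] <- mu
    keep <- keep & (sdv < sd_threshold_g)
  }
  means[keep, , drop = FALSE]
}

#' Fit autocalibration coefficients from stationary epochs
#'
#' Iterative per-axis weighted least squares in the spirit of accelerometer
#' autocalibration: each epoch mean is moved toward its closest point on the
#' unit sphere, and a per-axis affine map (`a' = gain * a + offset`) is
#' refitted against those targets until the mean absolute deviation of the
#' calibrated vector magnitude from 1 g improves by less than `tol` (or
#' `max_iter` iterations). The residual never increases across iterations.
#'
#' Requires at least `min_epochs` epochs with orientation diversity
#' (per-axis range of epoch means >= 0.3 g on at least two axes); otherwise
#' identity coefficients are returned with a diagnostic flag, never a hard
#' failure.
#'
#' @param epoch_means Matrix of stationary epoch means (from
#'   [find_stationary_epochs()]).
#' @param min_epochs Minimum number of epochs (default 10).
#' @param tol Convergence tolerance on the residual improvement, g (1e-6).
#' @param max_iter Iteration cap (100).
#' @return A `calibration_coefficients` object: `gain`, `offset` (per axis),
#'   `n_stationary_epochs`, `residual` (mean |VM - 1| after fit, g),
#'   `converged`, and `flag` (`"ok"` or `"insufficient sphere coverage"`).
#' @export
fit_calibration <- function(epoch_means, min_epochs = 10, tol = 1e-6,
                            max_iter = 100) {
  E <- as.matrix(epoch_means)
  identity_out <- function(flag) {
    structure(list(gain = c(1, 1, 1), offset = c(0, 0, 0),
                   n_stationary_epochs = nrow(E),
                   residual = if (nrow(E)) mean(abs(sqrt(rowSums(E^2)) - 1)) else NA_real_,
                   residual_path = numeric(0),
                   converged = FALSE, flag = flag),
              class = "calibration_coefficients")
  }
  if (nrow(E) < min_epochs) return(identity_out("insufficient sphere coverage"))
  ranges <- apply(E, 2, function(v) diff(range(v)))
  if (sum(ranges >= 0.3) < 2) return(identity_out("insufficient sphere coverage"))

  gain <- c(1, 1, 1); offset <- c(0, 0, 0)
  resid_of <- function(g, o) {
    cal <- sweep(sweep(E, 2, g, "*"), 2, o, "+")
    mean(abs(sqrt(rowSums(cal^2)) - 1))
  }
  res <- resid_of(gain, offset)
  path <- res
  for (it in seq_len(max_iter)) {
    cal <- sweep(sweep(E, 2, gain, "*"), 2, offset, "+")
    vm <- sqrt(rowSums(cal^2))
    vm[vm < 1e-12] <- 1e-12
    target <- cal / vm               # closest unit-sphere points
    new_gain <- gain; new_offset <- offset
    for (a in 1:3) {
      fit <- stats::lm.fit(cbind(1, E[, a]), target[, a])
      new_offset[a] <- fit$coefficients[1]
      new_gain[a] <- fit$coefficients[2]
    }
    new_res <- resid_of(new_gain, new_offset)
    if (new_res > res) break         # keep the better previous estimate
    gain <- new_gain; offset <- new_offset
    improved <- res - new_res
    res <- new_res
    path <- c(path, res)
    if (improved < tol) break
  }
  structure(list(gain = gain, offset = offset,
                 n_stationary_epochs = nrow(E), residual = res,
                 residual_path = path,
                 converged = TRUE, flag = "ok"),
            class = "calibration_coefficients")
}

#' @export
print.calibration_coefficients <- function(x, ...) {
  cat(sprintf("<calibration: gain (%.4f, %.4f, %.4f), offset (%.4f, %.4f, %.4f) g,\n %d stationary epochs, residual %.5f g [%s]>\n",
              x$gain[1], x$gain[2], x$gain[3],
              x$offset[1], x$offset[2], x$offset[3],
              x$n_stationary_epochs, x$residual, x$flag))
  invisible(x)
}

#' Apply calibration coefficients to a trace
#'
#' `a' = gain * a + offset` per axis (offset after gain). Applying identity
#' coefficients returns the values unchanged.
#'
#' @param trace A [raw_trace()].
#' @param coeffs A `calibration_coefficients` object.
#' @return A calibrated [raw_trace()].
#' @export
apply_calibration <- function(trace, coeffs) {
  d <- sweep(sweep(trace$data, 2, coeffs$gain, "*"), 2, coeffs$offset, "+")
  raw_trace(d, trace$start_time, trace$sample_rate)
}

#' Calibrate a trace end to end
#'
#' Convenience wrapper: [find_stationary_epochs()] then [fit_calibration()]
#' then [apply_calibration()].
#'
#' @param trace A [raw_trace()].
#' @param window_s,sd_threshold_g Passed to [find_stationary_epochs()].
#' @return List with `trace` (calibrated) and `coeffs`.
#' @export
calibrate_trace <- function(trace, window_s = 10, sd_threshold_g = 0.013) {
  ep <- find_stationary_epochs(trace, window_s, sd_threshold_g)
  co <- fit_calibration(ep)
  list(trace = apply_calibration(trace, co), coeffs = co)
}
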
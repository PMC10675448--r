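#' Gaussian basis for the subspace-regularized estimator
#'
#' The single-trial evoked potential is expanded on `n_basis` Gaussian bumps
#' with common width `width_s` and delays spread uniformly over the
#' post-event window; the estimator solves for the bump coefficients.
#'
#' @param n_samples Samples in the analysis window.
#' @param sampling_rate_hz Sampling rate, Hz.
#' @param n_basis Number of basis functions (default 20).
#' @param width_s Gaussian width, seconds (default 0.1).
#' @return Object of class `gaussian_basis` with the `n_samples x n_basis`
#'   design matrix `H`, the `delays` (s) and the time axis.
#' @export
build_basis <- function(n_samples, sampling_rate_hz, n_basis = 20,
                        width_s = 0.1) {
  if (n_basis < 1) stopf("n_basis must be >= 1")
  if (width_s <= 0) stopf("width_s must be > 0")
  t <- (seq_len(n_samples) - 1) / sampling_rate_hz
  delays <- if (n_basis == 1) max(t) / 2 else
    seq(0, (n_samples - 1) / sampling_rate_hz, length.out = n_basis)
  H <- vapply(delays,
              function(tau) exp(-(t - tau)^2 / (2 * width_s^2)),
              numeric(n_samples))
  structure(list(H = H, delays = delays, width_s = width_s, time_s = t),
            class = "gaussian_basis")
}

#' Noise covariance from pre-stimulus background EEG
#'
#' The background statistics entering the estimator are taken from the
#' second before each stimulus: the sample covariance (sample x sample)
#' over the ensemble of pre-stimulus windows, ridge-regularised so it is
#' invertible on short windows.
#'
#' @param prestim `n_segments x n_samples` matrix of pre-stimulus windows
#'   for one channel.
#' @param ridge Relative ridge added to the diagonal, as a fraction of
#'   `trace / n_samples` (default 1e-6). With all-zero input the absolute
#'   value `ridge` is used.
#' @return Object of class `noise_model` with `Cv` and its inverse.
#' @export
estimate_noise_cov <- function(prestim, ridge = 1e-6) {
  prestim <- as.matrix(prestim)
  if (nrow(prestim) < 2 && ridge <= 0) {
    stopf("a single pre-stimulus segment gives a rank-deficient covariance; use ridge > 0")
  }
  Cv <- if (nrow(prestim) >= 2) stats::cov(prestim) else
    tcrossprod(as.numeric(prestim)) * 0
  eps <- ridge * mean(diag(Cv))
  if (!is.finite(eps) || eps <= 0) eps <- ridge
  Cv <- Cv + diag(eps, ncol(prestim))
  structure(list(Cv = Cv, Cv_inv = solve(Cv), source = "prestimulus",
                 ridge = ridge), class = "noise_model")
}

#' Empirical signal subspace
#'
#' Leading eigenvectors of the (uncentred) sample x sample correlation
#' matrix of the observed post-event epochs, plus the second-difference
#' operator used by the smoothing penalty.
#'
#' @param epochs `n_epochs x n_samples` matrix of post-event epochs for one
#'   channel.
#' @param n_eigvec Number of leading eigenvectors to keep (default 8).
#' @return Object of class `signal_subspace` with the orthonormal
#'   `n_samples x n_eigvec` matrix `Ks` and the `(n-2) x n` matrix `D`.
#' @export
signal_subspace <- function(epochs, n_eigvec = 8) {
  epochs <- as.matrix(epochs)
  n <- ncol(epochs)
  if (n_eigvec > n) stopf("n_eigvec (%d) exceeds the sample count (%d)",
                          n_eigvec, n)
  if (nrow(epochs) < n_eigvec) {
    stopf("need at least n_eigvec (%d) epochs, got %d", n_eigvec, nrow(epochs))
  }
  R <- crossprod(epochs) / nrow(epochs)
  eig <- eigen(R, symmetric = TRUE)
  Ks <- eig$vectors[, seq_len(n_eigvec), drop = FALSE]
  structure(list(Ks = Ks, D = second_diff_matrix(n),
                 eigenvalues = eig$values), class = "signal_subspace")
}

# (n-2) x n second-difference matrix with (1, -2, 1) stencils.
second_diff_matrix <- function(n) {
  if (n < 3) stopf("second-difference matrix needs n >= 3")
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

#' Configuration of the subspace-regularized estimator
#'
#' @param alpha Weight of the second-difference smoothing penalty
#'   (default 0.01).
#' @param alpha2 Weight of the subspace penalty, pulling the estimate
#'   toward the empirical signal subspace (default 10).
#' @param n_eigvec Dimension of the empirical signal subspace (default 8).
#' @param n_basis,width_s Gaussian basis parameters (defaults 20 and 0.1 s).
#' @param ridge Relative ridge for the noise covariance.
#' @return Object of class `subspace_config`.
#' @export
subspace_config <- function(alpha = 0.01, alpha2 = 10, n_eigvec = 8,
                            n_basis = 20, width_s = 0.1, ridge = 1e-6) {
  if (alpha < 0 || alpha2 < 0) stopf("alpha and alpha2 must be >= 0")
  if (n_eigvec < 1) stopf("n_eigvec must be >= 1")
  structure(list(alpha = alpha, alpha2 = alpha2, n_eigvec = n_eigvec,
                 n_basis = n_basis, width_s = width_s, ridge = ridge),
            class = "subspace_config")
}

# The estimator is linear in the observation; assemble the full
# n_samples x n_samples operator M with s_hat = M z:
#   M = (I + alpha^2 D'D)^-1 H (H'Cv^-1 H + alpha2^2 H'(I - Ks Ks')H)^-1 H'Cv^-1
# The larger parameter (alpha2 = 10) weights the subspace penalty — the
# regularisation the method is named after — and the smaller (alpha = 0.01)
# the second-difference smoother. With the roles exchanged the subspace
# penalty is O(1e-4) and inert while the smoother flattens the sharp ErrP
# peaks, and the estimator degrades rather than enhances single trials.
subspace_operator <- function(basis, noise, subspace, config) {
  H <- basis$H
  n <- nrow(H)
  DtD <- crossprod(subspace$D)
  P <- diag(n) - tcrossprod(subspace$Ks)
  inner <- crossprod(H, noise$Cv_inv %*% H) +
    config$alpha2^2 * crossprod(H, P %*% H)
  inner_inv <- tryCatch(solve(inner), error = function(e)
    stopf("singular inner matrix; increase alpha2 or the noise ridge (%s)",
          conditionMessage(e)))
  smooth_inv <- solve(diag(n) + config$alpha^2 * DtD)
  smooth_inv %*% H %*% inner_inv %*% crossprod(H, noise$Cv_inv)
}

#' Subspace-regularized single-trial estimate of one epoch
#'
#' Generalised-least-squares fit of the observation on the Gaussian basis,
#' penalised away from directions outside the empirical signal subspace and
#' smoothed by a second-difference penalty. Linear in the observation.
#'
#' @param epoch_channel Numeric vector, one channel of one epoch.
#' @param basis A [build_basis()] result.
#' @param noise A [estimate_noise_cov()] result.
#' @param subspace A [signal_subspace()] result.
#' @param config A [subspace_config()].
#' @return Numeric vector, the denoised single-trial estimate.
#' @export
subspace_estimate_st <- function(epoch_channel, basis, noise, subspace,
                                 config = subspace_config()) {
  M <- subspace_operator(basis, noise, subspace, config)
  as.numeric(M %*% epoch_channel)
}

#' Fit the subspace estimator on a training epoch set
#'
#' Per channel: noise covariance from the pre-stimulus windows, signal
#' subspace from the post-event epochs, and the resulting linear operator.
#' Fitting uses only the epochs it is given, so passing the training fold
#' keeps validation/test data out of the estimator statistics.
#'
#' @param epochs Training [epoch_set()] (must carry `prestim`).
#' @param config A [subspace_config()].
#' @return Object of class `subspace_fit` (one operator per channel).
#' @export
subspace_fit <- function(epochs, config = subspace_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$prestim)) {
    stopf("epoch set has no pre-stimulus windows; cannot estimate the noise covariance")
  }
  n_ch <- dim(epochs$data)[2]
  n <- dim(epochs$data)[3]
  basis <- build_basis(n, epochs$sampling_rate_hz, config$n_basis,
                       config$width_s)
  ops <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    noise <- estimate_noise_cov(epochs$prestim[, ch, ], config$ridge)
    sub <- signal_subspace(epochs$data[, ch, ], config$n_eigvec)
    ops[[ch]] <- subspace_operator(basis, noise, sub, config)
  }
  structure(list(operators = ops, basis = basis, config = config,
                 sampling_rate_hz = epochs$sampling_rate_hz),
            class = "subspace_fit")
}

#' Apply a fitted subspace estimator to an epoch set
#'
#' @param fit A [subspace_fit()].
#' @param epochs An [epoch_set()]; each channel of each epoch is replaced by
#'   its single-trial estimate. Labels and pre-stimulus data are untouched.
#' @return The denoised `epoch_set`.
#' @export
subspace_apply <- function(fit, epochs) {
  stopifnot(inherits(fit, "subspace_fit"), inherits(epochs, "epoch_set"))
  n_ch <- dim(epochs$data)[2]
  if (n_ch != length(fit$operators)) {
    stopf("fit has %d channels but epochs have %d", length(fit$operators), n_ch)
  }
  for (ch in seq_len(n_ch)) {
    # epochs x samples times t(M): linear operator applied to every epoch
    epochs$data[, ch, ] <- epochs$data[, ch, ] %*% t(fit$operators[[ch]])
  }
  epochs
}

#' Fit-and-apply convenience wrapper
#'
#' @inheritParams subspace_fit
#' @return The denoised `epoch_set`.
#' @export
subspace_estimate_epochset <- function(epochs, config = subspace_config()) {
  subspace_apply(subspace_fit(epochs, config), epochs)
}
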
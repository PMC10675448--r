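test_that("Gaussian basis columns have unit peaks at their delays", {
  b <- build_basis(64, 64, n_basis = 20, width_s = 0.1)
  expect_equal(dim(b$H), c(64, 20))
  # with delays on the sample grid each column peaks at exactly 1
  bg <- build_basis(64, 64, n_basis = 10, width_s = 0.1)
  for (i in c(1, 4, 10)) {
    j <- which.min(abs(bg$time_s - bg$delays[i]))
    expect_equal(max(bg$H[, i]), 1, tolerance = 1e-12)
    expect_equal(which.max(bg$H[, i]), j)
  }
  # narrow width tends to an impulse when the delay sits on the grid
  bn <- build_basis(16, 16, n_basis = 16, width_s = 1e-4)
  expect_equal(bn$H, diag(16), tolerance = 1e-12)
  expect_error(build_basis(64, 64, width_s = 0), "width")
})

test_that("noise covariance estimation matches its definition", {
  z <- estimate_noise_cov(matrix(0, 5, 8), ridge = 1e-3)
  expect_equal(z$Cv, diag(1e-3, 8))

  v <- c(1, 2, -1, 0.5)
  rep_v <- matrix(v, 6, 4, byrow = TRUE)
  cv <- estimate_noise_cov(rep_v, ridge = 1e-9)
  expect_equal(cv$Cv - diag(diag(cv$Cv)), matrix(0, 4, 4), tolerance = 1e-8)

  set.seed(10)
  w <- matrix(rnorm(5000 * 6), 5000, 6)
  cw <- estimate_noise_cov(w)
  expect_lt(max(abs(diag(cw$Cv) - 1)), 0.1)
  expect_lt(max(abs(cw$Cv[upper.tri(cw$Cv)])), 0.05)

  expect_error(estimate_noise_cov(matrix(1, 1, 4), ridge = 0), "rank")
})

test_that("signal subspace is orthonormal and captures dominant structure", {
  v <- sin(2 * pi * (1:32) / 32)
  ep <- matrix(v, 10, 32, byrow = TRUE)
  sub <- signal_subspace(ep, 1)
  expect_equal(abs(sum(sub$Ks[, 1] * v / sqrt(sum(v^2)))), 1, tolerance = 1e-8)

  set.seed(3)
  sub8 <- signal_subspace(matrix(rnorm(500 * 32), 500, 32), 8)
  expect_equal(crossprod(sub8$Ks), diag(8), tolerance = 1e-10)
  expect_equal(dim(sub8$D), c(30, 32))
  expect_true(all(sub8$D[1, 1:3] == c(1, -2, 1)))

  # flat spectrum for a large white ensemble
  set.seed(4)
  subw <- signal_subspace(matrix(rnorm(10000 * 16), 10000, 16), 4)
  expect_lt(max(subw$eigenvalues) / min(subw$eigenvalues), 2)

  expect_error(signal_subspace(matrix(rnorm(10 * 8), 10, 8), 9), "exceeds")
})

test_that("with no regularisation and white noise the estimator is least squares", {
  n <- 32
  b <- build_basis(n, 32, n_basis = 6, width_s = 0.15)
  noise <- list(Cv = diag(n), Cv_inv = diag(n))
  set.seed(5)
  sub <- signal_subspace(matrix(rnorm(50 * n), 50, n), 4)
  theta0 <- rnorm(6)
  z <- as.numeric(b$H %*% theta0)
  est <- subspace_estimate_st(z, b, noise, sub,
                              subspace_config(alpha = 0, alpha2 = 0,
                                              n_basis = 6))
  expect_lt(max(abs(est - z)), 1e-8)

  z0 <- subspace_estimate_st(numeric(n), b, noise, sub, subspace_config())
  expect_true(all(z0 == 0))
})

test_that("the estimator matches a from-scratch assembly on small problems", {
  n <- 16
  set.seed(6)
  b <- build_basis(n, 16, n_basis = 5, width_s = 0.12)
  pre <- matrix(rnorm(40 * n), 40, n)
  noise <- estimate_noise_cov(pre)
  ep <- matrix(rnorm(30 * n), 30, n)
  sub <- signal_subspace(ep, 3)
  cfg <- subspace_config(alpha = 0.01, alpha2 = 10, n_eigvec = 3, n_basis = 5)
  z <- rnorm(n)
  est <- subspace_estimate_st(z, b, noise, sub, cfg)

  # independent brute-force evaluation assembled term by term
  H <- b$H
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i + 0:2] <- c(1, -2, 1)
  Cvi <- solve(noise$Cv)
  P <- diag(n) - sub$Ks %*% t(sub$Ks)
  inner <- t(H) %*% Cvi %*% H + cfg$alpha2^2 * t(H) %*% P %*% H
  s_ref <- solve(diag(n) + cfg$alpha^2 * t(D) %*% D) %*%
    H %*% solve(inner) %*% t(H) %*% Cvi %*% z
  expect_equal(est, as.numeric(s_ref), tolerance = 1e-10)
})

test_that("the estimator is a linear operator", {
  ep <- small_epochs(n_events = 80, n_channels = 2, seed = 15)
  fit <- subspace_fit(ep)
  M <- fit$operators[[1]]
  set.seed(16)
  z1 <- rnorm(64); z2 <- rnorm(64)
  expect_equal(as.numeric(M %*% (2 * z1 - 3 * z2)),
               as.numeric(2 * M %*% z1 - 3 * M %*% z2), tolerance = 1e-10)
})

test_that("increasing the smoothing weight never roughens the estimate", {
  ep <- small_epochs(n_events = 80, n_channels = 2, seed = 17)
  n <- 64
  basis <- build_basis(n, 64)
  noise <- estimate_noise_cov(ep$prestim[, 1, ])
  sub <- signal_subspace(ep$data[, 1, ], 8)
  z <- ep$data[3, 1, ]
  D <- sub$D
  rough <- vapply(c(0, 0.01, 0.1, 1, 10), function(a) {
    est <- subspace_estimate_st(z, basis, noise, sub,
                                subspace_config(alpha = a, alpha2 = 10))
    sum((D %*% est)^2)
  }, numeric(1))
  expect_true(all(diff(rough) <= 1e-10))
})

test_that("estimates lie in the smoothed basis column space", {
  ep <- small_epochs(n_events = 80, n_channels = 2, seed = 18)
  basis <- build_basis(64, 64)
  noise <- estimate_noise_cov(ep$prestim[, 1, ])
  sub <- signal_subspace(ep$data[, 1, ], 8)
  cfg <- subspace_config()
  est <- subspace_estimate_st(ep$data[5, 1, ], basis, noise, sub, cfg)
  A <- solve(diag(64) + cfg$alpha^2 * crossprod(sub$D)) %*% basis$H
  proj <- A %*% qr.coef(qr(A), est)
  # tolerance reflects the conditioning of the 20-column Gaussian design
  expect_lt(sqrt(sum((est - proj)^2)) / max(sqrt(sum(est^2)), 1e-12), 1e-5)
})

test_that("batch application preserves geometry and labels", {
  ep <- small_epochs(n_events = 60, n_channels = 3, seed = 19)
  out <- subspace_estimate_epochset(ep)
  expect_equal(dim(out$data), dim(ep$data))
  expect_identical(out$labels, ep$labels)
  expect_identical(out$prestim, ep$prestim)

  zero <- ep
  zero$data[] <- 0
  outz <- subspace_apply(subspace_fit(ep), zero)
  expect_true(all(outz$data == 0))

  noprestim <- ep; noprestim$prestim <- NULL
  expect_error(subspace_fit(noprestim), "pre-stimulus")
})

test_that("subspace filtering enhances the template at 0 dB", {
  ep <- channel_epochs(n_events = 200, snr_db = 0, seed = 23)
  den <- subspace_estimate_epochset(ep)
  expect_gt(mean_template_cor(den), mean_template_cor(ep))
})
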
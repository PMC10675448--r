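test_that("grand averaging selects, averages and cancels", {
  ep <- small_epochs(n_events = 60, n_channels = 2, seed = 1)
  one <- subset_epochs(ep, which(ep$labels == 1)[1])
  expect_equal(grand_average(one, 1L), one$data[1, , ])

  v <- matrix(rnorm(2 * 64), 2, 64)
  dat <- array(0, c(2, 2, 64))
  dat[1, , ] <- v
  dat[2, , ] <- -v
  sym <- epoch_set(dat, c(1L, 1L), 64)
  expect_equal(grand_average(sym, 1L), matrix(0, 2, 64), tolerance = 1e-12)

  expect_error(grand_average(subset_epochs(ep, which(ep$labels == 0)), 1L),
               "no epoch")
})

test_that("the grand average converges to the template", {
  ep <- channel_epochs(n_events = 1000, snr_db = 0, seed = 2)
  ga <- grand_average(ep, 1L)
  expect_gt(cor(ga[1, ], ref_template()), 0.95)
})

test_that("least squares recovers noiseless ARX coefficients", {
  set.seed(3)
  n <- 64
  u <- rnorm(n)
  y <- numeric(n)
  for (t in 2:n) y[t] <- 0.5 * y[t - 1] + 1.0 * u[t - 1]
  m <- fit_arx(y, u, arx_orders(1, 1, 0))
  expect_equal(m$a_coeffs, 0.5, tolerance = 1e-6)
  expect_equal(m$b_coeffs, 1.0, tolerance = 1e-6)
  expect_lt(m$fit_cost, 1e-12)

  # white output against a zero-information input: AR coefficient near 0
  set.seed(4)
  yw <- rnorm(2000)
  mw <- suppressWarnings(fit_arx(yw, rep(0, 2000), arx_orders(1, 1, 0)))
  expect_lt(abs(mw$a_coeffs), 3 / sqrt(2000))

  # y == u: the evoked channel absorbs the fit, not the AR part
  tmpl <- ref_template()
  mi <- suppressWarnings(fit_arx(tmpl, tmpl, arx_orders(1, 1, 0)))
  expect_equal(mi$b_coeffs, 1, tolerance = 0.1)
  expect_equal(mi$a_coeffs, 0)
  expect_lt(mi$fit_cost, 0.02)
})

test_that("residuals are orthogonal to the regressors", {
  set.seed(5)
  n <- 128
  u <- rnorm(n)
  y <- as.numeric(stats::filter(u, c(0.8, -0.2), method = "recursive")) + rnorm(n)
  o <- arx_orders(2, 2, 1)
  m <- fit_arx(y, u, o)
  tt <- (max(o$na, o$nb + o$delay) + 1):n
  X <- cbind(u[tt - 1 - o$delay], u[tt - 2 - o$delay], y[tt - 1], y[tt - 2])
  pred <- X %*% c(m$b_coeffs, m$a_coeffs)
  expect_lt(max(abs(crossprod(X, y[tt] - pred))), 1e-8)
})

test_that("AIC penalises order and tracks the fit cost", {
  o22 <- arx_orders(2, 2); o44 <- arx_orders(4, 4)
  m22 <- structure(list(fit_cost = 0.5, orders = o22, n_fit = 60),
                   class = "arx_model")
  m44 <- structure(list(fit_cost = 0.5, orders = o44, n_fit = 60),
                   class = "arx_model")
  expect_lt(aic_score(m22), aic_score(m44))

  m22b <- m22; m22b$fit_cost <- 0.25
  expect_equal(aic_score(m22) - aic_score(m22b), 60 * log(2))

  m0 <- m22; m0$fit_cost <- 0
  expect_warning(expect_identical(aic_score(m0), -Inf), "perfect fit")
})

test_that("order selection is deterministic and recovers true orders", {
  set.seed(6)
  n <- 64
  u <- rnorm(n)
  grid <- expand.grid(na = 1:6, nb = 1:6, delay = 0)
  ydet <- numeric(n)
  for (t in 3:n) {
    ydet[t] <- 0.6 * ydet[t - 1] - 0.2 * ydet[t - 2] +
      1.0 * u[t - 1] + 0.5 * u[t - 2]
  }
  sd_e <- sqrt(var(ydet) / 100)       # 20 dB innovation SNR
  picks <- replicate(40, {
    e <- rnorm(n, sd = sd_e)
    y <- numeric(n)
    for (t in 3:n) {
      y[t] <- 0.6 * y[t - 1] - 0.2 * y[t - 2] +
        1.0 * u[t - 1] + 0.5 * u[t - 2] + e[t]
    }
    sel <- suppressWarnings(select_orders(y, u, grid))
    paste(sel$orders$na, sel$orders$nb)
  })
  expect_equal(names(which.max(table(picks))), "2 2")   # modal order is true

  single <- expand.grid(na = 3, nb = 2, delay = 1)
  s1 <- suppressWarnings(select_orders(rnorm(64), rnorm(64), single))
  expect_equal(unclass(s1$orders)[c("na", "nb", "delay")],
               list(na = 3L, nb = 2L, delay = 1L))

  set.seed(7); yy <- rnorm(64); uu <- rnorm(64)
  a <- suppressWarnings(select_orders(yy, uu))
  b <- suppressWarnings(select_orders(yy, uu))
  expect_identical(a$orders, b$orders)
  expect_identical(a$model$a_coeffs, b$model$a_coeffs)
})

test_that("AIC selection is invariant to common amplitude scaling", {
  set.seed(8)
  u <- rnorm(64)
  y <- as.numeric(stats::filter(u, 0.5, method = "recursive")) + rnorm(64, sd = 0.3)
  grid <- expand.grid(na = 1:4, nb = 1:4, delay = 0:1)
  s1 <- suppressWarnings(select_orders(y, u, grid))
  s2 <- suppressWarnings(select_orders(7.3 * y, 7.3 * u, grid))
  expect_identical(s1$orders, s2$orders)
})

test_that("noiseless ARX data is reproduced exactly by the estimate", {
  set.seed(9)
  u <- ref_template()
  m0 <- list(a_coeffs = c(0.6, -0.2), b_coeffs = c(1, 0.4),
             orders = arx_orders(2, 2, 0))
  y <- sterrp:::arx_deterministic(m0, u)
  est <- arx_estimate_st(y, u, expand.grid(na = 1:3, nb = 1:3, delay = 0))
  expect_lt(max(abs(est - y)), 1e-6)

  e0 <- arx_estimate_st(y, rep(0, length(y)),
                        expand.grid(na = 1:2, nb = 1:2, delay = 0))
  expect_true(all(e0 == 0))
})

test_that("ARX filtering enhances the template at 0 dB", {
  ep <- channel_epochs(n_events = 150, snr_db = 0, seed = 10)
  den <- arx_estimate_epochset(ep)
  expect_gt(mean_template_cor(den), mean_template_cor(ep))
  expect_identical(den$labels, ep$labels)
  expect_equal(dim(den$data), dim(ep$data))
})

test_that("surrogates are counted, labelled and shaped like the class", {
  ep <- channel_epochs(n_events = 300, snr_db = 0, seed = 11)
  sur <- generate_surrogates(ep, 120, seed = 12)
  expect_equal(dim(sur$data)[1], 120)
  expect_true(all(sur$labels == 1L))

  empty <- generate_surrogates(ep, 0, seed = 1)
  expect_equal(dim(empty$data)[1], 0)

  big <- generate_surrogates(ep, 400, seed = 13)
  ga <- grand_average(ep, 1L)
  expect_gt(cor(colMeans(big$data[, 1, ]), ga[1, ]), 0.8)
  # bounded: no unstable blow-up
  expect_lt(max(abs(big$data)), 20 * max(abs(ep$data)))
})

test_that("noise-free minority epochs give noise-free surrogates", {
  cfg <- sim_config(n_events = 40, n_channels = 1, snr_db = Inf, seed = 14,
                    topography = 1, fcz_channel = 1)
  ses <- simulate_session(cfg, background = background_model(innovation_std = 0))
  ep <- suppressWarnings(extract_epochs(ses$recording))
  sur <- suppressWarnings(generate_surrogates(ep, 10, seed = 15))
  # deterministic part only: every surrogate nearly equals the template epoch
  tmpl_ep <- ep$data[which(ep$labels == 1)[1], 1, ]
  for (s in 1:10) {
    expect_gt(cor(sur$data[s, 1, ], tmpl_ep), 0.99)
  }
})
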
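#' Grand average of selected epochs
#'
#' Sample-wise mean over the epochs matching `label_filter`, per channel.
#' Averaging suppresses the background EEG by sqrt(n) and yields the
#' reference ErrP waveform used as the exogenous ARX input.
#'
#' @param epochs An [epoch_set()].
#' @param label_filter Label value to average over (default 1 = ErrP), or
#'   `NULL` for all epochs.
#' @return `n_channels x n_samples` matrix.
#' @export
grand_average <- function(epochs, label_filter = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- if (is.null(label_filter)) seq_len(n_epochs(epochs)) else
    which(epochs$labels == label_filter)
  if (!length(idx)) stopf("no epoch matches label %s", label_filter)
  apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
}

#' ARX model orders
#'
#' @param na AR order (lags of the output), >= 1.
#' @param nb Exogenous order (lags of the reference input), >= 1.
#' @param delay Additional input delay, samples, >= 0.
#' @return Object of class `arx_orders`.
#' @export
arx_orders <- function(na, nb, delay = 0L) {
  if (na < 1 || nb < 1 || delay < 0) {
    stopf("need na >= 1, nb >= 1, delay >= 0")
  }
  structure(list(na = as.integer(na), nb = as.integer(nb),
                 delay = as.integer(delay)), class = "arx_orders")
}

#' Fit an ARX model by least squares
#'
#' Model: `y(t) = sum_j a_j y(t-j) + sum_k b_k u(t-k-delay) + e(t)`.
#' Coefficients minimise the mean squared one-step-ahead prediction error
#' over the samples with full regressor support.
#'
#' @param y Observed epoch (one channel), numeric vector.
#' @param u Reference input (class grand average), same length as `y`.
#' @param orders An [arx_orders()].
#' @return Object of class `arx_model` with `a_coeffs`, `b_coeffs`,
#'   `orders`, `fit_cost` (mean squared residual), `innovation_variance`
#'   and `n_fit` (number of fitted samples).
#' @export
fit_arx <- function(y, u, orders) {
  stopifnot(inherits(orders, "arx_orders"))
  N <- length(y)
  if (length(u) != N) stopf("y and u must have equal length")
  t0 <- max(orders$na, orders$nb + orders$delay) + 1L
  if (t0 > N - 1L) stopf("series too short (%d) for orders na=%d nb=%d delay=%d",
                         N, orders$na, orders$nb, orders$delay)
  tt <- t0:N
  # exogenous lags first: under rank deficiency (e.g. y proportional to u)
  # the pivoted least squares then attributes the evoked component to the
  # reference input rather than to the AR background part
  X <- matrix(0, length(tt), orders$na + orders$nb)
  for (k in seq_len(orders$nb)) X[, k] <- u[tt - k - orders$delay]
  for (j in seq_len(orders$na)) X[, orders$nb + j] <- y[tt - j]
  fit <- stats::lm.fit(X, y[tt])
  theta <- fit$coefficients
  theta[is.na(theta)] <- 0
  if (fit$rank < ncol(X)) {
    warnf("rank-deficient ARX regressor (rank %d of %d)", fit$rank, ncol(X))
  }
  res <- y[tt] - X %*% theta
  cost <- mean(res^2)
  structure(list(a_coeffs = unname(theta[orders$nb + seq_len(orders$na)]),
                 b_coeffs = unname(theta[seq_len(orders$nb)]),
                 orders = orders, fit_cost = cost,
                 innovation_variance = cost, n_fit = length(tt)),
            class = "arx_model")
}

#' Akaike information criterion for a least-squares ARX fit
#'
#' `N log(F) + 2 (na + nb)` with `F` the mean squared residual; lower is
#' better. A perfect fit (`F = 0`) returns `-Inf` with a warning.
#'
#' @param model An [arx_model()].
#' @param n_samples Number of samples used in the fit; default the model's.
#' @return Scalar AIC value.
#' @export
aic_score <- function(model, n_samples = model$n_fit) {
  k <- model$orders$na + model$orders$nb
  if (model$fit_cost <= 0) {
    warnf("zero fit cost: AIC is -Inf (perfect fit)")
    return(-Inf)
  }
  n_samples * log(model$fit_cost) + 2 * k
}

#' Default ARX order search space
#'
#' @param na_max,nb_max Maximum AR / exogenous orders.
#' @param delay_max Maximum input delay, samples.
#' @return Data frame of candidate `(na, nb, delay)` triples.
#' @export
arx_search_space <- function(na_max = 10L, nb_max = 10L, delay_max = 8L) {
  expand.grid(na = seq_len(na_max), nb = seq_len(nb_max),
              delay = 0:delay_max, KEEP.OUT.ATTRS = FALSE)
}

#' Select ARX orders by exhaustive AIC minimisation
#'
#' Ties are broken toward smaller `na + nb`, then smaller `delay`, then
#' smaller `na`, so the selection is deterministic. Models whose AR
#' polynomial is unstable are set aside: their free-run simulation (the
#' single-trial estimate) diverges, so the best stable candidate wins and
#' an unstable one is returned only when every candidate is unstable.
#'
#' @param y,u Epoch and reference input.
#' @param search_space Data frame with columns `na`, `nb`, `delay`.
#' @param require_stable Prefer stable AR polynomials (default TRUE).
#' @return List with the winning `orders` and fitted `model`.
#' @export
select_orders <- function(y, u, search_space = arx_search_space(),
                          require_stable = TRUE) {
  if (!nrow(search_space)) stopf("empty order search space")
  best_stable <- NULL; key_stable <- NULL
  best_any <- NULL; key_any <- NULL
  failures <- character()
  for (i in seq_len(nrow(search_space))) {
    o <- arx_orders(search_space$na[i], search_space$nb[i],
                    search_space$delay[i])
    m <- tryCatch(suppressWarnings(fit_arx(y, u, o)), error = function(e) e)
    if (inherits(m, "error")) {
      failures <- c(failures, sprintf("na=%d nb=%d delay=%d: %s", o$na, o$nb,
                                      o$delay, conditionMessage(m)))
      next
    }
    # common N across candidates: ranking is then invariant to a common
    # rescaling of y and u (which shifts every AIC by the same constant)
    aic <- suppressWarnings(aic_score(m, n_samples = length(y)))
    key <- c(aic, o$na + o$nb, o$delay, o$na)
    if (is.null(best_any) || tuple_less(key, key_any)) {
      best_any <- m; key_any <- key
    }
    if (require_stable && arx_is_stable(m) &&
        (is.null(best_stable) || tuple_less(key, key_stable))) {
      best_stable <- m; key_stable <- key
    }
  }
  best <- if (!is.null(best_stable)) best_stable else best_any
  if (is.null(best)) {
    stopf("all ARX fits failed:\n%s", paste(failures, collapse = "\n"))
  }
  list(orders = best$orders, model = best)
}

# lexicographic strictly-less over numeric tuples (NA-free)
tuple_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Deterministic part B(z)/A(z) u simulated with zero innovations.
arx_deterministic <- function(model, u) {
  b_full <- c(rep(0, model$orders$delay + 1L), model$b_coeffs)
  a_full <- c(1, -model$a_coeffs)
  as.numeric(signal::filter(b_full, a_full, u))
}

arx_is_stable <- function(model) {
  all(Mod(polyroot(c(1, -model$a_coeffs))) > 1)
}

# Reflect unstable roots of A(z) = 1 - sum a_j z^-j across the unit circle
# (an all-pass factor: the magnitude spectrum of 1/A is preserved) so the
# polynomial can drive stable simulations.
stabilize_ar <- function(a, margin = 1.01) {
  if (!length(a)) return(a)
  r <- polyroot(c(1, -a))
  bad <- Mod(r) <= 1
  if (!any(bad)) return(a)
  r[bad] <- margin / Conj(r[bad])
  coef <- 1
  for (ri in r) coef <- c(coef, 0) - c(0, coef / ri)
  coef <- Re(coef) / Re(coef[1])
  -coef[-1]
}

#' ARX single-trial estimate of one epoch
#'
#' Selects orders by AIC, fits the model, and returns the deterministic
#' component `B(z)/A(z) u` — the epoch's evoked-response part, with the
#' AR-modelled background stripped off.
#'
#' @param y Observed epoch (one channel).
#' @param u Reference input (class grand average for that channel).
#' @param search_space Candidate orders; see [arx_search_space()].
#' @return Numeric vector with attributes `model` and `stable`.
#' @export
arx_estimate_st <- function(y, u, search_space = arx_search_space()) {
  if (all(u == 0)) {
    est <- numeric(length(y))
    attr(est, "stable") <- TRUE
    return(est)
  }
  sel <- select_orders(y, u, search_space)
  if (!arx_is_stable(sel$model)) {
    warnf("selected ARX model (na=%d) is unstable; estimate kept",
          sel$orders$na)
  }
  est <- arx_deterministic(sel$model, u)
  attr(est, "model") <- sel$model
  attr(est, "stable") <- arx_is_stable(sel$model)
  est
}

#' Fit the ARX reference input on training data
#'
#' The reference waveform is the per-channel grand average of the
#' ErrP-labelled training epochs only, so validation/test epochs never
#' leak into the estimator.
#'
#' @param epochs Training [epoch_set()].
#' @param search_space Candidate orders used when the fit is applied.
#' @return Object of class `arx_fit`.
#' @export
arx_fit <- function(epochs, search_space = arx_search_space(4, 4, 2)) {
  structure(list(u = grand_average(epochs, 1L), search_space = search_space),
            class = "arx_fit")
}

#' Apply the ARX estimator to every channel of every epoch
#'
#' @param fit An [arx_fit()].
#' @param epochs An [epoch_set()].
#' @return The denoised `epoch_set` (labels untouched).
#' @export
arx_apply <- function(fit, epochs) {
  stopifnot(inherits(fit, "arx_fit"), inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      epochs$data[i, ch, ] <- suppressWarnings(
        arx_estimate_st(epochs$data[i, ch, ], fit$u[ch, ], fit$search_space))
    }
  }
  epochs
}

#' @rdname arx_apply
#' @inheritParams arx_fit
#' @export
arx_estimate_epochset <- function(epochs, search_space = arx_search_space(4, 4, 2)) {
  arx_apply(arx_fit(epochs, search_space), epochs)
}

#' ARX surrogate epochs for class balancing
#'
#' For each surrogate a real minority-class epoch is drawn, its ARX model
#' against the class grand average is fitted, and a new epoch is produced as
#' the deterministic part plus an AR-coloured innovation sequence resampled
#' with the residual variance. The surrogates inherit the minority label.
#'
#' @param epochs An [epoch_set()] (training set only).
#' @param n_needed Number of surrogates; 0 or less returns an empty set.
#' @param seed Integer seed.
#' @param minority_label Label of the class to synthesise (default 1).
#' @param search_space Candidate orders (small by default; surrogate
#'   generation fits one model per channel per surrogate).
#' @return An `epoch_set` with `n_needed` epochs.
#' @export
generate_surrogates <- function(epochs, n_needed, seed = NULL,
                                minority_label = 1L,
                                search_space = expand.grid(na = c(2L, 4L),
                                                           nb = c(2L, 4L),
                                                           delay = 0L)) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_needed <- as.integer(n_needed)
  if (n_needed <= 0L) {
    return(epoch_set(array(0, c(0, d[2], d[3])), integer(),
                     epochs$sampling_rate_hz, epochs$window_s,
                     prestim = if (is.null(epochs$prestim)) NULL else
                       array(0, c(0, dim(epochs$prestim)[2], dim(epochs$prestim)[3])),
                     channel_names = epochs$channel_names))
  }
  minority <- which(epochs$labels == minority_label)
  if (!length(minority)) stopf("no epoch carries the minority label %d",
                               minority_label)
  u <- grand_average(epochs, minority_label)
  with_seed(seed, {
    pick <- sample(minority, n_needed, replace = TRUE)
    out <- array(0, c(n_needed, d[2], d[3]))
    pre <- if (is.null(epochs$prestim)) NULL else
      array(0, c(n_needed, dim(epochs$prestim)[2], dim(epochs$prestim)[3]))
    for (s in seq_len(n_needed)) {
      for (ch in seq_len(d[2])) {
        y <- epochs$data[pick[s], ch, ]
        sel <- tryCatch(suppressWarnings(select_orders(y, u[ch, ], search_space)),
                        error = function(e) NULL)
        if (is.null(sel)) { out[s, ch, ] <- y; next }
        model <- sel$model
        # a least-squares AR fit on one short epoch is often unstable;
        # reflect unstable roots so both the deterministic simulation and
        # the innovation colouring stay bounded
        model$a_coeffs <- stabilize_ar(model$a_coeffs)
        det <- arx_deterministic(model, u[ch, ])
        innov <- rnorm(d[3], sd = sqrt(max(model$innovation_variance, 0)))
        coloured <- as.numeric(signal::filter(1, c(1, -model$a_coeffs), innov))
        # belt-and-braces amplitude guard near the unit circle
        smax <- 5 * max(stats::sd(y), 1e-12)
        if (stats::sd(coloured) > smax) {
          coloured <- coloured * smax / stats::sd(coloured)
        }
        if (stats::sd(det) > smax) det <- det * smax / stats::sd(det)
        out[s, ch, ] <- det + coloured
      }
      if (!is.null(pre)) pre[s, , ] <- epochs$prestim[pick[s], , ]
    }
    epoch_set(out, rep(minority_label, n_needed), epochs$sampling_rate_hz,
              epochs$window_s, prestim = pre,
              channel_names = epochs$channel_names)
  })
}
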
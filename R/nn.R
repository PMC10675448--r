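# Minimal neural-network core for the compact EEG classifiers.
#
# Tensors are 3-D arrays (maps x time x batch); dense activations are
# matrices (features x batch). Each layer is a list with a `type`, a
# `params` list of arrays and static shape fields; `nn_forward` /
# `nn_backward` dispatch on the type and implement the exact gradients.
# Training uses Adam on the flattened parameter list. Everything is plain
# R: input windows are tiny (tens of channels x 64 samples), so GEMM-based
# convolutions are fast enough and the arithmetic is bit-reproducible
# under a fixed seed.

pad_time <- function(x, pl, pr) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + pl + pr, d[3]))
  out[, pl + seq_len(d[2]), ] <- x
  out
}

nn_layer <- function(type, ...) c(list(type = type), list(...))

# Linear indices into the padded tensor (dims M x (T+k-1) x B) for the
# im2col gather: row r = (m, t, b) in output order, column kk = tap.
conv_idx <- function(d, k) {
  M <- d[1]; T <- d[2]; B <- d[3]
  Tp <- T + k - 1L
  base <- rep(seq_len(M), T * B) +
    rep(rep((seq_len(T) - 1L) * M, each = M), B) +
    rep((seq_len(B) - 1L) * M * Tp, each = M * T)
  outer(base, (seq_len(k) - 1L) * M, `+`)
}

# ---- parameter initialisation -------------------------------------------

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

nn_init_layer <- function(layer) {
  p <- switch(layer$type,
    conv_time = list(W = glorot(layer$k, layer$filters,
                                layer$k, layer$filters),
                     b = numeric(layer$filters)),
    depthwise_time = list(W = glorot(layer$k, layer$maps, layer$k, 1),
                          b = numeric(layer$maps)),
    spatial_depthwise = list(
      W = array(stats::runif(layer$group_size * layer$mult * layer$groups,
                             -sqrt(6 / layer$group_size),
                             sqrt(6 / layer$group_size)),
                c(layer$group_size, layer$mult, layer$groups)),
      b = numeric(layer$mult * layer$groups)),
    pointwise = list(W = glorot(layer$maps_in, layer$maps_out,
                                layer$maps_in, layer$maps_out),
                     b = numeric(layer$maps_out)),
    dense = list(W = glorot(layer$n_in, layer$n_out, layer$n_in, layer$n_out),
                 b = numeric(layer$n_out)),
    batchnorm = list(gamma = rep(1, layer$maps), beta = numeric(layer$maps)),
    NULL)
  layer$params <- p
  if (layer$type == "batchnorm") {
    layer$run_mean <- numeric(layer$maps)
    layer$run_var <- rep(1, layer$maps)
  }
  layer
}

# ---- forward -------------------------------------------------------------

nn_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    conv_time = {
      # im2col + GEMM: rows ordered (map, time, batch), one column per tap
      d <- dim(x); k <- layer$k; F <- layer$filters
      pl <- (k - 1L) %/% 2L
      xp <- pad_time(x, pl, k - 1L - pl)
      idx <- conv_idx(d, k)
      Xcol <- matrix(xp[as.vector(idx)], nrow(idx), k)
      o <- Xcol %*% layer$params$W                 # (M*T*B) x F
      dim(o) <- c(d[1], d[2], d[3], F)
      out <- aperm(o, c(1, 4, 2, 3))               # maps ordered (m, f)
      dim(out) <- c(F * d[1], d[2], d[3])
      out <- out + rep(layer$params$b, each = d[1])
      list(out = out, cache = list(Xcol = Xcol, idx = idx, d = d,
                                   np = dim(xp)))
    },
    depthwise_time = {
      d <- dim(x); k <- layer$k
      pl <- (k - 1L) %/% 2L
      xp <- pad_time(x, pl, k - 1L - pl)
      idx <- conv_idx(d, k)
      Xcol <- matrix(xp[as.vector(idx)], nrow(idx), k)
      grp <- rep(seq_len(d[1]), d[2] * d[3])
      Wexp <- t(layer$params$W)[grp, , drop = FALSE]
      out <- array(rowSums(Xcol * Wexp) + layer$params$b[grp], d)
      list(out = out, cache = list(Xcol = Xcol, idx = idx, d = d,
                                   np = dim(xp), grp = grp, Wexp = Wexp))
    },
    spatial_depthwise = {
      d <- dim(x); G <- layer$groups; C <- layer$group_size; D <- layer$mult
      out <- array(0, c(G * D, d[2], d[3]))
      xg <- vector("list", G)
      for (g in seq_len(G)) {
        Xg <- matrix(x[(g - 1L) * C + seq_len(C), , ], C, d[2] * d[3])
        xg[[g]] <- Xg
        out[(g - 1L) * D + seq_len(D), , ] <-
          crossprod(layer$params$W[, , g], Xg)
      }
      out <- out + layer$params$b
      list(out = out, cache = list(xg = xg, d = d))
    },
    pointwise = {
      d <- dim(x)
      xm <- matrix(x, d[1], d[2] * d[3])
      out <- array(crossprod(layer$params$W, xm) + layer$params$b,
                   c(layer$maps_out, d[2], d[3]))
      list(out = out, cache = list(xm = xm, d = d))
    },
    batchnorm = {
      d <- dim(x)
      xm <- matrix(x, d[1], d[2] * d[3])
      if (training) {
        mu <- rowMeans(xm)
        v <- rowMeans((xm - mu)^2)
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      inv <- 1 / sqrt(v + 1e-5)
      xhat <- (xm - mu) * inv
      out <- array(layer$params$gamma * xhat + layer$params$beta, d)
      list(out = out,
           cache = list(xhat = xhat, inv = inv, d = d, mu = mu, v = v,
                        training = training))
    },
    act = {
      if (layer$fun == "elu") {
        out <- x
        neg <- x <= 0
        out[neg] <- exp(x[neg]) - 1
      } else {
        out <- pmax(x, 0)
      }
      list(out = out, cache = list(x = x))
    },
    pool_mean = {
      d <- dim(x); P <- layer$pool
      To <- d[2] %/% P
      xc <- x[, seq_len(To * P), , drop = FALSE]
      xr <- array(xc, c(d[1], P, To, d[3]))
      out <- array(0, c(d[1], To, d[3]))
      for (p in seq_len(P)) {
        out <- out + array(xr[, p, , , drop = FALSE], c(d[1], To, d[3]))
      }
      out <- out / P
      list(out = out, cache = list(d = d, To = To))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(x)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(x)
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1] * d[2], d[3]), cache = list(d = d))
    },
    dense = {
      out <- crossprod(layer$params$W, x) + layer$params$b
      list(out = out, cache = list(x = x))
    },
    stopf("unknown layer type %s", layer$type))
}

# ---- backward ------------------------------------------------------------

nn_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv_time = {
      d <- cache$d; k <- layer$k; F <- layer$filters
      pl <- (k - 1L) %/% 2L
      dim(dout) <- c(d[1], F, d[2], d[3])
      dcol <- aperm(dout, c(1, 3, 4, 2))
      dim(dcol) <- c(prod(d), F)
      db <- colSums(dcol)
      dW <- crossprod(cache$Xcol, dcol)
      dXcol <- dcol %*% t(layer$params$W)          # (M*T*B) x k
      dxp <- numeric(prod(cache$np))
      for (kk in seq_len(k)) {
        ii <- cache$idx[, kk]
        dxp[ii] <- dxp[ii] + dXcol[, kk]
      }
      dim(dxp) <- cache$np
      list(dx = dxp[, pl + seq_len(d[2]), , drop = FALSE],
           grads = list(W = dW, b = db))
    },
    depthwise_time = {
      d <- cache$d; k <- layer$k
      pl <- (k - 1L) %/% 2L
      dv <- as.numeric(dout)
      db <- rowSums(matrix(dout, d[1], d[2] * d[3]))
      dW <- t(rowsum(cache$Xcol * dv, cache$grp, reorder = TRUE))
      dxp <- numeric(prod(cache$np))
      for (kk in seq_len(k)) {
        ii <- cache$idx[, kk]
        dxp[ii] <- dxp[ii] + dv * cache$Wexp[, kk]
      }
      dim(dxp) <- cache$np
      list(dx = dxp[, pl + seq_len(d[2]), , drop = FALSE],
           grads = list(W = dW, b = db))
    },
    spatial_depthwise = {
      d <- cache$d; G <- layer$groups; C <- layer$group_size; D <- layer$mult
      dW <- array(0, dim(layer$params$W))
      db <- rowSums(matrix(dout, G * D, d[2] * d[3]))
      dx <- array(0, d)
      for (g in seq_len(G)) {
        dOg <- matrix(dout[(g - 1L) * D + seq_len(D), , ], D, d[2] * d[3])
        dW[, , g] <- cache$xg[[g]] %*% t(dOg)
        dx[(g - 1L) * C + seq_len(C), , ] <- layer$params$W[, , g] %*% dOg
      }
      list(dx = dx, grads = list(W = dW, b = db))
    },
    pointwise = {
      d <- cache$d
      dm <- matrix(dout, layer$maps_out, d[2] * d[3])
      list(dx = array(layer$params$W %*% dm, d),
           grads = list(W = cache$xm %*% t(dm), b = rowSums(dm)))
    },
    batchnorm = {
      d <- cache$d
      N <- d[2] * d[3]
      dm <- matrix(dout, d[1], N)
      dgamma <- rowSums(dm * cache$xhat)
      dbeta <- rowSums(dm)
      if (cache$training) {
        dxhat <- dm * layer$params$gamma
        dxm <- cache$inv / N *
          (N * dxhat - rowSums(dxhat) -
             cache$xhat * rowSums(dxhat * cache$xhat))
      } else {
        dxm <- dm * layer$params$gamma * cache$inv
      }
      list(dx = array(dxm, d), grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      x <- cache$x
      if (layer$fun == "elu") {
        g <- array(1, dim(x))
        neg <- x <= 0
        g[neg] <- exp(x[neg])
        dx <- dout * g
      } else {
        dx <- dout * (x > 0)
      }
      list(dx = dx, grads = NULL)
    },
    pool_mean = {
      d <- cache$d; P <- layer$pool; To <- cache$To
      dx <- array(0, d)
      dr <- array(0, c(d[1], P, To, d[3]))
      for (p in seq_len(P)) dr[, p, , ] <- dout / P
      dx[, seq_len(To * P), ] <- array(dr, c(d[1], To * P, d[3]))
      list(dx = dx, grads = NULL)
    },
    dropout = {
      dx <- if (is.null(cache$mask)) dout else dout * cache$mask
      list(dx = dx, grads = NULL)
    },
    flatten = {
      list(dx = array(dout, cache$d), grads = NULL)
    },
    dense = {
      list(dx = layer$params$W %*% dout,
           grads = list(W = cache$x %*% t(dout), b = rowSums(dout)))
    },
    stopf("unknown layer type %s", layer$type))
}

# Full-network forward; returns output plus per-layer caches.
nn_model_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    r <- nn_forward(model$layers[[i]], x, training)
    caches[[i]] <- r$cache
    x <- r$out
    if (training && model$layers[[i]]$type == "batchnorm") {
      m <- model$layers[[i]]$momentum %||% 0.9
      model$layers[[i]]$run_mean <-
        m * model$layers[[i]]$run_mean + (1 - m) * r$cache$mu
      model$layers[[i]]$run_var <-
        m * model$layers[[i]]$run_var + (1 - m) * r$cache$v
    }
  }
  list(out = x, caches = caches, model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full-network backward; returns gradient lists parallel to layers and dx.
nn_model_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    r <- nn_backward(model$layers[[i]], caches[[i]], dout)
    grads[i] <- list(r$grads)   # [[<-]] with NULL would drop the slot
    dout <- r$dx
  }
  list(grads = grads, dx = dout)
}

# Softmax cross-entropy on n_class logits; y is an integer class index
# vector (1-based). Returns loss and dlogits.
softmax_xent <- function(logits, y) {
  mx <- apply(logits, 2, max)
  z <- sweep(logits, 2, mx)
  ez <- exp(z)
  p <- sweep(ez, 2, colSums(ez), "/")
  B <- ncol(logits)
  idx <- cbind(y, seq_len(B))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / B, probs = p)
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (is.null(l$params)) return(NULL)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(model, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      model$layers[[i]]$params[[nm]] <-
        model$layers[[i]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(model = model, state = state)
}

count_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (is.null(l$params)) 0L else
      sum(vapply(l$params, length, integer(1)))
  }, integer(1)))
}
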
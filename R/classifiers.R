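#' Training configuration for the compact CNN classifiers
#'
#' Defaults follow the common training recipe for all three families:
#' Adam, binary cross-entropy, 300 training epochs, batch size 16.
#'
#' @param n_train_epochs Passes over the training set (default 300).
#' @param batch_size Mini-batch size (default 16).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed for weight init, shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(n_train_epochs = 300, batch_size = 16,
                         learning_rate = 1e-3, seed = 1L) {
  if (n_train_epochs < 0 || batch_size < 1) stopf("invalid training config")
  structure(list(optimizer = "adam", loss = "binary_cross_entropy",
                 n_train_epochs = as.integer(n_train_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

#' Architecture specification
#'
#' @param family `"eegnet"`, `"lcnn"` or `"siamese"`.
#' @param eegnet_filters `(F1, D, F2)`: temporal filters, depthwise spatial
#'   multiplier, separable pointwise filters (default `c(8, 2, 16)`).
#' @param lcnn_kernels Named list: `temporal_k`, `n_temporal`,
#'   `n_feature_maps`, `pool`. `NULL` entries are scaled to the input length
#'   (the published kernel lengths of 25 and 75 samples assume 512 Hz
#'   windows; they are rescaled by `T/512` for shorter inputs).
#' @param siamese_embed_dim Embedding dimension of the twin network.
#' @param dropout_rate Dropout probability (default 0.25).
#' @return Object of class `arch_spec`.
#' @export
arch_spec <- function(family = c("eegnet", "lcnn", "siamese"),
                      eegnet_filters = c(8, 2, 16),
                      lcnn_kernels = list(temporal_k = NULL, n_temporal = 4,
                                          n_feature_maps = 40, pool = NULL),
                      siamese_embed_dim = 16,
                      dropout_rate = 0.25) {
  family <- match.arg(family)
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout must be in [0, 1)")
  structure(list(family = family, eegnet_filters = eegnet_filters,
                 lcnn_kernels = lcnn_kernels,
                 siamese_embed_dim = siamese_embed_dim,
                 dropout_rate = dropout_rate),
            class = "arch_spec")
}

new_nn_model <- function(layers, input_shape, family, spec) {
  structure(list(layers = lapply(layers, nn_init_layer),
                 input_shape = input_shape, family = family, spec = spec,
                 fitted = FALSE, history = numeric()),
            class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model:%s> input %d ch x %d samples, %d parameters%s\n",
              x$family, x$input_shape[1], x$input_shape[2],
              count_parameters(x), if (x$fitted) ", fitted" else ""))
  invisible(x)
}

#' Build the EEGNet-style classifier
#'
#' Block 1: temporal convolution (F1 filters shared across channels) with
#' batch normalisation, then a depthwise spatial convolution over all
#' channels (multiplier D), batch normalisation, ELU, mean pooling and
#' dropout. Block 2: separable convolution (depthwise temporal kernel
#' followed by F2 pointwise filters), batch normalisation, ELU, pooling,
#' dropout. Block 3: a fully connected layer to the 2-class output. The
#' depthwise/separable structure keeps the parameter count low.
#'
#' @param spec An [arch_spec()] with `family = "eegnet"`.
#' @param input_shape `c(n_channels, n_samples)`.
#' @param seed Seed for weight initialisation.
#' @return An untrained `nn_model`.
#' @export
build_eegnet <- function(spec = arch_spec("eegnet"), input_shape,
                         seed = 1L) {
  C <- input_shape[1]; T <- input_shape[2]
  F1 <- spec$eegnet_filters[1]; D <- spec$eegnet_filters[2]
  F2 <- spec$eegnet_filters[3]
  k1 <- max(3L, round(T / 5))
  if (k1 > T) stopf("input of %d samples shorter than temporal kernel %d", T, k1)
  p1 <- 4L; p2 <- min(8L, max(2L, (T %/% p1) %/% 2L))
  k2 <- max(3L, round(T / 16))
  To <- (T %/% p1) %/% p2
  layers <- list(
    nn_layer("conv_time", filters = F1, k = k1),
    nn_layer("batchnorm", maps = F1 * C),
    nn_layer("spatial_depthwise", groups = F1, group_size = C, mult = D),
    nn_layer("batchnorm", maps = F1 * D),
    nn_layer("act", fun = "elu"),
    nn_layer("pool_mean", pool = p1),
    nn_layer("dropout", rate = spec$dropout_rate),
    nn_layer("depthwise_time", maps = F1 * D, k = k2),
    nn_layer("pointwise", maps_in = F1 * D, maps_out = F2),
    nn_layer("batchnorm", maps = F2),
    nn_layer("act", fun = "elu"),
    nn_layer("pool_mean", pool = p2),
    nn_layer("dropout", rate = spec$dropout_rate),
    nn_layer("flatten"),
    nn_layer("dense", n_in = F2 * To, n_out = 2L))
  with_seed(seed, new_nn_model(layers, input_shape, "eegnet", spec))
}

#' Build the light CNN (L-CNN) classifier
#'
#' A temporal convolutional layer across samples, a spatial convolutional
#' layer across all electrodes producing `n_feature_maps` maps, one mean
#' pooling layer and a dense layer with two outputs read through a
#' logarithmic (log-softmax) activation. The published kernel lengths
#' (25 and 75 samples) assume 512 Hz windows and are rescaled to the input
#' length by default; literal sizes can be forced through `lcnn_kernels`.
#'
#' @inheritParams build_eegnet
#' @return An untrained `nn_model`.
#' @export
build_lcnn <- function(spec = arch_spec("lcnn"), input_shape, seed = 1L) {
  C <- input_shape[1]; T <- input_shape[2]
  kk <- spec$lcnn_kernels
  k1 <- kk$temporal_k %||% max(3L, round(25 * T / 512))
  Ft <- kk$n_temporal %||% 4L
  M <- kk$n_feature_maps %||% 40L
  P <- kk$pool %||% max(2L, round(75 * T / 512))
  if (k1 > T) {
    stopf("temporal kernel %d exceeds the %d-sample input; try %d",
          k1, T, max(3L, round(25 * T / 512)))
  }
  if (P > T) stopf("pooling kernel %d exceeds the %d-sample input", P, T)
  To <- T %/% P
  layers <- list(
    nn_layer("conv_time", filters = Ft, k = k1),
    nn_layer("act", fun = "relu"),
    nn_layer("pointwise", maps_in = Ft * C, maps_out = M),
    nn_layer("act", fun = "relu"),
    nn_layer("pool_mean", pool = P),
    nn_layer("flatten"),
    nn_layer("dense", n_in = M * To, n_out = 2L))
  with_seed(seed, new_nn_model(layers, input_shape, "lcnn", spec))
}

#' Build the Siamese twin network
#'
#' One embedding CNN (two convolutional layers followed by two fully
#' connected layers) applied with shared weights to both inputs of a pair;
#' the output is the Euclidean distance between the two embeddings, trained
#' with a contrastive objective so that same-class pairs score low.
#'
#' @inheritParams build_eegnet
#' @return An untrained `nn_model` (the shared embedding branch).
#' @export
build_siamese <- function(spec = arch_spec("siamese"), input_shape,
                          seed = 1L) {
  C <- input_shape[1]; T <- input_shape[2]
  F1 <- 8L; M2 <- 16L
  k1 <- max(3L, round(T / 8))
  p <- 4L
  To <- (T %/% p) %/% p
  if (To < 1) stopf("input of %d samples too short for the siamese branch", T)
  layers <- list(
    nn_layer("conv_time", filters = F1, k = k1),
    nn_layer("act", fun = "relu"),
    nn_layer("pool_mean", pool = p),
    nn_layer("pointwise", maps_in = F1 * C, maps_out = M2),
    nn_layer("act", fun = "relu"),
    nn_layer("pool_mean", pool = p),
    nn_layer("flatten"),
    nn_layer("dense", n_in = M2 * To, n_out = 32L),
    nn_layer("act", fun = "relu"),
    nn_layer("dense", n_in = 32L, n_out = spec$siamese_embed_dim))
  m <- with_seed(seed, new_nn_model(layers, input_shape, "siamese", spec))
  m$margin <- 1
  m
}

#' Build a classifier by family name
#'
#' @param spec An [arch_spec()].
#' @param input_shape `c(n_channels, n_samples)`.
#' @param seed Seed for weight initialisation.
#' @return An untrained `nn_model`.
#' @export
build_classifier <- function(spec, input_shape, seed = 1L) {
  switch(spec$family,
         eegnet = build_eegnet(spec, input_shape, seed),
         lcnn = build_lcnn(spec, input_shape, seed),
         siamese = build_siamese(spec, input_shape, seed))
}

# epoch_set -> (channels x samples x epochs) tensor
epochs_tensor <- function(epochs, idx = seq_len(n_epochs(epochs))) {
  aperm(epochs$data[idx, , , drop = FALSE], c(2, 3, 1))
}

#' Train a classifier on an epoch set
#'
#' Adam on the binary cross-entropy (softmax over the two output units) for
#' EEGNet/L-CNN; contrastive loss over epoch pairs for the Siamese family
#' (same/different-class pairs are drawn from the training set in each
#' mini-batch, without any surrogate augmentation). With
#' `n_train_epochs = 0` the initial weights are returned untouched.
#'
#' @param model An untrained or trained `nn_model`.
#' @param epochs Training [epoch_set()] with binary labels.
#' @param config A [train_config()].
#' @return The fitted `nn_model` with a `history` of per-epoch mean losses.
#' @export
train_classifier <- function(model, epochs, config = train_config()) {
  stopifnot(inherits(model, "nn_model"), inherits(epochs, "epoch_set"))
  if (!all(epochs$labels %in% c(0L, 1L))) stopf("labels must be binary")
  d <- dim(epochs$data)
  if (d[2] != model$input_shape[1] || d[3] != model$input_shape[2]) {
    stopf("epochs are %d ch x %d samples but the model expects %d x %d",
          d[2], d[3], model$input_shape[1], model$input_shape[2])
  }
  if (model$family == "siamese") {
    return(train_siamese(model, epochs, config))
  }
  x_all <- epochs_tensor(epochs)
  y_all <- epochs$labels + 1L
  n <- d[1]
  state <- adam_init(model)
  t_step <- 0L
  with_seed(config$seed, {
    history <- numeric(config$n_train_epochs)
    for (ep in seq_len(config$n_train_epochs)) {
      ord <- sample.int(n)
      losses <- numeric()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        fw <- nn_model_forward(model, x_all[, , idx, drop = FALSE],
                               training = TRUE)
        model <- fw$model
        ls <- softmax_xent(fw$out, y_all[idx])
        if (!is.finite(ls$loss)) {
          stopf("training diverged (non-finite loss); reduce the learning rate")
        }
        bw <- nn_model_backward(model, fw$caches, ls$dlogits)
        t_step <- t_step + 1L
        upd <- adam_step(model, bw$grads, state, config$learning_rate, t_step)
        model <- upd$model; state <- upd$state
        losses <- c(losses, ls$loss)
      }
      history[ep] <- mean(losses)
    }
    model$history <- history
  })
  model$fitted <- TRUE
  model$train_config <- config
  model
}

# Contrastive training of the shared embedding branch.
train_siamese <- function(model, epochs, config) {
  x_all <- epochs_tensor(epochs)
  y <- epochs$labels
  n <- length(y)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (!length(pos) || !length(neg)) stopf("siamese training needs both classes")
  state <- adam_init(model)
  t_step <- 0L
  margin <- model$margin %||% 1
  with_seed(config$seed, {
    history <- numeric(config$n_train_epochs)
    steps <- max(1L, ceiling(n / config$batch_size))
    for (ep in seq_len(config$n_train_epochs)) {
      losses <- numeric(steps)
      for (s in seq_len(steps)) {
        B <- config$batch_size
        same <- stats::rbinom(B, 1L, 0.5)
        i1 <- integer(B); i2 <- integer(B)
        draw <- function(x, k, repl = FALSE) x[sample.int(length(x), k, replace = repl)]
        for (b in seq_len(B)) {
          if (same[b] == 1L) {
            cls <- if (stats::runif(1) < 0.5) pos else neg
            pr <- draw(cls, 2L, repl = length(cls) < 2L)
          } else {
            pr <- c(draw(pos, 1L), draw(neg, 1L))
          }
          i1[b] <- pr[1]; i2[b] <- pr[2]
        }
        f1 <- nn_model_forward(model, x_all[, , i1, drop = FALSE], TRUE)
        model <- f1$model
        f2 <- nn_model_forward(model, x_all[, , i2, drop = FALSE], TRUE)
        model <- f2$model
        diff <- f1$out - f2$out                       # embed_dim x B
        dist <- sqrt(colSums(diff^2) + 1e-12)
        # L = same d^2 + (1 - same) max(0, margin - d)^2
        hinge <- pmax(margin - dist, 0)
        loss <- mean(same * dist^2 + (1 - same) * hinge^2)
        if (!is.finite(loss)) {
          stopf("training diverged (non-finite loss); reduce the learning rate")
        }
        ddist <- (2 * same * dist - 2 * (1 - same) * hinge) / length(dist)
        dd <- sweep(diff, 2, ddist / dist, "*")
        b1 <- nn_model_backward(model, f1$caches, dd)
        b2 <- nn_model_backward(model, f2$caches, -dd)
        grads <- mapply(function(g1, g2) {
          if (is.null(g1)) return(NULL)
          mapply(`+`, g1, g2, SIMPLIFY = FALSE)
        }, b1$grads, b2$grads, SIMPLIFY = FALSE)
        t_step <- t_step + 1L
        upd <- adam_step(model, grads, state, config$learning_rate, t_step)
        model <- upd$model; state <- upd$state
        losses[s] <- loss
      }
      history[ep] <- mean(losses)
    }
    model$history <- history
  })
  model$fitted <- TRUE
  model$train_config <- config
  # calibrate the same-class distance threshold on training pairs (F1-max)
  model <- calibrate_siamese_threshold(model, epochs, config$seed)
  model$train_ref <- epochs
  model
}

siamese_embed <- function(model, epochs) {
  nn_model_forward(model, epochs_tensor(epochs), training = FALSE)$out
}

# Threshold on the pair distance maximising F1 of "same class" over a
# sample of training pairs.
calibrate_siamese_threshold <- function(model, epochs, seed) {
  emb <- siamese_embed(model, epochs)
  y <- epochs$labels
  n <- length(y)
  with_seed(sub_seed(seed, 17L), {
    m <- min(2000L, n * (n - 1L) %/% 2L)
    i1 <- sample.int(n, m, replace = TRUE)
    i2 <- sample.int(n, m, replace = TRUE)
    keep <- i1 != i2
    i1 <- i1[keep]; i2 <- i2[keep]
    d <- sqrt(colSums((emb[, i1, drop = FALSE] - emb[, i2, drop = FALSE])^2))
    same <- as.integer(y[i1] == y[i2])
    cand <- unique(stats::quantile(d, seq(0.02, 0.98, by = 0.02), names = FALSE))
    f1s <- vapply(cand, function(th) {
      pred <- as.integer(d < th)
      tp <- sum(pred & same); fp <- sum(pred & !same); fn <- sum(!pred & same)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    model$pair_threshold <- cand[which.max(f1s)]
  })
  model
}

#' Per-epoch class probabilities
#'
#' For EEGNet/L-CNN: softmax over the two output units, one row per epoch.
#' For a Siamese model use [predict_by_pairing()].
#'
#' @param model A fitted `nn_model`.
#' @param epochs An [epoch_set()].
#' @return `n_epochs x 2` matrix of probabilities (columns: non-ErrP, ErrP).
#' @export
predict_proba <- function(model, epochs) {
  stopifnot(inherits(model, "nn_model"))
  if (!model$fitted) stopf("model is not fitted")
  if (model$family == "siamese") {
    stopf("use predict_by_pairing() for the siamese family")
  }
  out <- nn_model_forward(model, epochs_tensor(epochs), training = FALSE)$out
  z <- sweep(out, 2, apply(out, 2, max))
  ez <- exp(z)
  t(sweep(ez, 2, colSums(ez), "/"))
}

#' Predicted labels
#'
#' @inheritParams predict_proba
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(model, epochs) {
  if (model$family == "siamese") return(predict_by_pairing(model, epochs))
  as.integer(predict_proba(model, epochs)[, 2] > 0.5)
}

#' Siamese classification by pairing with the training set
#'
#' Each test epoch is paired with every training epoch; a pair with
#' embedding distance below the calibrated threshold votes for the training
#' epoch's label, otherwise for the opposite label. The majority of votes
#' decides (ties go to the non-ErrP class).
#'
#' @param model A fitted siamese `nn_model`.
#' @param epochs Test [epoch_set()].
#' @param training_set Training [epoch_set()]; defaults to the set the model
#'   was trained on.
#' @return Integer vector of 0/1 labels.
#' @export
predict_by_pairing <- function(model, epochs, training_set = model$train_ref) {
  stopifnot(inherits(model, "nn_model"), model$family == "siamese")
  if (!model$fitted) stopf("model is not fitted")
  if (is.null(training_set)) stopf("no training reference set available")
  emb_tr <- siamese_embed(model, training_set)
  emb_te <- siamese_embed(model, epochs)
  y_tr <- training_set$labels
  th <- model$pair_threshold
  vapply(seq_len(ncol(emb_te)), function(i) {
    d <- sqrt(colSums((emb_tr - emb_te[, i])^2))
    votes <- ifelse(d < th, y_tr, 1L - y_tr)
    as.integer(sum(votes == 1L) > length(votes) / 2)
  }, integer(1))
}
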
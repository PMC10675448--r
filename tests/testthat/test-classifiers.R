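test_that("backpropagation matches finite differences on a small network", {
  set.seed(42)
  model <- build_eegnet(arch_spec("eegnet", eegnet_filters = c(2, 2, 4),
                                  dropout_rate = 0), c(4L, 32L), seed = 7)
  x <- array(rnorm(4 * 32 * 3), c(4, 32, 3))
  y <- c(1L, 2L, 1L)
  lossfun <- function(m) {
    sterrp:::softmax_xent(sterrp:::nn_model_forward(m, x, TRUE)$out, y)$loss
  }
  fw <- sterrp:::nn_model_forward(model, x, TRUE)
  ls <- sterrp:::softmax_xent(fw$out, y)
  bw <- sterrp:::nn_model_backward(model, fw$caches, ls$dlogits)
  worst <- 0
  for (li in seq_along(model$layers)) {
    g <- bw$grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      p <- model$layers[[li]]$params[[nm]]
      for (ii in sample(seq_along(p), min(3, length(p)))) {
        eps <- 1e-5
        m2 <- model; m2$layers[[li]]$params[[nm]][ii] <- p[ii] + eps
        m3 <- model; m3$layers[[li]]$params[[nm]][ii] <- p[ii] - eps
        fd <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
        worst <- max(worst, abs(fd - g[[nm]][ii]) /
                       max(1e-4, abs(fd) + abs(g[[nm]][ii])))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("mean pooling equals brute-force window means", {
  set.seed(1)
  l <- sterrp:::nn_init_layer(sterrp:::nn_layer("pool_mean", pool = 4L))
  x <- array(rnorm(3 * 17 * 2), c(3, 17, 2))
  out <- sterrp:::nn_forward(l, x, FALSE)$out
  expect_equal(dim(out), c(3, 4, 2))
  for (m in 1:3) for (o in 1:4) for (b in 1:2) {
    expect_equal(out[m, o, b], mean(x[m, (o - 1) * 4 + 1:4, b]))
  }
})

test_that("forward passes satisfy the probability contract", {
  ep <- toy_classification_set(n = 8)
  for (fam in c("eegnet", "lcnn")) {
    m <- build_classifier(arch_spec(fam), c(4L, 32L), seed = 3)
    m <- train_classifier(m, ep, train_config(n_train_epochs = 1, seed = 3))
    pr <- predict_proba(m, ep)
    expect_equal(dim(pr), c(8, 2))
    expect_true(all(pr >= 0 & pr <= 1))
    expect_equal(rowSums(pr), rep(1, 8), tolerance = 1e-9)
  }
})

test_that("the EEGNet-style network is smaller than the L-CNN", {
  e <- build_eegnet(arch_spec("eegnet"), c(8L, 64L), seed = 1)
  l <- build_lcnn(arch_spec("lcnn"), c(8L, 64L), seed = 1)
  expect_lt(sterrp:::count_parameters(e), sterrp:::count_parameters(l))
})

test_that("both softmax families overfit a separable toy problem", {
  ep <- toy_classification_set(n = 40)
  for (fam in c("eegnet", "lcnn")) {
    m <- build_classifier(arch_spec(fam), c(4L, 32L), seed = 2)
    m <- train_classifier(m, ep, train_config(n_train_epochs = 50, seed = 2))
    expect_gte(mean(predict_labels(m, ep) == ep$labels), 0.95)
    # loss history trends downward
    expect_lt(mean(tail(m$history, 5)), mean(head(m$history, 5)))
  }
})

test_that("training is seeded and zero-epoch training is a no-op", {
  ep <- toy_classification_set(n = 24)
  m0 <- build_classifier(arch_spec("eegnet"), c(4L, 32L), seed = 5)
  a <- train_classifier(m0, ep, train_config(n_train_epochs = 3, seed = 9))
  b <- train_classifier(m0, ep, train_config(n_train_epochs = 3, seed = 9))
  expect_identical(a$history, b$history)
  expect_identical(a$layers[[1]]$params$W, b$layers[[1]]$params$W)

  z <- train_classifier(m0, ep, train_config(n_train_epochs = 0, seed = 9))
  expect_identical(z$layers[[1]]$params$W, m0$layers[[1]]$params$W)
  expect_length(z$history, 0)
})

test_that("label and shape validation fails loudly", {
  ep <- toy_classification_set(n = 8)
  m <- build_classifier(arch_spec("eegnet"), c(4L, 32L), seed = 1)
  bad <- ep; bad$labels[1] <- 2L
  expect_error(train_classifier(m, bad, train_config(1)), "binary")
  m2 <- build_classifier(arch_spec("eegnet"), c(6L, 32L), seed = 1)
  expect_error(train_classifier(m2, ep, train_config(1)), "expects")
  expect_error(predict_proba(m, ep), "not fitted")
})

test_that("siamese embeddings give zero self-distance and symmetry", {
  m <- build_siamese(arch_spec("siamese"), c(4L, 32L), seed = 4)
  ep <- toy_classification_set(n = 6)
  emb <- sterrp:::siamese_embed(m, ep)
  d12 <- sqrt(sum((emb[, 1] - emb[, 2])^2))
  d21 <- sqrt(sum((emb[, 2] - emb[, 1])^2))
  expect_equal(d12, d21)
  expect_equal(sqrt(sum((emb[, 3] - emb[, 3])^2)), 0)
})

test_that("trained siamese separates classes and votes by pairing", {
  ok <- 0L
  for (seed in 1:2) {
    ep <- toy_classification_set(n = 30, seed = seed)
    m <- build_siamese(arch_spec("siamese"), c(4L, 32L), seed = seed)
    m <- train_classifier(m, ep, train_config(n_train_epochs = 25, seed = seed))
    emb <- sterrp:::siamese_embed(m, ep)
    dmat <- as.matrix(dist(t(emb)))
    same <- outer(ep$labels, ep$labels, "==") & upper.tri(dmat)
    diff <- outer(ep$labels, ep$labels, "!=") & upper.tri(dmat)
    if (mean(dmat[same]) < mean(dmat[diff])) ok <- ok + 1L
    te <- toy_classification_set(n = 10, seed = seed + 50)
    expect_true(all(predict_by_pairing(m, te) %in% 0:1))
  }
  expect_gte(ok, 1L)
})

test_that("pairing with a one-exemplar-per-class reference picks the nearer", {
  ep <- toy_classification_set(n = 30, seed = 3)
  m <- build_siamese(arch_spec("siamese"), c(4L, 32L), seed = 3)
  m <- train_classifier(m, ep, train_config(n_train_epochs = 20, seed = 3))
  ref <- subset_epochs(ep, c(which(ep$labels == 0)[1], which(ep$labels == 1)[1]))
  te <- subset_epochs(ep, 3:8)
  pred <- predict_by_pairing(m, te, ref)
  emb_r <- sterrp:::siamese_embed(m, ref)
  emb_t <- sterrp:::siamese_embed(m, te)
  # brute-force recount of the degenerate two-voter election
  th <- m$pair_threshold
  manual <- vapply(seq_len(ncol(emb_t)), function(i) {
    d <- sqrt(colSums((emb_r - emb_t[, i])^2))
    votes <- ifelse(d < th, ref$labels, 1L - ref$labels)
    as.integer(sum(votes == 1L) > 1)
  }, integer(1))
  expect_identical(pred, manual)
})
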
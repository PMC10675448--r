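test_that("metrics reproduce hand-computed contingency values", {
  r <- compute_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(r$balanced_accuracy, 1)
  expect_equal(r$f1_score, 1)

  r2 <- compute_metrics(list(TP = 30, FN = 10, TN = 40, FP = 20))
  expect_equal(r2$recall_error, 0.75)
  expect_equal(r2$recall_correct, 2 / 3)
  expect_equal(r2$balanced_accuracy, (0.75 + 2 / 3) / 2)
  expect_equal(r2$f1_score, 2 / 3)

  und <- compute_metrics(list(TP = 0, FN = 0, TN = 10, FP = 0))
  expect_true(is.na(und$recall_error))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "empty")
})

test_that("metric identities hold on random confusion tables", {
  set.seed(1)
  for (i in 1:50) {
    cc <- list(TP = rpois(1, 20), TN = rpois(1, 50),
               FP = rpois(1, 10), FN = rpois(1, 10))
    if (cc$TP + cc$FN == 0 || cc$TN + cc$FP == 0) next
    r <- compute_metrics(cc)
    expect_equal(r$balanced_accuracy, (r$recall_correct + r$recall_error) / 2)
    expect_equal(r$f1_score, 2 * cc$TP / (2 * cc$TP + cc$FP + cc$FN))
    expect_true(all(unlist(r[1:4]) >= 0 & unlist(r[1:4]) <= 1))
  }
})

test_that("random predictions on balanced data give chance-level accuracy", {
  set.seed(2)
  n <- 1e4
  truth <- rep(0:1, each = n / 2)
  pred <- sample(0:1, n, replace = TRUE)
  r <- compute_metrics(confusion_counts(truth, pred))
  expect_lt(abs(r$balanced_accuracy - 0.5), 0.015)
})

test_that("utility gain follows its closed form and domain", {
  p_grid <- seq(0.70, 1.00, by = 0.01)
  expect_equal(utility_gain(p_grid, 1, 0), rep(1, length(p_grid)))
  expect_equal(utility_gain(0.7, 1, 1), 0.7 / 0.4)
  expect_equal(utility_gain(0.8, 0, 1), 0)
  expect_error(utility_gain(0.5, 1, 1), "singular")
  expect_error(utility_gain(0.4, 1, 1), "0.5")

  r <- compute_metrics(list(TP = 30, FN = 10, TN = 40, FP = 20))
  cv <- utility_curve(r)
  expect_equal(cv$p, p_grid)
  expect_equal(cv$gain[1], utility_gain(0.70, 2 / 3, 0.75))
})

test_that("stratified splits preserve ratios and partition the data", {
  ep <- small_epochs(n_events = 100, n_channels = 2, seed = 3,
                     error_probability = 0.2)
  # force exactly 20 positives for the arithmetic check
  ep$labels <- rep(c(1L, rep(0L, 4)), 20)
  plan <- split_plan(shuffle_seed = 11)
  sp <- make_split(ep, plan)
  expect_length(sp$test, 20)
  expect_equal(sum(ep$labels[sp$test]), 4)

  sp2 <- make_split(ep, plan)
  expect_identical(sp, sp2)

  all_idx <- sort(c(sp$test, unlist(sp$folds)))
  expect_identical(all_idx, seq_len(100))
  for (f in sp$folds) expect_length(intersect(f, sp$test), 0)
  sizes <- lengths(sp$folds)
  expect_lte(max(sizes) - min(sizes), 2)

  mono <- ep; mono$labels[] <- 0L
  expect_error(make_split(mono, plan), "both classes")
})

test_that("training-set balancing equalises counts and touches nothing else", {
  ep <- small_epochs(n_events = 100, n_channels = 2, seed = 4)
  ep$labels <- rep(c(1L, rep(0L, 4)), 20)           # 20 / 80
  bal <- balance_training_set(ep, seed = 5)
  expect_equal(n_epochs(bal), 160)
  expect_equal(sum(bal$labels == 1), 80)
  expect_equal(sum(bal$labels == 0), 80)
  # original epochs are the leading block, bit-identical
  expect_identical(bal$data[1:100, , ], ep$data)
  expect_identical(bal$labels[1:100], ep$labels)

  already <- bal
  expect_identical(balance_training_set(already, seed = 6), already)
})

test_that("majority voting follows the strict-majority rule", {
  votes <- matrix(c(1, 1, 0, 0, 1), 5, 1)
  expect_identical(majority_vote(votes), 1L)
  expect_identical(majority_vote(matrix(c(1, 0, 0, 0, 1), 5, 1)), 0L)
  # even split among four voters breaks to the non-ErrP class
  expect_identical(majority_vote(matrix(c(1, 1, 0, 0), 4, 1)), 0L)
  # constant-positive voters label everything positive
  expect_identical(majority_vote(matrix(1L, 5, 7)), rep(1L, 7))
})

test_that("hyperparameter cycles fix winners sequentially", {
  # objective: known quadratic with optimum (a = 2, b = -1)
  evals <- new.env(); evals$n <- 0L
  fn <- function(cfg) {
    evals$n <- evals$n + 1L
    -(cfg$a - 2)^2 - (cfg$b + 1)^2
  }
  cycles <- list(list(params = list(a = c(0, 1, 2, 3))),
                 list(params = list(b = c(-2, -1, 0))))
  res <- hyperparam_search(cycles, fn, base = list(a = 0, b = 0), seed = 1)
  expect_equal(res$best$a, 2)
  expect_equal(res$best$b, -1)
  expect_equal(evals$n, 7L)
  # the stored best score matches an independent re-evaluation
  expect_equal(res$score, fn(res$best))

  single <- hyperparam_search(list(list(params = list(a = 5))), fn,
                              base = list(b = 0))
  expect_equal(single$best$a, 5)

  expect_error(hyperparam_search(list(list(params = list())), fn), "empty")
})

test_that("random-search cycles respect budgets and seeds", {
  fn <- function(cfg) cfg$a + cfg$b
  cycles <- list(list(params = list(a = 1:100), budget = 5),
                 list(params = list(b = 1:3)))
  r1 <- hyperparam_search(cycles, fn, base = list(a = 0, b = 0), seed = 4)
  r2 <- hyperparam_search(cycles, fn, base = list(a = 0, b = 0), seed = 4)
  expect_identical(r1$best, r2$best)
  expect_equal(sum(r1$trace$cycle == 1), 5)
})

test_that("cross-validated majority vote beats or matches its worst fold", {
  ep <- toy_classification_set(n = 120, seed = 6, noise_sd = 0.8)
  sp <- make_split(ep, split_plan(shuffle_seed = 7))
  trainval <- subset_epochs(ep, sort(unlist(sp$folds)))
  test <- subset_epochs(ep, sp$test)
  all_idx <- sort(unlist(sp$folds))
  folds <- lapply(sp$folds, function(f) match(f, all_idx))
  cv <- crossval_majority(trainval, folds, test,
                          arch_spec("eegnet", eegnet_filters = c(4, 2, 8)),
                          train_config(n_train_epochs = 10, seed = 8),
                          balance = FALSE)
  expect_equal(dim(cv$votes), c(5, n_epochs(test)))
  expect_length(cv$predictions, n_epochs(test))
  fold_accs <- vapply(seq_len(5), function(f)
    mean(cv$votes[f, ] == test$labels), numeric(1))
  vote_acc <- mean(cv$predictions == test$labels)
  expect_gte(vote_acc, min(fold_accs))
})

test_that("a full experiment is reproducible and leaks nothing into the test set", {
  ep <- small_epochs(n_events = 150, n_channels = 2, seed = 9, snr_db = 5)
  cfg <- experiment_config(st_method = "subspace", classifier = "eegnet",
                           seed = 3,
                           spec = arch_spec("eegnet", eegnet_filters = c(4, 2, 8)),
                           train = train_config(n_train_epochs = 5, seed = 3))
  snapshot <- serialize(ep, NULL)
  res <- run_experiment(ep, cfg)
  expect_identical(serialize(ep, NULL), snapshot)   # inputs untouched
  expect_s3_class(res$report, "metrics_report")
  expect_true(all(c("p", "gain") %in% names(res$utility)))

  cfg_none <- cfg; cfg_none$st_method <- "none"
  res2 <- run_experiment(ep, cfg_none)
  expect_identical(res$split$test, res2$split$test)  # same split, same seed

  res3 <- run_experiment(ep, cfg)
  expect_identical(res$report, res3$report)

  # round-trips through serialisation
  path <- tempfile(fileext = ".rds")
  saveRDS(res, path)
  expect_identical(readRDS(path)$report, res$report)
})
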
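#' Confusion counts with ErrP as the positive class
#'
#' @param truth,pred Binary vectors (1 = ErrP).
#' @return Object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  structure(list(TP = sum(truth == 1 & pred == 1),
                 TN = sum(truth == 0 & pred == 0),
                 FP = sum(truth == 0 & pred == 1),
                 FN = sum(truth == 1 & pred == 0)),
            class = "confusion_counts")
}

#' Classification metrics for imbalanced ErrP detection
#'
#' Recall of correct events `rC = TN / (TN + FP)`, recall of erroneous
#' events `rE = TP / (TP + FN)`, balanced accuracy `(rC + rE) / 2` and the
#' minority-class `F1 = 2 TP / (2 TP + FP + FN)`. An empty denominator
#' yields `NA` (reported as undefined, never silently 0).
#'
#' @param confusion A [confusion_counts()] or a list with TP/TN/FP/FN.
#' @return Object of class `metrics_report`.
#' @export
compute_metrics <- function(confusion) {
  TP <- confusion$TP; TN <- confusion$TN
  FP <- confusion$FP; FN <- confusion$FN
  if (TP + TN + FP + FN == 0) stopf("empty confusion table")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  rC <- safe(TN, TN + FP)
  rE <- safe(TP, TP + FN)
  structure(list(recall_correct = rC, recall_error = rE,
                 balanced_accuracy = mean(c(rC, rE)),
                 f1_score = safe(2 * TP, 2 * TP + FP + FN),
                 confusion = confusion),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics> balanced accuracy %.3f | F1 %.3f | rC %.3f | rE %.3f (TP %d FP %d TN %d FN %d)\n",
    x$balanced_accuracy, x$f1_score, x$recall_correct, x$recall_error,
    x$confusion$TP, x$confusion$FP, x$confusion$TN, x$confusion$FN))
  invisible(x)
}

#' Utility gain of an ErrP-driven correction system
#'
#' `g(p) = (p rC + (1 - p) rE + p - 1) / (2 p - 1)` where `p` is the
#' baseline accuracy of the uncorrected BCI. `g > 1` means the corrector
#' improves the system; a corrector that never flags errors (`rC = 1`,
#' `rE = 0`) gives `g = 1` identically. `p = 0.5` is a singularity and
#' `p <= 0.5` is outside the domain.
#'
#' @param p Baseline BCI accuracy, in (0.5, 1].
#' @param rC,rE Recalls of correct and erroneous events.
#' @return The gain `g(p)`.
#' @export
utility_gain <- function(p, rC, rE) {
  if (any(p == 0.5)) stopf("utility gain is singular at p = 0.5")
  if (any(p <= 0.5 | p > 1)) stopf("p must lie in (0.5, 1]")
  (p * rC + (1 - p) * rE + p - 1) / (2 * p - 1)
}

#' @rdname utility_gain
#' @param report A [compute_metrics()] report.
#' @param p_grid Baseline accuracies to evaluate (default 0.70 to 1.00).
#' @return For `utility_curve`: a data frame with `p` and `gain`.
#' @export
utility_curve <- function(report, p_grid = seq(0.70, 1.00, by = 0.01)) {
  data.frame(p = p_grid,
             gain = utility_gain(p_grid, report$recall_correct,
                                 report$recall_error))
}

#' Split plan
#'
#' 20% of the epochs are held out as the test set; the remainder is cut
#' into stratified cross-validation folds. Stratification keeps the class
#' ratio of every part within one epoch of the global ratio.
#'
#' @param test_fraction Fraction held out for testing (default 0.2).
#' @param val_fraction_of_remainder Fraction of the non-test data acting as
#'   the validation part of each fold arrangement (default 0.2, i.e. the
#'   held-out fold of 5-fold CV).
#' @param n_folds Number of CV folds (default 5).
#' @param shuffle_seed Seed for the stratified shuffle.
#' @param mode `"population_wise"` or `"subject_wise"` (bookkeeping label).
#' @return Object of class `split_plan`.
#' @export
split_plan <- function(test_fraction = 0.2, val_fraction_of_remainder = 0.2,
                       n_folds = 5, shuffle_seed = 1L,
                       mode = c("population_wise", "subject_wise")) {
  if (test_fraction <= 0 || test_fraction >= 1) stopf("test_fraction in (0,1)")
  if (n_folds < 2) stopf("need at least 2 folds")
  structure(list(test_fraction = test_fraction,
                 val_fraction_of_remainder = val_fraction_of_remainder,
                 n_folds = as.integer(n_folds),
                 shuffle_seed = as.integer(shuffle_seed),
                 mode = match.arg(mode)),
            class = "split_plan")
}

# Stratified assignment of indices to `k` groups with proportions `prop`
# (length k, sums to 1), preserving the class ratio within each group.
stratified_groups <- function(labels, prop) {
  groups <- vector("list", length(prop))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    bounds <- round(cumsum(prop) * length(idx))
    start <- 1L
    for (g in seq_along(prop)) {
      if (bounds[g] >= start) {
        groups[[g]] <- c(groups[[g]], idx[start:bounds[g]])
      }
      start <- bounds[g] + 1L
    }
  }
  lapply(groups, sort)
}

#' Stratified test/fold split
#'
#' @param epochs An [epoch_set()] containing both classes.
#' @param plan A [split_plan()].
#' @return List with `test` (indices), `folds` (list of `n_folds` index
#'   vectors partitioning the remainder) and the `plan`.
#' @export
make_split <- function(epochs, plan = split_plan()) {
  stopifnot(inherits(epochs, "epoch_set"))
  labels <- epochs$labels
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  with_seed(plan$shuffle_seed, {
    tt <- stratified_groups(labels, c(1 - plan$test_fraction,
                                      plan$test_fraction))
    rest <- tt[[1]]; test <- tt[[2]]
    folds <- stratified_groups_of(labels, rest, plan$n_folds)
    for (f in folds) {
      if (!all(c(0L, 1L) %in% labels[f])) {
        stopf("a class is absent from a fold; too few minority epochs for %d folds",
              plan$n_folds)
      }
    }
    list(test = test, folds = folds, plan = plan)
  })
}

# Stratified k-way partition of a given index subset.
stratified_groups_of <- function(labels, subset, k) {
  sub_labels <- labels[subset]
  groups <- stratified_groups(sub_labels, rep(1 / k, k))
  lapply(groups, function(g) sort(subset[g]))
}

#' Balance a training set with ARX surrogates
#'
#' Appends surrogate minority-class epochs (see [generate_surrogates()])
#' until both classes have equal counts. Only the set passed in is touched;
#' callers keep validation/test sets away from this function.
#'
#' @param train Training [epoch_set()].
#' @param seed Integer seed for the surrogate innovations.
#' @param search_space ARX orders for the surrogate models.
#' @return The balanced `epoch_set`.
#' @export
balance_training_set <- function(train, seed = NULL,
                                 search_space = arx_search_space(4, 4, 0)) {
  stopifnot(inherits(train, "epoch_set"))
  n1 <- sum(train$labels == 1L); n0 <- sum(train$labels == 0L)
  if (n1 == n0) return(train)
  minority <- if (n1 < n0) 1L else 0L
  need <- abs(n0 - n1)
  sur <- generate_surrogates(train, need, seed = seed,
                             minority_label = minority,
                             search_space = search_space)
  bind_epoch_sets(train, sur)
}

#' Concatenate two epoch sets
#' @param a,b [epoch_set()]s with identical channel/sample geometry.
#' @return The combined `epoch_set`.
#' @export
bind_epoch_sets <- function(a, b) {
  stopifnot(inherits(a, "epoch_set"), inherits(b, "epoch_set"))
  da <- dim(a$data); db <- dim(b$data)
  if (!all(da[-1] == db[-1])) stopf("epoch sets have different geometry")
  dat <- array(0, c(da[1] + db[1], da[2], da[3]))
  if (da[1]) dat[seq_len(da[1]), , ] <- a$data
  if (db[1]) dat[da[1] + seq_len(db[1]), , ] <- b$data
  pre <- NULL
  if (!is.null(a$prestim) && !is.null(b$prestim)) {
    dpa <- dim(a$prestim)
    pre <- array(0, c(da[1] + db[1], dpa[2], dpa[3]))
    if (da[1]) pre[seq_len(da[1]), , ] <- a$prestim
    if (db[1]) pre[da[1] + seq_len(db[1]), , ] <- b$prestim
  }
  epoch_set(dat, c(a$labels, b$labels), a$sampling_rate_hz, a$window_s,
            prestim = pre, channel_names = a$channel_names)
}

#' Cross-validated training with majority vote on the test set
#'
#' One model is trained per fold arrangement (training on the other folds,
#' with the held fold as validation); each of the `n_folds` models predicts
#' the test set and the final label is the class receiving the strict
#' majority of votes. The training folds are balanced with ARX surrogates
#' before training; validation and test epochs are never balanced or used
#' for fitting.
#'
#' @param trainval An [epoch_set()] (the non-test data).
#' @param folds List of index vectors into `trainval` (from [make_split()],
#'   re-indexed to `trainval`), or an integer fold count.
#' @param test Test [epoch_set()].
#' @param spec An [arch_spec()].
#' @param config A [train_config()].
#' @param balance Balance training folds with ARX surrogates (default TRUE).
#' @return List: `report` ([compute_metrics()]), `votes` (fold x test-epoch
#'   matrix), `fold_reports`, `models`.
#' @export
crossval_majority <- function(trainval, folds, test, spec,
                              config = train_config(), balance = TRUE) {
  stopifnot(inherits(trainval, "epoch_set"), inherits(test, "epoch_set"))
  if (is.numeric(folds) && length(folds) == 1L) {
    folds <- with_seed(config$seed,
                       stratified_groups(trainval$labels,
                                         rep(1 / folds, folds)))
  }
  n_folds <- length(folds)
  votes <- matrix(NA_integer_, n_folds, n_epochs(test))
  fold_reports <- vector("list", n_folds)
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr_idx <- sort(unlist(folds[-f]))
    tr <- subset_epochs(trainval, tr_idx)
    if (balance) {
      tr <- balance_training_set(tr, seed = sub_seed(config$seed, 100L + f))
    }
    model <- build_classifier(spec, dim(tr$data)[2:3],
                              seed = sub_seed(config$seed, f))
    model <- train_classifier(model, tr,
                              config_with_seed(config, sub_seed(config$seed, 200L + f)))
    pred <- predict_labels(model, test)
    votes[f, ] <- pred
    val <- subset_epochs(trainval, folds[[f]])
    fold_reports[[f]] <- compute_metrics(
      confusion_counts(val$labels, predict_labels(model, val)))
    models[[f]] <- model
  }
  final <- majority_vote(votes)
  list(report = compute_metrics(confusion_counts(test$labels, final)),
       votes = votes, predictions = final, fold_reports = fold_reports,
       models = models)
}

config_with_seed <- function(config, seed) {
  config$seed <- as.integer(seed %% 2147483647)
  config
}

#' Majority vote over fold predictions
#'
#' Strict majority of 1-votes wins; exact ties (possible only with an even
#' number of voters) break to the non-ErrP class, the conservative choice
#' for a corrector.
#'
#' @param votes fold x epoch matrix of 0/1 votes (NA rows are dropped).
#' @return Integer vector of final labels.
#' @export
majority_vote <- function(votes) {
  votes <- votes[stats::complete.cases(votes), , drop = FALSE]
  as.integer(colSums(votes == 1L) > nrow(votes) / 2)
}

#' Sequential hyperparameter search in cycles
#'
#' Cycles run in ascending order; each cycle evaluates candidates for its
#' own parameter subset (exhaustively for grids, by seeded random draws
#' when `budget` is smaller than the grid), fixes the winner into the
#' running configuration, and passes it on. The objective is the F1 score
#' (or any scalar `objective_fn`), evaluated by the caller-supplied
#' function.
#'
#' @param cycles List of cycles; each a list with `params` (named list of
#'   candidate value vectors) and optional `budget` (max evaluations).
#' @param eval_fn `function(config_list) -> scalar` objective (higher is
#'   better); receives the full named configuration.
#' @param base Starting configuration (named list).
#' @param seed Seed for random-search draws.
#' @return List with `best` (configuration), `score`, and a `trace` data
#'   frame of all evaluations.
#' @export
hyperparam_search <- function(cycles, eval_fn, base = list(), seed = 1L) {
  trace <- list()
  current <- base
  best_score <- -Inf
  for (ci in seq_along(cycles)) {
    cyc <- cycles[[ci]]
    if (!length(cyc$params)) stopf("cycle %d has an empty parameter grid", ci)
    grid <- expand.grid(cyc$params, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    budget <- cyc$budget %||% nrow(grid)
    rows <- if (budget >= nrow(grid)) seq_len(nrow(grid)) else
      with_seed(sub_seed(seed, ci), sample.int(nrow(grid), budget))
    cyc_best <- NULL; cyc_score <- -Inf
    for (r in rows) {
      cand <- current
      cand[names(grid)] <- lapply(grid[r, , drop = FALSE], identity)
      sc <- eval_fn(cand)
      trace[[length(trace) + 1L]] <-
        data.frame(cycle = ci, grid[r, , drop = FALSE], score = sc)
      if (sc > cyc_score) { cyc_score <- sc; cyc_best <- cand }
    }
    current <- cyc_best
    best_score <- cyc_score
  }
  all_cols <- unique(unlist(lapply(trace, names)))
  trace <- lapply(trace, function(d) {
    miss <- setdiff(all_cols, names(d))
    for (m in miss) d[[m]] <- NA
    d[all_cols]
  })
  list(best = current, score = best_score, trace = do.call(rbind, trace))
}

#' Standard four-cycle hyperparameter plan
#'
#' The search runs in four ordered cycles, each fixing one related group
#' before the next: (1) the optimisation itself — learning rate and batch
#' size; (2) regularising layers — pooling length and dropout placement;
#' (3) convolutional layer sizes (F1, D, F2); (4) fine regularisation —
#' dropout rate. Pass the result to [hyperparam_search()] with an
#' objective that trains and scores a model (F1 by convention).
#'
#' @param budget Optional per-cycle evaluation cap (random draws beyond a
#'   full grid).
#' @return List of cycles for [hyperparam_search()].
#' @export
default_hyperparam_cycles <- function(budget = NULL) {
  cyc <- list(
    list(params = list(learning_rate = c(3e-4, 1e-3, 3e-3),
                       batch_size = c(8L, 16L, 32L))),
    list(params = list(pool1 = c(2L, 4L), dropout_on = c(TRUE, FALSE))),
    list(params = list(F1 = c(4L, 8L), D = c(1L, 2L), F2 = c(8L, 16L))),
    list(params = list(dropout_rate = c(0.1, 0.25, 0.5))))
  if (!is.null(budget)) cyc <- lapply(cyc, function(c) { c$budget <- budget; c })
  cyc
}

# ---- single-trial stage dispatch ----------------------------------------

#' Fit / apply a single-trial estimation stage by name
#'
#' `method` is one of `"none"`, `"subspace"`, `"arx"`, `"wavelet"`. The
#' stage is fitted on training epochs only and then applied to any epoch
#' set, which keeps grand averages, noise statistics and wavelet masks free
#' of validation/test leakage.
#'
#' @param train_epochs Training [epoch_set()].
#' @param method Stage name.
#' @param options Named list of method options (`subspace_config()` fields,
#'   `arx_search_space()` bounds, wavelet `n_scales`/`scheme`).
#' @return An `st_fit` object with an `apply` method via [st_apply()].
#' @export
st_fit <- function(train_epochs, method = c("none", "subspace", "arx", "wavelet"),
                   options = list()) {
  method <- match.arg(method)
  fit <- switch(method,
    none = NULL,
    subspace = subspace_fit(train_epochs,
                            do.call(subspace_config, options)),
    arx = if (length(options)) {
      arx_fit(train_epochs, do.call(arx_search_space, options))
    } else {
      arx_fit(train_epochs)
    },
    wavelet = do.call(select_mask_from_grand_average,
                      c(list(train_epochs), options)))
  structure(list(method = method, fit = fit), class = "st_fit")
}

#' @rdname st_fit
#' @param st An `st_fit`.
#' @param epochs An [epoch_set()] to denoise.
#' @export
st_apply <- function(st, epochs) {
  stopifnot(inherits(st, "st_fit"))
  switch(st$method,
         none = epochs,
         subspace = subspace_apply(st$fit, epochs),
         arx = arx_apply(st$fit, epochs),
         wavelet = wavelet_apply(st$fit, epochs))
}

# ---- full experiment ------------------------------------------------------

#' Default experiment configuration
#'
#' @param st_method Single-trial stage: none/subspace/arx/wavelet.
#' @param classifier Classifier family: eegnet/lcnn/siamese.
#' @param mode population_wise or subject_wise (label only; callers loop
#'   subjects for subject-wise analyses).
#' @param seed Master seed: drives the split, the balancing surrogates and
#'   the network training.
#' @param st_options,spec,train,plan Stage options, [arch_spec()],
#'   [train_config()], [split_plan()].
#' @return Named list, the full experiment configuration.
#' @export
experiment_config <- function(st_method = "none", classifier = "eegnet",
                              mode = "population_wise", seed = 1L,
                              st_options = list(),
                              spec = NULL, train = NULL, plan = NULL) {
  list(st_method = st_method, classifier = classifier, mode = mode,
       seed = as.integer(seed), st_options = st_options,
       spec = spec %||% arch_spec(classifier),
       train = train %||% train_config(seed = seed),
       plan = plan %||% split_plan(shuffle_seed = seed, mode = mode))
}

#' Run a full two-stage detection experiment
#'
#' Pipeline: stratified split, single-trial stage fitted on the non-test
#' data and applied everywhere, ARX balancing of each training fold,
#' cross-validated training, majority vote on the test set, metrics and
#' the utility-gain curve.
#'
#' @param epochs A preprocessed [epoch_set()].
#' @param config An [experiment_config()].
#' @return List: `config`, `report`, `utility`, `split`, `predictions`,
#'   `fold_reports`.
#' @export
run_experiment <- function(epochs, config = experiment_config()) {
  stopifnot(inherits(epochs, "epoch_set"))
  split <- make_split(epochs, config$plan)
  trainval <- subset_epochs(epochs, sort(unlist(split$folds)))
  test <- subset_epochs(epochs, split$test)
  # re-index folds into trainval
  all_idx <- sort(unlist(split$folds))
  folds <- lapply(split$folds, function(f) match(f, all_idx))

  st <- st_fit(trainval, config$st_method, config$st_options)
  trainval_st <- st_apply(st, trainval)
  test_st <- st_apply(st, test)

  cv <- crossval_majority(trainval_st, folds, test_st, config$spec,
                          config$train)
  list(config = config, report = cv$report,
       utility = utility_curve(cv$report),
       split = split, predictions = cv$predictions,
       fold_reports = cv$fold_reports)
}
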
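#' Stratified k-fold assignment
#'
#' Shuffles indices within each outcome class (consuming the current RNG
#' stream) and deals them round-robin into `k` folds, so every fold holds
#' both classes whenever each class has at least `k` members.
#'
#' @param outcome Binary outcome vector.
#' @param k Number of folds.
#' @return Integer fold labels in `1:k`.
#' @export
stratified_folds <- function(outcome, k = 5) {
  outcome <- as.integer(outcome)
  if (min(table(outcome)) < k) {
    stop("cannot stratify: a class has fewer than k members", call. = FALSE)
  }
  fold <- integer(length(outcome))
  for (cls in unique(outcome)) {
    idx <- sample(which(outcome == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_predict <- function(ft, features, train, test, model, rf_ntree,
                        rf_nodesize_grid) {
  xtr <- ft[train, features, drop = FALSE]
  xte <- ft[test, features, drop = FALSE]
  ytr <- factor(ft$outcome[train], levels = c(0, 1))
  if (model == "logistic") {
    d <- cbind(xtr, .y = as.integer(as.character(ytr)))
    fit <- suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
    p <- stats::predict(fit, newdata = xte, type = "response")
    as.integer(p > 0.5)
  } else {
    # small nodesize grid tuned on the training fold's out-of-bag error only
    best <- rf_nodesize_grid[1]
    if (length(rf_nodesize_grid) > 1) {
      oob <- vapply(rf_nodesize_grid, function(ns) {
        f <- randomForest::randomForest(x = xtr, y = ytr, ntree = rf_ntree,
                                        nodesize = ns)
        f$err.rate[rf_ntree, "OOB"]
      }, numeric(1))
      best <- rf_nodesize_grid[which.min(oob)]
    }
    fit <- randomForest::randomForest(x = xtr, y = ytr, ntree = rf_ntree,
                                      nodesize = best)
    as.integer(as.character(stats::predict(fit, newdata = xte)))
  }
}

cv_correct <- function(ft, features, model, folds, rf_ntree, rf_nodesize_grid) {
  correct <- logical(nrow(ft))
  for (f in sort(unique(folds))) {
    test <- folds == f
    pred <- fit_predict(ft, features, !test, test, model, rf_ntree,
                        rf_nodesize_grid)
    correct[test] <- pred == ft$outcome[test]
  }
  correct
}

#' Recursive feature elimination under a random forest
#'
#' Starting from the full candidate set, repeatedly measures stratified
#' cross-validated accuracy of a random forest on the current subset, then
#' drops the feature with the lowest importance (mean decrease in Gini
#' impurity, from a forest fit on all rows; ties drop the earliest
#' column).  All randomness is consumed from the RNG stream seeded by
#' `seed`, so the run is reproducible.
#'
#' @param ft Feature table with `outcome`.
#' @param features Candidate features (default all available).
#' @param k_folds Cross-validation folds.
#' @param ntree Trees per forest.
#' @param seed Integer seed.
#' @return A list with `curve` (data.frame `size`, `accuracy`, and the
#'   retained `features` at that size, comma-joined) and
#'   `elimination_order` (first-dropped first; the survivor is last).
#' @export
rfe_rank <- function(ft, features = intersect(feature_names(), names(ft)),
                     k_folds = 5, ntree = 300, seed = 1) {
  ft <- feature_matrix(ft, features)
  set.seed(as.integer(seed))
  remaining <- features
  eliminated <- character(0)
  curve <- list()
  while (length(remaining) >= 1L) {
    folds <- stratified_folds(ft$outcome, k_folds)
    acc <- mean(cv_correct(ft, remaining, "rf", folds, ntree, 5))
    curve[[length(curve) + 1L]] <- data.frame(
      size = length(remaining), accuracy = acc,
      features = paste(remaining, collapse = ","), stringsAsFactors = FALSE)
    if (length(remaining) == 1L) break
    fit <- randomForest::randomForest(
      x = ft[, remaining, drop = FALSE],
      y = factor(ft$outcome, levels = c(0, 1)), ntree = ntree)
    imp <- fit$importance[, "MeanDecreaseGini"]
    drop <- remaining[which.min(imp)]
    eliminated <- c(eliminated, drop)
    remaining <- setdiff(remaining, drop)
  }
  list(curve = do.call(rbind, curve),
       elimination_order = c(eliminated, remaining))
}

#' Cross-validated comparison of linear and ensemble classifiers
#'
#' For every (feature set, model family) cell, runs repeated stratified
#' k-fold cross-validation and reports the accuracy mean and SD over
#' repeats-by-folds.  Pairwise differences between cells are tested by a
#' paired sign-flip permutation over the per-prediction correctness
#' indicators (each of the `n * repeats` paired indicators has its
#' difference sign flipped with probability 1/2), a procedure that needs
#' no distributional assumptions.  All randomness is seeded.
#'
#' @param ft Feature table with `outcome`.
#' @param feature_sets Named list of character vectors (default the three
#'   sets uGMI, HbA1c, and both).
#' @param models Model families to fit (`"logistic"`, `"rf"`).
#' @param k_folds,repeats Cross-validation layout (default 5-fold, 4
#'   repeats).
#' @param n_perm Permutations for the paired test (default 10000).
#' @param seed Integer seed.
#' @param rf_ntree Trees per forest.
#' @param rf_nodesize_grid Nodesize grid tuned inside training folds by
#'   out-of-bag error.
#' @return An object of class `model_comparison`: list with `summary`
#'   (data.frame `cell`, `model`, `features`, `accuracy_mean`,
#'   `accuracy_sd`), `pairwise` (data.frame `cell_a`, `cell_b`, `diff`,
#'   `p_value`), and the resolved settings.
#' @export
model_comparison <- function(ft,
                             feature_sets = list(ugmi = "ugmi",
                                                 hba1c = "hba1c",
                                                 both = c("ugmi", "hba1c")),
                             models = c("logistic", "rf"),
                             k_folds = 5, repeats = 4, n_perm = 10000,
                             seed = 1, rf_ntree = 300,
                             rf_nodesize_grid = c(1, 5, 10)) {
  all_feats <- unique(unlist(feature_sets))
  ft <- feature_matrix(ft, all_feats)
  set.seed(as.integer(seed))
  cells <- expand.grid(model = models, set = names(feature_sets),
                       stringsAsFactors = FALSE)
  cell_names <- paste(cells$set, cells$model, sep = ".")
  correct <- matrix(NA, nrow(ft) * repeats, nrow(cells),
                    dimnames = list(NULL, cell_names))
  fold_acc <- matrix(NA_real_, k_folds * repeats, nrow(cells),
                     dimnames = list(NULL, cell_names))
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(ft$outcome, k_folds)
    for (j in seq_len(nrow(cells))) {
      cc <- cv_correct(ft, feature_sets[[cells$set[j]]], cells$model[j],
                       folds, rf_ntree, rf_nodesize_grid)
      correct[(r - 1) * nrow(ft) + seq_len(nrow(ft)), j] <- cc
      for (f in seq_len(k_folds)) {
        fold_acc[(r - 1) * k_folds + f, j] <- mean(cc[folds == f])
      }
    }
  }
  summary <- data.frame(cell = cell_names, model = cells$model,
                        features = vapply(cells$set, function(s)
                          paste(feature_sets[[s]], collapse = ","), character(1)),
                        accuracy_mean = colMeans(fold_acc),
                        accuracy_sd = apply(fold_acc, 2, stats::sd),
                        row.names = NULL, stringsAsFactors = FALSE)
  pairs <- if (nrow(cells) >= 2) utils::combn(seq_len(nrow(cells)), 2) else
    matrix(integer(0), nrow = 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    d <- correct[, a] - correct[, b]
    d_obs <- mean(d)
    flips <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                    nrow = length(d))
    d_perm <- colMeans(flips * d)
    data.frame(cell_a = cell_names[a], cell_b = cell_names[b], diff = d_obs,
               p_value = (sum(abs(d_perm) >= abs(d_obs)) + 1) / (n_perm + 1),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, pairwise = pairwise,
                 settings = list(k_folds = k_folds, repeats = repeats,
                                 n_perm = n_perm, seed = seed,
                                 rf_ntree = rf_ntree,
                                 rf_nodesize_grid = rf_nodesize_grid)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
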
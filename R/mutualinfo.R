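#' Equal-frequency (quantile) binning
#'
#' Assigns each value to one of `k` rank-ordered bins whose sizes differ
#' by at most one (larger bins first).  Ties are broken by stable order of
#' (value, row index), so the assignment is deterministic.
#'
#' @param values Numeric vector, `length(values) >= k`.
#' @param k Number of bins, at least 2.
#' @return Integer vector of bin labels in `1:k` (all 1 with a warning if
#'   the input is constant).
#' @export
#' @examples
#' table(quantile_bin(1:10, 5))
quantile_bin <- function(values, k = 5) {
  n <- length(values)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("need at least k observations (n = ", n, ", k = ", k, ")",
                  call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (length(unique(values)) == 1L) {
    warning("constant input: all observations assigned to a single bin")
    return(rep(1L, n))
  }
  r <- rank(values, ties.method = "first")
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  rep(seq_len(k), sizes)[r]
}

#' Mutual information of two discrete vectors (nats)
#'
#' Plug-in estimate from the empirical contingency table:
#' `MI = sum p(x,y) log[ p(x,y) / (p(x) p(y)) ]`, natural logarithm.
#' Non-negative; zero exactly when the empirical table factorizes.
#'
#' @param x,y Discrete vectors (factors, integers, ...) of equal length.
#' @return Mutual information in nats.
#' @export
#' @examples
#' mutual_info(rep(0:1, each = 50), rep(0:1, each = 50))  # ln 2
mutual_info <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) == 0L) stop("at least one observation required", call. = FALSE)
  tab <- table(x, y)
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' Shannon entropy of a discrete vector (nats)
#'
#' @param x Discrete vector.
#' @return Entropy in nats.
#' @export
entropy <- function(x) {
  p <- table(x) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

feature_matrix <- function(ft, features) {
  stopifnot(is.data.frame(ft), "outcome" %in% names(ft))
  missing <- setdiff(features, names(ft))
  if (length(missing)) {
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(ft[features]) || anyNA(ft$outcome)) {
    stop("feature table contains missing values", call. = FALSE)
  }
  if (!all(ft$outcome %in% c(0, 1))) {
    stop("outcome must be binary 0/1", call. = FALSE)
  }
  ft
}

bin_features <- function(ft, features, k_bins) {
  sapply(features, function(f) quantile_bin(ft[[f]], k_bins))
}

#' Mutual information ranking of candidate features
#'
#' Each continuous feature is quantile-binned ([quantile_bin()]) and scored
#' by its mutual information with the binary outcome.  The result is
#' sorted by descending score; ties keep the canonical column order, so
#' the ranking is deterministic.
#'
#' @param ft Feature table: a data.frame with an `outcome` column and the
#'   candidate features.
#' @param features Feature columns to rank (default [feature_names()],
#'   intersected with the available columns).
#' @param k_bins Bins for discretization (default 5).
#' @return A data.frame `feature`, `mis` (nats), ordered by rank.
#' @export
mis_ranking <- function(ft, features = intersect(feature_names(), names(ft)),
                        k_bins = 5) {
  ft <- feature_matrix(ft, features)
  binned <- bin_features(ft, features, k_bins)
  mis <- vapply(features, function(f) mutual_info(binned[, f], ft$outcome),
                numeric(1))
  ord <- order(-mis, seq_along(mis))
  data.frame(feature = features[ord], mis = unname(mis[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Minimum-redundancy maximum-relevance (mRMR) feature ranking
#'
#' Greedy difference-form mRMR on quantile-binned features: the first pick
#' maximizes relevance `MI(f; outcome)`; each subsequent candidate is
#' scored `MI(f; outcome) - mean over selected s of MI(f; s)`, and the
#' maximizer is selected.  A positive score means a feature carries more
#' outcome-relevant information than it shares with the features already
#' selected; a negative score marks it as predominantly redundant.  Ties
#' keep the canonical column order.
#'
#' @inheritParams mis_ranking
#' @return A data.frame `step`, `feature`, `score` (nats; the first row's
#'   score is its relevance), in selection order.
#' @export
mrmr_rank <- function(ft, features = intersect(feature_names(), names(ft)),
                      k_bins = 5) {
  ft <- feature_matrix(ft, features)
  binned <- bin_features(ft, features, k_bins)
  rel <- vapply(features, function(f) mutual_info(binned[, f], ft$outcome),
                numeric(1))
  p <- length(features)
  mi_ff <- matrix(NA_real_, p, p, dimnames = list(features, features))
  selected <- character(0)
  scores <- numeric(0)
  remaining <- features
  while (length(remaining)) {
    cand_score <- vapply(remaining, function(f) {
      if (!length(selected)) return(rel[[f]])
      red <- vapply(selected, function(s) {
        if (is.na(mi_ff[f, s])) {
          mi_ff[f, s] <<- mi_ff[s, f] <<- mutual_info(binned[, f], binned[, s])
        }
        mi_ff[f, s]
      }, numeric(1))
      rel[[f]] - mean(red)
    }, numeric(1))
    best <- remaining[which.max(cand_score)]  # which.max: first maximum wins
    selected <- c(selected, best)
    scores <- c(scores, cand_score[[best]])
    remaining <- setdiff(remaining, best)
  }
  data.frame(step = seq_along(selected), feature = selected,
             score = scores, row.names = NULL, stringsAsFactors = FALSE)
}
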
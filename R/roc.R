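#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique scores (classifying positive when
#' `score > t`) and integrates the resulting curve by the trapezoid rule.
#' With ties this equals the rank-sum (concordance) statistic counting
#' tied case-control pairs as 1/2.  Higher scores are taken to indicate
#' the positive class; set `direction = "auto"` to flip the sign when the
#' point-biserial correlation with the labels is negative (appropriate
#' for protective metrics such as time in range).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @param direction `">"` (default: higher score = positive) or `"auto"`.
#' @return An object of class `roc_result`: list with `curve` (data.frame
#'   `threshold`, `tpr`, `fpr`), `auc`, `flipped` (logical: whether auto
#'   direction negated the scores).
#' @export
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc  # 1
roc_auc <- function(scores, labels, direction = c(">", "auto")) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed", call. = FALSE)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("labels must contain both classes (0 and 1)", call. = FALSE)
  }
  flipped <- FALSE
  if (direction == "auto" && stats::cor(scores, labels) < 0) {
    scores <- -scores
    flipped <- TRUE
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr),
                 auc = auc, flipped = flipped),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d thresholds%s)\n", x$auc,
              nrow(x$curve), if (x$flipped) ", direction flipped" else ""))
  invisible(x)
}

#' AUC for every candidate feature
#'
#' Convenience wrapper applying [roc_auc()] with automatic direction to
#' each feature column, reporting which features were sign-flipped.
#'
#' @inheritParams mis_ranking
#' @return A data.frame `feature`, `auc`, `flipped`, sorted by descending
#'   AUC (ties keep column order).
#' @export
auc_ranking <- function(ft, features = intersect(feature_names(), names(ft))) {
  ft <- feature_matrix(ft, features)
  res <- lapply(features, function(f) roc_auc(ft[[f]], ft$outcome, "auto"))
  auc <- vapply(res, `[[`, numeric(1), "auc")
  ord <- order(-auc, seq_along(auc))
  data.frame(feature = features[ord], auc = auc[ord],
             flipped = vapply(res, `[[`, logical(1), "flipped")[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cumulative-rate curves: accuracy, TPR and FPR versus threshold
#'
#' For each threshold `t`, classifies positive when `score > t` and
#' reports the overall accuracy, the true positive rate (sensitivity) and
#' the false positive rate.  The default grid is the sorted unique scores
#' extended one step below the minimum, so the curves span the whole range
#' from "everyone positive" (TPR = FPR = 1, accuracy = prevalence) to
#' "everyone negative" (TPR = FPR = 0, accuracy = 1 - prevalence).  At
#' every threshold `accuracy = prevalence * TPR + (1 - prevalence) * (1 - FPR)`.
#'
#' @inheritParams roc_auc
#' @param thresholds Optional explicit threshold grid.
#' @return An object of class `cumulative_rate_curve`: a data.frame
#'   `threshold`, `accuracy`, `tpr`, `fpr` with attribute `prevalence`.
#' @export
cumulative_rate_curves <- function(scores, labels, thresholds = NULL) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("labels must contain both classes (0 and 1)", call. = FALSE)
  }
  if (is.null(thresholds)) {
    u <- sort(unique(scores))
    thresholds <- c(u[1] - 1, u)
  }
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  prev <- mean(labels)
  tpr <- vapply(thresholds, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(neg > t), numeric(1))
  acc <- vapply(thresholds, function(t) mean((scores > t) == labels), numeric(1))
  structure(data.frame(threshold = thresholds, accuracy = acc,
                       tpr = tpr, fpr = fpr),
            prevalence = prev, class = c("cumulative_rate_curve", "data.frame"))
}
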
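#' Risk-rate increase per 1% NGSP of a glycemic index
#'
#' The change in outcome rate between two quantile bins divided by the
#' change in their mean metric expressed in % NGSP, rounded to the nearest
#' integer.  Following the reporting convention, the NGSP means are first
#' rounded to one decimal place.
#'
#' @param rate_lo,rate_hi Outcome rates (%) in the lower and upper bins.
#' @param ngsp_lo,ngsp_hi Bin mean metric in % NGSP (1 d.p.).
#' @return Integer rate increase in percentage points of risk per 1% NGSP
#'   (NA with a warning when the NGSP means coincide).
#' @export
#' @examples
#' rate_increase_per_pct(18, 68, 6.4, 8.2)  # 28
#' rate_increase_per_pct(18, 56, 6.4, 8.0)  # 24
rate_increase_per_pct <- function(rate_lo, rate_hi, ngsp_lo, ngsp_hi) {
  d <- ngsp_hi - ngsp_lo
  if (d == 0) {
    warning("bin NGSP means coincide; rate increase undefined")
    return(NA_real_)
  }
  round((rate_hi - rate_lo) / d)
}

two_bin_test <- function(k1, n1, k2, n2, test) {
  if (test == "fisher") {
    stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2))$p.value
  } else {
    suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$p.value)
  }
}

#' Quantile-bin risk table for a glycemic metric
#'
#' Groups participants into `k` equal-sized bins of the metric (IFCC
#' scale), reporting per bin the size, the mean metric in mmol/mol and in
#' % NGSP (rounded to 1 d.p.), and the outcome rate in percent.  Adds the
#' pairwise comparisons used for quintiles (1st vs 4th and 2nd vs 3rd bin
#' outcome rates) and the rate increase per 1% NGSP between the 1st and
#' 4th bins ([rate_increase_per_pct()]).
#'
#' @param metric Metric values on the IFCC scale (mmol/mol).
#' @param outcome Binary outcome (0/1).
#' @param k Number of bins (default 5).
#' @param test `"fisher"` (two-sided Fisher exact, default) or `"ztest"`
#'   (two-proportion z-test without continuity correction).
#' @param cc A [conversion_constants()] object.
#' @return An object of class `risk_table`: list with `table` (data.frame
#'   `bin`, `n`, `mean_ifcc`, `mean_ngsp`, `rate_pct`), `p_q1_q4`,
#'   `p_q2_q3`, `rate_increase_per_pct`, `test`, `prevalence_pct`.
#' @export
quintile_risk_table <- function(metric, outcome, k = 5,
                                test = c("fisher", "ztest"),
                                cc = conversion_constants()) {
  test <- match.arg(test)
  stopifnot(length(metric) == length(outcome))
  outcome <- as.integer(outcome)
  if (length(metric) < k) stop("need at least k observations", call. = FALSE)
  bins <- quantile_bin(metric, k)
  tab <- do.call(rbind, lapply(seq_len(k), function(b) {
    idx <- bins == b
    mi <- mean(metric[idx])
    data.frame(bin = b, n = sum(idx), mean_ifcc = mi,
               mean_ngsp = round(ifcc_to_ngsp(mi, cc), 1),
               rate_pct = 100 * mean(outcome[idx]))
  }))
  count <- function(b) c(sum(outcome[bins == b]), sum(bins == b))
  p14 <- p23 <- NA_real_
  if (k >= 4) {
    a <- count(1); b <- count(4)
    p14 <- two_bin_test(a[1], a[2], b[1], b[2], test)
    a <- count(2); b <- count(3)
    p23 <- two_bin_test(a[1], a[2], b[1], b[2], test)
  }
  ri <- if (k >= 4) {
    rate_increase_per_pct(tab$rate_pct[1], tab$rate_pct[4],
                          tab$mean_ngsp[1], tab$mean_ngsp[4])
  } else NA_real_
  structure(list(table = tab, p_q1_q4 = p14, p_q2_q3 = p23,
                 rate_increase_per_pct = ri, test = test,
                 prevalence_pct = 100 * mean(outcome)),
            class = "risk_table")
}

#' @export
print.risk_table <- function(x, ...) {
  cat("<risk_table> (", x$test, " test)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat(sprintf("p(1st vs 4th) = %.3g   p(2nd vs 3rd) = %.3g\n", x$p_q1_q4, x$p_q2_q3))
  cat("rate increase per 1% NGSP:", x$rate_increase_per_pct, "\n")
  invisible(x)
}

tree_node <- function(variable, threshold, idx, outcome, path_positive, depth,
                      vars, thrs, ft) {
  n <- sum(idx)
  node <- list(variable = variable, threshold = threshold, n = n,
               n_control = sum(outcome[idx] == 0L), n_case = sum(outcome[idx] == 1L),
               majority = if (n == 0) NA_integer_ else
                 as.integer(sum(outcome[idx] == 1L) >= sum(outcome[idx] == 0L)),
               predict_positive = path_positive)
  if (depth <= length(vars)) {
    v <- vars[depth]; t <- thrs[depth]
    gt <- idx & ft[[v]] > t
    le <- idx & !(ft[[v]] > t)
    node$variable <- v; node$threshold <- t
    node$children <- list(
      le = tree_node(NA, NA, le, outcome, FALSE, depth + 1, vars, thrs, ft),
      gt = tree_node(NA, NA, gt, outcome, path_positive, depth + 1, vars, thrs, ft))
  }
  node
}

collect_leaves <- function(node) {
  if (is.null(node$children)) return(list(node))
  c(collect_leaves(node$children$le), collect_leaves(node$children$gt))
}

#' Fixed-threshold decision tree report
#'
#' Builds a decision tree at pre-specified clinical thresholds (no
#' threshold learning).  With one variable this is a single splitting
#' node; with two, the root splits on the first variable and both children
#' split on the second.  The induced classifier predicts the positive
#' class for a participant whose value exceeds the threshold at every
#' level (e.g. `ugmi > 53` and `hba1c > 53` in the two-layer tree);
#' per-node totals, class counts, and leaf majority labels are reported
#' alongside the classifier's sensitivity, specificity and accuracy.
#'
#' @param ft Feature table (data.frame with `outcome` and the split
#'   variables).
#' @param variables Character vector of one or two split variables, root
#'   first.
#' @param thresholds Numeric thresholds, parallel to `variables` (IFCC
#'   mmol/mol for glycemic indices; default 53, the 7.0% NGSP target).
#' @return An object of class `tree_report`: list with `root` (nested node
#'   structure), `variables`, `thresholds`, `sensitivity_pct`,
#'   `specificity_pct`, `accuracy_pct`, `n`.
#' @export
#' @examples
#' ft <- data.frame(hba1c = c(50, 45, 55, 60), outcome = c(0, 0, 1, 1))
#' threshold_tree(ft, "hba1c", 53)$sensitivity_pct  # 100
threshold_tree <- function(ft, variables, thresholds = rep(53, length(variables))) {
  stopifnot(is.data.frame(ft), "outcome" %in% names(ft),
            length(variables) %in% 1:2, length(thresholds) == length(variables))
  missing <- setdiff(variables, names(ft))
  if (length(missing)) {
    stop("unknown split variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  outcome <- as.integer(ft$outcome)
  n <- nrow(ft)
  root <- tree_node(NA, NA, rep(TRUE, n), outcome, TRUE, 1,
                    variables, thresholds, ft)
  leaves <- collect_leaves(root)
  tp <- sum(vapply(leaves, function(l) if (l$predict_positive) l$n_case else 0L, numeric(1)))
  fp <- sum(vapply(leaves, function(l) if (l$predict_positive) l$n_control else 0L, numeric(1)))
  fn <- sum(vapply(leaves, function(l) if (!l$predict_positive) l$n_case else 0L, numeric(1)))
  tn <- sum(vapply(leaves, function(l) if (!l$predict_positive) l$n_control else 0L, numeric(1)))
  structure(list(root = root, variables = variables, thresholds = thresholds,
                 sensitivity_pct = 100 * tp / (tp + fn),
                 specificity_pct = 100 * tn / (tn + fp),
                 accuracy_pct = 100 * (tp + tn) / n, n = n),
            class = "tree_report")
}

#' @export
print.tree_report <- function(x, ...) {
  cat("<tree_report>", paste(sprintf("%s > %g", x$variables, x$thresholds),
                             collapse = " then "), "\n")
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  (n = %d)\n",
              x$sensitivity_pct, x$specificity_pct, x$accuracy_pct, x$n))
  invisible(x)
}
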
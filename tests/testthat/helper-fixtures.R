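# Shared fixtures and independent oracles, built in code at test time.

# Build a trace from raw values at a fixed interval (minutes).
make_trace <- function(values, start = "2020-01-01", interval_min = 5,
                       id = "T1") {
  t0 <- as.POSIXct(as.Date(start), tz = "UTC")
  cgm_trace(id, t0 + (seq_along(values) - 1) * interval_min * 60, values,
            nominal_interval = interval_min, quiet = TRUE)
}

# Small, fast cohort configuration (hourly sampling) for pipeline tests.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_cases = 6, n_controls = 8,
                                 interval_min = 60, visits_min = 2,
                                 visits_max = 3),
                            list(...))
  do.call(simulation_config, args)
}

# Independent mutual-information oracle: explicit double loop over a
# contingency table (counts matrix), natural log.
mi_oracle <- function(tab) {
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  acc <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        pij <- tab[i, j] / n
        acc <- acc + pij * log(pij / ((rs[i] / n) * (cs[j] / n)))
      }
    }
  }
  acc
}

# Expand a counts table into paired label vectors.
table_to_vectors <- function(tab) {
  x <- integer(0); y <- integer(0)
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      x <- c(x, rep(i, tab[i, j])); y <- c(y, rep(j, tab[i, j]))
    }
  }
  list(x = x, y = y)
}

# Tie-corrected rank-sum (concordance) AUC oracle: mean over all
# case-control pairs of 1 (case higher), 1/2 (tie), 0 (lower).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
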
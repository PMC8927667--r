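# Tiny hand-built panel/matrix fixtures used across test files.

tiny_panel <- function(n_endo = 3, n_neg = 2, n_pos = 4, n_hk = 3) {
  probe_annotation(
    probe_id = c(sprintf("G%d", seq_len(n_endo)),
                 sprintf("N%d", seq_len(n_neg)),
                 sprintf("P%d", seq_len(n_pos)),
                 sprintf("H%d", seq_len(n_hk))),
    probe_class = rep(c("endogenous", "negative", "positive", "housekeeping"),
                      c(n_endo, n_neg, n_pos, n_hk)),
    nominal_concentration = c(rep(NA, n_endo + n_neg),
                              128 / 4^(seq_len(n_pos) - 1), rep(NA, n_hk)),
    reference_tier = c(rep("none", n_endo + n_neg + n_pos),
                       rep(c("high", "medium", "low"), length.out = n_hk))
  )
}

tiny_matrix <- function(counts, panel = NULL, ...) {
  if (is.null(panel)) panel <- tiny_panel(...)
  count_matrix(counts, panel)
}

# brute-force AUC: explicit loop over all (positive, negative) pairs,
# ties counting one half -- independent of the rank-based implementation
auc_bruteforce <- function(marker, labels) {
  labels <- as.logical(labels)
  ps <- marker[labels]; ns <- marker[!labels]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# mean silhouette width for a 1-d score split into two known clusters
silhouette_1d <- function(x, cluster) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- x[cluster == cluster[i]]
    oth <- x[cluster != cluster[i]]
    a <- if (length(own) > 1) sum(abs(x[i] - own)) / (length(own) - 1) else 0
    b <- mean(abs(x[i] - oth))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
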
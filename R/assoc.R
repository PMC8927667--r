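#' Normality-gated choice between Welch t and Wilcoxon
#'
#' Shapiro-Wilk is applied to each group; the parametric branch (Welch
#' unequal-variance t) is chosen only when both groups pass at `alpha_norm`,
#' else the non-parametric Wilcoxon rank-sum branch. Groups too small for
#' Shapiro-Wilk (n < 3) or constant groups fall back to Wilcoxon with a
#' note.
#'
#' @param group_a,group_b numeric vectors.
#' @param alpha_norm normality significance level (default 0.05).
#' @return list: `test` (`"welch_t"` or `"wilcoxon"`), `note` (character or
#'   NULL), `p_norm_a`, `p_norm_b`.
#' @export
gate_test <- function(group_a, group_b, alpha_norm = 0.05) {
  pn <- function(x) {
    if (length(x) < 3) return(NA_real_)
    if (stats::var(x) == 0) return(0)  # degenerate: clearly non-Gaussian fit
    stats::shapiro.test(x)$p.value
  }
  pa <- pn(group_a); pb <- pn(group_b)
  if (is.na(pa) || is.na(pb)) {
    return(list(test = "wilcoxon",
                note = "group below Shapiro-Wilk minimum (n < 3); normality untestable",
                p_norm_a = pa, p_norm_b = pb))
  }
  test <- if (pa > alpha_norm && pb > alpha_norm) "welch_t" else "wilcoxon"
  list(test = test, note = NULL, p_norm_a = pa, p_norm_b = pb)
}

#' Signed fold change between group locations
#'
#' `-log2(location(A) / location(B))` with location = mean on the parametric
#' branch, median on the non-parametric branch, after a +1 pseudocount. With
#' A = ongoing response and B = resistant (the default orientation), genes
#' higher in resistant patients get positive values.
#'
#' @param group_a,group_b numeric vectors (counts).
#' @param parametric logical: mean (TRUE) or median (FALSE) location.
#' @return signed numeric fold change.
#' @export
fold_change <- function(group_a, group_b, parametric = TRUE) {
  loc <- if (parametric) mean else stats::median
  la <- loc(group_a + 1); lb <- loc(group_b + 1)
  if (la <= 0 || lb <= 0) stop("non-positive location after pseudocount")
  -log2(la / lb)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; input order preserved.
#'
#' @param p numeric p-values in `[0, 1]` (NA allowed, passed through).
#' @return q-values in input order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pair-counting AUC (Mann-Whitney identity)
#'
#' Fraction of (positive, negative) score pairs ranked concordantly, ties
#' counting one half.
#'
#' @param marker numeric scores.
#' @param labels binary labels (logical or 0/1); 1/TRUE = positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(marker, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(marker)  # midranks handle ties = 1/2 pair weight
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC with bootstrap-validated AUC and Youden operating point
#'
#' AUC by the Mann-Whitney pair-counting identity; percentile bootstrap
#' confidence interval over class-stratified resamples (so no resample is
#' ever one-class); operating point maximizing Youden's J
#' (sensitivity + specificity - 1), ties broken toward the lower cutpoint.
#' Deterministic under a fixed seed.
#'
#' @param marker numeric scores (higher = more positive-like).
#' @param labels binary labels; 1/TRUE = positive class.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return list: auc, ci_low, ci_high, cutpoint, sensitivity, specificity,
#'   youden, n_boot.
#' @export
roc_bootstrap <- function(marker, labels, n_boot = 1000, seed = 1,
                          conf = 0.95) {
  labels <- as.logical(labels)
  if (length(marker) != length(labels)) stop("length mismatch")
  pos <- which(labels); neg <- which(!labels)
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  if (n_boot < 1) stop("n_boot must be >= 1")
  auc <- auc_mann_whitney(marker, labels)
  set.seed(seed)
  boot_auc <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    auc_mann_whitney(marker[i], labels[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot_auc, c(a, 1 - a), type = 7))
  cuts <- sort(unique(marker))
  # candidate cutpoints: predict positive when marker >= cut
  stats_at <- vapply(cuts, function(ct) {
    sens <- mean(marker[pos] >= ct)
    spec <- mean(marker[neg] < ct)
    c(sens, spec)
  }, numeric(2))
  j <- stats_at[1, ] + stats_at[2, ] - 1
  best <- which.max(j)  # which.max takes the first (lowest) maximizer
  list(auc = auc, ci_low = min(ci[1], auc), ci_high = max(ci[2], auc),
       cutpoint = cuts[best], sensitivity = stats_at[1, best],
       specificity = stats_at[2, best], youden = j[best], n_boot = n_boot)
}

#' Contingency-table association test
#'
#' 2x2 tables get Fisher's exact test (two-sided, exact hypergeometric
#' enumeration); larger tables get Pearson's chi-squared with
#' (r-1)(c-1) degrees of freedom (no continuity correction).
#'
#' @param tab non-negative integer matrix of counts.
#' @return list: method, p_value, statistic (chi-squared only).
#' @export
contingency_tests <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab))) {
    stop("contingency table must hold non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in contingency table")
  }
  if (all(dim(tab) == c(2, 2))) {
    ft <- stats::fisher.test(tab)
    list(method = "fisher_exact", p_value = ft$p.value, statistic = NA_real_)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "chi_squared", p_value = ct$p.value,
         statistic = unname(ct$statistic))
  }
}

#' Correlation with significance test
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return list: estimate, p_value, method.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value, method = method)
}

#' Normality-gated multi-group location test
#'
#' Utility wrapper extending the two-group gate to ordinal variables with
#' more than two groups: one-way ANOVA when every group passes
#' Shapiro-Wilk at `alpha_norm`, Kruskal-Wallis otherwise.
#'
#' @param values numeric vector.
#' @param groups factor/character of group membership (>= 2 levels).
#' @param alpha_norm normality gate level (default 0.05).
#' @return list: test (`"anova"` or `"kruskal_wallis"`), p_value.
#' @export
group_test <- function(values, groups, alpha_norm = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  norm_ok <- vapply(split(values, groups), function(x) {
    length(x) >= 3 && stats::var(x) > 0 &&
      stats::shapiro.test(x)$p.value > alpha_norm
  }, logical(1))
  if (all(norm_ok)) {
    p <- summary(stats::aov(values ~ groups))[[1]][["Pr(>F)"]][1]
    list(test = "anova", p_value = p)
  } else {
    list(test = "kruskal_wallis",
         p_value = stats::kruskal.test(values, groups)$p.value)
  }
}

#' Gene-wise differential-expression scan against the therapy outcome
#'
#' Per gene: the normality-gated two-group test ([gate_test()]), the signed
#' fold change on the matching location (mean for the parametric branch,
#' median otherwise), optional bootstrap ROC, and BH-FDR adjustment across
#' all genes. Orientation: group A = ongoing response, group B = resistant,
#' so positive fold changes mean higher expression in resistant patients.
#'
#' @param expr numeric matrix samples x genes (normalized counts).
#' @param outcome per-sample labels, `"resistant"` / `"ongoing_response"`
#'   (NA dropped with a count).
#' @param alpha_norm Shapiro-Wilk gate level (default 0.05).
#' @param roc logical; also compute bootstrap ROC per gene (default TRUE).
#' @param n_boot bootstrap iterations for the ROC (default 1000).
#' @param seed bootstrap seed.
#' @return data.frame: gene, test_used, p_value, q_value, log2fc, auc,
#'   auc_ci_low, auc_ci_high, sensitivity, specificity; attribute
#'   `n_dropped` (NA-label samples) and `orientation`.
#' @export
de_scan <- function(expr, outcome, alpha_norm = 0.05, roc = TRUE,
                    n_boot = 1000, seed = 1) {
  stopifnot(nrow(expr) == length(outcome))
  keep <- !is.na(outcome)
  n_dropped <- sum(!keep)
  expr <- expr[keep, , drop = FALSE]
  outcome <- outcome[keep]
  is_res <- outcome == "resistant"
  if (!any(is_res) || !all(c(TRUE, FALSE) %in% unique(is_res))) {
    stop("both outcome groups must be non-empty")
  }
  rows <- lapply(colnames(expr), function(g) {
    a <- expr[!is_res, g]  # ongoing response
    b <- expr[is_res, g]   # resistant
    gate <- gate_test(a, b, alpha_norm)
    parametric <- gate$test == "welch_t"
    p <- if (parametric) {
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (a[1] == b[1]) 1 else 0
      } else stats::t.test(a, b)$p.value
    } else {
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }
    fc <- fold_change(a, b, parametric = parametric)
    row <- data.frame(gene = g, test_used = gate$test, p_value = p,
                      log2fc = fc, stringsAsFactors = FALSE)
    if (roc) {
      rb <- roc_bootstrap(expr[, g], is_res, n_boot = n_boot, seed = seed)
      row$auc <- rb$auc; row$auc_ci_low <- rb$ci_low
      row$auc_ci_high <- rb$ci_high
      row$sensitivity <- rb$sensitivity; row$specificity <- rb$specificity
    }
    row
  })
  res <- do.call(rbind, rows)
  res$q_value <- fdr_adjust(res$p_value)
  attr(res, "n_dropped") <- n_dropped
  attr(res, "orientation") <- "A=ongoing_response, B=resistant; log2fc = -log2(loc(A)/loc(B))"
  res
}
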
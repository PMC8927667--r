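#' Positive-control standard-curve check
#'
#' The six spiked positive controls form a known titration; a lane that
#' hybridized well shows log-linear growth of counts along it. Per sample,
#' ordinary least squares of `log2(count + 1)` on `log2(nominal
#' concentration)` gives a coefficient of determination and slope.
#'
#' @param matrix a [count_matrix()] with >= 3 positive controls at distinct
#'   concentrations.
#' @return data.frame: sample_id, pos_control_r2, pos_control_slope.
#' @export
positive_control_check <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  pos <- matrix$panel$probe_class == "positive"
  conc <- matrix$panel$nominal_concentration[pos]
  if (length(unique(conc)) < 3) {
    stop("need >= 3 positive controls with distinct nominal concentrations")
  }
  x <- log2(conc)
  y <- log2p1(class_counts(matrix, "positive"))
  res <- t(apply(y, 1, function(yy) {
    fit <- stats::lm(yy ~ x)
    r2 <- if (stats::var(yy) == 0) 0 else summary(fit)$r.squared
    c(r2 = r2, slope = unname(stats::coef(fit)[2]))
  }))
  data.frame(sample_id = matrix$sample_ids,
             pos_control_r2 = res[, "r2"],
             pos_control_slope = res[, "slope"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample background statistics from negative controls
#'
#' Mean and sample standard deviation (n-1 denominator) of the
#' negative-control counts of each lane; the background threshold is
#' `mean + 2 * sd` and is subtracted from target counts during technical
#' normalization.
#'
#' @param matrix a [count_matrix()] with >= 2 negative controls.
#' @return data.frame: sample_id, background_mean, background_sd,
#'   background_threshold.
#' @export
background_stats <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  neg <- class_counts(matrix, "negative")
  if (ncol(neg) < 2) stop("need >= 2 negative controls (sd undefined)")
  m <- rowMeans(neg)
  s <- apply(neg, 1, stats::sd)
  data.frame(sample_id = matrix$sample_ids,
             background_mean = m, background_sd = s,
             background_threshold = m + 2 * s,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag samples failing positive-control linearity or background level
#'
#' Flagged samples are reported, never dropped; exclusion is a downstream
#' choice.
#'
#' @param pos_report output of [positive_control_check()].
#' @param bg_report output of [background_stats()].
#' @param r2_min minimum acceptable standard-curve R^2 (default 0.95).
#' @param background_max maximum acceptable background mean; default is the
#'   cohort median background + 3 MAD.
#' @return data.frame with per-sample QC metrics and a `flags` column
#'   (comma-separated; empty when clean).
#' @export
flag_samples <- function(pos_report, bg_report, r2_min = 0.95,
                         background_max = NULL) {
  rep <- merge(pos_report, bg_report, by = "sample_id", sort = FALSE)
  if (is.null(background_max)) {
    background_max <- stats::median(rep$background_mean) +
      3 * stats::mad(rep$background_mean)
  }
  flags <- character(nrow(rep))
  nl <- rep$pos_control_r2 < r2_min
  eb <- rep$background_mean > background_max
  flags[nl] <- "nonlinear_positive_controls"
  flags[eb] <- ifelse(nchar(flags[eb]) > 0,
                      paste0(flags[eb], ",elevated_background"),
                      "elevated_background")
  rep$flags <- flags
  attr(rep, "r2_min") <- r2_min
  attr(rep, "background_max") <- background_max
  rep
}

#' Mean-versus-variance outlier screen
#'
#' Computes mean and variance of `log2(count + 1)` along genes or samples,
#' fits log-variance on log-mean by iterated reweighted least squares
#' (Tukey bisquare), and flags entries whose absolute residual exceeds
#' `k` median absolute deviations of the residuals.
#'
#' @param matrix a [count_matrix()].
#' @param axis `"gene"` (default) or `"sample"`.
#' @param k MAD multiplier for the outlier rule (default 4).
#' @return list with `table` (id, mean, variance, residual, outlier) and
#'   `outliers` (ids).
#' @export
mean_variance_screen <- function(matrix, axis = c("gene", "sample"), k = 4) {
  stopifnot(inherits(matrix, "count_matrix"))
  axis <- match.arg(axis)
  lg <- log2p1(matrix$counts)
  if (axis == "gene") {
    m <- colMeans(lg); v <- apply(lg, 2, stats::var); ids <- colnames(lg)
  } else {
    m <- rowMeans(lg); v <- apply(lg, 1, stats::var); ids <- rownames(lg)
  }
  if (length(ids) < 3) stop("need >= 3 entries along axis '", axis, "'")
  out <- data.frame(id = ids, mean = m, variance = v,
                    residual = NA_real_, outlier = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  pos <- v > 0
  if (sum(pos) >= 3) {
    x <- m[pos]; y <- log2(v[pos])
    w <- rep(1, length(x))
    for (it in 1:20) {   # bisquare IRLS; robust to planted variance outliers
      fit <- stats::lm(y ~ x, weights = w)
      r <- stats::resid(fit)
      s <- stats::mad(r)
      if (s == 0) break
      u <- pmin(abs(r) / (4.685 * s), 1)
      w_new <- (1 - u^2)^2
      if (max(abs(w_new - w)) < 1e-8) { w <- w_new; break }
      w <- w_new
    }
    r <- y - stats::predict(fit, newdata = data.frame(x = x))
    s <- stats::mad(r)
    out$residual[pos] <- r
    if (s > 0) out$outlier[pos] <- abs(r) > k * s
  }
  list(table = out, outliers = out$id[out$outlier])
}

#' Exploratory correlation, clustering and PCA summaries
#'
#' Pearson correlation matrices of the `log2(count + 1)` data on both axes,
#' average-linkage hierarchical clustering on distance `1 - r`, and PCA via
#' singular value decomposition of the column-centered log2 matrix.
#' Zero-variance rows/columns are excluded from correlations with a warning.
#'
#' @param matrix a [count_matrix()] with >= 2 samples and >= 2 genes.
#' @return list: `sample_cor`, `gene_cor`, `sample_hclust`, `gene_hclust`,
#'   `pca` (list of scores, loadings, variance_share).
#' @export
explore_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  lg <- log2p1(matrix$counts)
  if (nrow(lg) < 2 || ncol(lg) < 2) stop("need >= 2 samples and >= 2 genes")
  gene_ok <- apply(lg, 2, stats::var) > 0
  samp_ok <- apply(lg, 1, stats::var) > 0
  if (!all(gene_ok)) warning(sum(!gene_ok),
                             " zero-variance genes excluded from correlation")
  if (!all(samp_ok)) warning(sum(!samp_ok),
                             " zero-variance samples excluded from correlation")
  sample_cor <- stats::cor(t(lg[, gene_ok, drop = FALSE]))
  gene_cor <- stats::cor(lg[samp_ok, gene_ok, drop = FALSE])
  sh <- if (nrow(sample_cor) >= 2) {
    stats::hclust(stats::as.dist(1 - sample_cor), method = "average")
  } else NULL
  gh <- if (nrow(gene_cor) >= 2) {
    stats::hclust(stats::as.dist(1 - gene_cor), method = "average")
  } else NULL
  centered <- scale(lg, center = TRUE, scale = FALSE)
  sv <- svd(centered)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- rownames(lg)
  var_share <- sv$d^2 / sum(sv$d^2)
  list(sample_cor = sample_cor, gene_cor = gene_cor,
       sample_hclust = sh, gene_hclust = gh,
       pca = list(scores = scores, loadings = sv$v,
                  variance_share = var_share))
}
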
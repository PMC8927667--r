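#' Technical normalization: background subtraction
#'
#' Subtracts each sample's background threshold (negative-control mean plus
#' two standard deviations, see [background_stats()]) from every target
#' (endogenous and housekeeping) count, flooring at zero. Negative- and
#' positive-control probes pass through unchanged for audit.
#'
#' @param matrix a [count_matrix()].
#' @param thresholds per-sample numeric vector of background thresholds, in
#'   sample order (e.g. `background_stats(matrix)$background_threshold`).
#' @return A [count_matrix()] (`raw = FALSE`) of background-subtracted counts.
#' @export
technical_normalize <- function(matrix, thresholds) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (length(thresholds) != nrow(matrix$counts)) {
    stop("threshold vector length must equal number of samples")
  }
  target <- matrix$panel$probe_class %in% c("endogenous", "housekeeping")
  counts <- matrix$counts
  counts[, target] <- pmax(counts[, target, drop = FALSE] - thresholds, 0)
  count_matrix(counts, matrix$panel, matrix$lane_attributes, raw = FALSE)
}

#' Biological normalization: reference-gene geometric-mean scaling
#'
#' The per-sample normalization factor is the geometric mean over samples of
#' the per-sample reference-gene geometric means, divided by that sample's
#' own reference-gene geometric mean. Every endogenous and housekeeping
#' count is multiplied by the factor and then rounded half away from zero to
#' an integer. Zeros among the reference-gene counts are replaced by 1
#' (pseudocount) with a warning so the quotient stays defined.
#'
#' @param matrix a background-subtracted [count_matrix()].
#' @return list: `matrix` (normalized integer [count_matrix()]),
#'   `factors` (per-sample normalization factors),
#'   `prerounded` (target counts before integer rounding, for invariants).
#' @export
biological_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  hk <- class_counts(matrix, "housekeeping")
  if (ncol(hk) < 1) stop("need >= 1 housekeeping probe")
  if (any(hk == 0)) {
    warning(sum(hk == 0), " zero reference-gene counts replaced by 1 ",
            "(pseudocount) before geometric means")
    hk[hk == 0] <- 1
  }
  sample_gm <- apply(hk, 1, geomean)
  if (any(!is.finite(sample_gm)) || any(sample_gm <= 0)) {
    stop("reference geometric mean undefined for sample(s): ",
         paste(matrix$sample_ids[!is.finite(sample_gm) | sample_gm <= 0],
               collapse = ", "))
  }
  factors <- geomean(sample_gm) / sample_gm
  target <- matrix$panel$probe_class %in% c("endogenous", "housekeeping")
  counts <- matrix$counts
  pre <- counts[, target, drop = FALSE] * factors
  counts[, target] <- round_half_away(pre)
  list(matrix = count_matrix(counts, matrix$panel, matrix$lane_attributes),
       factors = stats::setNames(factors, matrix$sample_ids),
       prerounded = pre)
}

#' Exclude genes not expressed above background
#'
#' Per endogenous gene, a one-sided two-sample location test of that gene's
#' per-sample counts against the pooled raw negative-control counts of all
#' samples (alternative: gene counts exceed the negative controls). A gene
#' is retained iff p < `alpha`. When both groups are constant and equal the
#' tie rule applies (p = 1, excluded).
#'
#' @param matrix the matrix whose gene counts are tested (normalized by
#'   default in [normalize_pipeline()]).
#' @param negatives matrix of raw (pre-subtraction) negative-control counts,
#'   samples x negative probes; defaults to the negatives inside `matrix`.
#' @param alpha significance level (default 0.05).
#' @param test `"welch_t"` (one-sided Welch two-sample t, default) or
#'   `"wilcoxon"` (one-sided rank-sum).
#' @return list: `retained` (gene ids), `excluded` (gene ids), `p_values`
#'   (named, every endogenous gene).
#' @export
exclude_noise_genes <- function(matrix, negatives = NULL, alpha = 0.05,
                                test = c("welch_t", "wilcoxon")) {
  stopifnot(inherits(matrix, "count_matrix"))
  test <- match.arg(test)
  if (nrow(matrix$counts) < 2) stop("need >= 2 samples")
  if (is.null(negatives)) negatives <- class_counts(matrix, "negative")
  neg_pool <- as.numeric(negatives)
  endo <- matrix$panel$probe_id[matrix$panel$probe_class == "endogenous"]
  p <- vapply(endo, function(g) {
    x <- matrix$counts[, g]
    if (stats::var(x) == 0 && stats::var(neg_pool) == 0 &&
        x[1] == neg_pool[1]) {
      return(1)  # identical degenerate distributions
    }
    if (test == "welch_t") {
      if (stats::var(x) == 0 && stats::var(neg_pool) == 0) {
        return(if (x[1] > neg_pool[1]) 0 else 1)
      }
      stats::t.test(x, neg_pool, alternative = "greater")$p.value
    } else {
      suppressWarnings(
        stats::wilcox.test(x, neg_pool, alternative = "greater")$p.value)
    }
  }, numeric(1))
  retained <- endo[p < alpha]
  list(retained = retained, excluded = setdiff(endo, retained), p_values = p)
}

#' Full count-processing pipeline
#'
#' Chains [background_stats()], [technical_normalize()],
#' [biological_normalize()] and [exclude_noise_genes()], retaining the full
#' audit trail: per-sample thresholds and factors and the exclusion set with
#' p-values.
#'
#' @param matrix a raw [count_matrix()].
#' @param alpha noise-exclusion significance level (default 0.05).
#' @param noise_test `"welch_t"` or `"wilcoxon"`.
#' @param noise_on `"normalized"` (default: test after biological
#'   normalization) or `"subtracted"` (test right after background
#'   subtraction).
#' @return A `normalization_result` list: `normalized` ([count_matrix()] of
#'   integer counts), `background_thresholds`, `normalization_factors`,
#'   `excluded_genes` (data.frame gene, p_value), `retained_genes`,
#'   `noise_p_values`.
#' @export
normalize_pipeline <- function(matrix, alpha = 0.05,
                               noise_test = c("welch_t", "wilcoxon"),
                               noise_on = c("normalized", "subtracted")) {
  stopifnot(inherits(matrix, "count_matrix"))
  noise_test <- match.arg(noise_test)
  noise_on <- match.arg(noise_on)
  bg <- background_stats(matrix)
  sub <- technical_normalize(matrix, bg$background_threshold)
  bio <- biological_normalize(sub)
  raw_neg <- class_counts(matrix, "negative")
  test_mat <- if (noise_on == "normalized") bio$matrix else sub
  noise <- exclude_noise_genes(test_mat, negatives = raw_neg, alpha = alpha,
                               test = noise_test)
  res <- list(
    normalized = bio$matrix,
    background_thresholds = stats::setNames(bg$background_threshold,
                                            bg$sample_id),
    normalization_factors = bio$factors,
    excluded_genes = data.frame(gene = noise$excluded,
                                p_value = unname(noise$p_values[noise$excluded]),
                                stringsAsFactors = FALSE),
    retained_genes = noise$retained,
    noise_p_values = noise$p_values,
    alpha = alpha, noise_test = noise_test, noise_on = noise_on
  )
  class(res) <- "normalization_result"
  res
}

#' @export
print.normalization_result <- function(x, ...) {
  cat(sprintf(paste0("normalization_result: %d samples, %d genes retained, ",
                     "%d excluded as background noise (alpha = %g)\n"),
              nrow(x$normalized$counts), length(x$retained_genes),
              nrow(x$excluded_genes), x$alpha))
  invisible(x)
}

#' Extract normalized counts for retained endogenous genes
#' @param result a `normalization_result`.
#' @return numeric matrix samples x retained genes.
#' @export
retained_counts <- function(result) {
  stopifnot(inherits(result, "normalization_result"))
  result$normalized$counts[, result$retained_genes, drop = FALSE]
}
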
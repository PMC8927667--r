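#' Derive the binary therapy-outcome label from recurrence-free survival
#'
#' A patient is labelled `"resistant"` iff the recurrence event was observed
#' and occurred below 6 months after therapy completion; otherwise
#' `"ongoing_response"`. Patients censored before 6 months keep the
#' ongoing-response label but are flagged with a caveat (their true status
#' is unknowable). Missing RFS gives `NA`.
#'
#' @param rfs_time months; recurrence-free survival time(s).
#' @param rfs_event logical; event observed.
#' @param cutoff months (default 6).
#' @return character vector of labels with attribute `caveat` (logical:
#'   censored before the cutoff).
#' @export
derive_outcome <- function(rfs_time, rfs_event, cutoff = 6) {
  out <- ifelse(is.na(rfs_time) | is.na(rfs_event), NA_character_,
                ifelse(rfs_event & rfs_time < cutoff, "resistant",
                       "ongoing_response"))
  caveat <- !is.na(rfs_time) & !is.na(rfs_event) &
    !rfs_event & rfs_time < cutoff
  if (any(caveat)) {
    message(sum(caveat), " record(s) censored before ", cutoff,
            " months labelled ongoing_response with a caveat")
  }
  attr(out, "caveat") <- caveat
  out
}

#' Cox proportional-hazards fit with the standard test battery
#'
#' Partial-likelihood fit (Efron tie handling) of one or more covariates;
#' reports the hazard ratio with 95% Wald confidence interval for each
#' covariate and the likelihood-ratio, Wald and score (logrank) test
#' p-values for the model.
#'
#' @param covariates numeric vector, matrix or data.frame (samples x
#'   covariates).
#' @param time event/censoring times (months).
#' @param event logical/0-1 event indicators.
#' @param ties tie-handling method passed to [survival::coxph()].
#' @return data.frame (one row per covariate): term, coef, hr, ci_low,
#'   ci_high, p_lrt, p_wald, p_score, n, n_event, converged.
#' @export
fit_cox <- function(covariates, time, event, ties = "efron") {
  x <- as.data.frame(covariates)
  if (ncol(x) == 1 && is.null(colnames(covariates))) names(x) <- "x"
  if (sum(event) < 2) stop("need >= 2 events for a Cox fit")
  if (anyNA(x) || anyNA(time) || anyNA(event)) {
    stop("missing values among covariates or survival fields")
  }
  dat <- cbind(x, .time = time, .event = as.integer(event))
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(x), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = dat, ties = ties))
      attr(f, "flagged") <- conditionMessage(w)
      f
    })
  sm <- summary(fit)
  flagged <- !is.null(attr(fit, "flagged")) ||
    any(!is.finite(sqrt(diag(fit$var)))) ||
    any(abs(stats::coef(fit)) > 15)  # monotone likelihood / separation
  data.frame(
    term = names(stats::coef(fit)),
    coef = unname(stats::coef(fit)),
    hr = unname(sm$conf.int[, "exp(coef)"]),
    ci_low = unname(sm$conf.int[, "lower .95"]),
    ci_high = unname(sm$conf.int[, "upper .95"]),
    p_lrt = unname(sm$logtest["pvalue"]),
    p_wald = unname(sm$waldtest["pvalue"]),
    p_score = unname(sm$sctest["pvalue"]),
    n = sm$n, n_event = sm$nevent,
    converged = !flagged,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Kaplan-Meier estimate with median and time-point survival queries
#'
#' Product-limit estimator per group. The median is the smallest time with
#' S(t) <= 0.5 (`NA` = not reached); `survival_at` values are step-function
#' lookups.
#'
#' @param time,event survival data.
#' @param groups optional per-sample group labels (single group if omitted).
#' @param at optional times (months) at which to report S(t).
#' @return list: `curves` (data.frame group, time, n_risk, n_event,
#'   survival), `median` (named per group), `survival_at` (data.frame when
#'   `at` given), `fit` (the [survival::survfit()] object).
#' @export
km_estimate <- function(time, event, groups = NULL, at = NULL) {
  if (!length(time)) stop("empty survival input")
  if (is.null(groups)) groups <- rep("all", length(time))
  if (any(table(groups) == 0)) stop("empty group")
  df <- data.frame(time = time, event = as.integer(event),
                   group = factor(groups))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(levels(df$group)[1], length(sm$time)) else
    sub("^group=", "", as.character(sm$strata))
  curves <- data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, survival = sm$surv,
                       stringsAsFactors = FALSE)
  med <- vapply(split(curves, curves$group), function(cv) {
    hit <- cv$time[cv$survival <= 0.5]
    if (length(hit)) min(hit) else NA_real_
  }, numeric(1))
  surv_at <- NULL
  if (!is.null(at)) {
    surv_at <- do.call(rbind, lapply(split(curves, curves$group), function(cv) {
      s <- vapply(at, function(t0) {
        past <- cv$survival[cv$time <= t0]
        if (length(past)) past[length(past)] else 1
      }, numeric(1))
      data.frame(group = cv$group[1], time = at, survival = s,
                 stringsAsFactors = FALSE)
    }))
    rownames(surv_at) <- NULL
  }
  list(curves = curves, median = med, survival_at = surv_at, fit = fit)
}

#' Median split of expression into high/low groups
#'
#' Values equal to the cohort median go to `"low"` (documented tie rule).
#'
#' @param values numeric vector with >= 2 distinct values.
#' @return character vector of `"low"` / `"high"`.
#' @export
dichotomize_expression <- function(values) {
  if (length(unique(values)) < 2) stop("constant vector cannot be dichotomized")
  med <- stats::median(values)
  ifelse(values > med, "high", "low")
}

#' Gene-wise Cox survival scan
#'
#' One single-covariate Cox fit per retained gene on standardized
#' `log2(count + 1)` expression, against overall or recurrence-free
#' survival. Records with missing survival are excluded (and counted).
#' P-values (score/logrank by default, per the forest-plot convention) are
#' FDR-adjusted within the endpoint family.
#'
#' @param expr numeric matrix samples x genes (normalized counts).
#' @param clinical clinical data.frame as from [generate_clinical()].
#' @param endpoint `"OS"` or `"RFS"`.
#' @return data.frame: gene, hr, ci_low, ci_high, p_lrt, p_wald, p_score,
#'   q_value (BH on p_score), n_used, converged; attribute `n_excluded`.
#' @export
genewise_survival_scan <- function(expr, clinical, endpoint = c("OS", "RFS")) {
  endpoint <- match.arg(endpoint)
  stopifnot(nrow(expr) == nrow(clinical))
  keep <- !clinical$survival_missing
  n_excluded <- sum(!keep)
  cl <- clinical[keep, ]
  ex <- expr[keep, , drop = FALSE]
  time <- if (endpoint == "OS") cl$os_time else cl$rfs_time
  event <- if (endpoint == "OS") cl$os_event else cl$rfs_event
  rows <- lapply(colnames(ex), function(g) {
    x <- log2p1(ex[, g])
    s <- stats::sd(x)
    if (s == 0) {
      return(data.frame(gene = g, hr = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_lrt = NA_real_,
                        p_wald = NA_real_, p_score = NA_real_,
                        n_used = sum(keep), converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    z <- (x - mean(x)) / s
    fit <- fit_cox(data.frame(z = z), time, event)
    data.frame(gene = g, hr = fit$hr, ci_low = fit$ci_low,
               ci_high = fit$ci_high, p_lrt = fit$p_lrt,
               p_wald = fit$p_wald, p_score = fit$p_score,
               n_used = fit$n, converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- fdr_adjust(res$p_score)
  res$endpoint <- endpoint
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Overlap between OS- and RFS-associated genes
#'
#' @param os_scan,rfs_scan outputs of [genewise_survival_scan()].
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param use `"q_value"` (default) or `"p_score"`.
#' @return list: `os_genes`, `rfs_genes`, `overlap`.
#' @export
survival_overlap <- function(os_scan, rfs_scan, alpha = 0.05,
                             use = c("q_value", "p_score")) {
  use <- match.arg(use)
  os_g <- os_scan$gene[!is.na(os_scan[[use]]) & os_scan[[use]] < alpha]
  rfs_g <- rfs_scan$gene[!is.na(rfs_scan[[use]]) & rfs_scan[[use]] < alpha]
  list(os_genes = os_g, rfs_genes = rfs_g,
       overlap = intersect(os_g, rfs_g))
}
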
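#' Simulation configuration for synthetic nCounter cohorts
#'
#' Describes a synthetic panel and patient cohort mimicking a targeted
#' nCounter study: endogenous targets, negative controls (background),
#' titrated positive controls (standard curve), tiered reference genes,
#' per-lane scale factors, negative-binomial count noise, planted fold
#' changes between outcome groups and planted log-hazard effects on
#' recurrence-free survival.
#'
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @param n_samples number of patients/lanes.
#' @param n_targets number of endogenous probes.
#' @param n_negatives number of negative-control probes.
#' @param n_positives number of positive-control probes (titration ladder).
#' @param n_reference number of housekeeping probes; must be divisible by 3
#'   (high/medium/low tiers).
#' @param background_mean expected negative-control count (Poisson mean).
#' @param lane_factors per-sample positive scale multipliers; recycled scalar
#'   allowed. Length must equal `n_samples`.
#' @param dispersion negative-binomial dispersion phi >= 0 so that
#'   `var = mu + phi * mu^2`; `0` degenerates to Poisson.
#' @param de_genes named numeric vector: gene -> fold change (> 0) applied to
#'   the second ("resistant") outcome group.
#' @param hazard_genes named numeric vector: gene -> log hazard ratio per SD
#'   of log2 normalized expression.
#' @param baseline_hazard recurrence events per month.
#' @param censor_window months; independent uniform censoring on
#'   `[0, censor_window]`.
#' @param missing_survival_fraction proportion in `[0, 1]` of records whose
#'   survival fields are marked missing.
#' @param positive_ladder nominal fM concentrations of the positive controls,
#'   a 4-fold dilution series by default.
#' @param positive_scale expected counts per fM at lane factor 1.
#' @param hk_means expected counts of the high/medium/low reference tiers.
#' @param target_meanlog,target_sdlog log-normal law for endogenous baseline
#'   expression.
#' @param target_baselines optional explicit vector of endogenous baseline
#'   expected counts (length `n_targets`); overrides the log-normal draw.
#'   Zeros mean "background-level" genes (counts are pure background).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 24L,
                       n_targets = 221L,
                       n_negatives = 8L,
                       n_positives = 6L,
                       n_reference = 9L,
                       background_mean = 5,
                       lane_factors = 1,
                       dispersion = 0.05,
                       de_genes = NULL,
                       hazard_genes = NULL,
                       baseline_hazard = log(2) / 9,
                       censor_window = 60,
                       missing_survival_fraction = 0,
                       positive_ladder = 128 / 4^(0:5),
                       positive_scale = 8,
                       hk_means = c(high = 2000, medium = 500, low = 125),
                       target_meanlog = log(300),
                       target_sdlog = 1,
                       target_baselines = NULL) {
  if (length(lane_factors) == 1) lane_factors <- rep(lane_factors, n_samples)
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_targets = as.integer(n_targets),
              n_negatives = as.integer(n_negatives),
              n_positives = as.integer(n_positives),
              n_reference = as.integer(n_reference),
              background_mean = background_mean,
              lane_factors = lane_factors, dispersion = dispersion,
              de_genes = de_genes, hazard_genes = hazard_genes,
              baseline_hazard = baseline_hazard,
              censor_window = censor_window,
              missing_survival_fraction = missing_survival_fraction,
              positive_ladder = positive_ladder,
              positive_scale = positive_scale,
              hk_means = hk_means,
              target_meanlog = target_meanlog, target_sdlog = target_sdlog,
              target_baselines = target_baselines)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 1 || n_targets < 1 || n_negatives < 1 ||
        n_positives < 1 || n_reference < 1) {
      stop("all probe-class and sample counts must be positive", call. = FALSE)
    }
    if (n_reference %% 3 != 0) {
      stop("n_reference must be divisible by 3 (high/medium/low tiers)",
           call. = FALSE)
    }
    if (length(lane_factors) != n_samples) {
      stop("lane_factors length must equal n_samples", call. = FALSE)
    }
    if (any(lane_factors <= 0)) stop("lane_factors must be > 0", call. = FALSE)
    if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
    if (background_mean < 0) stop("background_mean must be >= 0", call. = FALSE)
    if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
    if (censor_window <= 0) stop("censor_window must be > 0", call. = FALSE)
    if (missing_survival_fraction < 0 || missing_survival_fraction > 1) {
      stop("missing_survival_fraction must lie in [0, 1]", call. = FALSE)
    }
    if (!is.null(de_genes) && any(de_genes <= 0)) {
      stop("de_genes fold changes must be > 0", call. = FALSE)
    }
    if (n_positives > 1 && length(positive_ladder) < n_positives) {
      stop("positive_ladder shorter than n_positives", call. = FALSE)
    }
    if (!is.null(target_baselines)) {
      if (length(target_baselines) != n_targets) {
        stop("target_baselines length must equal n_targets", call. = FALSE)
      }
      if (any(target_baselines < 0)) {
        stop("target_baselines must be >= 0", call. = FALSE)
      }
    }
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic panel annotation
#'
#' Builds the four probe classes: `n_targets` endogenous genes (GENE001,
#' ...), negative controls (NEG01, ...), positive controls carrying a
#' strictly decreasing geometric titration of nominal concentrations, and
#' reference genes tagged high/medium/low in equal thirds.
#'
#' @param config a [sim_config()].
#' @return A [probe_annotation()] with
#'   `n_targets + n_negatives + n_positives + n_reference` rows.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_t <- config$n_targets; n_n <- config$n_negatives
  n_p <- config$n_positives; n_r <- config$n_reference
  ladder <- config$positive_ladder[seq_len(n_p)]
  tiers <- rep(c("high", "medium", "low"), each = n_r / 3)
  probe_annotation(
    probe_id = c(sprintf("GENE%03d", seq_len(n_t)),
                 sprintf("NEG%02d", seq_len(n_n)),
                 sprintf("POS%02d", seq_len(n_p)),
                 sprintf("REF%02d", seq_len(n_r))),
    probe_class = rep(c("endogenous", "negative", "positive", "housekeeping"),
                      c(n_t, n_n, n_p, n_r)),
    nominal_concentration = c(rep(NA_real_, n_t + n_n), ladder,
                              rep(NA_real_, n_r)),
    reference_tier = c(rep("none", n_t + n_n + n_p), tiers)
  )
}

#' Baseline expected counts per probe (lane factor 1, no planted effects)
#' @keywords internal
baseline_expression <- function(config, panel) {
  n_r <- config$n_reference
  hk <- rep(config$hk_means, each = n_r / 3)
  base <- numeric(nrow(panel))
  endo <- panel$probe_class == "endogenous"
  if (!is.null(config$target_baselines)) {
    base[endo] <- config$target_baselines
  } else {
    # endogenous baselines are drawn once, deterministically from the seed,
    # so panel + config fully determine the generative law
    base[endo] <- local({
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(config$seed + 1000L)
      stats::rlnorm(sum(endo), config$target_meanlog, config$target_sdlog)
    })
  }
  base[panel$probe_class == "housekeeping"] <- hk
  names(base) <- panel$probe_id
  base
}

#' Generate synthetic nCounter counts
#'
#' Negative controls are Poisson at `background_mean`; positive controls are
#' Poisson at `lane_factor * positive_scale * nominal_concentration`;
#' endogenous and housekeeping probes are negative-binomial with mean
#' `lane_factor * baseline * fold_change + background_mean` (fold change
#' applied only for genes in `de_genes` and samples in the second group) and
#' variance `mu + dispersion * mu^2`.
#'
#' @param config a [sim_config()].
#' @param panel a panel from [generate_panel()] (or compatible).
#' @param group_labels optional per-sample factor/character with two levels;
#'   the *second* level receives the planted fold changes. Defaults to all
#'   samples in one group (no DE).
#' @return A [count_matrix()] of raw integer counts.
#' @export
generate_counts <- function(config, panel, group_labels = NULL) {
  stopifnot(inherits(config, "sim_config"))
  panel <- validate_probe_annotation(panel)
  n <- config$n_samples
  if (is.null(group_labels)) group_labels <- rep("onR", n)
  if (length(group_labels) != n) {
    stop("group_labels length must equal n_samples")
  }
  grp <- factor(group_labels)
  base <- baseline_expression(config, panel)
  de <- config$de_genes
  if (!is.null(de)) {
    unknown <- setdiff(names(de), panel$probe_id)
    if (length(unknown)) stop("de_genes not in panel: ",
                              paste(unknown, collapse = ", "))
  }
  set.seed(config$seed)
  counts <- matrix(0L, nrow = n, ncol = nrow(panel),
                   dimnames = list(sprintf("SAMPLE%03d", seq_len(n)),
                                   panel$probe_id))
  in_second <- if (nlevels(grp) >= 2) grp == levels(grp)[2] else rep(FALSE, n)
  for (j in seq_len(nrow(panel))) {
    cls <- panel$probe_class[j]
    if (cls == "negative") {
      counts[, j] <- stats::rpois(n, config$background_mean)
    } else if (cls == "positive") {
      mu <- config$lane_factors * config$positive_scale *
        panel$nominal_concentration[j]
      counts[, j] <- stats::rpois(n, mu)
    } else {
      fc <- rep(1, n)
      if (!is.null(de) && panel$probe_id[j] %in% names(de)) {
        fc[in_second] <- de[[panel$probe_id[j]]]
      }
      mu <- config$lane_factors * base[j] * fc + config$background_mean
      if (config$dispersion == 0) {
        counts[, j] <- stats::rpois(n, mu)
      } else {
        counts[, j] <- stats::rnbinom(n, size = 1 / config$dispersion, mu = mu)
      }
    }
  }
  count_matrix(counts, panel)
}

#' Generate synthetic clinical records tied to expression
#'
#' Recurrence-free survival times are exponential with rate
#' `baseline_hazard * exp(sum_g beta_g z_g)` where `z_g` is the standardized
#' log2(count+1) expression of hazard gene g; overall survival is RFS plus an
#' independent exponential post-recurrence time. Both endpoints are censored
#' by independent uniform draws on `[0, censor_window]`. The binary therapy
#' outcome is `"resistant"` iff the RFS event is observed before 6 months,
#' else `"ongoing_response"`. A `missing_survival_fraction` share of records
#' (rounded to the nearest count) has survival fields marked missing.
#'
#' @param config a [sim_config()].
#' @param expression a [count_matrix()] containing every gene named in
#'   `config$hazard_genes`.
#' @return A `data.frame` of clinical records (one row per sample) with
#'   columns sample_id, age, grade, stage, os_time, os_event, rfs_time,
#'   rfs_event, outcome, fap_positive, survival_missing.
#' @export
generate_clinical <- function(config, expression) {
  stopifnot(inherits(config, "sim_config"), inherits(expression, "count_matrix"))
  n <- nrow(expression$counts)
  hz <- config$hazard_genes
  lp <- rep(0, n)
  if (!is.null(hz) && length(hz)) {
    unknown <- setdiff(names(hz), colnames(expression$counts))
    if (length(unknown)) stop("hazard_genes not in expression matrix: ",
                              paste(unknown, collapse = ", "))
    for (g in names(hz)) {
      x <- log2p1(expression$counts[, g])
      s <- stats::sd(x)
      z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
      lp <- lp + hz[[g]] * z
    }
  }
  set.seed(config$seed + 2000L)
  rate <- config$baseline_hazard * exp(lp)
  rfs_true <- stats::rexp(n, rate)
  post <- stats::rexp(n, config$baseline_hazard / 2)
  os_true <- rfs_true + post
  cens <- stats::runif(n, 0, config$censor_window)
  rfs_time <- pmin(rfs_true, cens)
  rfs_event <- rfs_true <= cens
  os_time <- pmin(os_true, cens)
  os_event <- os_true <= cens
  n_missing <- round(config$missing_survival_fraction * n)
  missing_idx <- if (n_missing > 0) sample.int(n, n_missing) else integer(0)
  survival_missing <- seq_len(n) %in% missing_idx
  outcome <- derive_outcome(rfs_time, rfs_event)
  outcome[survival_missing] <- NA_character_
  rec <- data.frame(
    sample_id = rownames(expression$counts),
    age = round(stats::rnorm(n, 62, 10)),
    grade = sample(2:3, n, replace = TRUE),
    stage = sample(1:4, n, replace = TRUE, prob = c(.1, .2, .4, .3)),
    os_time = os_time, os_event = os_event,
    rfs_time = rfs_time, rfs_event = rfs_event,
    outcome = outcome,
    fap_positive = stats::runif(n) < 7 / 24,
    survival_missing = survival_missing,
    stringsAsFactors = FALSE
  )
  rec$os_time[survival_missing] <- NA_real_
  rec$os_event[survival_missing] <- NA
  rec$rfs_time[survival_missing] <- NA_real_
  rec$rfs_event[survival_missing] <- NA
  rec
}
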
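#' Pipeline configuration
#'
#' Exactly one input mode: `"synthetic"` (generate a cohort from a
#' [sim_config()]), `"rcc_dir"` (a directory of RCC lane files plus a
#' clinical TSV), or `"counts_csv"` (counts + panel CSVs plus a clinical
#' TSV).
#'
#' @param input `"synthetic"`, `"rcc_dir"` or `"counts_csv"`.
#' @param sim a [sim_config()] (synthetic mode).
#' @param rcc_dir directory of `.RCC` files.
#' @param counts_csv,panel_csv CSV paths (counts_csv mode).
#' @param clinical_tsv clinical table TSV (non-synthetic modes).
#' @param outdir output directory.
#' @param alpha noise-exclusion and significance level.
#' @param alpha_norm Shapiro-Wilk gate level.
#' @param n_boot ROC bootstrap iterations.
#' @param seed analysis seed (bootstraps etc.).
#' @param noise_test,noise_on passed to [normalize_pipeline()].
#' @param gmt optional GMT path for enrichment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = c("synthetic", "rcc_dir", "counts_csv"),
                            sim = sim_config(), rcc_dir = NULL,
                            counts_csv = NULL, panel_csv = NULL,
                            clinical_tsv = NULL, outdir = "rccflow_out",
                            alpha = 0.05, alpha_norm = 0.05,
                            n_boot = 1000, seed = 1,
                            noise_test = "welch_t", noise_on = "normalized",
                            gmt = NULL) {
  input <- match.arg(input)
  cfg <- list(input = input, sim = sim, rcc_dir = rcc_dir,
              counts_csv = counts_csv, panel_csv = panel_csv,
              clinical_tsv = clinical_tsv, outdir = outdir, alpha = alpha,
              alpha_norm = alpha_norm, n_boot = n_boot,
              seed = as.integer(seed),
              noise_test = noise_test, noise_on = noise_on, gmt = gmt)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a clinical table TSV
#'
#' Expected columns: sample_id, age, grade, stage, os_time, os_event,
#' rfs_time, rfs_event, fap_positive, survival_missing (the last two
#' optional). The outcome label is (re-)derived from RFS.
#'
#' @param path TSV path.
#' @return clinical data.frame.
#' @export
read_clinical_tsv <- function(path) {
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "os_time", "os_event", "rfs_time", "rfs_event")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(cl$survival_missing)) {
    cl$survival_missing <- is.na(cl$rfs_time) | is.na(cl$os_time)
  }
  cl$outcome <- suppressMessages(derive_outcome(cl$rfs_time, cl$rfs_event))
  cl
}

#' Run the full analysis pipeline
#'
#' Generate or load counts and clinical data, run QC, two-stage
#' normalization with noise-gene exclusion, gene-wise Cox survival scans on
#' OS and RFS, the differential-expression battery against the therapy
#' outcome, optional gene-set overrepresentation, and write all results as
#' TSV/JSON under `config$outdir`. Deterministic for a fixed seed: the same
#' configuration writes byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return invisibly, a list with all stage results plus `manifest`.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[rccflow] ", ...)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  # --- input stage ---------------------------------------------------------
  if (config$input == "synthetic") {
    say("generating synthetic cohort (n=", config$sim$n_samples, ")")
    panel <- generate_panel(config$sim)
    mat <- generate_counts(config$sim, panel)
    clinical <- generate_clinical(config$sim, mat)
  } else if (config$input == "rcc_dir") {
    say("reading RCC lanes from ", config$rcc_dir)
    mat <- read_rcc_dir(config$rcc_dir)
    clinical <- read_clinical_tsv(config$clinical_tsv)
  } else {
    say("reading counts CSV ", config$counts_csv)
    mat <- read_counts_csv(config$counts_csv, config$panel_csv)
    clinical <- read_clinical_tsv(config$clinical_tsv)
  }
  if (!identical(clinical$sample_id, mat$sample_ids)) {
    clinical <- clinical[match(mat$sample_ids, clinical$sample_id), ]
    if (anyNA(clinical$sample_id)) {
      stop("stage input: clinical table does not cover all samples")
    }
  }

  # --- qc ------------------------------------------------------------------
  say("QC: positive-control linearity and background")
  qc_rep <- flag_samples(positive_control_check(mat), background_stats(mat))
  n_flagged <- sum(nchar(qc_rep$flags) > 0)
  if (n_flagged) say(n_flagged, " sample(s) flagged (kept; see qc_report.tsv)")
  write_tsv_stable(qc_rep, file.path(outdir, "qc_report.tsv"))

  # --- normalize -----------------------------------------------------------
  say("normalization: background subtraction + reference-gene scaling")
  norm <- normalize_pipeline(mat, alpha = config$alpha,
                             noise_test = config$noise_test,
                             noise_on = config$noise_on)
  say(length(norm$retained_genes), " genes retained, ",
      nrow(norm$excluded_genes), " excluded as background noise")
  expr <- retained_counts(norm)
  norm_df <- data.frame(sample_id = rownames(expr), expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_stable(norm_df, file.path(outdir, "normalized_counts.tsv"))
  audit <- list(background_thresholds = as.list(norm$background_thresholds),
                normalization_factors = as.list(norm$normalization_factors),
                excluded_genes = norm$excluded_genes,
                alpha = norm$alpha, noise_test = norm$noise_test,
                noise_on = norm$noise_on)
  jsonlite::write_json(audit, file.path(outdir, "normalization_audit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- survival scans ------------------------------------------------------
  os_scan <- rfs_scan <- overlap <- NULL
  n_events <- function(ev) sum(ev, na.rm = TRUE)
  usable <- !clinical$survival_missing
  if (sum(usable) >= 3 && n_events(clinical$os_event[usable]) >= 2) {
    say("survival scan: OS and RFS over ", ncol(expr), " genes (",
        sum(!usable), " samples excluded for missing survival)")
    os_scan <- genewise_survival_scan(expr, clinical, "OS")
    rfs_scan <- genewise_survival_scan(expr, clinical, "RFS")
    overlap <- survival_overlap(os_scan, rfs_scan)
    write_tsv_stable(os_scan, file.path(outdir, "survival_os.tsv"))
    write_tsv_stable(rfs_scan, file.path(outdir, "survival_rfs.tsv"))
  } else {
    say("survival scan skipped: too few usable records or events")
  }

  # --- differential expression --------------------------------------------
  de <- NULL
  oc <- clinical$outcome
  if (length(unique(stats::na.omit(oc))) == 2) {
    say("differential expression vs therapy outcome")
    de <- de_scan(expr, oc, alpha_norm = config$alpha_norm,
                  n_boot = config$n_boot, seed = config$seed)
    write_tsv_stable(de, file.path(outdir, "de_results.tsv"))
  } else {
    say("DE scan skipped: outcome has fewer than two groups")
  }

  # --- enrichment ----------------------------------------------------------
  enr <- fc_table <- NULL
  if (!is.null(config$gmt) && !is.null(de)) {
    say("overrepresentation analysis against ", config$gmt)
    sets <- load_gmt(config$gmt)
    hits <- de$gene[de$p_value < config$alpha]
    enr <- suppressMessages(ora(hits, de$gene, sets))
    fc_table <- pathway_fc_table(de, sets)
    write_tsv_stable(enr, file.path(outdir, "enrichment.tsv"))
    write_tsv_stable(fc_table, file.path(outdir, "pathway_fc.tsv"))
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("rccflow")),
    seed = config$seed,
    input_mode = config$input,
    n_samples = nrow(mat$counts),
    n_probes = ncol(mat$counts),
    n_flagged_samples = n_flagged,
    n_excluded_genes = nrow(norm$excluded_genes),
    n_retained_genes = length(norm$retained_genes),
    n_survival_missing = sum(clinical$survival_missing),
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  clinical_out <- clinical
  write_tsv_stable(clinical_out, file.path(outdir, "clinical.tsv"))
  invisible(list(matrix = mat, clinical = clinical, qc = qc_rep,
                 normalization = norm, os_scan = os_scan,
                 rfs_scan = rfs_scan, overlap = overlap, de = de,
                 enrichment = enr, pathway_fc = fc_table,
                 manifest = manifest))
}

#' Stable hash of a pipeline configuration
#' @keywords internal
config_hash <- function(config) {
  cfg <- unclass(config)
  # paths identify a location, not an analysis; keep the hash content-based
  cfg[c("outdir", "rcc_dir", "counts_csv", "panel_csv", "clinical_tsv",
        "gmt")] <- NULL
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small polynomial rolling hash over the printed config; stable across runs
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 1e9
  sprintf("%09d", h)
}
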
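PROBE_CLASSES <- c("endogenous", "negative", "positive", "housekeeping")
REFERENCE_TIERS <- c("high", "medium", "low", "none")

#' Construct a probe annotation table
#'
#' The panel map of an nCounter codeset: one row per probe, with the probe
#' class (endogenous target, negative control, titrated positive control, or
#' housekeeping/reference gene), the nominal spike-in concentration for
#' positive controls, and the expression tier for reference genes.
#'
#' @param probe_id character; unique probe identifiers.
#' @param gene_symbol character; gene symbols (defaults to `probe_id`).
#' @param probe_class character; one of `"endogenous"`, `"negative"`,
#'   `"positive"`, `"housekeeping"`.
#' @param nominal_concentration numeric; fM concentration for positive
#'   controls, `NA` for all other classes.
#' @param reference_tier character; `"high"`, `"medium"` or `"low"` for
#'   housekeeping probes, `"none"` otherwise.
#' @return A `probe_annotation` data frame.
#' @export
probe_annotation <- function(probe_id, gene_symbol = probe_id, probe_class,
                             nominal_concentration = NA_real_,
                             reference_tier = "none") {
  df <- data.frame(
    probe_id = as.character(probe_id),
    gene_symbol = as.character(gene_symbol),
    probe_class = as.character(probe_class),
    nominal_concentration = as.numeric(nominal_concentration),
    reference_tier = as.character(reference_tier),
    stringsAsFactors = FALSE
  )
  validate_probe_annotation(df)
}

validate_probe_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("probe_id", "gene_symbol", "probe_class",
           "nominal_concentration", "reference_tier")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("probe annotation lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id in panel: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$probe_class), PROBE_CLASSES)
  if (length(bad)) stop("unknown probe_class: ", paste(bad, collapse = ", "))
  is_pos <- df$probe_class == "positive"
  if (any(is_pos & !is.finite(df$nominal_concentration))) {
    stop("positive-control probes must carry a nominal_concentration")
  }
  if (any(!is_pos & is.finite(df$nominal_concentration))) {
    stop("nominal_concentration is only defined for positive controls")
  }
  is_hk <- df$probe_class == "housekeeping"
  if (any(is_hk & !(df$reference_tier %in% c("high", "medium", "low")))) {
    stop("housekeeping probes must carry a reference_tier (high/medium/low)")
  }
  if (any(!is_hk & df$reference_tier != "none")) {
    stop("reference_tier must be 'none' for non-housekeeping probes")
  }
  class(df) <- c("probe_annotation", "data.frame")
  df
}

#' Construct a cohort count matrix
#'
#' Samples-by-probes counts with the panel annotation and per-lane metadata
#' attached. Raw counts must be non-negative integers; normalized stages may
#' relax integrality via `raw = FALSE`.
#'
#' @param counts numeric matrix, samples in rows, probes in columns; column
#'   names must equal `panel$probe_id` in order.
#' @param panel a [probe_annotation()] table.
#' @param lane_attributes optional named list (one entry per sample) of
#'   free-form lane metadata.
#' @param raw logical; if `TRUE` (default) counts must be integers.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, panel, lane_attributes = NULL, raw = TRUE) {
  panel <- validate_probe_annotation(panel)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) colnames(counts) <- panel$probe_id
  if (!identical(colnames(counts), panel$probe_id)) {
    stop("count matrix columns must match panel probe_id order")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (raw && any(counts != floor(counts))) {
    stop("raw counts must be integers")
  }
  obj <- list(
    counts = counts,
    panel = panel,
    sample_ids = rownames(counts),
    lane_attributes = lane_attributes
  )
  class(obj) <- "count_matrix"
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cls <- table(factor(x$panel$probe_class, levels = PROBE_CLASSES))
  cat(sprintf("count_matrix: %d samples x %d probes (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(cls), cls), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset helper: counts for one probe class
#' @param x a `count_matrix`.
#' @param cls probe class to extract.
#' @return numeric matrix (samples x class probes).
#' @keywords internal
class_counts <- function(x, cls) {
  x$counts[, x$panel$probe_class == cls, drop = FALSE]
}
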
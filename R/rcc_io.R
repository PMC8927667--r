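CODECLASS_MAP <- c(Endogenous = "endogenous", Negative = "negative",
                   Positive = "positive", Housekeeping = "housekeeping")

#' Read an nCounter RCC lane file
#'
#' Parses the sectioned plain-text RCC layout (`<Header>`,
#' `<Sample_Attributes>`, `<Lane_Attributes>`, `<Code_Summary>` blocks with
#' comma-separated records). Each `Code_Summary` row becomes one probe count;
#' the `CodeClass` field maps onto the four probe classes. Positive-control
#' nominal concentrations are recovered from probe names of the vendor form
#' `POS_X(128)`, or from an `Accession` field of the form `fM:<value>` as
#' written by [write_rcc()].
#'
#' @param path RCC file path.
#' @return A list with elements `panel` ([probe_annotation()] fragment),
#'   `counts` (named integer vector), and `attributes` (named list of the
#'   non-count sections, preserved verbatim for round-tripping).
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  opens <- grep("^<[^/]", lines)
  sections <- list()
  for (o in opens) {
    name <- sub("^<([^>]+)>.*$", "\\1", lines[o])
    close_at <- grep(paste0("^</", name, ">"), lines)
    close_at <- close_at[close_at > o][1]
    if (is.na(close_at)) stop("unterminated RCC section <", name, ">")
    body <- if (close_at > o + 1) lines[(o + 1):(close_at - 1)] else character(0)
    sections[[name]] <- body
  }
  if (is.null(sections[["Code_Summary"]])) {
    stop("RCC parse error: missing Code_Summary section in ", path)
  }
  cs <- sections[["Code_Summary"]]
  header <- strsplit(cs[1], ",", fixed = TRUE)[[1]]
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% header)) {
    stop("Code_Summary header must contain CodeClass, Name, Count")
  }
  rows <- do.call(rbind, strsplit(cs[-1], ",", fixed = TRUE))
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(rows) <- header
  count_num <- suppressWarnings(as.numeric(rows$Count))
  if (any(is.na(count_num)) || any(count_num < 0) ||
      any(count_num != floor(count_num))) {
    stop("RCC data error: counts must be non-negative integers")
  }
  cls <- CODECLASS_MAP[rows$CodeClass]
  if (any(is.na(cls))) {
    stop("unknown CodeClass: ",
         paste(unique(rows$CodeClass[is.na(cls)]), collapse = ", "))
  }
  conc <- rep(NA_real_, nrow(rows))
  tier <- rep("none", nrow(rows))
  is_pos <- cls == "positive"
  if (any(is_pos)) {
    acc <- if ("Accession" %in% header) rows$Accession[is_pos] else ""
    from_acc <- suppressWarnings(as.numeric(sub("^fM:", "", acc)))
    from_name <- suppressWarnings(
      as.numeric(sub("^.*\\(([-0-9.eE]+)\\).*$", "\\1", rows$Name[is_pos])))
    conc[is_pos] <- ifelse(!is.na(from_acc), from_acc, from_name)
    if (any(is.na(conc[is_pos]))) {
      stop("positive-control nominal concentration not recoverable from file")
    }
  }
  is_hk <- cls == "housekeeping"
  if (any(is_hk) && "Accession" %in% header) {
    t <- sub("^tier:", "", rows$Accession[is_hk])
    tier[is_hk] <- ifelse(t %in% c("high", "medium", "low"), t, "medium")
  } else if (any(is_hk)) {
    tier[is_hk] <- "medium"
  }
  panel <- probe_annotation(
    probe_id = rows$Name, probe_class = unname(cls),
    nominal_concentration = conc, reference_tier = tier
  )
  counts <- as.integer(count_num)
  names(counts) <- rows$Name
  list(panel = panel, counts = counts,
       attributes = sections[setdiff(names(sections), "Code_Summary")])
}

#' Write a single nCounter lane as an RCC file
#'
#' Inverse of [read_rcc()]: emits Header, Sample_Attributes, Lane_Attributes
#' and Code_Summary sections with byte-stable ordering, so
#' write -> read -> write reproduces identical bytes. Nominal concentrations
#' and reference tiers are encoded in the Accession field (`fM:<conc>`,
#' `tier:<tier>`).
#'
#' @param counts named integer vector (names = probe ids).
#' @param panel a [probe_annotation()] covering the probes.
#' @param path output file path.
#' @param sample_id lane identifier written to Sample_Attributes.
#' @param attributes optional named list of verbatim section bodies (as
#'   returned by [read_rcc()]); overrides the defaults.
#' @return `path`, invisibly.
#' @export
write_rcc <- function(counts, panel, path, sample_id = "sample",
                      attributes = NULL) {
  panel <- validate_probe_annotation(panel)
  if (length(counts) == 0) stop("empty lane: nothing to write")
  if (!all(names(counts) %in% panel$probe_id)) {
    stop("probe without class annotation: ",
         paste(setdiff(names(counts), panel$probe_id), collapse = ", "))
  }
  panel <- panel[match(names(counts), panel$probe_id), ]
  rev_map <- stats::setNames(names(CODECLASS_MAP), CODECLASS_MAP)
  accession <- ifelse(panel$probe_class == "positive",
                      paste0("fM:", format(panel$nominal_concentration,
                                           trim = TRUE, scientific = FALSE)),
                      ifelse(panel$probe_class == "housekeeping",
                             paste0("tier:", panel$reference_tier), "NA"))
  if (is.null(attributes)) {
    attributes <- list(
      Header = c("FileVersion,1.7", "SoftwareVersion,rccflow"),
      Sample_Attributes = c(paste0("ID,", sample_id), "Owner,", "Comments,",
                            "Date,", "GeneRLF,rccflow-panel"),
      Lane_Attributes = c("ID,1", "FovCount,555", "FovCounted,555",
                          "BindingDensity,1.0")
    )
  }
  out <- character(0)
  for (nm in names(attributes)) {
    out <- c(out, paste0("<", nm, ">"), attributes[[nm]], paste0("</", nm, ">"))
  }
  out <- c(out, "<Code_Summary>", "CodeClass,Name,Accession,Count",
           paste(rev_map[panel$probe_class], panel$probe_id, accession,
                 as.integer(counts), sep = ","),
           "</Code_Summary>")
  writeLines(out, path)
  invisible(path)
}

#' Write every lane of a cohort as RCC files
#'
#' @param matrix a [count_matrix()].
#' @param dir output directory (created if absent).
#' @return character vector of file paths.
#' @export
write_rcc_set <- function(matrix, dir) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(matrix$sample_ids)) {
    sid <- matrix$sample_ids[i]
    p <- file.path(dir, paste0(sid, ".RCC"))
    write_rcc(matrix$counts[i, ], matrix$panel, p, sample_id = sid)
    paths <- c(paths, p)
  }
  paths
}

#' Assemble single-lane reads into a cohort count matrix
#'
#' All lanes must share an identical panel (same probe ids after the
#' canonical `(probe_class, probe_id)` sort). Lane order defines row order;
#' columns follow the canonical probe order.
#'
#' @param lanes list of lane objects as returned by [read_rcc()]; names (or
#'   Sample_Attributes ID) become sample ids.
#' @return A [count_matrix()].
#' @export
assemble_matrix <- function(lanes) {
  if (!length(lanes)) stop("no lanes to assemble")
  canon <- function(panel) {
    panel[order(panel$probe_class, panel$probe_id), ]
  }
  ref <- canon(lanes[[1]]$panel)
  for (i in seq_along(lanes)) {
    p <- canon(lanes[[i]]$panel)
    if (!identical(p$probe_id, ref$probe_id)) {
      bad <- union(setdiff(p$probe_id, ref$probe_id),
                   setdiff(ref$probe_id, p$probe_id))
      stop("panel mismatch between lanes at lane ", i, ": ",
           paste(bad, collapse = ", "))
    }
  }
  ids <- names(lanes)
  if (is.null(ids)) {
    ids <- vapply(seq_along(lanes), function(i) {
      sa <- lanes[[i]]$attributes[["Sample_Attributes"]]
      id <- sa[grepl("^ID,", sa)]
      if (length(id)) sub("^ID,", "", id[1]) else paste0("S", i)
    }, character(1))
  }
  counts <- t(vapply(lanes, function(l) unname(l$counts[ref$probe_id]),
                     numeric(nrow(ref))))
  rownames(counts) <- ids
  colnames(counts) <- ref$probe_id
  rownames(ref) <- NULL
  count_matrix(counts, ref)
}

#' Read a cohort of RCC files from a directory
#' @param dir directory containing `*.RCC` files.
#' @return A [count_matrix()].
#' @export
read_rcc_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.RCC$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files)) stop("no RCC files found in ", dir)
  lanes <- lapply(files, read_rcc)
  names(lanes) <- sub("\\.RCC$", "", basename(files), ignore.case = TRUE)
  assemble_matrix(lanes)
}

#' Write counts and panel annotation as CSV
#'
#' Counts CSV has samples as rows (first column `sample_id`), probes as
#' columns; the panel CSV is the annotation table.
#'
#' @param matrix a [count_matrix()].
#' @param counts_path,panel_path output CSV paths (`NULL` to skip one).
#' @return invisibly, the paths written.
#' @export
write_counts_csv <- function(matrix, counts_path, panel_path = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  df <- data.frame(sample_id = matrix$sample_ids,
                   matrix$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, counts_path, row.names = FALSE, quote = FALSE)
  if (!is.null(panel_path)) {
    utils::write.csv(as.data.frame(matrix$panel), panel_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(c(counts_path, panel_path))
}

#' Read a counts CSV plus panel annotation CSV into a count matrix
#' @param counts_path CSV with first column `sample_id`, one column per probe.
#' @param panel_path panel annotation CSV.
#' @return A [count_matrix()].
#' @export
read_counts_csv <- function(counts_path, panel_path) {
  df <- utils::read.csv(counts_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  panel <- utils::read.csv(panel_path, stringsAsFactors = FALSE)
  panel$nominal_concentration <- as.numeric(panel$nominal_concentration)
  panel <- validate_probe_annotation(panel)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$sample_id
  counts <- counts[, panel$probe_id, drop = FALSE]
  count_matrix(counts, panel)
}
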
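#' Read gene sets from a GMT file
#'
#' Tab-separated lines: set id, description, then members. Duplicate members
#' within a set are collapsed with a warning.
#'
#' @param path GMT file.
#' @return named list of gene sets; each element is a character vector of
#'   members with attributes `set_id` and `name` (description).
#' @export
load_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    }
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members collapsed in set '", f[1], "'")
      members <- unique(members)
    }
    attr(members, "set_id") <- f[1]
    attr(members, "name") <- f[2]
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets as a GMT file
#' @param sets named list of character vectors (as from [load_gmt()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    nm <- attr(sets[[id]], "name") %||% id
    paste(c(id, nm, as.character(sets[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric overrepresentation analysis
#'
#' Per gene set, the upper-tail hypergeometric probability of observing at
#' least the realized overlap between the selected genes and the set, given
#' the universe; BH-FDR across sets. Sets with fewer than `min_size` members
#' mapped into the universe are skipped with a message.
#'
#' @param selected character vector of selected (e.g. outcome-associated)
#'   genes; must be a subset of `universe`.
#' @param universe character vector: the retained panel genes.
#' @param sets named list of gene sets (see [load_gmt()]).
#' @param min_size minimum mapped set size (default 3).
#' @return data.frame: set_id, name, set_size (mapped), overlap_count,
#'   universe_size, selected_size, p_hyper, q_value, overlap_genes
#'   (comma-separated).
#' @export
ora <- function(selected, universe, sets, min_size = 3) {
  selected <- unique(selected); universe <- unique(universe)
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop("selected genes absent from universe: ", paste(extra, collapse = ", "))
  }
  rows <- lapply(names(sets), function(id) {
    mapped <- intersect(sets[[id]], universe)
    if (length(mapped) < min_size) {
      message("skipping set '", id, "': fewer than ", min_size,
              " mapped members")
      return(NULL)
    }
    ov <- intersect(mapped, selected)
    # P(X >= |ov|), X ~ Hypergeom(universe, mapped, draws = |selected|)
    p <- stats::phyper(length(ov) - 1, length(mapped),
                       length(universe) - length(mapped),
                       length(selected), lower.tail = FALSE)
    data.frame(set_id = id, name = attr(sets[[id]], "name") %||% id,
               set_size = length(mapped), overlap_count = length(ov),
               universe_size = length(universe),
               selected_size = length(selected),
               p_hyper = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(set_id = character(0), name = character(0),
                      set_size = integer(0), overlap_count = integer(0),
                      universe_size = integer(0), selected_size = integer(0),
                      p_hyper = numeric(0), q_value = numeric(0),
                      overlap_genes = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$q_value <- fdr_adjust(res$p_hyper)
  res
}

#' Per-pathway member table with signed fold changes
#'
#' Long-format export (set_id, gene, log2fc, q_value, measured) suitable for
#' coloring external pathway maps; genes in a set but absent from the DE
#' results are flagged as not measured.
#'
#' @param de_results a [de_scan()] result.
#' @param sets named list of gene sets.
#' @return data.frame in long format.
#' @export
pathway_fc_table <- function(de_results, sets) {
  rows <- lapply(names(sets), function(id) {
    genes <- as.character(sets[[id]])
    idx <- match(genes, de_results$gene)
    data.frame(set_id = id, gene = genes,
               log2fc = de_results$log2fc[idx],
               q_value = de_results$q_value[idx],
               measured = !is.na(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
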
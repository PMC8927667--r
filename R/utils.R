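#' Geometric mean
#'
#' @param x numeric vector, all values > 0.
#' @return exp(mean(log(x))).
#' @keywords internal
geomean <- function(x) {
  if (any(x <= 0)) stop("geomean() requires strictly positive values")
  exp(mean(log(x)))
}

#' Round half away from zero
#'
#' Commercial rounding: 2.5 -> 3, -2.5 -> -3. Distinct from R's `round()`,
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' log2(count + 1) transform
#' @param x numeric; counts.
#' @keywords internal
log2p1 <- function(x) log2(x + 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as TSV with stable formatting
#' @keywords internal
write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
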
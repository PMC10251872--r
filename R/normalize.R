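#' Log2 counts-per-million transform
#'
#' Converts an RNA-seq count matrix to log2 CPM:
#' \code{log2(count / column_sum * 1e6 + pseudocount)}.  A count of 0 with the
#' default pseudocount of 1 maps to exactly 0, and rescaling a whole library
#' leaves its CPM values unchanged.
#'
#' @param counts non-negative numeric matrix, genes/probes in rows, samples in
#'   columns.
#' @param pseudocount positive value added to CPM before the log; default 1.
#' @return numeric matrix of the same shape on the log2 scale.
#' @export
log2_cpm <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0, na.rm = TRUE)) {
    stop_invalid("`counts` must be a non-negative numeric matrix")
  }
  if (any(is.na(counts))) stop_invalid("`counts` must not contain NA")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop_invalid("`pseudocount` must be a single positive number")
  }
  libsize <- colSums(counts)
  bad <- which(libsize == 0)
  if (length(bad)) {
    nm <- colnames(counts)[bad] %||% as.character(bad)
    stop_invalid("degenerate sample(s) with zero library size: ",
                 paste(nm, collapse = ", "))
  }
  cpm <- sweep(counts, 2L, libsize, "/") * 1e6
  log2(cpm + pseudocount)
}

#' Quantile normalization
#'
#' Forces every column (sample) to share the same empirical distribution: the
#' row-wise mean of the sorted columns.  Ties within a column share the mean
#' of their target quantiles.  Delegates to
#' \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param values numeric matrix without missing values.
#' @return normalized matrix of the same shape with dimnames preserved.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_invalid("`values` must be numeric")
  if (any(is.na(values))) {
    stop_invalid("`values` must not contain missing values; impute or drop first")
  }
  if (ncol(values) == 1L) {
    warning("single-column input: quantile normalization is the identity")
    return(values)
  }
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}
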
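#' Chi-square category enrichment test
#'
#' Compares the proportion of significant genes falling in a category
#' (`k_sig / n_sig`) against the chip-wide reference proportion
#' (`k_chip / n_chip`) with a one-degree-of-freedom Pearson chi-square on
#' the category-vs-rest 2x2 table, and reports the negative log of the
#' p-value as the enrichment score.
#'
#' @param k_sig significant genes in the category.
#' @param n_sig total significant genes.
#' @param k_chip chip genes in the category.
#' @param n_chip total genes on the chip.
#' @param log_base base of the negative-log score; default 10.
#' @param correct apply the Yates continuity correction; default `FALSE`.
#' @param category optional category id carried into the result.
#' @return one-row data.frame of class `enrichment_result`: category, k_sig,
#'   n_sig, k_chip, n_chip, chi2, p, score, flagged (TRUE when a zero
#'   expected count forced p = 1).
#' @export
enrichment_test <- function(k_sig, n_sig, k_chip, n_chip,
                            log_base = 10, correct = FALSE,
                            category = NA_character_) {
  cnt <- c(k_sig, n_sig, k_chip, n_chip)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop_invalid("counts must be non-negative integers")
  }
  if (n_sig <= 0 || n_chip <= 0) stop_invalid("totals must be positive")
  if (k_sig > n_sig || k_chip > n_chip || k_sig > k_chip) {
    stop_invalid("inconsistent counts: need k_sig <= n_sig, k_chip <= n_chip, ",
                 "k_sig <= k_chip")
  }
  tab <- rbind(sig = c(k_sig, n_sig - k_sig),
               chip = c(k_chip, n_chip - k_chip))
  flagged <- any(colSums(tab) == 0)
  if (flagged) {
    chi2 <- 0; p <- 1
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    chi2 <- unname(ht$statistic)
    p <- unname(ht$p.value)
  }
  score <- if (p > 0) -log(p, base = log_base) else Inf
  if (p >= 1) score <- 0
  structure(
    data.frame(category = category, k_sig = k_sig, n_sig = n_sig,
               k_chip = k_chip, n_chip = n_chip, chi2 = chi2, p = p,
               score = score, flagged = flagged, stringsAsFactors = FALSE),
    class = c("enrichment_result", "data.frame")
  )
}

#' Enrichment scores for every category
#'
#' Runs [enrichment_test()] on each category of a collection against the
#' chip universe and returns the results ranked by score (ties broken by
#' category name).
#'
#' @param sig_genes character set of significant genes; must be a subset of
#'   `chip_genes`.
#' @param categories a [pathway_collection()] (or named list of gene sets).
#' @param chip_genes character set of all genes on the platform.
#' @param ... passed to [enrichment_test()] (`log_base`, `correct`).
#' @return data.frame, one row per category, sorted by decreasing score.
#' @export
enrich_all <- function(sig_genes, categories, chip_genes, ...) {
  sig_genes <- unique(as.character(sig_genes))
  chip_genes <- unique(as.character(chip_genes))
  off <- setdiff(sig_genes, chip_genes)
  if (length(off)) {
    stop_invalid("significant gene(s) absent from the chip universe: ",
                 paste(off, collapse = ", "))
  }
  if (!length(chip_genes)) stop_invalid("empty chip universe")
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], chip_genes)
    if (!length(sig_genes)) {
      # nothing significant: every category scores 0 by convention
      return(data.frame(category = nm, k_sig = 0L, n_sig = 0L,
                        k_chip = length(cat_genes),
                        n_chip = length(chip_genes), chi2 = 0, p = 1,
                        score = 0, flagged = FALSE, stringsAsFactors = FALSE))
    }
    enrichment_test(length(intersect(cat_genes, sig_genes)),
                    length(sig_genes),
                    length(cat_genes), length(chip_genes),
                    category = nm, ...)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
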
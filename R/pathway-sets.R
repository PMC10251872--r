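#' Call differentially expressed pathways
#'
#' Filters a gene-set results table to entries with `q <= fdr_max` and
#' `|fc| >= min_abs_fc`, annotates each with its direction, and orders
#' deterministically by q then pathway name.  Discovery used FDR 0.05 with a
#' 2-fold-change floor; replication used FDR alone (`min_abs_fc = 1`).
#'
#' @param results data.frame from [fit_gene_sets()] (needs columns
#'   `pathway`, `fc`, `q`).
#' @param fdr_max FDR threshold.
#' @param min_abs_fc minimum absolute signed fold change; must be `>= 1`.
#' @param contrast optional contrast name stored on the list.
#' @return a `diff_pathway_list`: data.frame (pathway, fc, q, direction)
#'   with attributes `contrast` and `thresholds`.
#' @export
call_differential <- function(results, fdr_max = 0.05, min_abs_fc = 2,
                              contrast = NA_character_) {
  if (!all(c("pathway", "fc", "q") %in% names(results))) {
    stop_invalid("`results` needs columns pathway, fc, q")
  }
  if (!is.finite(fdr_max) || fdr_max < 0 || fdr_max > 1) {
    stop_invalid("`fdr_max` must be in [0, 1]")
  }
  if (!is.finite(min_abs_fc) || min_abs_fc < 1) {
    stop_invalid("`min_abs_fc` < 1 is invalid under the signed convention")
  }
  keep <- !is.na(results$q) & results$q <= fdr_max &
    abs(results$fc) >= min_abs_fc
  out <- results[keep, c("pathway", "fc", "q"), drop = FALSE]
  out$direction <- ifelse(out$fc >= 1, "up", "down")
  out <- out[order(out$q, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("diff_pathway_list", "data.frame"),
            contrast = contrast,
            thresholds = c(fdr_max = fdr_max, min_abs_fc = min_abs_fc))
}

#' @export
print.diff_pathway_list <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("Differential pathways (", attr(x, "contrast"), "): ", nrow(x),
      " at FDR <= ", th["fdr_max"], ", |FC| >= ", th["min_abs_fc"], "\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Venn partition of differential-pathway lists
#'
#' Computes the exact region memberships of 2-4 differential-pathway lists:
#' for every non-empty subset of lists, the pathways found in exactly those
#' lists.  Regions are disjoint and their counts sum to the size of the
#' union.
#'
#' @param lists named list of 2-4 `diff_pathway_list` objects (or data
#'   frames with a `pathway` column, or plain character vectors).
#' @return object of class `venn_partition`: list with `lists` (the input
#'   names), `members` (region key -> pathway ids, keys like "A&B"),
#'   `counts`, and `sets` (the input memberships).
#' @export
venn_partition <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L || length(lists) > 4L) {
    stop_invalid("need 2-4 named lists")
  }
  if (is.null(names(lists)) || any(names(lists) == "")) {
    stop_invalid("lists must be named")
  }
  sets <- lapply(lists, function(l) {
    ids <- if (is.data.frame(l)) l$pathway else as.character(l)
    if (anyDuplicated(ids)) stop_invalid("duplicate pathway within one list")
    ids
  })
  nms <- names(sets)
  universe <- sort(unique(unlist(sets)))
  member_of <- vapply(sets, function(s) universe %in% s,
                      logical(length(universe)))
  if (length(universe) == 1L) member_of <- matrix(member_of, nrow = 1L)
  key <- apply(member_of, 1L, function(r) paste(nms[r], collapse = "&"))
  members <- split(universe, key)
  # order regions by subset size then name, for stable output
  ord <- order(vapply(strsplit(names(members), "&", fixed = TRUE), length, 0L),
               names(members))
  members <- members[ord]
  structure(
    list(lists = nms, members = members,
         counts = vapply(members, length, 0L), sets = sets),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of ", length(x$lists), " lists (",
      paste(x$lists, collapse = ", "), ")\n", sep = "")
  for (k in names(x$counts)) cat(sprintf("  %-40s %d\n", k, x$counts[[k]]))
  invisible(x)
}

#' Overlap percentage between two lists of a partition
#'
#' `100 * |of ∩ in| / |of|`, the headline quantity of the intersection
#' analysis (e.g. 43 of 53 inflammation pathways also differential in
#' carcinoma: 81%).  Returns full precision; round for display.
#'
#' @param partition a [venn_partition()].
#' @param of_list,in_list names of the two lists.
#' @return percentage (numeric scalar, full precision).
#' @export
overlap_percentage <- function(partition, of_list, in_list) {
  stopifnot(inherits(partition, "venn_partition"))
  for (nm in c(of_list, in_list)) {
    if (!nm %in% partition$lists) stop_invalid("unknown list: ", nm)
  }
  of <- partition$sets[[of_list]]
  if (!length(of)) stop_invalid("overlap percentage undefined for empty list")
  100 * length(intersect(of, partition$sets[[in_list]])) / length(of)
}

#' Direction concordance of two differential-pathway lists
#'
#' Fraction of pathways shared by both lists that carry the same direction
#' (up/down) in each.
#'
#' @param listA,listB `diff_pathway_list` objects.
#' @return fraction in \eqn{[0, 1]}.
#' @export
direction_concordance <- function(listA, listB) {
  for (l in list(listA, listB)) {
    if (!all(c("pathway", "direction") %in% names(l))) {
      stop_invalid("lists need pathway and direction columns")
    }
  }
  shared <- intersect(listA$pathway, listB$pathway)
  if (!length(shared)) stop_invalid("concordance undefined: empty intersection")
  dA <- listA$direction[match(shared, listA$pathway)]
  dB <- listB$direction[match(shared, listB$pathway)]
  mean(dA == dB)
}
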
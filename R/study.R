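#' Expression study container
#'
#' Bundles a probe-by-sample log2 expression matrix with a probe-to-gene map
#' and per-sample metadata.  Validates that sample ids are unique, that every
#' matrix column has a metadata row (and vice versa), and that person and
#' tissue jointly identify at most one sample.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids), log2 scale after transform.
#' @param samples data.frame with at least columns `sample_id`, `person_id`,
#'   `tissue` (levels "tumor"/"normal"); typically also `group`, `sex`,
#'   `stage`, `grade`, `MSI`, `KRAS`, `TIL`.
#' @param probe_to_gene named character vector mapping probe id to gene
#'   symbol; defaults to the identity map over rownames.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(values, samples, probe_to_gene = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_invalid("`values` needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop_invalid("duplicate probe ids")
  if (anyDuplicated(colnames(values))) stop_invalid("duplicate sample ids")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "person_id", "tissue")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop_invalid("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop_invalid("duplicate sample ids in metadata")
  extra <- setdiff(colnames(values), samples$sample_id)
  if (length(extra)) {
    stop_invalid("matrix sample(s) missing from metadata: ", paste(extra, collapse = ", "))
  }
  orphan <- setdiff(samples$sample_id, colnames(values))
  if (length(orphan)) {
    stop_invalid("metadata sample(s) missing from matrix: ", paste(orphan, collapse = ", "))
  }
  if (!all(samples$tissue %in% c("tumor", "normal"))) {
    stop_invalid("`tissue` must be 'tumor' or 'normal'")
  }
  if (anyDuplicated(samples[, c("person_id", "tissue")])) {
    stop_invalid("person and tissue must jointly identify at most one sample")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(probe_to_gene)) {
    probe_to_gene <- stats::setNames(rownames(values), rownames(values))
  }
  if (is.null(names(probe_to_gene)) ||
      !all(rownames(values) %in% names(probe_to_gene))) {
    stop_invalid("`probe_to_gene` must name every probe")
  }
  structure(
    list(values = values, samples = samples,
         probe_to_gene = probe_to_gene[rownames(values)]),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat("Expression study: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  persons: ", length(unique(x$samples$person_id)),
      "; tumor/normal: ", sum(x$samples$tissue == "tumor"), "/",
      sum(x$samples$tissue == "normal"), "\n", sep = "")
  if (!is.null(attr(x, "truth"))) cat("  (simulated; planted truth attached)\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Methylation study container
#'
#' Beta-value matrix (markers by samples, values in \eqn{[0,1]} or missing)
#' plus per-marker annotation (gene, functional group, relation to CpG
#' island) and the same sample metadata layout as [expression_study()].
#'
#' @param beta numeric matrix, markers in rows, samples in columns; values in
#'   \eqn{[0,1]} or `NA`.
#' @param annotation data.frame with columns `marker`, `gene`,
#'   `functional_group` (e.g. "promoter", "body", "other") and
#'   `relation_to_island` (one of "Island", "Shore", "Shelf", "OpenSea").
#'   Multi-gene markers separate symbols with ";".
#' @param samples sample metadata as in [expression_study()].
#' @return an object of class `methylation_study`.
#' @export
methylation_study <- function(beta, annotation, samples) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop_invalid("`beta` needs marker rownames and sample colnames")
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop_invalid("beta values must lie in [0, 1]")
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("marker", "gene", "functional_group", "relation_to_island")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) stop_invalid("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (!all(rownames(beta) %in% annotation$marker)) {
    stop_invalid("every marker must be annotated")
  }
  ok_rel <- c("Island", "Shore", "Shelf", "OpenSea")
  if (!all(annotation$relation_to_island %in% ok_rel)) {
    stop_invalid("relation_to_island must be one of ", paste(ok_rel, collapse = ", "))
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!setequal(colnames(beta), samples$sample_id)) {
    stop_invalid("beta columns and metadata sample ids must match")
  }
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  annotation <- annotation[match(rownames(beta), annotation$marker), , drop = FALSE]
  rownames(annotation) <- NULL
  structure(list(beta = beta, annotation = annotation, samples = samples),
            class = "methylation_study")
}

#' @export
print.methylation_study <- function(x, ...) {
  cat("Methylation study: ", nrow(x$beta), " markers x ", ncol(x$beta),
      " samples\n", sep = "")
  tab <- table(x$annotation$relation_to_island)
  cat("  relation to island: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pathway collection (named gene sets)
#'
#' @param sets named list of character vectors of member gene symbols.
#' @return object of class `pathway_collection`.
#' @seealso [read_gmt()], [write_gmt()]
#' @export
pathway_collection <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop_invalid("`sets` must be a fully named list of gene vectors")
  }
  if (anyDuplicated(names(sets))) stop_invalid("duplicate pathway names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  structure(sets, class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- lengths(x)
  cat("Pathway collection: ", length(x), " sets, sizes ",
      min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' @export
`[.pathway_collection` <- function(x, i) {
  pathway_collection(unclass(x)[i])
}
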
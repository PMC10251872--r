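#' Methylation score (beta value) from probe intensities
#'
#' `beta = X / (X + Y)` where X is the methylated and Y the unmethylated
#' channel intensity.  Fully unmethylated loci (X = 0) score 0, fully
#' methylated loci (Y = 0) score 1, and an equal split scores 0.5.  A locus
#' with both intensities zero has no information: it becomes a missing
#' value, counted and reported via a message rather than an error.
#'
#' @param X,Y non-negative numeric vectors or matrices of equal shape.
#' @return beta values in \eqn{[0, 1]} (`NA` where `X + Y == 0`), preserving
#'   matrix shape.
#' @export
#' @examples
#' beta_from_intensities(50, 50)   # 0.5
#' beta_from_intensities(0, 120)   # 0
#' beta_from_intensities(80, 0)    # 1
beta_from_intensities <- function(X, Y) {
  if (any(dim(X) != dim(Y)) || length(X) != length(Y)) {
    stop_invalid("`X` and `Y` must have the same shape")
  }
  if (any(!is.finite(X) & !is.na(X)) || any(X < 0, na.rm = TRUE) ||
      any(!is.finite(Y) & !is.na(Y)) || any(Y < 0, na.rm = TRUE)) {
    stop_invalid("intensities must be finite and non-negative")
  }
  total <- X + Y
  beta <- X / total
  zero <- which(total == 0)
  if (length(zero)) {
    beta[zero] <- NA_real_
    message(length(zero), " locus/loci with zero total intensity set to NA")
  }
  beta
}

#' Filter methylation markers by annotation category
#'
#' Retains markers outside the excluded island-relation categories and (when
#' given) inside the kept functional groups.  The chip-wide convention drops
#' open-sea markers; the promoter analysis further restricts to
#' promoter-associated markers in CpG islands
#' (`exclude_relations = c("Shore", "Shelf", "OpenSea"),
#' keep_functional = "promoter"`).  Counts of removed markers per category
#' are reported via messages.
#'
#' @param study a [methylation_study()].
#' @param exclude_relations island-relation categories to drop.
#' @param keep_functional functional groups to keep; `NULL` keeps all.
#' @return the filtered [methylation_study()].
#' @export
filter_markers <- function(study, exclude_relations = character(0),
                           keep_functional = NULL) {
  stopifnot(inherits(study, "methylation_study"))
  ann <- study$annotation
  vocab_rel <- c("Island", "Shore", "Shelf", "OpenSea")
  bad <- setdiff(exclude_relations, vocab_rel)
  if (length(bad)) stop_invalid("unknown relation categories: ",
                                paste(bad, collapse = ", "))
  if (!is.null(keep_functional)) {
    bad <- setdiff(keep_functional, unique(ann$functional_group))
    if (length(bad)) stop_invalid("unknown functional groups: ",
                                  paste(bad, collapse = ", "))
  }
  keep <- !(ann$relation_to_island %in% exclude_relations)
  if (length(exclude_relations)) {
    drops <- table(ann$relation_to_island[!keep])
    if (length(drops)) {
      message("removed by relation: ",
              paste(names(drops), drops, sep = "=", collapse = ", "))
    }
  }
  if (!is.null(keep_functional)) {
    fkeep <- ann$functional_group %in% keep_functional
    drops <- table(ann$functional_group[keep & !fkeep])
    if (length(drops)) {
      message("removed by functional group: ",
              paste(names(drops), drops, sep = "=", collapse = ", "))
    }
    keep <- keep & fkeep
  }
  if (!any(keep)) stop_invalid("filter removed all markers")
  methylation_study(study$beta[ann$marker[keep], , drop = FALSE],
                    ann[keep, , drop = FALSE], study$samples)
}

#' Classify a delta-beta value as hyper- or hypo-methylation
#'
#' Positive tumor-minus-normal delta-beta reflects hyper-methylation,
#' negative hypo-methylation.  An exact zero is labelled "hypo" by
#' convention and flagged as a boundary case via the `boundary` attribute.
#'
#' @param delta_beta finite numeric vector of tumor-minus-normal beta
#'   differences.
#' @return character vector of "hyper"/"hypo" with a logical `boundary`
#'   attribute.
#' @export
classify_direction <- function(delta_beta) {
  if (any(!is.finite(delta_beta))) stop_invalid("`delta_beta` must be finite")
  out <- ifelse(delta_beta > 0, "hyper", "hypo")
  attr(out, "boundary") <- delta_beta == 0
  out
}

#' Promoter delta-beta gene-set analysis
#'
#' Applies the gene-set mixed ANOVA to beta values (untransformed, as the
#' models use the beta value directly as the response) with markers nested
#' in genes: fixed tissue and marker-baseline effects, random person and
#' sample effects with method-of-moments components.  The set-level
#' delta-beta is the unweighted mean of the member genes' tumor effects in
#' beta units.  Missing betas are dropped observation-wise.  Typically run
#' after [filter_markers()] has restricted the study to promoter-associated
#' island markers.
#'
#' @param study a [methylation_study()] with a paired design.
#' @param pathway character vector of member gene symbols.
#' @param name pathway id carried into the result.
#' @param level confidence level.
#' @return object of class `delta_beta_fit`: `delta_beta`, `se`, `df`, `p`,
#'   `direction`, the per-gene table, and variance components.
#' @export
delta_beta_gene_set <- function(study, pathway, name = NA_character_,
                                level = 0.95) {
  stopifnot(inherits(study, "methylation_study"))
  pathway <- as.character(pathway)
  ann <- study$annotation
  gene_lists <- strsplit(ann$gene, ";", fixed = TRUE)
  hits <- lapply(seq_along(gene_lists), function(i) {
    intersect(gene_lists[[i]], pathway)
  })
  idx <- which(lengths(hits) > 0)
  genes_present <- unique(unlist(hits[idx]))
  if (length(genes_present) < 2L) {
    stop_invalid("pathway '", name, "' has ", length(genes_present),
                 " member gene(s) with retained markers; need >= 2 (skipped)")
  }
  s <- study$samples
  rows <- list()
  for (i in idx) {
    for (g in hits[[i]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        y = study$beta[ann$marker[i], ],
        feature = ann$marker[i], gene = g,
        sample_id = s$sample_id, person = s$person_id, tissue = s$tissue,
        stringsAsFactors = FALSE
      )
    }
  }
  obs <- do.call(rbind, rows)
  obs <- obs[is.finite(obs$y), , drop = FALSE]
  out <- fit_set_stacked(obs, level = level, id = name,
                         effect_name = "delta_beta")
  q_t <- stats::qt(1 - (1 - level) / 2, df = out$df)
  structure(
    list(pathway = name, n_genes = out$n_genes,
         n_markers = length(unique(obs$feature)),
         delta_beta = out$d_bar, se = out$se, df = out$df, F = out$F,
         p = out$p, q = NA_real_,
         ci = c(out$d_bar - q_t * out$se, out$d_bar + q_t * out$se),
         direction = classify_direction(out$d_bar),
         per_gene = out$per_gene, variance_components = out$varcomp,
         n_obs = out$n_obs, level = level),
    class = "delta_beta_fit"
  )
}

#' Delta-beta analysis for every pathway of a collection
#'
#' @param study a (filtered) [methylation_study()].
#' @param collection a [pathway_collection()].
#' @param level confidence level.
#' @return data.frame (pathway, n_genes, n_markers, delta_beta, se, df, p,
#'   q, direction); skipped pathways in `attr(result, "skipped")`.
#' @export
delta_beta_gene_sets <- function(study, collection, level = 0.95) {
  stopifnot(inherits(collection, "pathway_collection"))
  rows <- list(); skipped <- character(0)
  for (nm in names(collection)) {
    f <- tryCatch(delta_beta_gene_set(study, collection[[nm]], name = nm,
                                      level = level),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      skipped[nm] <- f
      next
    }
    rows[[nm]] <- data.frame(
      pathway = nm, n_genes = f$n_genes, n_markers = f$n_markers,
      delta_beta = f$delta_beta, se = f$se, df = f$df, p = f$p,
      direction = as.character(f$direction), stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop_invalid("no pathway could be analyzed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- benjamini_hochberg(out$p)
  out <- out[, c("pathway", "n_genes", "n_markers", "delta_beta", "se", "df",
                 "p", "q", "direction")]
  if (length(skipped)) attr(out, "skipped") <- skipped
  out
}
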
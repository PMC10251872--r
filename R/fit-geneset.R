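# Gene-set (pathway-level) mixed ANOVA: observations from all member
# probes/markers are stacked and modeled as
#   y = mu + tissue + gene/feature baseline + person + sample(tissue x person) + error
# with person and sample random (method-of-moments components).  The analysis
# is performed at the gene level and expressed at the set level by averaging
# the member genes' tumor effects; the contrast variance comes from the
# stacked model and so accounts for the shared sample effect.

# obs: data.frame(y, feature, gene, sample_id, person, tissue), NA rows removed
fit_set_stacked <- function(obs, level = 0.95, id = NA_character_,
                            effect_name = "d") {
  genes_used <- sort(unique(obs$gene))
  # per-gene effects via the same paired machinery (feature baselines
  # absorbed when a gene has several features)
  per_gene <- vapply(genes_used, function(g) {
    o <- obs[obs$gene == g, , drop = FALSE]
    X <- indicator_matrix(o$feature)
    X <- cbind(X, tumor = as.numeric(o$tissue == "tumor"))
    Zp <- indicator_matrix(o$person)
    f <- mom_mixed_fit(o$y, X, list(person = Zp),
                       contrast = c(rep(0, ncol(X) - 1L), 1))
    f$effect
  }, 0)
  d_bar <- mean(per_gene)

  X <- indicator_matrix(obs$feature)
  X <- cbind(X, tumor = as.numeric(obs$tissue == "tumor"))
  Zp <- indicator_matrix(obs$person)
  Zs <- indicator_matrix(obs$sample_id)
  fit <- mom_mixed_fit(obs$y, X, list(person = Zp, sample = Zs),
                       contrast = c(rep(0, ncol(X) - 1L), 1))
  se <- fit$se
  df <- fit$df
  Fstat <- if (se > 0) (d_bar / se)^2 else if (abs(d_bar) > 0) Inf else 0
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  list(id = id, n_genes = length(genes_used),
       per_gene = data.frame(gene = genes_used, d = unname(per_gene),
                             stringsAsFactors = FALSE),
       d_bar = d_bar, se = se, df = df, F = Fstat, p = p,
       varcomp = fit$varcomp, n_obs = nrow(obs), level = level,
       effect_name = effect_name)
}

#' Gene-set mixed ANOVA for a pathway
#'
#' Stacks the observations of all member probes over all samples and fits
#' the set-level mixed model with tissue and gene/probe baselines fixed and
#' person and sample (nested in tissue-by-person) random, estimating the
#' variance components by method of moments.  The set-level effect is the
#' unweighted mean of the member genes' tumor effects; its standard error
#' comes from the stacked model's tissue contrast, so genes sharing a sample
#' are not treated as independent.
#'
#' @param study an [expression_study()] with a paired design.
#' @param pathway character vector of member gene symbols (one element of a
#'   [pathway_collection()]).
#' @param name pathway id carried into the result.
#' @param level confidence level for the fold-change interval.
#' @return object of class `gene_set_fit` with the set effect `d_bar`,
#'   signed `fc` with `fc_ci`, F/p, variance components, and the per-gene
#'   contribution table.
#' @export
fit_gene_set_model <- function(study, pathway, name = NA_character_,
                               level = 0.95) {
  stopifnot(inherits(study, "expression_study"))
  pathway <- as.character(pathway)
  probes <- rownames(study$values)[study$probe_to_gene %in% pathway]
  genes_present <- unique(unname(study$probe_to_gene[probes]))
  if (length(genes_present) < 2L) {
    stop_invalid("pathway '", name, "' has ", length(genes_present),
                 " member gene(s) on the platform; need >= 2 (skipped)")
  }
  s <- study$samples
  n_s <- nrow(s)
  obs <- data.frame(
    y = as.vector(study$values[probes, , drop = FALSE]),
    feature = rep(probes, times = n_s),
    gene = rep(unname(study$probe_to_gene[probes]), times = n_s),
    sample_id = rep(s$sample_id, each = length(probes)),
    person = rep(s$person_id, each = length(probes)),
    tissue = rep(s$tissue, each = length(probes)),
    stringsAsFactors = FALSE
  )
  obs <- obs[is.finite(obs$y), , drop = FALSE]
  out <- fit_set_stacked(obs, level = level, id = name)
  fc <- fold_change_from_log2(out$d_bar)
  ci <- if (out$se > 0) fc_confidence_interval(out$d_bar, out$se, out$df, level)
        else c(fc, fc)
  structure(
    list(pathway = name, n_genes = out$n_genes, d_bar = out$d_bar,
         se = out$se, df = out$df, F = out$F, p = out$p, q = NA_real_,
         fc = fc, fc_ci = ci, per_gene = out$per_gene,
         variance_components = out$varcomp, n_obs = out$n_obs, level = level),
    class = "gene_set_fit"
  )
}

#' Fit every pathway of a collection
#'
#' Applies [fit_gene_set_model()] to each gene set, adjusts p-values by
#' Benjamini-Hochberg across the fitted pathways, and records skipped
#' pathways (fewer than 2 member genes on the platform) with their reasons
#' in `attr(result, "skipped")`.
#'
#' @param study an [expression_study()].
#' @param collection a [pathway_collection()].
#' @param level confidence level for fold-change intervals.
#' @return data.frame with columns pathway, n_genes, d, se, df, F, p, q, fc,
#'   fc_lo, fc_hi, n_used.
#' @export
fit_gene_sets <- function(study, collection, level = 0.95) {
  stopifnot(inherits(collection, "pathway_collection"))
  rows <- list(); skipped <- character(0)
  for (nm in names(collection)) {
    f <- tryCatch(fit_gene_set_model(study, collection[[nm]], name = nm,
                                     level = level),
                  error = function(e) conditionMessage(e))
    if (is.character(f)) {
      skipped[nm] <- f
      next
    }
    rows[[nm]] <- data.frame(
      pathway = nm, n_genes = f$n_genes, d = f$d_bar, se = f$se, df = f$df,
      F = f$F, p = f$p, fc = f$fc, fc_lo = f$fc_ci[1L], fc_hi = f$fc_ci[2L],
      n_used = f$n_obs, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop_invalid("no pathway could be fitted")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- benjamini_hochberg(out$p)
  out <- out[, c("pathway", "n_genes", "d", "se", "df", "F", "p", "q",
                 "fc", "fc_lo", "fc_hi", "n_used")]
  if (length(skipped)) attr(out, "skipped") <- skipped
  out
}
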
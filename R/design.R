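#' Simulation design for a paired expression study
#'
#' Describes a paired tumor/normal cohort with the exact hierarchical
#' structure the mixed models assume: a grand mean, per-gene baselines,
#' pathway-driven tumor effects (optionally modified per stratum level),
#' person-level random effects, sample-level random effects nested in person
#' and tissue, and independent Gaussian error — all on the log2 scale.
#'
#' @param n_persons total number of persons; may be omitted when `groups`
#'   is given.
#' @param groups named integer vector of persons per diagnosis group, e.g.
#'   `c(sporadic_CRC = 8, UC_CRC = 10)`.
#' @param tissues_per_person character vector of tissue labels collected per
#'   person; at most one "tumor" and one "normal".
#' @param n_genes number of genes (one probe per gene; the fitters accept
#'   many-to-one probe maps).
#' @param pathways list of effect entries built with [pathway_effect()];
#'   empty list = null design (all tumor effects 0).
#' @param grand_mean grand mean on the log2 scale.
#' @param sd_person,sd_sample,sd_error standard deviations (log2 units) of
#'   the person effect, the nested sample effect, and the residual error;
#'   all `>= 0`.
#' @param gene_baseline_sd sd of per-gene baseline expression around the
#'   grand mean (log2 units).
#' @param strata named list of stratum assignment probabilities per person;
#'   each element a named probability vector summing to 1.
#' @param seed integer seed; a fixed seed gives bitwise-identical studies.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(n_persons = NULL,
                              groups = NULL,
                              tissues_per_person = c("tumor", "normal"),
                              n_genes = 100,
                              pathways = list(),
                              grand_mean = 5,
                              sd_person = 0.5,
                              sd_sample = 0.3,
                              sd_error = 0.5,
                              gene_baseline_sd = 1,
                              strata = default_strata(),
                              seed = 1) {
  if (is.null(groups)) {
    if (is.null(n_persons)) stop_invalid("give `n_persons` or `groups`")
    groups <- c(sporadic_CRC = as.integer(n_persons))
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop_invalid("`groups` must be a named vector of person counts")
  }
  if (any(groups < 1)) stop_invalid("group person counts must be positive")
  if (!is.null(n_persons) && sum(groups) != n_persons) {
    stop_invalid("`n_persons` disagrees with sum(groups)")
  }
  n_persons <- sum(groups)
  if (!all(tissues_per_person %in% c("tumor", "normal")) ||
      anyDuplicated(tissues_per_person)) {
    stop_invalid("`tissues_per_person` allows at most one tumor and one normal")
  }
  if (n_genes < 1) stop_invalid("`n_genes` must be positive")
  for (s in c(sd_person, sd_sample, sd_error, gene_baseline_sd)) {
    if (!is.finite(s) || s < 0) stop_invalid("sd fields must be >= 0")
  }
  for (nm in names(strata)) {
    p <- strata[[nm]]
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop_invalid("stratum '", nm, "' probabilities must be named and sum to 1")
    }
  }
  genes <- padded_ids("gene_", n_genes)
  for (pe in pathways) {
    if (!inherits(pe, "pathway_effect")) {
      stop_invalid("`pathways` entries must come from pathway_effect()")
    }
    if (!all(pe$genes %in% genes)) {
      stop_invalid("pathway '", pe$name, "' has members outside the gene universe")
    }
    if (!is.null(pe$interaction_factor) &&
        !pe$interaction_factor %in% names(strata)) {
      stop_invalid("interaction factor '", pe$interaction_factor,
                   "' is not a stratum")
    }
  }
  structure(
    list(n_persons = n_persons, groups = groups,
         tissues_per_person = tissues_per_person, n_genes = n_genes,
         genes = genes, pathways = pathways, grand_mean = grand_mean,
         sd_person = sd_person, sd_sample = sd_sample, sd_error = sd_error,
         gene_baseline_sd = gene_baseline_sd, strata = strata,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' Default person-level stratum assignment probabilities
#'
#' Sex, tumor stage (1-3), grade, MSI status, KRAS mutation and
#' tumor-infiltrating-leucocyte status, assigned independently per person.
#' @return named list of named probability vectors.
#' @export
default_strata <- function() {
  list(
    sex   = c(male = 0.5, female = 0.5),
    stage = c(`1` = 1 / 3, `2` = 1 / 3, `3` = 1 / 3),
    grade = c(low = 0.5, high = 0.5),
    MSI   = c(MSI = 0.3, MSS = 0.7),
    KRAS  = c(mutant = 0.4, wild = 0.6),
    TIL   = c(present = 0.5, absent = 0.5)
  )
}

#' Pathway effect entry for a simulation design
#'
#' @param name pathway name.
#' @param genes member gene ids (subset of the design's gene universe).
#' @param tumor_log2_effect log2 tumor-minus-normal shift applied to member
#'   genes in tumor samples (e.g. -1 = 2-fold down).
#' @param interaction_factor optional stratum name (e.g. "stage") whose
#'   levels modify the tumor effect.
#' @param interaction_deltas named numeric of per-level additive deltas on
#'   the log2 tumor effect; required when `interaction_factor` is set.
#' @return object of class `pathway_effect`.
#' @export
pathway_effect <- function(name, genes, tumor_log2_effect,
                           interaction_factor = NULL,
                           interaction_deltas = NULL) {
  if (!is.character(name) || length(name) != 1L) stop_invalid("bad pathway name")
  if (!length(genes)) stop_invalid("pathway needs member genes")
  if (!is.finite(tumor_log2_effect)) stop_invalid("bad tumor_log2_effect")
  if (!is.null(interaction_factor) && is.null(interaction_deltas)) {
    stop_invalid("interaction_deltas required with interaction_factor")
  }
  structure(list(name = name, genes = unique(as.character(genes)),
                 tumor_log2_effect = tumor_log2_effect,
                 interaction_factor = interaction_factor,
                 interaction_deltas = interaction_deltas),
            class = "pathway_effect")
}

#' Methylation simulation design
#'
#' 450K-style marker layout: a mean number of markers per gene (default 17),
#' a mix of relations to the nearest CpG island (Island / Shore 0-2 kb /
#' Shelf 2-4 kb / OpenSea >4 kb), a functional-group mix, and optional
#' promoter hyper-methylation effects on selected pathways.  Beta values are
#' generated through Gamma-distributed methylated/unmethylated intensity
#' pairs, so they are naturally bounded in \eqn{[0,1]}.
#'
#' @param markers_per_gene mean markers per gene (default 17).
#' @param relation_mix named proportions over
#'   `c(Island, Shore, Shelf, OpenSea)`; defaults follow the 450K chip-wide
#'   category counts.
#' @param functional_mix named proportions over
#'   `c(promoter, body, other)`.
#' @param hyper_pathways named numeric: pathway name -> delta-beta effect in
#'   (-1, 1) applied to that pathway's promoter-island markers in tumor
#'   tissue.  Membership is taken from the paired expression design.
#' @param intensity_scale arbitrary intensity units for the stored
#'   methylated/unmethylated channels.
#' @param precision Beta-distribution concentration of marker-level beta
#'   values around their target mean (larger = tighter).
#' @param sd_person_logit sd of a person-level shift on the logit of the
#'   marker mean, giving within-person correlation of betas.
#' @param seed integer seed.
#' @return object of class `methylation_design`.
#' @export
methylation_design <- function(markers_per_gene = 17,
                               relation_mix = c(Island = 0.31, Shore = 0.23,
                                                Shelf = 0.10, OpenSea = 0.36),
                               functional_mix = c(promoter = 0.4, body = 0.4,
                                                  other = 0.2),
                               hyper_pathways = numeric(0),
                               intensity_scale = 1000,
                               precision = 30,
                               sd_person_logit = 0.3,
                               seed = 1) {
  if (markers_per_gene < 1) stop_invalid("`markers_per_gene` must be >= 1")
  for (mx in list(relation_mix, functional_mix)) {
    if (is.null(names(mx)) || any(mx < 0) || abs(sum(mx) - 1) > 1e-8) {
      stop_invalid("mix proportions must be named, non-negative, and sum to 1")
    }
  }
  if (!setequal(names(relation_mix), c("Island", "Shore", "Shelf", "OpenSea"))) {
    stop_invalid("relation_mix must cover Island/Shore/Shelf/OpenSea")
  }
  if (length(hyper_pathways)) {
    if (is.null(names(hyper_pathways))) stop_invalid("hyper_pathways must be named")
    if (any(abs(hyper_pathways) >= 1)) {
      stop_invalid("delta-beta effects must lie in (-1, 1)")
    }
  }
  if (intensity_scale <= 0 || precision <= 0) {
    stop_invalid("intensity_scale and precision must be positive")
  }
  structure(
    list(markers_per_gene = markers_per_gene, relation_mix = relation_mix,
         functional_mix = functional_mix, hyper_pathways = hyper_pathways,
         intensity_scale = intensity_scale, precision = precision,
         sd_person_logit = sd_person_logit, seed = as.integer(seed)),
    class = "methylation_design"
  )
}
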
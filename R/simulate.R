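#' Generate random (possibly overlapping) gene sets
#'
#' Stand-in for curated pathway definitions: draws `n_pathways` sets of
#' `genes_per_pathway` members uniformly without replacement from a gene
#' universe `gene_001 ... gene_N`.  Deterministic under `seed`.
#'
#' @param n_genes size of the gene universe.
#' @param n_pathways number of sets.
#' @param genes_per_pathway members per set; `<= n_genes`.
#' @param seed integer seed.
#' @return a [pathway_collection()].
#' @export
generate_pathways <- function(n_genes, n_pathways, genes_per_pathway, seed = 1) {
  if (n_genes < 1 || n_pathways < 1 || genes_per_pathway < 1) {
    stop_invalid("counts must be positive")
  }
  if (genes_per_pathway > n_genes) {
    stop_invalid("genes_per_pathway exceeds the gene universe")
  }
  genes <- padded_ids("gene_", n_genes)
  with_seed(seed, {
    sets <- lapply(seq_len(n_pathways), function(i) {
      sort(sample(genes, genes_per_pathway))
    })
    names(sets) <- padded_ids("PW_", n_pathways)
    pathway_collection(sets)
  })
}

# person/sample layout shared by the expression and methylation generators;
# must be the first thing drawn under the design seed so both generators
# agree on it
build_layout <- function(design) {
  persons <- padded_ids("person_", design$n_persons)
  group <- rep(names(design$groups), design$groups)
  strata <- lapply(design$strata, function(p) {
    sample(names(p), design$n_persons, replace = TRUE, prob = p)
  })
  tissues <- design$tissues_per_person
  samples <- data.frame(
    sample_id = paste0(rep(persons, each = length(tissues)), "_",
                       rep(tissues, times = design$n_persons)),
    person_id = rep(persons, each = length(tissues)),
    tissue = rep(tissues, times = design$n_persons),
    group = rep(group, each = length(tissues)),
    stringsAsFactors = FALSE
  )
  for (nm in names(strata)) {
    samples[[nm]] <- rep(strata[[nm]], each = length(tissues))
  }
  samples
}

# per-gene tumor effect for each sample, given the design's pathway effects;
# overlapping pathways add up
true_effect_matrix <- function(design, samples) {
  eff <- matrix(0, design$n_genes, nrow(samples),
                dimnames = list(design$genes, samples$sample_id))
  tumor <- samples$tissue == "tumor"
  for (pe in design$pathways) {
    delta <- rep(pe$tumor_log2_effect, nrow(samples))
    if (!is.null(pe$interaction_factor)) {
      lev <- samples[[pe$interaction_factor]]
      add <- pe$interaction_deltas[lev]
      add[is.na(add)] <- 0
      delta <- delta + add
    }
    delta[!tumor] <- 0
    eff[pe$genes, ] <- eff[pe$genes, , drop = FALSE] +
      matrix(delta, length(pe$genes), nrow(samples), byrow = TRUE)
  }
  eff
}

#' Simulate a paired tumor/normal expression study
#'
#' Draws a log2-scale probe-by-sample matrix from exactly the decomposition
#' the mixed models assume: grand mean + gene baseline + pathway-driven
#' tumor effect (with any stratum-by-tumor interaction) + person effect
#' N(0, sd_person^2) + nested sample effect N(0, sd_sample^2) + error
#' N(0, sd_error^2).  The returned study carries the planted truth in
#' `attr(study, "truth")` for recovery tests.
#'
#' @param design a [simulation_design()].
#' @return an [expression_study()] with a `truth` attribute (list with the
#'   gene baselines, per-gene/sample tumor effect matrix, and the drawn
#'   person and sample effects).
#' @export
simulate_expression_study <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, {
    samples <- build_layout(design)
    n_s <- nrow(samples)
    baseline <- stats::rnorm(design$n_genes, 0, design$gene_baseline_sd)
    person_eff <- stats::rnorm(design$n_persons, 0, design$sd_person)
    names(person_eff) <- unique(samples$person_id)
    sample_eff <- stats::rnorm(n_s, 0, design$sd_sample)
    names(sample_eff) <- samples$sample_id
    err <- matrix(stats::rnorm(design$n_genes * n_s, 0, design$sd_error),
                  design$n_genes, n_s)
    eff <- true_effect_matrix(design, samples)
    values <- design$grand_mean + baseline + eff +
      matrix(person_eff[samples$person_id] + sample_eff, design$n_genes, n_s,
             byrow = TRUE) + err
    dimnames(values) <- list(design$genes, samples$sample_id)
    study <- expression_study(values, samples)
    attr(study, "truth") <- list(
      design = design, gene_baseline = stats::setNames(baseline, design$genes),
      tumor_effect = eff, person_effect = person_eff, sample_effect = sample_eff
    )
    study
  })
}

#' Simulate a 450K-style methylation study on a paired layout
#'
#' Shares the person/tissue layout of `expr_design` (same seed-determined
#' sample table).  Markers are assigned to genes (mean
#' `markers_per_gene` per gene), to an island-relation category and to a
#' functional group.  Marker-level beta values arise from Gamma-distributed
#' methylated/unmethylated intensity pairs, so `beta = X/(X+Y)` is naturally
#' in \eqn{[0,1]}; island markers are mostly unmethylated, open-sea markers
#' mostly methylated.  For pathways listed in `hyper_pathways`, the target
#' mean of their promoter-island markers is shifted by the delta-beta effect
#' in tumor samples.
#'
#' @param expr_design the paired [simulation_design()] providing persons,
#'   tissues, strata and pathway memberships.
#' @param meth_design a [methylation_design()].
#' @return a [methylation_study()] with a `truth` attribute.
#' @export
simulate_methylation_study <- function(expr_design, meth_design) {
  stopifnot(inherits(expr_design, "simulation_design"),
            inherits(meth_design, "methylation_design"))
  samples <- with_seed(expr_design$seed, build_layout(expr_design))
  hyper <- meth_design$hyper_pathways
  if (length(hyper)) {
    known <- vapply(expr_design$pathways, function(pe) pe$name, "")
    bad <- setdiff(names(hyper), known)
    if (length(bad)) {
      stop_invalid("hyper pathway(s) not in the expression design: ",
                   paste(bad, collapse = ", "))
    }
  }
  with_seed(meth_design$seed, {
    genes <- expr_design$genes
    n_per_gene <- 1L + stats::rpois(length(genes),
                                    max(meth_design$markers_per_gene - 1, 0))
    gene_of_marker <- rep(genes, n_per_gene)
    n_m <- length(gene_of_marker)
    markers <- paste0("cg", formatC(seq_len(n_m), width = 8, flag = "0"))
    relation <- sample(names(meth_design$relation_mix), n_m, replace = TRUE,
                       prob = meth_design$relation_mix)
    functional <- sample(names(meth_design$functional_mix), n_m, replace = TRUE,
                         prob = meth_design$functional_mix)
    # baseline means by island relation: islands hypomethylated, open sea
    # methylated (typical 450K marginal pattern)
    rel_mean <- c(Island = 0.15, Shore = 0.35, Shelf = 0.55, OpenSea = 0.75)
    m0 <- stats::plogis(stats::qlogis(rel_mean[relation]) +
                          stats::rnorm(n_m, 0, 0.5))
    person_shift <- stats::rnorm(expr_design$n_persons, 0,
                                 meth_design$sd_person_logit)
    names(person_shift) <- unique(samples$person_id)

    # per-marker hyper-methylation delta in tumor samples
    delta <- numeric(n_m)
    hyper_mask <- functional == "promoter" & relation == "Island"
    for (pw in names(hyper)) {
      pe <- expr_design$pathways[[match(pw, vapply(expr_design$pathways,
                                                   function(p) p$name, ""))]]
      sel <- hyper_mask & gene_of_marker %in% pe$genes
      delta[sel] <- delta[sel] + hyper[[pw]]
    }

    n_s <- nrow(samples)
    tumor <- samples$tissue == "tumor"
    eps <- 1e-4
    # person-correlated baseline on the logit scale; the delta-beta effect is
    # then additive on the probability scale so the tumor-normal contrast of
    # the target means equals the configured effect
    target <- stats::plogis(stats::qlogis(m0) +
                              matrix(person_shift[samples$person_id],
                                     n_m, n_s, byrow = TRUE))
    target <- target + outer(delta, as.numeric(tumor))
    target <- pmin(pmax(target, eps), 1 - eps)
    kap <- meth_design$precision
    X <- matrix(stats::rgamma(n_m * n_s, shape = kap * target, rate = 1),
                n_m, n_s) * meth_design$intensity_scale
    Y <- matrix(stats::rgamma(n_m * n_s, shape = kap * (1 - target), rate = 1),
                n_m, n_s) * meth_design$intensity_scale
    beta <- beta_from_intensities(X, Y)
    dimnames(beta) <- list(markers, samples$sample_id)
    annotation <- data.frame(
      marker = markers, gene = gene_of_marker,
      functional_group = functional, relation_to_island = relation,
      stringsAsFactors = FALSE
    )
    study <- methylation_study(beta, annotation, samples)
    attr(study, "truth") <- list(
      meth_design = meth_design, marker_mean = m0, tumor_delta = delta,
      hyper_pathways = hyper
    )
    study
  })
}

#' Remove named samples from a study
#'
#' Reproduces unbalanced designs (e.g. one normal-tissue sample failing on
#' the array): the named samples are dropped from the matrix and the
#' metadata; a person losing both samples disappears entirely.  Downstream
#' fits must still succeed on the unbalanced study.
#'
#' @param study an [expression_study()].
#' @param sample_ids character vector of sample ids to remove (may be empty).
#' @return the reduced study (planted truth, if any, reduced to match).
#' @export
inject_missing <- function(study, sample_ids) {
  stopifnot(inherits(study, "expression_study"))
  if (!length(sample_ids)) return(study)
  unknown <- setdiff(sample_ids, colnames(study$values))
  if (length(unknown)) {
    stop_invalid("unknown sample id(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(colnames(study$values), sample_ids)
  out <- expression_study(study$values[, keep, drop = FALSE],
                          study$samples[study$samples$sample_id %in% keep, ,
                                        drop = FALSE],
                          study$probe_to_gene)
  truth <- attr(study, "truth")
  if (!is.null(truth)) {
    truth$tumor_effect <- truth$tumor_effect[, keep, drop = FALSE]
    truth$sample_effect <- truth$sample_effect[keep]
    attr(out, "truth") <- truth
  }
  out
}
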
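# Pipeline orchestration: discovery (pathway fits -> differential lists ->
# Venn intersection), gene-level enrichment, stratified replication with
# interaction tests, and promoter delta-beta methylation, with every table
# written to a flat results directory plus a machine-readable manifest.

pipeline_keys <- c("contrasts", "simulate", "transform", "pseudocount",
                   "discovery", "replication", "strata", "enrichment",
                   "methylation", "seed", "out_dir")

#' Build and validate a pipeline configuration
#'
#' @param contrasts named list of input descriptions, each
#'   `list(matrix = path, metadata = path)`; or `NULL` when `simulate` is
#'   given.
#' @param simulate named list of generator settings (see [demo_config()]);
#'   used when no file inputs are given.
#' @param transform one of "none", "log2cpm", "quantile".
#' @param pseudocount pseudocount for the log2-CPM transform.
#' @param discovery list(fdr_max, min_abs_fc) for discovery calling.
#' @param replication list(fdr_max, min_abs_fc) for replication calling
#'   (FDR-only by default).
#' @param strata character vector of metadata columns to test for
#'   tumor-by-stratum interactions.
#' @param enrichment list(log_base, correct) for the chi-square score.
#' @param methylation list(exclude_relations, keep_functional) marker
#'   filters; `NULL` disables the methylation stage.
#' @param seed integer seed for any simulation.
#' @param out_dir results directory (created if needed).
#' @return validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(contrasts = NULL, simulate = NULL,
                            transform = c("none", "log2cpm", "quantile"),
                            pseudocount = 1,
                            discovery = list(fdr_max = 0.05, min_abs_fc = 2),
                            replication = list(fdr_max = 0.05, min_abs_fc = 1),
                            strata = c("stage", "MSI"),
                            enrichment = list(log_base = 10, correct = FALSE),
                            methylation = list(
                              exclude_relations = c("Shore", "Shelf", "OpenSea"),
                              keep_functional = "promoter"),
                            seed = 1, out_dir = tempfile("gsanova_run_")) {
  transform <- match.arg(transform)
  if (is.null(contrasts) && is.null(simulate)) {
    stop_invalid("give `contrasts` (file inputs) or `simulate`")
  }
  for (th in list(discovery, replication)) {
    if (th$fdr_max < 0 || th$fdr_max > 1) stop_invalid("fdr_max out of range")
    if (th$min_abs_fc < 1) stop_invalid("min_abs_fc must be >= 1")
  }
  cfg <- list(contrasts = contrasts, simulate = simulate,
              transform = transform, pseudocount = pseudocount,
              discovery = discovery, replication = replication,
              strata = strata, enrichment = enrichment,
              methylation = methylation, seed = as.integer(seed),
              out_dir = out_dir)
  unknown <- setdiff(names(cfg), pipeline_keys)
  if (length(unknown)) stop_invalid("unknown config keys: ",
                                    paste(unknown, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file whose keys mirror [pipeline_config()] arguments.
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(lst), pipeline_keys)
  if (length(unknown)) stop_invalid("unknown config keys: ",
                                    paste(unknown, collapse = ", "))
  do.call(pipeline_config, lst)
}

#' Demonstration configuration on simulated data
#'
#' Emulates the study layout end-to-end: three paired contrasts (an
#' inflammation contrast, a colitis-associated carcinoma contrast, and a
#' sporadic carcinoma contrast) over a shared pathway universe in which five
#' "inflammation" pathways are planted 2.8-fold down-regulated in all three
#' contrasts, one extra pathway is down-regulated in each carcinoma contrast
#' alone, and two of the shared pathways are promoter hyper-methylated in
#' tumor tissue.
#'
#' @param out_dir results directory.
#' @param seed integer seed.
#' @param n_persons persons per contrast (default 20).
#' @return a `pipeline_config`.
#' @export
demo_config <- function(out_dir = tempfile("gsanova_demo_"), seed = 1,
                        n_persons = 20) {
  pipeline_config(
    simulate = list(n_persons = n_persons, n_genes = 80, n_pathways = 10,
                    genes_per_pathway = 6, shared_down = 5,
                    effect_log2 = -1.5,
                    hyper = c(PW_01 = 0.15, PW_02 = 0.20)),
    seed = seed, out_dir = out_dir
  )
}

simulate_pipeline_inputs <- function(sim, seed) {
  # disjoint gene blocks so the planted differential structure is exactly
  # the configured one (overlapping sets would inherit each other's effects)
  genes <- padded_ids("gene_", sim$n_genes)
  stopifnot(sim$n_pathways * sim$genes_per_pathway <= sim$n_genes)
  sets <- split(genes[seq_len(sim$n_pathways * sim$genes_per_pathway)],
                rep(seq_len(sim$n_pathways), each = sim$genes_per_pathway))
  names(sets) <- padded_ids("PW_", sim$n_pathways)
  pw <- pathway_collection(sets)
  nms <- names(pw)
  shared <- nms[seq_len(sim$shared_down)]
  mk_effects <- function(extra = NULL) {
    eff <- lapply(shared, function(nm) {
      pathway_effect(nm, pw[[nm]], sim$effect_log2)
    })
    if (!is.null(extra) && extra <= length(nms)) {
      eff <- c(eff, list(pathway_effect(nms[extra], pw[[nms[extra]]],
                                        sim$effect_log2)))
    }
    eff
  }
  designs <- list(
    inflammation = simulation_design(
      n_persons = sim$n_persons, n_genes = sim$n_genes,
      pathways = mk_effects(), seed = seed + 101L),
    colitis_carcinoma = simulation_design(
      n_persons = sim$n_persons, n_genes = sim$n_genes,
      pathways = mk_effects(extra = sim$shared_down + 1L), seed = seed + 202L),
    sporadic_carcinoma = simulation_design(
      n_persons = sim$n_persons, n_genes = sim$n_genes,
      pathways = mk_effects(extra = sim$shared_down + 2L), seed = seed + 303L)
  )
  studies <- lapply(designs, simulate_expression_study)
  meth <- NULL
  if (length(sim$hyper)) {
    hyper <- unlist(sim$hyper)
    mdes <- methylation_design(hyper_pathways = hyper, seed = seed + 404L)
    meth <- simulate_methylation_study(designs$sporadic_carcinoma, mdes)
  }
  list(studies = studies, pathways = pw, methylation = meth)
}

stage <- function(name, expr) {
  message("[", name, "] started")
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message("[", name, "] done")
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates: data loading or simulation, optional transform, gene-set
#' fits per contrast, differential-pathway calling, Venn intersection of the
#' contrast lists, gene-level fits with chi-square enrichment, stratified
#' replication with interaction tests on the last contrast, and promoter
#' delta-beta methylation.  All result tables are written as full-precision
#' TSVs under `config$out_dir` together with `manifest.json`; reruns with
#' the same config and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the studies, per-contrast results,
#'   differential lists, Venn partition, enrichment table, replication
#'   tables and methylation results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- stage("data", {
    if (!is.null(config$contrasts)) {
      studies <- lapply(config$contrasts, function(cc) {
        read_expression(cc$matrix, cc$metadata, cc$gene_map %||% NULL)
      })
      pw <- read_gmt(config$contrasts[[1L]]$gmt %||%
                       stop_invalid("contrasts need a `gmt` entry"))
      list(studies = studies, pathways = pw, methylation = NULL)
    } else {
      simulate_pipeline_inputs(config$simulate, config$seed)
    }
  })
  studies <- stage("transform", {
    lapply(inputs$studies, function(st) {
      st$values <- switch(config$transform,
        none = st$values,
        log2cpm = log2_cpm(st$values, config$pseudocount),
        quantile = quantile_normalize(st$values))
      st
    })
  })
  set_results <- stage("gene-set fits", {
    res <- lapply(names(studies), function(nm) {
      r <- fit_gene_sets(studies[[nm]], inputs$pathways)
      write_results_table(r, file.path(config$out_dir,
                                       paste0("pathway_results_", nm, ".tsv")))
      sk <- attr(r, "skipped")
      if (length(sk)) message("  ", nm, ": skipped ", length(sk),
                              " pathway(s): ", paste(names(sk), collapse = ", "))
      r
    })
    names(res) <- names(studies)
    res
  })
  diff_lists <- stage("differential calling", {
    dl <- lapply(names(set_results), function(nm) {
      d <- call_differential(set_results[[nm]], config$discovery$fdr_max,
                             config$discovery$min_abs_fc, contrast = nm)
      message("  ", nm, ": ", nrow(d), " differential pathway(s)")
      write_results_table(as.data.frame(d),
                          file.path(config$out_dir,
                                    paste0("differential_", nm, ".tsv")))
      d
    })
    names(dl) <- names(set_results)
    dl
  })
  venn <- stage("venn", {
    vp <- venn_partition(diff_lists)
    regions <- data.frame(region = names(vp$counts),
                          n = as.integer(vp$counts),
                          pathways = vapply(vp$members, paste, "",
                                            collapse = ","),
                          stringsAsFactors = FALSE)
    write_results_table(regions, file.path(config$out_dir, "venn_regions.tsv"))
    jsonlite::write_json(as.list(vp$counts),
                         file.path(config$out_dir, "venn_summary.json"),
                         auto_unbox = TRUE)
    vp
  })
  enr <- stage("enrichment", {
    st <- studies[[length(studies)]]
    gene_res <- fit_all_genes(st, model = "paired")
    write_results_table(gene_res,
                        file.path(config$out_dir, "gene_results.tsv"))
    sig <- unique(gene_res$gene[gene_res$q <= config$discovery$fdr_max])
    chip <- unique(unname(st$probe_to_gene))
    e <- enrich_all(sig, inputs$pathways, chip,
                    log_base = config$enrichment$log_base,
                    correct = config$enrichment$correct)
    write_results_table(e, file.path(config$out_dir, "enrichment.tsv"))
    e
  })
  repl <- stage("stratified replication", {
    st <- studies[[length(studies)]]
    out <- lapply(config$strata, function(f) {
      r <- replicate_stratified(st, inputs$pathways, f)
      write_results_table(r, file.path(config$out_dir,
                                       paste0("replication_", f, ".tsv")))
      r
    })
    names(out) <- config$strata
    out
  })
  meth <- NULL
  if (!is.null(inputs$methylation) && !is.null(config$methylation)) {
    meth <- stage("methylation", {
      ms <- filter_markers(inputs$methylation,
                           exclude_relations = config$methylation$exclude_relations,
                           keep_functional = config$methylation$keep_functional)
      r <- delta_beta_gene_sets(ms, inputs$pathways)
      write_results_table(r, file.path(config$out_dir,
                                       "methylation_delta_beta.tsv"))
      r
    })
  }
  stage("manifest", {
    jsonlite::write_json(
      list(config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
           seed = config$seed,
           package = "gsanova",
           version = as.character(utils::packageVersion("gsanova"))),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  })
  invisible(list(studies = studies, pathways = inputs$pathways,
                 set_results = set_results, diff_lists = diff_lists,
                 venn = venn, enrichment = enr, replication = repl,
                 methylation = meth, out_dir = config$out_dir))
}

#' Stratified replication table for a pathway collection
#'
#' For each pathway, stacks the member-probe observations and fits the
#' two-way fixed tumor-by-stratum interaction model (probe baselines
#' absorbed), reporting the per-stratum fold change with confidence interval
#' and the interaction p-value — the layout of a stratified replication
#' table.
#'
#' @param study an [expression_study()].
#' @param collection a [pathway_collection()].
#' @param factor metadata column to stratify by (e.g. "stage", "MSI").
#' @param level confidence level.
#' @return data.frame: pathway, then fc/fc_lo/fc_hi per stratum level, then
#'   interaction_p; skipped pathways in `attr(result, "skipped")`.
#' @export
replicate_stratified <- function(study, collection, factor, level = 0.95) {
  stopifnot(inherits(study, "expression_study"),
            inherits(collection, "pathway_collection"))
  s <- study$samples
  if (!factor %in% names(s)) stop_invalid("no metadata column '", factor, "'")
  rows <- list(); skipped <- character(0)
  for (nm in names(collection)) {
    probes <- rownames(study$values)[study$probe_to_gene %in% collection[[nm]]]
    genes_present <- unique(unname(study$probe_to_gene[probes]))
    if (length(genes_present) < 2L) {
      skipped[nm] <- "fewer than 2 member genes on the platform"
      next
    }
    n_s <- nrow(s)
    y <- as.vector(study$values[probes, , drop = FALSE])
    tissue <- rep(s$tissue, each = length(probes))
    stratum <- rep(as.character(s[[factor]]), each = length(probes))
    baseline <- rep(probes, times = n_s)
    f <- tryCatch(
      fit_interaction_model(y, tissue, stratum, baseline = baseline,
                            level = level, id = nm),
      error = function(e) conditionMessage(e))
    if (is.character(f)) {
      skipped[nm] <- f
      next
    }
    row <- data.frame(pathway = nm, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(f$strata))) {
      lv <- f$strata$stratum[i]
      row[[paste0("fc_", lv)]] <- f$strata$fc[i]
      row[[paste0("fc_lo_", lv)]] <- f$strata$fc_lo[i]
      row[[paste0("fc_hi_", lv)]] <- f$strata$fc_hi[i]
    }
    row$interaction_p <- f$interaction_p
    rows[[nm]] <- row
  }
  if (!length(rows)) stop_invalid("no pathway could be replicated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(skipped)) attr(out, "skipped") <- skipped
  out
}
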
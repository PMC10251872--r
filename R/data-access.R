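#' Bundled replication-cohort fold-change tables
#'
#' Stage- and MSI-stratified pathway fold changes (with 95% confidence
#' intervals and interaction p-values) for the 28 colon-inflammation-related
#' pathways replicated in the sporadic-carcinoma microarray cohort, as
#' published.  These printed tables are inputs: [percent_regulation()]
#' applied to their signed fold changes yields the reported per-stratum
#' percent down-regulation (e.g. nitrogen metabolism stage 2, FC -1.76,
#' down-regulated by 76%).
#'
#' @param stratification "stage" (stage 1/2/3 vs paired normal) or "MSI"
#'   (MSI vs MSS tumors vs paired normal).
#' @return data.frame with pathway, per-stratum `fc`/`fc_lo`/`fc_hi`
#'   columns, and `interaction_p`.
#' @export
#' @examples
#' tab <- replication_fold_changes("stage")
#' fc <- tab$fc_stage2[tab$pathway == "Nitrogen metabolism"]
#' percent_regulation(fc)   # -76: down-regulated by 76%
replication_fold_changes <- function(stratification = c("stage", "MSI")) {
  stratification <- match.arg(stratification)
  f <- system.file("extdata",
                   paste0("replication_",
                          ifelse(stratification == "stage", "stage", "msi"),
                          "_fc.tsv"),
                   package = "gsanova", mustWork = TRUE)
  utils::read.delim(f, check.names = FALSE, stringsAsFactors = FALSE)
}
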
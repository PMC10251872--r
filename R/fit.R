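# Gene-level fits: unpaired one-way ANOVA, paired mixed ANOVA with
# method-of-moments person variance, and the two-way fixed interaction model.

new_gene_fit <- function(id, mu_hat, d, se_d, df, F, p, varcomp, n, level) {
  fc <- fold_change_from_log2(d)
  ci <- if (se_d > 0 && is.finite(df) && df > 0) {
    fc_confidence_interval(d, se_d, df, level)
  } else c(fc, fc)
  structure(
    list(id = id, mu_hat = mu_hat, d = d, se_d = se_d, df = df,
         F = F, p = p, q = NA_real_, fc = fc, fc_ci = ci,
         variance_components = varcomp, n = n, level = level),
    class = "gene_fit"
  )
}

#' Unpaired two-group fit (one-way ANOVA)
#'
#' For contrasts between different persons (e.g. diseased mucosa vs control
#' mucosa from different patients): one-way fixed-effect ANOVA on a single
#' probe.  The effect `d` is mean(other level) - mean(reference) on the log2
#' scale; on two balanced groups the F statistic equals the squared pooled
#' two-sample t statistic.
#'
#' @param y numeric response (log2 scale).
#' @param group two-level factor or character vector.
#' @param ref reference level; defaults to "normal" when present, otherwise
#'   the first level.
#' @param level confidence level for the fold-change interval.
#' @param id optional probe/gene id carried into the result.
#' @return object of class `gene_fit`.
#' @export
fit_unpaired_model <- function(y, group, ref = NULL, level = 0.95, id = NA_character_) {
  group <- as.character(group)
  if (length(y) != length(group)) stop_invalid("`y` and `group` lengths differ")
  levs <- unique(group)
  if (length(levs) != 2L) stop_invalid("`group` must have exactly two levels")
  if (is.null(ref)) ref <- if ("normal" %in% levs) "normal" else levs[1L]
  if (!ref %in% levs) stop_invalid("reference level not present")
  other <- setdiff(levs, ref)
  cnt <- table(group)
  if (any(cnt < 2)) {
    stop_invalid("insufficient replication: every level needs >= 2 samples")
  }
  y_ref <- y[group == ref]
  y_oth <- y[group == other]
  d <- mean(y_oth) - mean(y_ref)
  df <- length(y) - 2L
  s2 <- (sum((y_ref - mean(y_ref))^2) + sum((y_oth - mean(y_oth))^2)) / df
  se <- sqrt(s2 * (1 / length(y_ref) + 1 / length(y_oth)))
  Fstat <- if (se > 0) (d / se)^2 else if (d != 0) Inf else 0
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  varcomp <- list(components = numeric(0), residual = s2,
                  clamped = logical(0), method = "ols")
  new_gene_fit(id, mean(y_ref), d, se, df, Fstat, p,
               varcomp, length(y), level)
}

#' Paired tumor/normal mixed-model fit
#'
#' Fits `y = mu + tumor + person + error` with person as a random effect for
#' a single probe.  The person variance comes from Henderson Method III
#' quadratic forms (method of moments), the tumor effect and its standard
#' error from GLS at the plug-in components, and the denominator degrees of
#' freedom from a Satterthwaite approximation.  Handles the unbalanced case
#' in which some persons contribute only one tissue; on fully balanced data
#' the tumor F statistic equals the squared paired t statistic.
#'
#' @param y numeric response (log2 scale), one value per sample.
#' @param tissue character/factor with levels "tumor" and "normal".
#' @param person person identifier per sample.
#' @param level confidence level for the fold-change interval.
#' @param id optional probe/gene id.
#' @return object of class `gene_fit`; `d` is tumor minus normal.
#' @export
fit_paired_model <- function(y, tissue, person, level = 0.95, id = NA_character_) {
  tissue <- as.character(tissue)
  person <- as.character(person)
  n <- length(y)
  if (length(tissue) != n || length(person) != n) {
    stop_invalid("`y`, `tissue`, `person` lengths differ")
  }
  if (!all(tissue %in% c("tumor", "normal"))) {
    stop_invalid("`tissue` must be 'tumor' or 'normal'")
  }
  per_counts <- table(person)
  if (length(per_counts) < 3L) stop_invalid("need >= 3 persons")
  if (any(per_counts > 2L)) stop_invalid("at most one sample per tissue per person")
  n_paired <- sum(rowSums(table(person, tissue) > 0) == 2L)
  if (n_paired == 0L) {
    stop_invalid("model unidentifiable: no person has both tissues; ",
                 "use fit_unpaired_model()")
  }
  X <- cbind(`(Intercept)` = 1, tumor = as.numeric(tissue == "tumor"))
  Zp <- indicator_matrix(person)
  fit <- mom_mixed_fit(y, X, list(person = Zp), contrast = c(0, 1))
  Fstat <- if (fit$se > 0) (fit$effect / fit$se)^2 else
    if (abs(fit$effect) > 0) Inf else 0
  p <- stats::pf(Fstat, 1, fit$df, lower.tail = FALSE)
  varcomp <- list(components = fit$varcomp$components,
                  residual = fit$varcomp$residual,
                  clamped = fit$varcomp$clamped,
                  method = fit$varcomp$method)
  new_gene_fit(id, fit$beta[1L], fit$effect, fit$se, fit$df, Fstat, p,
               varcomp, n, level)
}

#' Tumor-by-stratum interaction fit (two-way fixed ANOVA)
#'
#' Fits `y = mu + tumor + stratum + tumor:stratum + error` with all terms
#' fixed, as used for stratified replication (by stage, grade, MSI, KRAS,
#' sex, or TIL).  Reports the per-stratum tumor effect with signed fold
#' change and confidence interval, and the interaction F test.  Strata
#' containing only one tissue are dropped with a warning.  An optional
#' `baseline` factor (probe or marker id) absorbs feature-level baselines
#' when observations from several probes are stacked.
#'
#' @param y numeric response.
#' @param tissue "tumor"/"normal" labels per observation.
#' @param stratum stratum level per observation (at least 2 usable levels).
#' @param baseline optional factor of feature ids to adjust for.
#' @param person optional person ids; when given, person is included as a
#'   fixed blocking factor.  The default model matches the printed
#'   specification, which carries no person term despite the paired design.
#' @param level confidence level for per-stratum fold-change intervals.
#' @param id optional identifier (gene or pathway) carried into the result.
#' @return object of class `interaction_fit` with elements `strata`
#'   (data.frame: stratum, n_tumor, n_normal, d, se, fc, fc_lo, fc_hi),
#'   `interaction_F`, `interaction_p`, `df`.
#' @export
fit_interaction_model <- function(y, tissue, stratum, baseline = NULL,
                                  person = NULL,
                                  level = 0.95, id = NA_character_) {
  tissue <- as.character(tissue)
  stratum <- as.character(stratum)
  n <- length(y)
  if (length(tissue) != n || length(stratum) != n) {
    stop_invalid("`y`, `tissue`, `stratum` lengths differ")
  }
  if (!all(tissue %in% c("tumor", "normal"))) {
    stop_invalid("`tissue` must be 'tumor' or 'normal'")
  }
  if (length(unique(stratum)) < 2L) {
    stop_invalid("interaction undefined with a single-level stratum")
  }
  usable <- names(which(apply(table(stratum, tissue) > 0, 1L, all)))
  dropped <- setdiff(unique(stratum), usable)
  if (length(dropped)) {
    warning("dropping stratum level(s) with a single tissue: ",
            paste(dropped, collapse = ", "))
    keep <- stratum %in% usable
    y <- y[keep]; tissue <- tissue[keep]; stratum <- stratum[keep]
    if (!is.null(baseline)) baseline <- baseline[keep]
    if (!is.null(person)) person <- person[keep]
  }
  if (length(unique(stratum)) < 2L) stop_invalid("fewer than 2 usable strata")
  tis <- factor(tissue, levels = c("normal", "tumor"))
  str <- factor(stratum)
  dat <- data.frame(y = y, tis = tis, str = str)
  rhs <- "tis * str"
  if (!is.null(person)) {
    dat$pers <- factor(as.character(person))
    rhs <- paste("pers +", rhs)
  }
  if (!is.null(baseline)) {
    dat$base <- factor(as.character(baseline))
    rhs <- paste("base +", rhs)
  }
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = dat)
  an <- stats::anova(fit)
  irow <- grep("tis:str", rownames(an), fixed = TRUE)
  int_F <- an[irow, "F value"]
  int_p <- an[irow, "Pr(>F)"]
  df_res <- fit$df.residual
  cf <- stats::coef(fit)
  cf <- cf[!is.na(cf)]          # drop aliased terms (e.g. person-level strata)
  V <- stats::vcov(fit)
  V <- V[names(cf), names(cf), drop = FALSE]
  levs <- levels(str)
  res <- lapply(levs, function(s) {
    L <- stats::setNames(numeric(length(cf)), names(cf))
    L["tistumor"] <- 1
    nm <- paste0("tistumor:str", s)
    if (nm %in% names(L)) L[nm] <- 1
    d <- sum(L * cf)
    se <- sqrt(drop(t(L) %*% V %*% L))
    ci <- if (se > 0) fc_confidence_interval(d, se, df_res, level) else
      rep(fold_change_from_log2(d), 2L)
    data.frame(stratum = s,
               n_tumor = sum(tis == "tumor" & str == s),
               n_normal = sum(tis == "normal" & str == s),
               d = d, se = se, fc = fold_change_from_log2(d),
               fc_lo = ci[1L], fc_hi = ci[2L], stringsAsFactors = FALSE)
  })
  structure(
    list(id = id, factor = deparse(substitute(stratum)),
         strata = do.call(rbind, res),
         interaction_F = int_F, interaction_p = int_p,
         df = df_res, dropped = dropped, level = level),
    class = "interaction_fit"
  )
}

#' Fit every probe of a study
#'
#' Loops the paired (or unpaired) gene-level model over all probes and
#' returns a results table with Benjamini-Hochberg adjusted q-values across
#' probes.
#'
#' @param study an [expression_study()].
#' @param model "paired" (tumor vs normal within person) or "unpaired"
#'   (two-level `group` contrast across persons).
#' @param level confidence level for fold-change intervals.
#' @return data.frame with columns id, gene, d, se, df, F, p, q, fc, fc_lo,
#'   fc_hi, n_used.
#' @export
fit_all_genes <- function(study, model = c("paired", "unpaired"), level = 0.95) {
  stopifnot(inherits(study, "expression_study"))
  model <- match.arg(model)
  probes <- rownames(study$values)
  s <- study$samples
  rows <- lapply(probes, function(pr) {
    y <- study$values[pr, ]
    f <- if (model == "paired") {
      fit_paired_model(y, s$tissue, s$person_id, level = level, id = pr)
    } else {
      fit_unpaired_model(y, s$group, level = level, id = pr)
    }
    data.frame(id = pr, gene = unname(study$probe_to_gene[pr]),
               d = f$d, se = f$se_d, df = f$df, F = f$F, p = f$p,
               fc = f$fc, fc_lo = f$fc_ci[1L], fc_hi = f$fc_ci[2L],
               n_used = f$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out[, c("id", "gene", "d", "se", "df", "F", "p", "q",
          "fc", "fc_lo", "fc_hi", "n_used")]
}
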
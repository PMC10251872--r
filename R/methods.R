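# print / summary / coef / confint methods for the fit classes

fmt_p <- function(p) format.pval(p, digits = 3, eps = 1e-16)

#' @export
print.gene_fit <- function(x, ...) {
  cat("Gene fit", if (!is.na(x$id)) paste0(" [", x$id, "]"), ": ",
      "d = ", signif(x$d, 4), " log2 (FC ", sprintf("%.2f", x$fc), ", ",
      round(100 * x$level), "% CI ", sprintf("%.2f", x$fc_ci[1]), " to ",
      sprintf("%.2f", x$fc_ci[2]), ")\n", sep = "")
  cat("  F = ", signif(x$F, 4), " on 1, ", signif(x$df, 4),
      " df;  p = ", fmt_p(x$p), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gene_fit <- function(object, ...) {
  vc <- object$variance_components
  cat("Tumor-vs-normal fit (", vc$method, ")\n", sep = "")
  print(object)
  if (length(vc$components)) {
    cat("  variance components (log2^2):\n")
    for (nm in names(vc$components)) {
      cat("    ", nm, " = ", signif(vc$components[[nm]], 4),
          if (isTRUE(vc$clamped[[nm]])) "  [clamped at 0]", "\n", sep = "")
    }
  }
  cat("    residual = ", signif(vc$residual, 4), "\n", sep = "")
  invisible(object)
}

#' @export
coef.gene_fit <- function(object, ...) {
  c(mu = object$mu_hat, d = object$d)
}

#' @export
confint.gene_fit <- function(object, parm, level = NULL, ...) {
  level <- level %||% object$level
  fc_confidence_interval(object$d, object$se_d, object$df, level)
}

#' @export
print.gene_set_fit <- function(x, ...) {
  cat("Gene-set fit [", x$pathway, "]: ", x$n_genes, " genes, ",
      x$n_obs, " observations\n", sep = "")
  cat("  set effect = ", signif(x$d_bar, 4), " log2 (FC ",
      sprintf("%.2f", x$fc), ", ", round(100 * x$level), "% CI ",
      sprintf("%.2f", x$fc_ci[1]), " to ", sprintf("%.2f", x$fc_ci[2]),
      ")\n", sep = "")
  cat("  F = ", signif(x$F, 4), " on 1, ", signif(x$df, 4), " df;  p = ",
      fmt_p(x$p), "\n", sep = "")
  invisible(x)
}

#' @export
summary.gene_set_fit <- function(object, ...) {
  print(object)
  vc <- object$variance_components
  cat("  variance components: person = ",
      signif(vc$components[["person"]], 4), ", sample = ",
      signif(vc$components[["sample"]], 4), ", residual = ",
      signif(vc$residual, 4), "\n", sep = "")
  cat("  per-gene effects (log2): ",
      paste(object$per_gene$gene, signif(object$per_gene$d, 3),
            sep = " ", collapse = ", "), "\n", sep = "")
  invisible(object)
}

#' @export
coef.gene_set_fit <- function(object, ...) {
  stats::setNames(object$per_gene$d, object$per_gene$gene)
}

#' @export
confint.gene_set_fit <- function(object, parm, level = NULL, ...) {
  level <- level %||% object$level
  fc_confidence_interval(object$d_bar, object$se, object$df, level)
}

#' Dot plot of per-gene contributions to a gene-set fit
#' @param x a `gene_set_fit`.
#' @param ... passed to [graphics::dotchart()].
#' @export
plot.gene_set_fit <- function(x, ...) {
  ord <- order(x$per_gene$d)
  graphics::dotchart(x$per_gene$d[ord], labels = x$per_gene$gene[ord],
                     xlab = "tumor effect (log2)",
                     main = paste0(x$pathway, ": set effect ",
                                   signif(x$d_bar, 3)), ...)
  graphics::abline(v = c(0, x$d_bar), lty = c(3, 1), col = c("grey40", "red"))
  invisible(x)
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("Tumor-by-stratum interaction fit",
      if (!is.na(x$id)) paste0(" [", x$id, "]"), "\n", sep = "")
  st <- x$strata
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-10s FC %6.2f (%.2f to %.2f)  n = %d/%d\n",
                st$stratum[i], st$fc[i], st$fc_lo[i], st$fc_hi[i],
                st$n_tumor[i], st$n_normal[i]))
  }
  cat("  interaction p = ", fmt_p(x$interaction_p), "\n", sep = "")
  invisible(x)
}

#' @export
coef.interaction_fit <- function(object, ...) {
  stats::setNames(object$strata$d, object$strata$stratum)
}

#' @export
print.delta_beta_fit <- function(x, ...) {
  cat("Delta-beta gene-set fit [", x$pathway, "]: ", x$n_genes, " genes, ",
      x$n_markers, " markers\n", sep = "")
  cat("  delta-beta = ", signif(x$delta_beta, 4), " (",
      as.character(x$direction), "-methylated), ", round(100 * x$level),
      "% CI ", signif(x$ci[1], 4), " to ", signif(x$ci[2], 4),
      ";  p = ", fmt_p(x$p), "\n", sep = "")
  invisible(x)
}

#' @export
coef.delta_beta_fit <- function(object, ...) {
  stats::setNames(object$per_gene$d, object$per_gene$gene)
}
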
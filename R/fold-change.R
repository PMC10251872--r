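#' Signed fold change from a log2 difference
#'
#' Converts a log2 expression difference (tumor minus normal) to the signed
#' fold-change convention used throughout the package: \code{FC = 2^d} for
#' \code{d >= 0} and \code{FC = -2^(-d)} for \code{d < 0}.  Under this
#' convention \code{|FC| >= 1} always; a value of \code{-1.72} reads "1.72-fold
#' down-regulated".
#'
#' @param d numeric vector of log2 differences (finite).
#' @return numeric vector of signed fold changes, never inside (-1, 1).
#' @seealso [log2_from_fold_change()] for the inverse,
#'   [percent_regulation()] for the percent convention.
#' @export
#' @examples
#' fold_change_from_log2(c(0, 1, -1, -0.782))
fold_change_from_log2 <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d))) {
    stop_invalid("`d` must be finite numeric")
  }
  ifelse(d >= 0, 2^d, -(2^(-d)))
}

#' Log2 difference from a signed fold change
#'
#' Inverse of [fold_change_from_log2()].  Signed fold changes inside the open
#' interval (-1, 1) are impossible under the convention and raise an error.
#'
#' @param fc numeric vector of signed fold changes with \code{|fc| >= 1}.
#' @return numeric vector of log2 differences.
#' @export
log2_from_fold_change <- function(fc) {
  if (!is.numeric(fc) || any(!is.finite(fc))) {
    stop_invalid("`fc` must be finite numeric")
  }
  if (any(abs(fc) < 1)) {
    stop_invalid("signed fold changes inside (-1, 1) are impossible")
  }
  out <- numeric(length(fc))
  up <- fc >= 1
  out[up] <- log2(fc[up])
  out[!up] <- -log2(-fc[!up])
  out
}

#' t-based confidence interval for a fold change
#'
#' Builds a t-interval on the log2 scale and maps both endpoints through the
#' signed fold-change transform.  Because the transform jumps from -1 to +1 at
#' a log2 difference of 0, an interval may straddle the +/-1 gap (e.g. a null
#' gene reported as FC 1.02, 95% CI -1.009 to 1.06).
#'
#' @param d log2 difference (scalar).
#' @param se_d standard error of `d` on the log2 scale, `>= 0`.
#' @param df degrees of freedom for the t quantile, `> 0`.
#' @param level confidence level, default 0.95.
#' @return numeric length-2 vector `c(lo, hi)` of signed fold changes.
#' @export
#' @examples
#' fc_confidence_interval(0.644, se_d = 0.2, df = 30)
fc_confidence_interval <- function(d, se_d, df, level = 0.95) {
  if (!is.finite(d)) stop_invalid("`d` must be finite")
  if (!is.finite(se_d) || se_d < 0) stop_invalid("`se_d` must be >= 0")
  if (!is.finite(df) || df <= 0) stop_invalid("`df` must be positive")
  if (level <= 0 || level >= 1) stop_invalid("`level` must be in (0, 1)")
  tq <- stats::qt(1 - (1 - level) / 2, df = df)
  lo <- d - tq * se_d
  hi <- d + tq * se_d
  c(fold_change_from_log2(lo), fold_change_from_log2(hi))
}

#' Percent up-/down-regulation from a signed fold change
#'
#' The percent convention pairs a fold change of -1.72 with "down-regulated by
#' 72%": magnitude \code{(|FC| - 1) * 100}, direction from the sign of the
#' fold change.  Note this is not \code{1 - 1/|FC|}.
#'
#' @param fc numeric vector of signed fold changes, \code{|fc| >= 1}.
#' @return signed percent: positive = up-regulated, negative = down-regulated.
#' @export
#' @examples
#' percent_regulation(c(-1.72, -1.09, 1))
percent_regulation <- function(fc) {
  if (!is.numeric(fc) || any(!is.finite(fc))) {
    stop_invalid("`fc` must be finite numeric")
  }
  if (any(abs(fc) < 1)) {
    stop_invalid("|fc| < 1 is impossible under the signed convention")
  }
  sign(fc) * (abs(fc) - 1) * 100
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' \code{stats::p.adjust(method = "BH")}).  Adjusted values satisfy
#' \code{q >= p} elementwise and are monotone in rank order.
#'
#' @param p numeric vector of p-values in \eqn{[0, 1]}.
#' @return numeric vector of adjusted values (q-values).
#' @export
benjamini_hochberg <- function(p) {
  if (!is.numeric(p)) stop_invalid("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_invalid("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
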
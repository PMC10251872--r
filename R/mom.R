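# Method-of-moments mixed-model engine.
#
# Fits y = X beta + sum_k Z_k u_k + e with u_k ~ N(0, sigma_k^2 I) and
# e ~ N(0, sigma_e^2 I).  Variance components come from Henderson Method III
# quadratic forms (sequential reductions in sums of squares); fixed effects
# and contrast standard errors from GLS at the plug-in components (Woodbury
# identity, so only q x q solves for q total random levels); denominator
# degrees of freedom from a Satterthwaite approximation obtained by
# linearizing the contrast variance in the observed quadratic forms.

# y        numeric response
# X        full-column-rank fixed design (first column intercept)
# Z        named list of 0/1 indicator matrices, one per random term, in
#          nesting order (outermost first, e.g. person then sample)
# contrast numeric vector L over columns of X; the reported effect is L'beta
mom_mixed_fit <- function(y, X, Z, contrast) {
  n <- length(y)
  stopifnot(nrow(X) == n, is.list(Z))
  K <- length(Z)
  for (k in seq_len(K)) stopifnot(nrow(Z[[k]]) == n)

  # sequential QR fits: X, [X Z1], [X Z1 Z2], ...
  mats <- vector("list", K + 1L)
  mats[[1L]] <- X
  if (K) for (k in seq_len(K)) mats[[k + 1L]] <- cbind(mats[[k]], Z[[k]])
  qrs <- lapply(mats, qr)
  ranks <- vapply(qrs, function(q) q$rank, 0L)
  ssr <- vapply(qrs, function(q) sum(qr.fitted(q, y)^2), 0)
  sse <- sum(y^2) - ssr[K + 1L]
  df_e <- n - ranks[K + 1L]
  if (df_e <= 0) stop_invalid("no residual degrees of freedom; model is saturated")
  sigma_e2 <- max(sse / df_e, 0)

  # reductions R_k = SSR([X Z1..Zk]) - SSR([X Z1..Z(k-1)]) and their
  # expectation coefficients: E[R_k] = e_k * sigma_e^2 +
  #   sum_{j >= k} tr(Z_j' (P_k - P_{k-1}) Z_j) * sigma_j^2
  # (terms j < k vanish because Z_j lies in both projection spaces)
  R <- if (K) ssr[-1L] - ssr[-(K + 1L)] else numeric(0)
  e_df <- if (K) ranks[-1L] - ranks[-(K + 1L)] else numeric(0)
  Cmat <- matrix(0, K, K)
  if (K) {
    for (k in seq_len(K)) {
      for (j in k:K) {
        Zj <- Z[[j]]
        tr_hi <- sum(qr.fitted(qrs[[k + 1L]], Zj) * Zj)
        tr_lo <- sum(qr.fitted(qrs[[k]], Zj) * Zj)
        Cmat[k, j] <- tr_hi - tr_lo
      }
    }
  }

  # back-solve the triangular moment equations; clamp negatives to zero
  sigma2 <- numeric(K)
  clamped <- logical(K)
  if (K) {
    for (k in rev(seq_len(K))) {
      num <- R[k] - e_df[k] * sigma_e2
      if (k < K) num <- num - sum(Cmat[k, (k + 1L):K] * sigma2[(k + 1L):K])
      est <- if (Cmat[k, k] > 0) num / Cmat[k, k] else 0
      if (est < 0) {
        clamped[k] <- TRUE
        est <- 0
      }
      sigma2[k] <- est
    }
    names(sigma2) <- names(clamped) <- names(Z)
  }

  scale_ref <- max(sigma_e2, sum(sigma2), mean(y^2), .Machine$double.eps)
  # GLS contrast variance at arbitrary component values (Woodbury); a tiny
  # floor on sigma_e^2 keeps V invertible in noise-free degenerate inputs
  U <- if (K) do.call(cbind, Z) else NULL
  qsizes <- if (K) vapply(Z, ncol, 0L) else integer(0)
  UtU <- if (K) crossprod(U) else NULL
  XtU <- if (K) crossprod(X, U) else NULL
  ytU <- if (K) crossprod(y, U) else NULL
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)

  gls <- function(s2, se2) {
    se2 <- max(se2, 1e-12 * scale_ref)
    act <- which(s2 > 0)
    if (!length(act)) {
      XtVX <- XtX / se2
      XtVy <- Xty / se2
    } else {
      idx <- unlist(mapply(function(k, q) rep(k, q), seq_len(K), qsizes,
                           SIMPLIFY = FALSE))
      keep <- idx %in% act
      A <- UtU[keep, keep, drop = FALSE]
      diag(A) <- diag(A) + se2 / s2[idx[keep]]
      rhs <- cbind(t(XtU[, keep, drop = FALSE]), t(ytU[, keep, drop = FALSE]))
      Ainv_rhs <- solve(A, rhs)  # columns: ncol(X) for X, then one for y
      XtVX <- (XtX - XtU[, keep, drop = FALSE] %*%
                 Ainv_rhs[, seq_len(ncol(X)), drop = FALSE]) / se2
      XtVy <- (Xty - XtU[, keep, drop = FALSE] %*%
                 Ainv_rhs[, ncol(X) + 1L, drop = FALSE]) / se2
    }
    XtVX <- (XtVX + t(XtVX)) / 2
    cov_beta <- solve(XtVX)
    beta <- cov_beta %*% XtVy
    list(beta = drop(beta), cov = cov_beta,
         se2 = drop(t(contrast) %*% cov_beta %*% contrast))
  }

  fit <- gls(sigma2, sigma_e2)
  effect <- sum(contrast * fit$beta)
  se2_hat <- fit$se2

  # Satterthwaite df: linearize se2 in (sigma_1^2..sigma_K^2, sigma_e^2),
  # translate to the observed quadratic forms Q = (R_1..R_K, SSE), and match
  # moments of the resulting linear combination of chi-square-like terms.
  df_sat <- df_e
  if (K) {
    g <- numeric(K + 1L)
    h_step <- 1e-4 * scale_ref
    for (k in seq_len(K)) {
      up <- sigma2; up[k] <- up[k] + h_step
      dn <- sigma2; dn[k] <- max(up[k] - 2 * h_step, 0)
      g[k] <- (gls(up, sigma_e2)$se2 - gls(dn, sigma_e2)$se2) / (up[k] - dn[k])
    }
    g[K + 1L] <- (gls(sigma2, sigma_e2 + h_step)$se2 -
                    gls(sigma2, max(sigma_e2 - h_step, 0))$se2) /
      (sigma_e2 + h_step - max(sigma_e2 - h_step, 0))
    # expectation matrix E: Q = Emat %*% (sigma_1^2..sigma_K^2, sigma_e^2)
    Emat <- matrix(0, K + 1L, K + 1L)
    for (k in seq_len(K)) {
      Emat[k, seq_len(K)] <- Cmat[k, ]
      Emat[k, K + 1L] <- e_df[k]
    }
    Emat[K + 1L, K + 1L] <- df_e
    h <- drop(t(solve(Emat)) %*% g)
    Q <- c(R, sse)
    dfs <- c(e_df, df_e)
    denom <- sum((h * Q)^2 / pmax(dfs, 1))
    if (is.finite(denom) && denom > 0) {
      df_sat <- max(se2_hat^2 / denom, 1)
    }
  }

  list(
    effect = effect,
    se = sqrt(max(se2_hat, 0)),
    df = df_sat,
    beta = fit$beta,
    cov_beta = fit$cov,
    varcomp = list(components = sigma2, residual = sigma_e2,
                   clamped = clamped, method = "method-of-moments"),
    df_residual = df_e
  )
}
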
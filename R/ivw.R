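#' Univariable IVW MR with correlated instruments
#'
#' Estimates the causal effect of an exposure on an outcome from per-instrument
#' summary effects, generalizing the inverse-variance weighted estimator to
#' (mildly) correlated instruments through the LD matrix `C`:
#' `theta = (bE' C^-1 bE)^-1 bE' C^-1 bY` (a generalized-least-squares slope).
#' The standard error is the Delta-method sandwich
#' `sqrt(A^-1 bE' C^-1/2 Sigma C^-1/2 bE A^-1)` with `A = bE' C^-1 bE` and
#' `Sigma` diagonal, `Sigma_ii = max(s2, var_Y_i)`, where `s2` is the
#' C^-1-weighted residual variance of the fit
#' (`s2 = r' C^-1 r / (m-1)`, `r = bY - theta bE`; for m = 1, `s2 = var_Y_1`).
#' `C^-1/2` is the symmetric square root via eigendecomposition after
#' eigenvalue clipping, so the result is invariant to instrument order. With
#' `C = I` and `Sigma_ii = var_Y_i` this reduces to textbook fixed-effect IVW.
#'
#' @param beta_E,beta_Y instrument effects on the exposure and outcome
#'   (standardized scale).
#' @param var_E,var_Y effect variances (1/n under standardization); scalars
#'   are recycled.
#' @param C LD correlation matrix between instruments, or `NULL` for
#'   independent instruments.
#' @return list of class `ivw_estimate`: `theta`, `se`, `pvalue`, `m`,
#'   `sigma_diag`, `s2`, `resid`.
#' @export
ivw_correlated <- function(beta_E, beta_Y, var_E, var_Y, C = NULL) {
  m <- length(beta_E)
  if (m == 0L) stop("no instruments supplied")
  stopifnot(length(beta_Y) == m)
  var_E <- rep_len(var_E, m)
  var_Y <- rep_len(var_Y, m)

  if (is.null(C)) {
    A <- sum(beta_E^2)
    if (A <= 0) stop("exposure effects are all zero; estimator undefined")
    theta <- sum(beta_E * beta_Y) / A
    r <- beta_Y - theta * beta_E
    s2 <- if (m >= 2) sum(r^2) / (m - 1) else var_Y[1]
    sigma <- pmax(s2, var_Y)
    se <- sqrt(sum(beta_E^2 * sigma)) / A
    u <- r
  } else {
    reg <- ld_regularize(C)
    Ci <- reg$inv
    A <- drop(crossprod(beta_E, Ci %*% beta_E))
    if (A <= 0) stop("exposure effects are all zero; estimator undefined")
    theta <- drop(crossprod(beta_E, Ci %*% beta_Y)) / A
    r <- beta_Y - theta * beta_E
    s2 <- if (m >= 2) drop(crossprod(r, Ci %*% r)) / (m - 1) else var_Y[1]
    sigma <- pmax(s2, var_Y)
    w <- drop(reg$inv_sqrt %*% beta_E)
    se <- sqrt(sum(w^2 * sigma)) / A
    u <- drop(reg$inv_sqrt %*% r)
  }
  structure(list(theta = theta, se = se,
                 pvalue = 2 * stats::pnorm(-abs(theta / se)),
                 m = m, sigma_diag = sigma, s2 = s2, resid = u),
            class = "ivw_estimate")
}

#' @export
print.ivw_estimate <- function(x, ...) {
  cat(sprintf("IVW estimate: theta = %.4g (SE %.4g, p = %.3g, m = %d)\n",
              x$theta, x$se, x$pvalue, x$m))
  invisible(x)
}

#' Univariable heterogeneity Q-statistic
#'
#' Quantifies the deviation of per-instrument causal estimates from the pooled
#' IVW estimate: `Q = sum(u_i^2 / Sigma_ii)` on decorrelated residuals
#' `u = C^-1/2 (bY - theta bE)`, referred to a chi-squared distribution with
#' `m - 1` degrees of freedom. With `C = I` this is the familiar Cochran's Q
#' over the IVW fit.
#'
#' @param est an [ivw_correlated()] result.
#' @return list `Q`, `df`, `p`.
#' @export
q_statistic_univariable <- function(est) {
  if (est$m < 2) stop("Q undefined for fewer than 2 instruments")
  Q <- sum(est$resid^2 / est$sigma_diag)
  df <- est$m - 1
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}
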
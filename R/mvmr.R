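#' Rank-score clumping of pooled exposure and mediator instruments
#'
#' Mediator-associated candidate instruments (already significance- and
#' Steiger-filtered) are prioritized by a rank score: within each mediator,
#' candidates are ranked by ascending association p-value (1 = strongest); an
#' instrument absent from a mediator's candidate list receives that mediator's
#' worst rank plus one. Each instrument's score is the sum of its per-mediator
#' ranks; lower scores are clumped first. Exposure instruments are kept
#' unconditionally and clumped first, so a mediator instrument in LD
#' (`r^2 >= r2_thresh`) with any kept exposure instrument is dropped. Ties are
#' broken by the instrument's minimum p-value across mediators, then position.
#'
#' @param exposure_ivs character vector of (already pruned) exposure
#'   instrument IDs.
#' @param mediator_candidates named list (one element per mediator) of data
#'   frames with columns `variant_id`, `pvalue`, `pos`.
#' @param ld an [ld_panel()] covering all candidates.
#' @param r2_thresh squared-correlation clumping threshold (default 0.05).
#' @return character vector: exposure IVs followed by kept mediator IVs.
#' @export
rank_score_clump <- function(exposure_ivs, mediator_candidates, ld,
                             r2_thresh = 0.05) {
  all_ids <- unique(unlist(lapply(mediator_candidates, function(d) d$variant_id)))
  all_ids <- setdiff(all_ids, exposure_ivs)
  if (!length(all_ids)) return(exposure_ivs)

  score <- stats::setNames(numeric(length(all_ids)), all_ids)
  minp <- stats::setNames(rep(1, length(all_ids)), all_ids)
  pos <- stats::setNames(rep(Inf, length(all_ids)), all_ids)
  for (d in mediator_candidates) {
    d <- d[order(d$pvalue), , drop = FALSE]
    rk <- stats::setNames(seq_len(nrow(d)), d$variant_id)
    worst <- nrow(d) + 1
    present <- intersect(all_ids, names(rk))
    score[present] <- score[present] + rk[present]
    score[setdiff(all_ids, present)] <- score[setdiff(all_ids, present)] + worst
    minp[present] <- pmin(minp[present], d$pvalue[match(present, d$variant_id)])
    if (!is.null(d$pos)) pos[present] <- pmin(pos[present], d$pos[match(present, d$variant_id)])
  }
  ord <- order(score, minp, pos)
  kept <- greedy_r2_clump(all_ids[ord], ld, r2_thresh, kept = exposure_ivs)
  c(exposure_ivs, kept)
}

#' Build the MVMR design matrix
#'
#' Assembles the effect matrix `B` (exposure effects in column 1, one column
#' per mediator) and the outcome vector over the pooled instrument set. Effects
#' absent from a table — typically exposure effects of mediator instruments,
#' which fall below the QTL dataset's reporting threshold — are set to exactly
#' zero, which reduces regression dilution from noisy sub-significant effects.
#' The outcome GWAS is assumed complete; pooled instruments missing from it
#' are dropped with a warning.
#'
#' @param exposure_stats [summary_stats()] for the exposure.
#' @param mediator_stats_list named list of [summary_stats()], one per mediator.
#' @param outcome_stats [summary_stats()] for the outcome.
#' @param pooled_ivs instrument IDs (e.g. from [rank_score_clump()]).
#' @param ld optional [ld_panel()]; when supplied, the matching LD submatrix is
#'   attached and rows follow `pooled_ivs` order.
#' @return list of class `mvmr_problem`: `iv_ids`, `B`, `beta_Y`, `var_Y`,
#'   `var_E`, `C`, `mediator_ids`.
#' @export
build_design_matrix <- function(exposure_stats, mediator_stats_list,
                                outcome_stats, pooled_ivs, ld = NULL) {
  out <- as.data.frame(outcome_stats)
  have_y <- pooled_ivs %in% out$variant_id
  if (any(!have_y)) {
    warning(sum(!have_y), " pooled instrument(s) missing from the outcome GWAS;",
            " dropped", call. = FALSE)
    pooled_ivs <- pooled_ivs[have_y]
  }
  if (!length(pooled_ivs)) stop("no pooled instruments with outcome effects")

  lookup <- function(stats, ids) {
    d <- as.data.frame(stats)
    i <- match(ids, d$variant_id)
    b <- ifelse(is.na(i), 0, d$beta[i])
    v <- ifelse(is.na(i), 1 / mean(d$n), d$se[i]^2)
    list(beta = b, var = v)
  }
  eff_E <- lookup(exposure_stats, pooled_ivs)
  med_ids <- names(mediator_stats_list)
  B <- matrix(0, nrow = length(pooled_ivs), ncol = 1 + length(mediator_stats_list),
              dimnames = list(pooled_ivs, c(attr(exposure_stats, "trait_id"), med_ids)))
  B[, 1] <- eff_E$beta
  for (j in seq_along(mediator_stats_list)) {
    B[, j + 1] <- lookup(mediator_stats_list[[j]], pooled_ivs)$beta
  }
  yy <- lookup(outcome_stats, pooled_ivs)
  C <- if (!is.null(ld)) ld_subset(ld, pooled_ivs)$R else NULL
  structure(list(iv_ids = pooled_ivs, B = B, beta_Y = yy$beta, var_Y = yy$var,
                 var_E = eff_E$var, C = C, mediator_ids = med_ids),
            class = "mvmr_problem")
}

# sequentially admit columns of B, skipping those that make the matrix
# numerically rank deficient (relative singular value < tol); column 1 always kept
admissible_columns <- function(B, tol = 1e-10) {
  keep <- 1L
  for (j in seq_len(ncol(B))[-1]) {
    d <- svd(B[, c(keep, j), drop = FALSE], nu = 0, nv = 0)$d
    if (length(d) && d[length(d)] / d[1] >= tol) keep <- c(keep, j)
  }
  keep
}

#' Multivariable MR with correlated instruments
#'
#' Estimates the direct effect of the exposure on the outcome conditional on
#' the mediators: `theta_D = (B' C^-1 B)^-1 B' C^-1 beta_Y`, with `B` the
#' instrument-effect matrix (exposure in column 1, mediators in the remaining
#' columns). The first element of the coefficient vector is the exposure's
#' direct effect; the remaining elements are per-mediator direct effects on the
#' outcome (`alpha_MY`). Standard errors use the multivariable analogue of the
#' univariable Delta-method sandwich with the same diagonal `Sigma`
#' (`Sigma_ii = max(s2, var_Y_i)`, `s2` the C^-1-weighted residual variance
#' with `m - (k+1)` degrees of freedom, floored at 1). Mediator columns that
#' render `B` numerically rank deficient (relative singular value < 1e-10) are
#' dropped before fitting and recorded in `dropped_mediators`.
#'
#' @param prob an `mvmr_problem` from [build_design_matrix()], or a list with
#'   at least `B`, `beta_Y`, `var_Y` and optionally `C`.
#' @return list of class `mvmr_estimate`: `theta_D`, `se_D`, `p_D`,
#'   `alpha_MY`, `se_MY`, `coef`, `se`, `m`, `k`, `sigma_diag`, `s2`, `resid`,
#'   `mediator_ids`, `dropped_mediators`.
#' @export
mvmr_correlated <- function(prob) {
  B <- as.matrix(prob$B)
  beta_Y <- prob$beta_Y
  m <- nrow(B)
  if (m < ncol(B)) stop("fewer instruments than coefficients")
  var_Y <- rep_len(prob$var_Y, m)
  med_ids <- prob$mediator_ids
  if (is.null(med_ids)) med_ids <- colnames(B)[-1]
  if (is.null(med_ids) && ncol(B) > 1) med_ids <- paste0("M", seq_len(ncol(B) - 1))

  keep <- admissible_columns(B)
  dropped <- if (length(keep) < ncol(B)) med_ids[setdiff(seq_len(ncol(B)), keep) - 1] else character(0)
  B <- B[, keep, drop = FALSE]
  kept_meds <- if (ncol(B) > 1) med_ids[keep[-1] - 1] else character(0)
  k <- ncol(B) - 1

  if (is.null(prob$C)) {
    A <- crossprod(B)
    rhs <- crossprod(B, beta_Y)
    theta <- drop(solve(A, rhs))
    r <- beta_Y - drop(B %*% theta)
    s2 <- sum(r^2) / max(m - ncol(B), 1)
    sigma <- pmax(s2, var_Y)
    mid <- crossprod(B, B * sigma)
    u <- r
  } else {
    reg <- ld_regularize(prob$C)
    CiB <- reg$inv %*% B
    A <- crossprod(B, CiB)
    theta <- drop(solve(A, crossprod(CiB, beta_Y)))
    r <- beta_Y - drop(B %*% theta)
    s2 <- drop(crossprod(r, reg$inv %*% r)) / max(m - ncol(B), 1)
    sigma <- pmax(s2, var_Y)
    W <- reg$inv_sqrt %*% B
    mid <- crossprod(W, W * sigma)
    u <- drop(reg$inv_sqrt %*% r)
  }
  Ai <- solve(A)
  covmat <- Ai %*% mid %*% Ai
  se <- sqrt(pmax(diag(covmat), 0))
  names(theta) <- names(se) <- c("exposure", kept_meds)

  alpha_MY <- if (k > 0) theta[-1] else numeric(0)
  se_MY <- if (k > 0) se[-1] else numeric(0)
  structure(list(theta_D = unname(theta[1]), se_D = unname(se[1]),
                 p_D = 2 * stats::pnorm(-abs(theta[1] / se[1])),
                 alpha_MY = alpha_MY, se_MY = se_MY,
                 coef = theta, se = se, m = m, k = k,
                 sigma_diag = sigma, s2 = s2, resid = u,
                 mediator_ids = kept_meds, dropped_mediators = dropped),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("MVMR estimate: theta_D = %.4g (SE %.4g, p = %.3g, m = %d, k = %d)\n",
              x$theta_D, x$se_D, x$p_D, x$m, x$k))
  invisible(x)
}

#' MVMR heterogeneity Q-statistic
#'
#' Cochran-type heterogeneity over the multivariable fit, computed on
#' decorrelated residuals `u = C^-1/2 (beta_Y - B theta_D)` as
#' `Q = sum(u_i^2 / Sigma_ii)` with `m - k` degrees of freedom (`m`
#' instruments, `k` mediators).
#'
#' @param est an [mvmr_correlated()] result.
#' @return list `Q`, `df`, `p`.
#' @export
q_statistic_mvmr <- function(est) {
  df <- est$m - est$k
  if (df < 1) stop("Q undefined: m <= k")
  Q <- sum(est$resid^2 / est$sigma_diag)
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Conditional F-statistic of the exposure given the mediators
#'
#' Instrument strength for the exposure conditional on the mediators, after
#' Sanderson: the exposure's instrument-effect column is regressed
#' (C^-1-weighted) on the mediator columns and the residual strength is
#' `F = n_E * delta' C^-1 delta / (m * sigma_v^2)`, where `delta` is the
#' residual vector and `sigma_v^2 = sigma_E^2 - 2 g' sigma_EM + g' Sigma_MM g`
#' is the implied variance of the exposure residualized on the mediators,
#' computed from the phenotypic covariance of (exposure, mediators). By
#' default the phenotypic correlation matrix is the identity (as used when
#' individual-level mediator correlations are unavailable), giving
#' `sigma_v^2 = 1 + sum(g^2)`. With `k = 0` the statistic reduces to the mean
#' per-instrument F of the exposure; an exactly collinear mediator column
#' drives it to 0. Values <= 10 indicate weak-instrument risk.
#'
#' @param prob an `mvmr_problem` (uses `B` and `C`).
#' @param n_E exposure QTL sample size (scales the statistic, since
#'   `var(beta_E) = 1/n_E` under standardization).
#' @param pheno_corr optional (k+1) x (k+1) phenotypic correlation matrix of
#'   (exposure, mediators); identity if `NULL`.
#' @return the conditional F-statistic (scalar).
#' @export
conditional_f <- function(prob, n_E, pheno_corr = NULL) {
  B <- as.matrix(prob$B)
  m <- nrow(B)
  k <- ncol(B) - 1
  if (m <= k) stop("conditional F undefined: m <= k")
  bE <- B[, 1]
  Ci <- if (is.null(prob$C)) NULL else ld_regularize(prob$C)$inv
  if (k == 0) {
    g <- numeric(0)
    delta <- bE
  } else {
    M <- B[, -1, drop = FALSE]
    if (is.null(Ci)) {
      g <- drop(qr.coef(qr(M), bE))
    } else {
      CiM <- Ci %*% M
      g <- drop(solve(crossprod(M, CiM), crossprod(CiM, bE)))
    }
    g[is.na(g)] <- 0
    delta <- bE - drop(M %*% g)
  }
  if (is.null(pheno_corr)) {
    sigma_v2 <- 1 + sum(g^2)
  } else {
    P <- as.matrix(pheno_corr)
    stopifnot(nrow(P) == k + 1, ncol(P) == k + 1)
    sigma_v2 <- P[1, 1] +
      (if (k > 0) drop(t(g) %*% P[-1, -1, drop = FALSE] %*% g) - 2 * sum(g * P[1, -1]) else 0)
  }
  strength <- if (is.null(Ci)) sum(delta^2) else drop(crossprod(delta, Ci %*% delta))
  n_E * strength / (m * sigma_v2)
}
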
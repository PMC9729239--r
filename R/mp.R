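#' Mediation proportion from direct and total effects
#'
#' Core estimator for a set of exposure-outcome pairs: the unmediated
#' proportion `gamma` is the no-intercept regression slope of the direct on
#' the total effects, `gamma = sum(theta_D * theta_T) / sum(theta_T^2)`.
#' Because the regressor `theta_T` is itself estimated with error, the slope
#' is attenuated (regression dilution); the corrected slope is
#' `gamma_cor = gamma / sqrt(1 - sum(SE^2(theta_T)) / sum(theta_T^2))`
#' and the mediation proportion is `MP = 1 - gamma_cor`. The standard error
#' of `gamma` uses the classical homoskedastic no-intercept formula and is
#' scaled by the same dilution denominator; the 95% CI is
#' `MP +/- 1.96 * se(gamma_cor)`.
#'
#' @param theta_D,theta_T per-pair direct and total effect estimates.
#' @param se_T per-pair standard errors of the total effects.
#' @return list of class `mp_estimate`: `n_pairs`, `gamma`, `se_gamma`,
#'   `gamma_cor`, `se_gamma_cor`, `mp`, `ci95`.
#' @export
mp_from_effects <- function(theta_D, theta_T, se_T) {
  n <- length(theta_T)
  stopifnot(length(theta_D) == n, length(se_T) == n)
  if (n < 2) stop("at least 2 pairs required")
  ss_T <- sum(theta_T^2)
  if (ss_T <= 0) stop("total effects are all zero")
  gamma <- sum(theta_D * theta_T) / ss_T
  resid <- theta_D - gamma * theta_T
  se_gamma <- sqrt(sum(resid^2) / (n - 1) / ss_T)
  shrink <- 1 - sum(se_T^2) / ss_T
  if (shrink <= 0) {
    stop("dilution correction undefined: sum(SE^2) >= sum(theta_T^2)")
  }
  gamma_cor <- gamma / sqrt(shrink)
  se_cor <- se_gamma / sqrt(shrink)
  mp <- 1 - gamma_cor
  structure(list(n_pairs = n, gamma = gamma, se_gamma = se_gamma,
                 gamma_cor = gamma_cor, se_gamma_cor = se_cor, mp = mp,
                 ci95 = c(mp - 1.96 * se_cor, mp + 1.96 * se_cor)),
            class = "mp_estimate")
}

#' @export
print.mp_estimate <- function(x, ...) {
  cat(sprintf("MP = %.1f%% (95%% CI: [%.1f%%-%.1f%%]; n = %d pairs)\n",
              100 * x$mp, 100 * x$ci95[1], 100 * x$ci95[2], x$n_pairs))
  invisible(x)
}

#' Group-level mediation proportions
#'
#' Aggregates per-pair results into dilution-corrected MP estimates, combined
#' or by a grouping column. `mode = "detectable"` uses only pairs with at
#' least one selected mediator; `mode = "overall"` additionally includes
#' non-detectable pairs (for which `theta_D = theta_T` by construction).
#' Pairs without any transcript in the cis window are excluded from both
#' modes, as are untestable pairs. Group MPs come only from the slope
#' regression, never from averaging per-pair MPs.
#'
#' @param pairs data frame (e.g. from [pairs_table()]) with columns
#'   `theta_T`, `se_T`, `theta_D`, `detectable`, `has_cis_transcript`,
#'   `status`, plus any grouping columns.
#' @param grouping optional column name to group by (`NULL` = all pairs
#'   combined).
#' @param min_pairs minimum pairs per group (default 10); smaller groups are
#'   skipped with a message.
#' @param mode `"detectable"` or `"overall"`.
#' @return data frame with one row per retained group: `group`, `n_pairs`,
#'   `gamma`, `se_gamma`, `gamma_cor`, `se_gamma_cor`, `mp`, `ci_lo`, `ci_hi`.
#' @export
estimate_mp <- function(pairs, grouping = NULL, min_pairs = 10,
                        mode = c("detectable", "overall")) {
  mode <- match.arg(mode)
  ok <- pairs$status == "ok" & pairs$has_cis_transcript
  ok <- ok & if (mode == "detectable") pairs$detectable else TRUE
  pairs <- pairs[ok, , drop = FALSE]
  groups <- if (is.null(grouping)) list(all = pairs) else
    split(pairs, pairs[[grouping]])
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    if (nrow(d) < min_pairs) {
      message("group '", g, "' skipped: ", nrow(d), " < ", min_pairs, " pairs")
      next
    }
    est <- tryCatch(mp_from_effects(d$theta_D, d$theta_T, d$se_T),
                    error = function(e) {
                      message("group '", g, "' skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(est)) next
    rows[[g]] <- data.frame(group = g, n_pairs = est$n_pairs,
                            gamma = est$gamma, se_gamma = est$se_gamma,
                            gamma_cor = est$gamma_cor,
                            se_gamma_cor = est$se_gamma_cor, mp = est$mp,
                            ci_lo = est$ci95[1], ci_hi = est$ci95[2],
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), n_pairs = integer(0), gamma = numeric(0),
               se_gamma = numeric(0), gamma_cor = numeric(0),
               se_gamma_cor = numeric(0), mp = numeric(0), ci_lo = numeric(0),
               ci_hi = numeric(0))
  rownames(out) <- NULL
  out
}

#' Compare two mediation-proportion estimates
#'
#' Two-sided z-test on the difference of dilution-corrected slopes:
#' `z = (gamma_cor_1 - gamma_cor_2) / sqrt(se_1^2 + se_2^2)`. Independence of
#' the two estimates is assumed, so p-values may be lenient when the
#' underlying pair sets overlap.
#'
#' @param a,b [mp_from_effects()] results (or single rows of
#'   [estimate_mp()] output).
#' @return list `z`, `p`.
#' @export
compare_mp <- function(a, b) {
  se1 <- a$se_gamma_cor; se2 <- b$se_gamma_cor
  if (!is.finite(se1) || !is.finite(se2) || se1 <= 0 || se2 <= 0) {
    stop("non-positive or missing standard errors")
  }
  z <- (a$gamma_cor - b$gamma_cor) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Stratify pairs by mediator effect sign and multiplicity
#'
#' Pairs with detectable mediation are stratified into a 3 x 2 table:
#' exposure-to-mediator effect sign (Negative / Positive / Bivalent, the
#' latter when a pair's mediators carry both signs) crossed with mediator
#' multiplicity (mono: 1 mediator; multi: > 1). Mono pairs cannot be
#' Bivalent. Per-stratum MPs come from the slope regression
#' ([mp_from_effects()]); signs are taken from the retained mediators'
#' univariable exposure-to-mediator estimates.
#'
#' @param pairs list of [mediate_pair()] results (detectable pairs are used).
#' @param min_pairs minimum pairs for a stratum MP (default 2).
#' @return data frame with columns `sign`, `multiplicity`, `n`, `mp`,
#'   `ci_lo`, `ci_hi`, `mean_n_med`.
#' @export
stratify_pairs <- function(pairs, min_pairs = 2) {
  det <- Filter(function(p) p$status == "ok" && isTRUE(p$detectable), pairs)
  info <- lapply(det, function(p) {
    signs <- sign(p$mediators$alpha_EM)
    cls <- if (all(signs < 0)) "Negative" else if (all(signs > 0)) "Positive" else "Bivalent"
    data.frame(sign = cls,
               multiplicity = if (p$n_med == 1) "mono" else "multi",
               theta_T = p$theta_T, se_T = p$se_T, theta_D = p$theta_D,
               n_med = p$n_med, stringsAsFactors = FALSE)
  })
  info <- if (length(info)) do.call(rbind, info) else
    data.frame(sign = character(0), multiplicity = character(0),
               theta_T = numeric(0), se_T = numeric(0), theta_D = numeric(0),
               n_med = integer(0))
  grid <- expand.grid(sign = c("Negative", "Positive", "Bivalent"),
                      multiplicity = c("mono", "multi"),
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$sign == "Bivalent" & grid$multiplicity == "mono"), ]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- info[info$sign == grid$sign[i] & info$multiplicity == grid$multiplicity[i], ]
    base <- data.frame(sign = grid$sign[i], multiplicity = grid$multiplicity[i],
                       n = nrow(d), mp = NA_real_, ci_lo = NA_real_,
                       ci_hi = NA_real_,
                       mean_n_med = if (nrow(d)) mean(d$n_med) else NA_real_,
                       stringsAsFactors = FALSE)
    if (nrow(d) >= max(2, min_pairs)) {
      est <- tryCatch(mp_from_effects(d$theta_D, d$theta_T, d$se_T),
                      error = function(e) NULL)
      if (!is.null(est)) {
        base$mp <- est$mp; base$ci_lo <- est$ci95[1]; base$ci_hi <- est$ci95[2]
      }
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
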
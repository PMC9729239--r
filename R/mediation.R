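#' Select cis mediator candidates by exposure-to-mediator MR
#'
#' For every transcript whose TSS lies within `window` bp of the exposure
#' feature (same chromosome), the exposure's causal effect on the transcript
#' (`alpha_EM`) is estimated by univariable IVW MR over the exposure
#' instruments, after Steiger-filtering those instruments against the
#' transcript; transcripts with `p_EM < p_em` are retained as mediators.
#' Transcript effects unreported at an exposure instrument are set to zero
#' (sub-reporting-threshold convention).
#'
#' @param exposure harmonized [summary_stats()] for the exposure, with
#'   `feature_chrom`/`feature_pos` attributes set.
#' @param transcripts named list of harmonized [summary_stats()] tables for
#'   candidate mediators, each with `feature_chrom`/`feature_pos` (TSS) set.
#' @param ld [ld_panel()] covering the instruments.
#' @param exposure_ivs exposure instrument IDs (selected and Steiger-filtered
#'   against the outcome).
#' @param window cis window half-width in bp (default 5e5).
#' @param p_em selection threshold on the exposure-to-mediator MR p-value
#'   (default 0.01).
#' @param t_rev Steiger threshold (default -2).
#' @param min_ivs minimum exposure instruments surviving the per-candidate
#'   Steiger filter (default 3).
#' @param keep_all return all assessed cis candidates (with a `selected`
#'   column) rather than only the retained ones.
#' @return data frame with columns `mediator_id`, `alpha_EM`, `se_EM`, `p_EM`,
#'   `n_ivs_EM`, `tss_distance`, `selected`.
#' @export
select_mediators <- function(exposure, transcripts, ld, exposure_ivs,
                             window = 5e5, p_em = 0.01, t_rev = -2,
                             min_ivs = 3, keep_all = FALSE) {
  probe_chrom <- attr(exposure, "feature_chrom")
  probe_pos <- attr(exposure, "feature_pos")
  exp_df <- as.data.frame(exposure)
  rows <- list()
  for (id in names(transcripts)) {
    tr <- transcripts[[id]]
    tss_chrom <- attr(tr, "feature_chrom")
    tss <- attr(tr, "feature_pos")
    if (is.na(tss) || is.na(probe_pos)) next
    if (!is.na(tss_chrom) && !is.na(probe_chrom) && tss_chrom != probe_chrom) next
    dist <- abs(tss - probe_pos)
    if (dist > window) next

    i <- match(exposure_ivs, exp_df$variant_id)
    bE <- exp_df$beta[i]; vE <- exp_df$se[i]^2
    tr_df <- as.data.frame(tr)
    if (!nrow(tr_df)) next  # transcript reported nothing in the region
    j <- match(exposure_ivs, tr_df$variant_id)
    bM <- ifelse(is.na(j), 0, tr_df$beta[j])
    vM <- ifelse(is.na(j), 1 / mean(tr_df$n), tr_df$se[j]^2)

    pass <- steiger_filter(bE, vE, bM, vM, t_rev)
    if (sum(pass) < min_ivs) next
    ids <- exposure_ivs[pass]
    est <- ivw_correlated(bE[pass], bM[pass], vE[pass], vM[pass],
                          C = ld_subset(ld, ids)$R)
    rows[[id]] <- data.frame(mediator_id = id, alpha_EM = est$theta,
                             se_EM = est$se, p_EM = est$pvalue,
                             n_ivs_EM = est$m, tss_distance = dist,
                             selected = est$pvalue < p_em,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mediator_id = character(0), alpha_EM = numeric(0),
               se_EM = numeric(0), p_EM = numeric(0), n_ivs_EM = integer(0),
               tss_distance = numeric(0), selected = logical(0))
  rownames(out) <- NULL
  if (keep_all) out else out[out$selected, , drop = FALSE]
}

#' Clump correlated mediators
#'
#' Greedy retention by ascending `p_EM`: a candidate is dropped if its
#' absolute correlation with any already-kept mediator is at least `r_med`.
#' Mediator correlations are computed from QTL effect sizes over a shared set
#' of independent instruments; pairs sharing fewer than 2 instruments with
#' effects in both tables are treated as uncorrelated (with a warning).
#'
#' @param cands data frame from [select_mediators()] (requires `mediator_id`,
#'   `p_EM`).
#' @param qtl_effects matrix of QTL effect sizes (instruments x mediators,
#'   `NA` for unreported) used for the correlations.
#' @param r_med correlation threshold (default 0.3).
#' @return the clumped candidate data frame.
#' @export
clump_mediators <- function(cands, qtl_effects, r_med = 0.3) {
  if (nrow(cands) < 2) return(cands)
  cands <- cands[order(cands$p_EM), , drop = FALSE]
  kept <- integer(0)
  warned <- FALSE
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    for (j in kept) {
      x <- qtl_effects[, cands$mediator_id[i]]
      y <- qtl_effects[, cands$mediator_id[j]]
      shared <- is.finite(x) & is.finite(y)
      if (sum(shared) < 2) {
        if (!warned) {
          warning("mediator pair(s) with < 2 shared instruments treated as ",
                  "uncorrelated", call. = FALSE)
          warned <- TRUE
        }
        next
      }
      r <- suppressWarnings(stats::cor(x[shared], y[shared]))
      if (is.finite(r) && abs(r) >= r_med) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  cands[kept, , drop = FALSE]
}

#' Default per-pair mediation settings
#'
#' @param p_iv instrument significance threshold (default 1e-6).
#' @param r2_iv instrument pruning threshold (default 0.05).
#' @param min_ivs minimum selected exposure instruments (default 5).
#' @param min_ivs_post_steiger minimum exposure instruments after all Steiger
#'   filters (default 3).
#' @param p_em mediator selection threshold (default 0.01).
#' @param window_mediators cis half-window for mediator candidacy, bp
#'   (default 5e5).
#' @param window_ivs cis half-window for instrument selection, bp
#'   (default 1e6).
#' @param t_rev Steiger threshold (default -2).
#' @param r_med mediator clumping threshold for the `uncorrelated` variant
#'   (default 0.3).
#' @return list of settings for [mediate_pair()].
#' @export
mediation_config <- function(p_iv = 1e-6, r2_iv = 0.05, min_ivs = 5,
                             min_ivs_post_steiger = 3, p_em = 0.01,
                             window_mediators = 5e5, window_ivs = 1e6,
                             t_rev = -2, r_med = 0.3) {
  list(p_iv = p_iv, r2_iv = r2_iv, min_ivs = min_ivs,
       min_ivs_post_steiger = min_ivs_post_steiger, p_em = p_em,
       window_mediators = window_mediators, window_ivs = window_ivs,
       t_rev = t_rev, r_med = r_med)
}

# effects of a table at given instrument ids (0 where unreported)
.effects_at <- function(stats, ids) {
  d <- as.data.frame(stats)
  i <- match(ids, d$variant_id)
  list(beta = ifelse(is.na(i), 0, d$beta[i]),
       var = ifelse(is.na(i), 1 / mean(d$n), d$se[i]^2),
       p = ifelse(is.na(i), 1, d$pvalue[i]))
}

#' Per-pair mediation analysis
#'
#' Runs the full exposure-outcome workflow for one pair: exposure instrument
#' selection and Steiger filtering against the outcome, total-effect IVW,
#' mediator selection in cis, Steiger filtering of exposure instruments
#' against each retained mediator, mediator instrument selection (with Steiger
#' filtering against the outcome), rank-score clumping of the pooled
#' instrument set, MVMR for the direct effect, conditional F and heterogeneity
#' diagnostics, and the per-pair mediation proportion `1 - theta_D/theta_T`
#' (unclamped). If no mediator passes selection, mediation is not detectable
#' and `theta_D` is set to `theta_T` (per-pair MP 0).
#'
#' @param exposure,outcome harmonized [summary_stats()] tables.
#' @param transcripts named list of harmonized [summary_stats()] mediator
#'   tables.
#' @param ld [ld_panel()] covering the region.
#' @param cfg settings from [mediation_config()].
#' @param variant one of `"full"`, `"top_mediator"` (sole lowest-`p_EM`
#'   mediator), `"uncorrelated"` ([clump_mediators()] first), `"leave_top_iv"`
#'   (drop the lowest-p exposure instrument from both effects).
#' @return list of class `pair_result` with effect estimates, diagnostics and
#'   the retained mediator table; `status` is `"ok"`, `"insufficient_ivs"` or
#'   `"insufficient_ivs_post_steiger"`.
#' @export
mediate_pair <- function(exposure, transcripts, outcome, ld,
                         cfg = mediation_config(),
                         variant = c("full", "top_mediator", "uncorrelated",
                                     "leave_top_iv")) {
  variant <- match.arg(variant)
  pair_id <- paste0(attr(exposure, "trait_id"), ":", attr(outcome, "trait_id"))
  res <- structure(list(pair_id = pair_id, variant = variant, status = "ok",
                        has_cis_transcript = FALSE, detectable = FALSE),
                   class = "pair_result")

  probe_chrom <- attr(exposure, "feature_chrom")
  probe_pos <- attr(exposure, "feature_pos")
  win <- if (!is.na(probe_pos)) probe_pos + c(-1, 1) * cfg$window_ivs else NULL
  ivs <- select_instruments(exposure, ld, cfg$p_iv, cfg$r2_iv,
                            window = win, chrom = probe_chrom)
  if (length(ivs) < cfg$min_ivs) {
    res$status <- "insufficient_ivs"; res$m_selected <- length(ivs)
    return(res)
  }
  res$m_selected <- length(ivs)

  eE <- .effects_at(exposure, ivs)
  eY <- .effects_at(outcome, ivs)
  pass <- steiger_filter(eE$beta, eE$var, eY$beta, eY$var, cfg$t_rev)
  ivs <- ivs[pass]

  if (variant == "leave_top_iv" && length(ivs)) {
    top <- ivs[which.min(.effects_at(exposure, ivs)$p)]
    ivs <- setdiff(ivs, top)
  }

  # cis mediator candidacy needs >= 3 exposure IVs per candidate; check later
  cands <- select_mediators(exposure, transcripts, ld, ivs,
                            window = cfg$window_mediators, p_em = cfg$p_em,
                            t_rev = cfg$t_rev,
                            min_ivs = cfg$min_ivs_post_steiger,
                            keep_all = TRUE)
  res$has_cis_transcript <- nrow(cands) > 0 || any(vapply(transcripts, function(tr) {
    tss <- attr(tr, "feature_pos"); tc <- attr(tr, "feature_chrom")
    !is.na(tss) && !is.na(probe_pos) &&
      (is.na(tc) || is.na(probe_chrom) || tc == probe_chrom) &&
      abs(tss - probe_pos) <= cfg$window_mediators
  }, logical(1)))
  res$candidates <- cands
  meds <- cands[cands$selected, , drop = FALSE]

  if (variant == "uncorrelated" && nrow(meds) > 1) {
    eff <- vapply(meds$mediator_id, function(id) {
      d <- as.data.frame(transcripts[[id]])
      i <- match(ivs, d$variant_id)
      ifelse(is.na(i), NA_real_, d$beta[i])
    }, numeric(length(ivs)))
    eff <- matrix(eff, nrow = length(ivs),
                  dimnames = list(ivs, meds$mediator_id))
    meds <- clump_mediators(meds, eff, cfg$r_med)
  }
  if (variant == "top_mediator" && nrow(meds) > 1) {
    meds <- meds[which.min(meds$p_EM), , drop = FALSE]
  }

  # exposure IVs must pass Steiger against every retained mediator
  if (nrow(meds)) {
    eE <- .effects_at(exposure, ivs)
    keep <- rep(TRUE, length(ivs))
    for (id in meds$mediator_id) {
      eM <- .effects_at(transcripts[[id]], ivs)
      keep <- keep & steiger_filter(eE$beta, eE$var, eM$beta, eM$var, cfg$t_rev)
    }
    ivs <- ivs[keep]
  }
  if (length(ivs) < cfg$min_ivs_post_steiger) {
    res$status <- "insufficient_ivs_post_steiger"
    res$m_post_steiger <- length(ivs)
    return(res)
  }
  res$m_post_steiger <- length(ivs)

  eE <- .effects_at(exposure, ivs)
  eY <- .effects_at(outcome, ivs)
  tot <- ivw_correlated(eE$beta, eY$beta, eE$var, eY$var,
                        C = ld_subset(ld, ivs)$R)
  res$theta_T <- tot$theta; res$se_T <- tot$se; res$p_T <- tot$pvalue
  res$m_T <- tot$m
  res$Q_uni <- if (tot$m >= 2) q_statistic_univariable(tot) else NULL

  if (!nrow(meds)) {
    res$detectable <- FALSE
    res$theta_D <- res$theta_T; res$se_D <- res$se_T
    res$mp_pair <- 0
    res$mediators <- meds; res$n_med <- 0L
    return(res)
  }
  res$detectable <- TRUE

  # mediator-associated instruments: cis-significant, pruned, Steiger vs outcome
  med_cand_ivs <- list()
  med_tables <- list()
  for (id in meds$mediator_id) {
    tr <- transcripts[[id]]
    tss <- attr(tr, "feature_pos")
    mwin <- if (!is.na(tss)) tss + c(-1, 1) * cfg$window_ivs else NULL
    miv <- select_instruments(tr, ld, cfg$p_iv, cfg$r2_iv, window = mwin,
                              chrom = attr(tr, "feature_chrom"))
    if (length(miv)) {
      eM <- .effects_at(tr, miv)
      eYm <- .effects_at(outcome, miv)
      miv <- miv[steiger_filter(eM$beta, eM$var, eYm$beta, eYm$var, cfg$t_rev)]
    }
    d <- as.data.frame(tr)
    i <- match(miv, d$variant_id)
    med_cand_ivs[[id]] <- data.frame(variant_id = miv, pvalue = d$pvalue[i],
                                     pos = d$pos[i], stringsAsFactors = FALSE)
    med_tables[[id]] <- tr
  }

  pooled <- rank_score_clump(ivs, med_cand_ivs, ld, cfg$r2_iv)
  prob <- build_design_matrix(exposure, med_tables, outcome, pooled, ld)
  fit <- mvmr_correlated(prob)

  # univariable mediator-to-outcome MR when a mediator has >= 3 own instruments
  alpha_MY <- fit$alpha_MY
  se_MY <- fit$se_MY
  for (id in fit$mediator_ids) {
    own <- med_cand_ivs[[id]]$variant_id
    own <- intersect(own, pooled)
    if (length(own) >= 3) {
      eM <- .effects_at(med_tables[[id]], own)
      eYm <- .effects_at(outcome, own)
      uni <- ivw_correlated(eM$beta, eYm$beta, eM$var, eYm$var,
                            C = ld_subset(ld, own)$R)
      alpha_MY[id] <- uni$theta; se_MY[id] <- uni$se
    }
  }

  res$theta_D <- fit$theta_D; res$se_D <- fit$se_D; res$p_D <- fit$p_D
  res$mp_pair <- 1 - fit$theta_D / res$theta_T
  meds$alpha_MY <- alpha_MY[match(meds$mediator_id, names(alpha_MY))]
  meds$se_MY <- se_MY[match(meds$mediator_id, names(se_MY))]
  res$mediators <- meds
  res$n_med <- nrow(meds)
  res$m_mvmr <- fit$m; res$k <- fit$k
  res$dropped_mediators <- fit$dropped_mediators
  res$F_cond <- conditional_f(prob, n_E = round(mean(exposure$n)))
  res$Q_mvmr <- if (fit$m > fit$k) q_statistic_mvmr(fit) else NULL
  res
}

#' @export
print.pair_result <- function(x, ...) {
  cat("<pair_result> ", x$pair_id, " [", x$variant, "] status=", x$status, "\n",
      sep = "")
  if (x$status == "ok") {
    cat(sprintf("  theta_T = %.4g (SE %.4g), theta_D = %.4g, MP = %.3f, n_med = %d\n",
                x$theta_T, x$se_T, x$theta_D, x$mp_pair,
                if (is.null(x$n_med)) 0L else x$n_med))
  }
  invisible(x)
}

#' Product-of-coefficients indirect effect
#'
#' Alternative to the difference method: the indirect effect is the sum over
#' retained mediators of the exposure-to-mediator effect times the
#' mediator-to-outcome direct effect, `theta_M = sum_k alpha_EM_k *
#' alpha_MY_k`; the implied direct effect is `theta_T - theta_M`. On a
#' noiseless causal chain the two methods agree exactly.
#'
#' @param pair a [mediate_pair()] result (needs `mediators` with `alpha_EM`,
#'   `alpha_MY`, and `theta_T`).
#' @return list `theta_M_alt`, `theta_D_alt`.
#' @export
product_of_coefficients <- function(pair) {
  med <- pair$mediators
  if (is.null(med) || !nrow(med)) return(list(theta_M_alt = 0, theta_D_alt = pair$theta_T))
  ok <- is.finite(med$alpha_MY)
  if (any(!ok)) {
    warning(sum(!ok), " mediator(s) without alpha_MY skipped", call. = FALSE)
  }
  theta_M <- sum(med$alpha_EM[ok] * med$alpha_MY[ok])
  list(theta_M_alt = theta_M, theta_D_alt = pair$theta_T - theta_M)
}

#' Collect per-pair results into a table
#'
#' @param pairs list of [mediate_pair()] results.
#' @return data frame with one row per pair (testable or not).
#' @export
pairs_table <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    data.frame(pair_id = p$pair_id, variant = p$variant, status = p$status,
               theta_T = p$theta_T %||% NA_real_, se_T = p$se_T %||% NA_real_,
               p_T = p$p_T %||% NA_real_, theta_D = p$theta_D %||% NA_real_,
               se_D = p$se_D %||% NA_real_, mp_pair = p$mp_pair %||% NA_real_,
               n_med = p$n_med %||% NA_integer_,
               detectable = isTRUE(p$detectable),
               has_cis_transcript = isTRUE(p$has_cis_transcript),
               F_cond = p$F_cond %||% NA_real_,
               Q_uni = if (!is.null(p$Q_uni)) p$Q_uni$Q else NA_real_,
               Q_uni_p = if (!is.null(p$Q_uni)) p$Q_uni$p else NA_real_,
               Q_mvmr = if (!is.null(p$Q_mvmr)) p$Q_mvmr$Q else NA_real_,
               Q_mvmr_p = if (!is.null(p$Q_mvmr)) p$Q_mvmr$p else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
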
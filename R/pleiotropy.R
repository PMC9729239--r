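#' Multivariable QTL effects from marginal effects
#'
#' Converts marginal (univariable) per-SNP QTL effects over a set of variants
#' in LD into joint (multivariable) effects: `beta_multi = C_M^-1 beta_M`,
#' with `C_M` the LD submatrix of the variants (regularized before
#' inversion). Round trip: `C_M beta_multi = beta_M`.
#'
#' @param beta_M marginal effect vector.
#' @param C_M LD correlation matrix of the same variants.
#' @return multivariable effect vector.
#' @export
multivariable_effects <- function(beta_M, C_M) {
  C_M <- as.matrix(C_M)
  stopifnot(length(beta_M) == nrow(C_M))
  drop(ld_regularize(C_M)$inv %*% beta_M)
}

#' Marginal effects implied at other variants through LD
#'
#' Given joint per-SNP effects `beta_multi` at one variant set, the marginal
#' effects induced at another variant set are `beta_marginal = C_cross
#' beta_multi`, with `C_cross` the LD matrix between the two sets.
#'
#' @param beta_multi multivariable effect vector (length m_M).
#' @param C_cross m_E x m_M cross-LD matrix.
#' @return implied marginal effect vector (length m_E).
#' @export
marginalize_effects <- function(beta_multi, C_cross) {
  C_cross <- as.matrix(C_cross)
  if (ncol(C_cross) != length(beta_multi)) {
    stop("C_cross must have one column per multivariable effect")
  }
  drop(C_cross %*% beta_multi)
}

#' Configuration for the by-chance-LD pleiotropy null simulation
#'
#' @param n_sim hypothetical transcripts to simulate per pair (default 1000;
#'   scale up for production runs).
#' @param r2_pool pruning threshold for the random SNP pool (default 0.5,
#'   lenient by design).
#' @param seed random seed.
#' @return list of class `pleiotropy_sim_config`.
#' @export
pleiotropy_sim_config <- function(n_sim = 1000, r2_pool = 0.5, seed = 1) {
  stopifnot(n_sim >= 1)
  structure(list(n_sim = n_sim, r2_pool = r2_pool, seed = seed),
            class = "pleiotropy_sim_config")
}

#' By-chance-LD horizontal-pleiotropy null simulation
#'
#' Tests whether an observed exposure-transcript MR association could arise
#' merely from chance LD between cis-QTL signals. The real transcript's
#' multivariable eQTL effects (`beta_multi`, from its instruments via
#' [multivariable_effects()]) are reassigned, in each replicate, to `m_M`
#' randomly drawn SNPs from a leniently pruned (`r^2 < r2_pool`,
#' position-ordered greedy) pool; the marginal transcript effects this implies
#' at the exposure instruments follow from [marginalize_effects()], and a
#' univariable exposure-to-transcript MR is run on them. The simulation
#' p-value is the fraction of replicates whose MR p-value undercuts the real
#' pair's: `P_sim = #(P_EM_j < P_EM) / n_sim`.
#'
#' @param pair list describing the real pair: `exposure_ivs` (IDs),
#'   `beta_E`, `var_E` (exposure effects at those IVs), `mediator_ivs` (IDs of
#'   the transcript's instruments), `beta_M` (marginal eQTL effects there),
#'   `var_M` (scalar or vector), `p_em_ref` (the real pair's MR p-value).
#' @param ld [ld_panel()] containing both IV sets and the sampling pool.
#' @param cfg a [pleiotropy_sim_config()].
#' @param pool optional character vector restricting the sampling pool (e.g.
#'   the cis region's variants); defaults to the whole panel.
#' @return list of class `pleiotropy_sim_result`: `p_sim`, `n_sim`,
#'   `null_p_values`.
#' @export
run_pleiotropy_sim <- function(pair, ld, cfg = pleiotropy_sim_config(),
                               pool = NULL) {
  m_M <- length(pair$mediator_ivs)
  stopifnot(m_M >= 1, length(pair$beta_M) == m_M)
  set.seed(cfg$seed)

  C_M <- ld_subset(ld, pair$mediator_ivs)$R
  beta_multi <- multivariable_effects(pair$beta_M, C_M)

  pool_ids <- if (is.null(pool)) ld$variant_ids else pool
  ord <- order(ld$pos[match(pool_ids, ld$variant_ids)])
  pruned <- greedy_r2_clump(pool_ids[ord], ld, cfg$r2_pool)
  if (length(pruned) < m_M) {
    stop("pruned SNP pool (", length(pruned), ") smaller than m_M = ", m_M)
  }

  var_M <- rep_len(pair$var_M, m_M)
  null_p <- vapply(seq_len(cfg$n_sim), function(j) {
    picked <- sample(pruned, m_M)
    C_cross <- ld$R[match(pair$exposure_ivs, ld$variant_ids),
                    match(picked, ld$variant_ids), drop = FALSE]
    beta_marg <- marginalize_effects(beta_multi, C_cross)
    est <- ivw_correlated(pair$beta_E, beta_marg, pair$var_E, mean(var_M),
                          C = ld_subset(ld, pair$exposure_ivs)$R)
    est$pvalue
  }, numeric(1))

  structure(list(p_sim = mean(null_p < pair$p_em_ref), n_sim = cfg$n_sim,
                 null_p_values = null_p),
            class = "pleiotropy_sim_result")
}

#' @export
print.pleiotropy_sim_result <- function(x, ...) {
  cat(sprintf("P_sim = %.4g (%d null replicates)\n", x$p_sim, x$n_sim))
  invisible(x)
}
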
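#' Select near-independent instruments by greedy p-value clumping
#'
#' Variants inside the cis window with association p-value below `p_thresh` are
#' visited in order of ascending p-value; a variant is kept iff its squared
#' correlation with every already-kept variant is below `r2_thresh`.
#'
#' @param stats a [summary_stats()] table harmonized against `ld`.
#' @param ld an [ld_panel()] covering the table's variants.
#' @param p_thresh significance threshold (default 1e-6, the cis-QTL
#'   reporting convention).
#' @param r2_thresh squared-correlation pruning threshold (default 0.05).
#' @param window optional `c(lo, hi)` basepair interval (inclusive) restricting
#'   candidates, e.g. a < 1 Mb cis window around the molecular feature.
#' @param chrom optional chromosome restriction accompanying `window`.
#' @return character vector of selected variant IDs (possibly empty), in
#'   selection order.
#' @export
select_instruments <- function(stats, ld, p_thresh = 1e-6, r2_thresh = 0.05,
                               window = NULL, chrom = NULL) {
  cand <- as.data.frame(stats)
  if (!is.null(window)) {
    cand <- cand[cand$pos >= window[1] & cand$pos <= window[2], , drop = FALSE]
  }
  if (!is.null(chrom)) cand <- cand[cand$chrom == chrom, , drop = FALSE]
  cand <- cand[cand$pvalue < p_thresh & cand$variant_id %in% ld$variant_ids, ,
               drop = FALSE]
  if (!nrow(cand)) return(character(0))
  cand <- cand[order(cand$pvalue, cand$pos), , drop = FALSE]
  greedy_r2_clump(cand$variant_id, ld, r2_thresh)
}

# greedy r^2 clumping of `ids` (already in priority order) against `kept`
greedy_r2_clump <- function(ids, ld, r2_thresh, kept = character(0)) {
  out <- kept
  for (id in ids) {
    if (!length(out)) { out <- id; next }
    r2 <- ld$R[id, out]^2
    if (all(r2 < r2_thresh)) out <- c(out, id)
  }
  setdiff(out, kept)
}

#' Steiger directionality filter
#'
#' Guards against reverse causation: an instrument for trait X is retained for
#' use against downstream trait Z only if its effect on Z is not credibly
#' larger than its effect on X, i.e.
#' `t = (|beta_X| - |beta_Z|) / sqrt(var_X + var_Z) > t_rev`.
#' The default `t_rev = -2` corresponds to a one-sided normal test at
#' p = 0.023 (see [steiger_threshold_p()]).
#'
#' @param beta_X,var_X instrument effects and variances on the upstream trait.
#' @param beta_Z,var_Z effects and variances on the downstream trait.
#' @param t_rev threshold (default -2).
#' @return logical mask, `TRUE` for instruments passing the filter.
#' @export
steiger_filter <- function(beta_X, var_X, beta_Z, var_Z, t_rev = -2) {
  stopifnot(length(beta_X) == length(beta_Z),
            length(var_X) == length(beta_X),
            length(var_Z) == length(beta_X))
  if (any(var_X <= 0) || any(var_Z <= 0)) stop("variances must be positive")
  t <- (abs(beta_X) - abs(beta_Z)) / sqrt(var_X + var_Z)
  t > t_rev
}

#' Convert between the Steiger threshold and its one-sided p-value
#'
#' `steiger_threshold_p(-2)` returns 0.023 (to three decimals): the one-sided
#' tail probability of the standard normal at the threshold.
#'
#' @param t_rev threshold on the directionality statistic.
#' @return one-sided p-value.
#' @export
steiger_threshold_p <- function(t_rev = -2) stats::pnorm(t_rev)

#' @rdname steiger_threshold_p
#' @param p one-sided p-value.
#' @export
steiger_p_threshold <- function(p) stats::qnorm(p)

#' Distance-based clumping of significant exposures
#'
#' Exposures (e.g. DNAm probes) retained after the total-effect significance
#' filter are clumped so that no two kept probes on the same chromosome lie
#' within `distance` bp of each other; priority is ascending p-value of the
#' total causal effect, ties broken by position.
#'
#' @param df data frame with columns `id`, `chrom`, `pos`, `p`.
#' @param distance clumping distance in bp (default 1e6).
#' @return character vector of kept IDs.
#' @export
distance_clump <- function(df, distance = 1e6) {
  df <- df[order(df$p, df$pos), , drop = FALSE]
  kept <- df[0, , drop = FALSE]
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    if (!nrow(kept) ||
        !any(kept$chrom == row$chrom & abs(kept$pos - row$pos) <= distance)) {
      kept <- rbind(kept, row)
    }
  }
  kept$id
}
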
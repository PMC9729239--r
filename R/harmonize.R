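palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary-statistic tables against an LD panel
#'
#' Restricts all tables and the panel to shared autosomal variants, aligns
#' alleles to the first table's effect allele (flipping effect signs and allele
#' frequencies on swaps), removes palindromic (A/T, C/G) variants, removes
#' variants whose allele frequency differs by more than `af_tol` between any
#' pair of datasets (after orienting frequencies to the common effect allele),
#' and returns tables ordered to match the LD panel. If the panel carries
#' allele columns, its correlation signs are aligned to the same effect-allele
#' convention. The operation is idempotent.
#'
#' @param tables list of [summary_stats()] tables (>= 2 recommended; 1 allowed).
#' @param ld an [ld_panel()].
#' @param af_tol maximum tolerated pairwise allele-frequency difference
#'   (default 0.05).
#' @param ref_af optional named numeric vector of reference allele frequencies
#'   (by variant ID, oriented to the first table's effect allele) substituted
#'   for tables lacking frequencies.
#' @return list with `tables` (harmonized, panel order) and `ld` (panel subset).
#' @export
harmonize <- function(tables, ld, af_tol = 0.05, ref_af = NULL) {
  if (!length(tables)) stop("no tables supplied")
  tables <- lapply(tables, function(t) ss_subset(t, t$chrom %in% 1:22))

  common <- Reduce(intersect, c(lapply(tables, function(t) t$variant_id),
                                list(ld$variant_ids)))
  if (!length(common)) stop("no variants shared by all tables and the LD panel")

  ref <- as.data.frame(tables[[1]])
  ref <- ref[match(common, ref$variant_id), ]
  keep <- !palindromic(ref$effect_allele, ref$other_allele)
  n_pal <- sum(!keep)
  if (n_pal) message(n_pal, " palindromic variant(s) removed")
  common <- common[keep]
  ref <- ref[keep, , drop = FALSE]
  if (!length(common)) stop("no variants left after palindrome removal")

  # align every table to the reference effect allele
  aligned <- vector("list", length(tables))
  drop_mismatch <- character(0)
  for (j in seq_along(tables)) {
    t <- as.data.frame(tables[[j]])
    t <- t[match(common, t$variant_id), , drop = FALSE]
    same <- t$effect_allele == ref$effect_allele & t$other_allele == ref$other_allele
    swap <- t$effect_allele == ref$other_allele & t$other_allele == ref$effect_allele
    bad <- !(same | swap)
    if (any(bad)) drop_mismatch <- union(drop_mismatch, t$variant_id[bad])
    t$beta[swap] <- -t$beta[swap]
    t$eaf[swap] <- 1 - t$eaf[swap]
    t$effect_allele <- ref$effect_allele
    t$other_allele <- ref$other_allele
    aligned[[j]] <- t
  }
  if (length(drop_mismatch)) {
    warning(length(drop_mismatch),
            " variant(s) dropped: alleles neither match nor swap", call. = FALSE)
    keep <- !(common %in% drop_mismatch)
    common <- common[keep]
    aligned <- lapply(aligned, function(t) t[keep, , drop = FALSE])
  }
  if (!length(common)) stop("no variants left after allele alignment")

  # allele-frequency consistency filter (pairwise, oriented frequencies)
  af <- vapply(aligned, function(t) t$eaf, numeric(length(common)))
  af <- matrix(af, nrow = length(common))
  if (!is.null(ref_af)) {
    sub <- ref_af[common]
    for (j in seq_len(ncol(af))) {
      miss <- is.na(af[, j]) & !is.na(sub)
      af[miss, j] <- sub[miss]
    }
  }
  rng <- apply(af, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) 0 else max(v) - min(v)
  })
  keep <- rng <= af_tol
  if (any(!keep)) {
    message(sum(!keep), " variant(s) removed by allele-frequency filter (> ",
            af_tol, ")")
    common <- common[keep]
    aligned <- lapply(aligned, function(t) t[keep, , drop = FALSE])
  }
  if (!length(common)) stop("no variants left after allele-frequency filter")

  # panel order; sign-align panel correlations if panel alleles are known
  panel_order <- ld$variant_ids[ld$variant_ids %in% common]
  sub <- ld_subset(ld, panel_order)
  ord <- match(panel_order, common)
  aligned <- lapply(aligned, function(t) t[ord, , drop = FALSE])
  ref_ea <- aligned[[1]]$effect_allele
  if (!is.null(sub$a1)) {
    flip <- sub$a1 != ref_ea & sub$a2 == ref_ea
    if (any(flip)) {
      s <- ifelse(flip, -1, 1)
      sub$R <- sub$R * (s %o% s)
      tmp <- sub$a1[flip]; sub$a1[flip] <- sub$a2[flip]; sub$a2[flip] <- tmp
      dimnames(sub$R) <- list(sub$variant_ids, sub$variant_ids)
    }
  }

  out <- Map(function(t, orig) {
    summary_stats(t, attr(orig, "trait_id"), attr(orig, "trait_role"),
                  feature_chrom = attr(orig, "feature_chrom"),
                  feature_pos = attr(orig, "feature_pos"), validate = FALSE)
  }, aligned, tables)
  list(tables = out, ld = sub)
}
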
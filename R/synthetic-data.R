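#' Blueprint for a synthetic cis region
#'
#' Describes one exposure (a DNAm-probe-like molecular feature), its cis
#' transcripts and an outcome over a shared LD panel with AR(1) correlation
#' structure (`r_ij = ld_decay^|i-j|`, positive definite by construction).
#' Causal QTL positions are laid out in disjoint blocks (exposure block first,
#' then one block per transcript) separated by `block_gap` grid steps so that
#' exposure and mediator QTL signals are in negligible LD unless requested
#' otherwise. Per-table reporting thresholds mimic the consortium convention
#' of publishing only significant cis associations (mQTL-style tables report
#' p < 1e-6 rows; eQTL-style tables report p < 1.8e-5; the GWAS reports all
#' variants), which exercises the set-to-zero rule downstream.
#'
#' @param region_id region label (used in variant IDs).
#' @param chrom chromosome (1..22).
#' @param start basepair position of the first variant.
#' @param n_snps grid size (default 120).
#' @param spacing basepair distance between adjacent variants (default 2000).
#' @param ld_decay AR(1) correlation parameter in [0, 1) (default 0.6).
#' @param maf_range allele-frequency range, drawn uniformly and shared across
#'   tables (default c(0.1, 0.5)).
#' @param n_exposure_qtls causal exposure QTLs (default 8).
#' @param h2_E exposure cis heritability (default 0.05).
#' @param qtl_stride grid steps between causal QTLs within a block
#'   (default 4; at the default decay this keeps causal QTLs near-independent).
#' @param block_gap grid steps between QTL blocks (default 10).
#' @param transcripts data frame with columns `id`, `tss_offset` (bp relative
#'   to the probe), `alpha_EM`, `alpha_MY`, `h2_direct`, `n_qtls`; zero rows
#'   for a region without cis transcripts.
#' @param theta_D direct exposure-to-outcome effect.
#' @param n_exposure,n_mediator,n_outcome sample sizes (defaults 32851, 31684
#'   and 300000, mirroring large consortium mQTL/eQTL/GWAS studies).
#' @param p_report_mqtl,p_report_eqtl,p_report_gwas per-table reporting
#'   thresholds.
#' @param af_perturb shift added to one table's allele frequencies (exposure
#'   table) to exercise the harmonizer's AF filter (default 0).
#' @return list of class `region_blueprint` with a computed `layout`
#'   (causal indices per feature).
#' @export
region_blueprint <- function(region_id = "region1", chrom = 1, start = 1e6,
                             n_snps = 120, spacing = 2000, ld_decay = 0.6,
                             maf_range = c(0.1, 0.5), n_exposure_qtls = 8,
                             h2_E = 0.05, qtl_stride = 4, block_gap = 10,
                             transcripts = data.frame(
                               id = "T1", tss_offset = 50000, alpha_EM = 0.4,
                               alpha_MY = 0.3, h2_direct = 0.05, n_qtls = 5),
                             theta_D = 0.1, n_exposure = 32851,
                             n_mediator = 31684, n_outcome = 3e5,
                             p_report_mqtl = 1e-6, p_report_eqtl = 1.8e-5,
                             p_report_gwas = 1, af_perturb = 0) {
  if (ld_decay >= 1 || ld_decay < 0) stop("ld_decay must be in [0, 1)")
  stopifnot(n_snps >= 2, chrom %in% 1:22)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)

  # causal-index layout: exposure block, then one block per transcript
  cursor <- 3L
  take_block <- function(n_qtls) {
    idx <- cursor + qtl_stride * (seq_len(n_qtls) - 1L)
    cursor <<- idx[length(idx)] + block_gap
    idx
  }
  layout <- list(exposure = take_block(n_exposure_qtls))
  for (i in seq_len(nrow(transcripts))) {
    layout[[transcripts$id[i]]] <- take_block(transcripts$n_qtls[i])
  }
  needed <- cursor - block_gap
  if (needed > n_snps) {
    stop("n_snps = ", n_snps, " too small for QTL layout (needs ", needed, ")")
  }
  probe_pos <- start + spacing * (stats::median(layout$exposure) - 1)
  structure(list(region_id = region_id, chrom = chrom, start = start,
                 n_snps = n_snps, spacing = spacing, ld_decay = ld_decay,
                 maf_range = maf_range, n_exposure_qtls = n_exposure_qtls,
                 h2_E = h2_E, transcripts = transcripts, theta_D = theta_D,
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome = n_outcome, p_report_mqtl = p_report_mqtl,
                 p_report_eqtl = p_report_eqtl, p_report_gwas = p_report_gwas,
                 af_perturb = af_perturb, layout = layout,
                 probe_pos = probe_pos),
            class = "region_blueprint")
}

#' Generate the AR(1) LD panel of a blueprint
#'
#' @param bp a [region_blueprint()].
#' @param seed unused (the panel is deterministic); kept for interface
#'   symmetry.
#' @return an [ld_panel()] with `r_ij = ld_decay^|i-j|`.
#' @export
generate_ld_panel <- function(bp, seed = NULL) {
  i <- seq_len(bp$n_snps)
  R <- bp$ld_decay^abs(outer(i, i, "-"))
  ids <- sprintf("%s_s%03d", bp$region_id, i)
  ld_panel(R, ids, chrom = rep(bp$chrom, bp$n_snps),
           pos = bp$start + bp$spacing * (i - 1))
}

# non-palindromic allele pairs
.allele_pairs <- rbind(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                       c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))

#' Generate a synthetic cis region in memory
#'
#' Draws causal per-SNP effects for the exposure, each transcript (own direct
#' QTLs plus the exposure-mediated component `alpha_EM * beta_E`) and the
#' outcome (`theta_D * beta_E + sum_k alpha_MY_k * beta_Mk`), maps them
#' through the LD panel to marginal effects (`beta_marginal = C
#' beta_causal`), adds sampling noise at each table's sample size, and applies
#' the reporting thresholds (suppressed rows are absent from the table).
#'
#' @param bp a [region_blueprint()].
#' @param seed random seed.
#' @return list: `exposure`, `transcripts` (named list), `outcome`
#'   ([summary_stats()] tables), `ld` ([ld_panel()]), `truth` (list with
#'   `theta_D`, `theta_M`, `theta_T`, `mp`, `mediators` data frame,
#'   `probe_pos`).
#' @export
generate_region <- function(bp, seed = 1) {
  set.seed(seed)
  ld <- generate_ld_panel(bp)
  n <- bp$n_snps
  tr <- bp$transcripts

  c_E <- numeric(n)
  c_E[bp$layout$exposure] <- draw_rescaled(bp$n_exposure_qtls, bp$h2_E)
  c_M <- matrix(0, n, nrow(tr))
  for (i in seq_len(nrow(tr))) {
    c_M[bp$layout[[tr$id[i]]], i] <- draw_rescaled(tr$n_qtls[i], tr$h2_direct[i])
    c_M[, i] <- c_M[, i] + tr$alpha_EM[i] * c_E
  }
  theta_M <- if (nrow(tr)) sum(tr$alpha_EM * tr$alpha_MY) else 0
  theta_T <- bp$theta_D + theta_M
  c_Y <- bp$theta_D * c_E +
    (if (nrow(tr)) drop(c_M %*% tr$alpha_MY) else 0)

  eaf <- stats::runif(n, bp$maf_range[1], bp$maf_range[2])
  al <- .allele_pairs[sample(nrow(.allele_pairs), n, replace = TRUE), , drop = FALSE]

  observe <- function(causal, nn, eaf_shift = 0) {
    b <- drop(ld$R %*% causal) + stats::rnorm(n, 0, sqrt(1 / nn))
    data.frame(variant_id = ld$variant_ids, chrom = bp$chrom, pos = ld$pos,
               effect_allele = al[, 1], other_allele = al[, 2],
               eaf = pmin(pmax(eaf + eaf_shift, 0.001), 0.999),
               beta = b, se = 1 / sqrt(nn),
               pvalue = 2 * stats::pnorm(-abs(b) * sqrt(nn)), n = nn,
               stringsAsFactors = FALSE)
  }
  report <- function(d, p_thresh) d[d$pvalue < p_thresh, , drop = FALSE]

  exposure <- summary_stats(
    report(observe(c_E, bp$n_exposure, bp$af_perturb), bp$p_report_mqtl),
    trait_id = paste0(bp$region_id, "_probe"), trait_role = "exposure",
    feature_chrom = bp$chrom, feature_pos = bp$probe_pos, validate = FALSE)
  transcripts <- list()
  for (i in seq_len(nrow(tr))) {
    transcripts[[tr$id[i]]] <- summary_stats(
      report(observe(c_M[, i], bp$n_mediator), bp$p_report_eqtl),
      trait_id = tr$id[i], trait_role = "mediator",
      feature_chrom = bp$chrom,
      feature_pos = bp$probe_pos + tr$tss_offset[i], validate = FALSE)
  }
  outcome <- summary_stats(
    report(observe(c_Y, bp$n_outcome), bp$p_report_gwas),
    trait_id = "outcome", trait_role = "outcome",
    validate = FALSE)

  truth <- list(theta_D = bp$theta_D, theta_M = theta_M, theta_T = theta_T,
                mp = if (theta_T != 0) 1 - bp$theta_D / theta_T else NA_real_,
                mediators = tr, probe_pos = bp$probe_pos)
  list(exposure = exposure, transcripts = transcripts, outcome = outcome,
       ld = ld, truth = truth, blueprint = bp)
}

#' Write a region fixture to disk
#'
#' Serializes a [generate_region()] result as the plain-text formats consumed
#' by [read_summary_stats()] / [read_ld_panel()]: `mqtl.txt`,
#' `eqtl_<id>.txt`, `gwas.txt`, `ld_matrix.txt`, `ld_index.txt`, plus a
#' key-value `truth.txt` sidecar and a `features.txt` table of feature
#' anchors.
#'
#' @param bp a [region_blueprint()].
#' @param dir output directory (created if needed).
#' @param seed random seed passed to [generate_region()].
#' @return the directory path, invisibly; the in-memory region as attribute
#'   `"region"`.
#' @export
generate_region_fixture <- function(bp, dir, seed = 1) {
  region <- generate_region(bp, seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_summary_stats(region$exposure, file.path(dir, "mqtl.txt"))
  for (id in names(region$transcripts)) {
    write_summary_stats(region$transcripts[[id]],
                        file.path(dir, paste0("eqtl_", id, ".txt")))
  }
  write_summary_stats(region$outcome, file.path(dir, "gwas.txt"))
  write_ld_panel(region$ld, file.path(dir, "ld_matrix.txt"),
                 file.path(dir, "ld_index.txt"))
  tr <- region$truth$mediators
  feats <- rbind(
    data.frame(feature_id = attr(region$exposure, "trait_id"), role = "exposure",
               chrom = bp$chrom, pos = bp$probe_pos, stringsAsFactors = FALSE),
    if (nrow(tr)) data.frame(feature_id = tr$id, role = "mediator",
                             chrom = bp$chrom,
                             pos = bp$probe_pos + tr$tss_offset,
                             stringsAsFactors = FALSE))
  utils::write.table(feats, file.path(dir, "features.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tru <- region$truth
  kv <- c(theta_D = tru$theta_D, theta_M = tru$theta_M, theta_T = tru$theta_T,
          mp = tru$mp)
  writeLines(paste(names(kv), kv, sep = "\t"), file.path(dir, "truth.txt"))
  out <- invisible(dir)
  attr(out, "region") <- region
  out
}

#' Load a region fixture from disk
#'
#' @param dir a directory written by [generate_region_fixture()].
#' @return the same structure as [generate_region()] (without `blueprint`;
#'   `truth` holds the sidecar values).
#' @export
load_region <- function(dir) {
  feats <- utils::read.delim(file.path(dir, "features.txt"),
                             stringsAsFactors = FALSE)
  exp_feat <- feats[feats$role == "exposure", ]
  exposure <- read_summary_stats(file.path(dir, "mqtl.txt"),
                                 trait_id = exp_feat$feature_id,
                                 trait_role = "exposure",
                                 feature_chrom = exp_feat$chrom,
                                 feature_pos = exp_feat$pos)
  med_feat <- feats[feats$role == "mediator", , drop = FALSE]
  transcripts <- list()
  for (i in seq_len(nrow(med_feat))) {
    id <- med_feat$feature_id[i]
    transcripts[[id]] <- read_summary_stats(
      file.path(dir, paste0("eqtl_", id, ".txt")), trait_id = id,
      trait_role = "mediator", feature_chrom = med_feat$chrom[i],
      feature_pos = med_feat$pos[i])
  }
  outcome <- read_summary_stats(file.path(dir, "gwas.txt"),
                                trait_id = "outcome", trait_role = "outcome")
  ld <- read_ld_panel(file.path(dir, "ld_matrix.txt"),
                      file.path(dir, "ld_index.txt"))
  kv <- utils::read.delim(file.path(dir, "truth.txt"), header = FALSE,
                          col.names = c("key", "value"))
  truth <- as.list(stats::setNames(kv$value, kv$key))
  list(exposure = exposure, transcripts = transcripts, outcome = outcome,
       ld = ld, truth = truth)
}

#' Generate a multi-region synthetic cohort
#'
#' Builds `n_regions` independent cis regions with randomized causal
#' architectures: `n_with_mediators` regions carry 1-3 transcripts with
#' non-zero mediation, `n_null_transcripts` regions carry transcripts with no
#' causal link to the exposure (testing the non-detectable path), and
#' `n_no_transcripts` regions have no cis transcript at all (excluded from MP
#' aggregation by design). Regions are placed far apart (cycling chromosomes,
#' >= 10 Mb spacing) so distance clumping never merges them.
#'
#' @param n_regions total regions (default 30).
#' @param n_null_transcripts regions whose transcripts have `alpha_EM = 0`
#'   (default: a fifth of the cohort).
#' @param n_no_transcripts regions without transcripts (default: two
#'   fifteenths of the cohort).
#' @param seed master seed.
#' @param outcome_id outcome trait label shared by all regions.
#' @return list of regions (as from [generate_region()]).
#' @export
generate_region_cohort <- function(n_regions = 30,
                                   n_null_transcripts = round(n_regions / 5),
                                   n_no_transcripts = round(n_regions * 2 / 15),
                                   seed = 1, outcome_id = "trait") {
  stopifnot(n_null_transcripts + n_no_transcripts <= n_regions)
  set.seed(seed)
  kinds <- c(rep("mediated", n_regions - n_null_transcripts - n_no_transcripts),
             rep("null_transcripts", n_null_transcripts),
             rep("no_transcripts", n_no_transcripts))
  regions <- vector("list", n_regions)
  for (r in seq_len(n_regions)) {
    kind <- kinds[r]
    n_tr <- if (kind == "no_transcripts") 0 else sample(1:3, 1)
    if (n_tr > 0) {
      alpha_EM <- if (kind == "mediated") {
        stats::runif(n_tr, 0.3, 0.6) * sample(c(-1, 1), n_tr, replace = TRUE)
      } else rep(0, n_tr)
      alpha_MY <- stats::runif(n_tr, 0.2, 0.5) *
        sample(c(-1, 1), n_tr, replace = TRUE)
      tr <- data.frame(id = sprintf("T%d_%d", r, seq_len(n_tr)),
                       tss_offset = sample(2e4 * (1:10), n_tr),
                       alpha_EM = alpha_EM, alpha_MY = alpha_MY,
                       h2_direct = 0.05, n_qtls = 5,
                       stringsAsFactors = FALSE)
    } else {
      tr <- data.frame(id = character(0), tss_offset = numeric(0),
                       alpha_EM = numeric(0), alpha_MY = numeric(0),
                       h2_direct = numeric(0), n_qtls = integer(0))
    }
    # orient the direct effect with the mediated effect so the total effect
    # never cancels below the screening threshold
    theta_M_r <- if (nrow(tr)) sum(tr$alpha_EM * tr$alpha_MY) else 0
    sgn <- if (theta_M_r == 0) sample(c(-1, 1), 1) else sign(theta_M_r)
    theta_D <- stats::runif(1, 0.08, 0.2) * sgn
    bp <- region_blueprint(region_id = sprintf("r%02d", r),
                           chrom = ((r - 1) %% 22) + 1,
                           start = 1e6 + 1e7 * ((r - 1) %/% 22),
                           transcripts = tr, theta_D = theta_D)
    region_seed <- seed * 1000 + r
    regions[[r]] <- generate_region(bp, seed = region_seed)
    attr(regions[[r]]$outcome, "trait_id") <- outcome_id
    regions[[r]]$kind <- kind
  }
  regions
}
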
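#' Genome-wide screen configuration
#'
#' @param p_T_thresh Bonferroni threshold on the total-effect p-value
#'   (default 0.05/50000 = 1e-6, the ~50,000-probe screen convention).
#' @param clump_distance distance-clumping window for significant exposures,
#'   bp (default 1 Mb).
#' @param min_pairs minimum pairs per group for MP estimation (default 10).
#' @param variants sensitivity variants of [mediate_pair()] to run in
#'   addition to `"full"`.
#' @param mediation per-pair settings from [mediation_config()].
#' @param af_tol harmonization allele-frequency tolerance (default 0.05).
#' @param seed seed recorded in the run manifest.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(p_T_thresh = 1e-6, clump_distance = 1e6,
                          min_pairs = 10, variants = character(0),
                          mediation = mediation_config(), af_tol = 0.05,
                          seed = 1) {
  stopifnot(p_T_thresh > 0, clump_distance > 0)
  structure(list(p_T_thresh = p_T_thresh, clump_distance = clump_distance,
                 min_pairs = min_pairs, variants = variants,
                 mediation = mediation, af_tol = af_tol, seed = seed),
            class = "screen_config")
}

# Harmonize a region anchored on the (complete) outcome GWAS. Molecular QTL
# tables report only significant rows, so they must not constrain each
# other's variant sets: each is aligned pairwise against the outcome, keeping
# its own reported variants; unreported effects become zeros downstream.
.harmonize_region <- function(region, af_tol = 0.05) {
  exposure <- tryCatch(
    harmonize(list(region$outcome, region$exposure), region$ld,
              af_tol = af_tol)$tables[[2]],
    error = function(e) ss_subset(region$exposure, integer(0)))
  transcripts <- lapply(region$transcripts, function(tr) {
    if (!nrow(tr)) return(tr)
    tryCatch(
      harmonize(list(region$outcome, tr), region$ld, af_tol = af_tol)$tables[[2]],
      error = function(e) ss_subset(tr, integer(0)))
  })
  out <- region$outcome
  keep <- out$chrom %in% 1:22 & out$variant_id %in% region$ld$variant_ids &
    !palindromic(out$effect_allele, out$other_allele)
  list(exposure = exposure, transcripts = transcripts,
       outcome = ss_subset(out, keep), ld = region$ld)
}

#' Run the exposure-to-outcome mediation screen
#'
#' Orchestrates the full workflow over a set of cis regions (one exposure
#' each, sharing an outcome trait): harmonization, per-pair total effects,
#' the total-effect significance gate, distance clumping of significant
#' exposures, per-pair mediation (plus requested sensitivity variants), and
#' MP aggregation in detectable and overall modes, combined and per trait.
#' Sensitivity summaries (conditional-F > 10 subset, heterogeneity-clean
#' subset with both Q p-values > 0.01) and a run manifest with per-stage
#' counts are returned alongside.
#'
#' @param regions list of regions, each a list with `exposure`,
#'   `transcripts`, `outcome`, `ld` (see [generate_region()] /
#'   [load_region()]).
#' @param cfg a [screen_config()].
#' @param trait_map optional data frame (`trait`, `category`) mapping outcome
#'   traits to physiological categories for per-category MPs.
#' @return list of class `screen_result`: `pairs` (per-pair table), `results`
#'   (named list of [mediate_pair()] objects for clumped survivors), `mp`
#'   (detectable/overall estimates), `variants` (per-variant pair tables),
#'   `sensitivity`, `counts`, `manifest`.
#' @export
run_screen <- function(regions, cfg = screen_config(), trait_map = NULL) {
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    names(regions) <- vapply(regions, function(r) attr(r$exposure, "trait_id"),
                             character(1))
  }
  counts <- list(tested = length(regions))

  harmonized <- lapply(regions, .harmonize_region, af_tol = cfg$af_tol)
  first_pass <- lapply(harmonized, function(h) {
    mediate_pair(h$exposure, h$transcripts, h$outcome, h$ld, cfg$mediation,
                 variant = "full")
  })
  pt <- pairs_table(first_pass)
  pt$trait <- vapply(harmonized, function(h) attr(h$outcome, "trait_id"),
                     character(1))
  counts$insufficient_ivs <- sum(pt$status != "ok")
  ok <- pt$status == "ok"
  counts$with_min_ivs <- sum(ok)

  sig <- ok & pt$p_T < cfg$p_T_thresh
  counts$significant_total_effect <- sum(sig)
  if (!any(sig)) {
    message("screen stopped: no exposure passed the total-effect threshold")
    return(structure(list(pairs = pt, results = list(), mp = NULL,
                          counts = counts,
                          manifest = .screen_manifest(cfg, counts)),
                     class = "screen_result"))
  }

  clump_df <- data.frame(
    id = names(regions)[sig],
    chrom = vapply(harmonized[sig], function(h) attr(h$exposure, "feature_chrom"),
                   numeric(1)),
    pos = vapply(harmonized[sig], function(h) attr(h$exposure, "feature_pos"),
                 numeric(1)),
    p = pt$p_T[sig], stringsAsFactors = FALSE)
  kept <- distance_clump(clump_df, cfg$clump_distance)
  counts$after_distance_clump <- length(kept)

  results <- first_pass[kept]
  pairs <- pt[match(kept, names(regions)), , drop = FALSE]
  counts$no_cis_transcript <- sum(!pairs$has_cis_transcript)
  counts$detectable <- sum(pairs$detectable & pairs$has_cis_transcript)
  counts$not_detectable_with_cis <-
    sum(!pairs$detectable & pairs$has_cis_transcript)

  if (!is.null(trait_map)) {
    pairs$category <- trait_map$category[match(pairs$trait, trait_map$trait)]
  }

  mp <- list(
    detectable = estimate_mp(pairs, min_pairs = cfg$min_pairs, mode = "detectable"),
    overall = estimate_mp(pairs, min_pairs = cfg$min_pairs, mode = "overall"),
    by_trait = estimate_mp(pairs, grouping = "trait",
                           min_pairs = cfg$min_pairs, mode = "detectable"))
  if (!is.null(trait_map)) {
    mp$by_category <- estimate_mp(pairs, grouping = "category",
                                  min_pairs = cfg$min_pairs,
                                  mode = "detectable")
  }

  variant_tables <- list()
  for (v in cfg$variants) {
    vres <- lapply(kept, function(id) {
      h <- harmonized[[id]]
      mediate_pair(h$exposure, h$transcripts, h$outcome, h$ld, cfg$mediation,
                   variant = v)
    })
    vt <- pairs_table(vres)
    vt$trait <- pairs$trait
    variant_tables[[v]] <- vt
  }

  sens <- list()
  strong <- pairs[!is.na(pairs$F_cond) & pairs$F_cond > 10, , drop = FALSE]
  sens$f_gt_10 <- estimate_mp(strong, min_pairs = cfg$min_pairs,
                              mode = "detectable")
  clean <- pairs[(is.na(pairs$Q_uni_p) | pairs$Q_uni_p > 0.01) &
                   (is.na(pairs$Q_mvmr_p) | pairs$Q_mvmr_p > 0.01), ,
                 drop = FALSE]
  sens$q_clean <- estimate_mp(clean, min_pairs = cfg$min_pairs,
                              mode = "detectable")
  if ("leave_top_iv" %in% names(variant_tables)) {
    sens$leave_top_iv <- estimate_mp(variant_tables$leave_top_iv,
                                     min_pairs = cfg$min_pairs,
                                     mode = "detectable")
  }

  structure(list(pairs = pairs, results = results, mp = mp,
                 variants = variant_tables, sensitivity = sens,
                 counts = counts, manifest = .screen_manifest(cfg, counts)),
            class = "screen_result")
}

.screen_manifest <- function(cfg, counts) {
  list(seed = cfg$seed,
       config = cfg[c("p_T_thresh", "clump_distance", "min_pairs", "af_tol")],
       mediation = cfg$mediation, counts = counts,
       package_version = as.character(utils::packageVersion("mrmediate")))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n  stage counts:\n")
  for (nm in names(x$counts)) cat("    ", nm, ": ", x$counts[[nm]], "\n", sep = "")
  if (!is.null(x$mp) && nrow(x$mp$detectable)) {
    cat(sprintf("  detectable MP = %.1f%%; overall MP = %.1f%%\n",
                100 * x$mp$detectable$mp[1],
                if (nrow(x$mp$overall)) 100 * x$mp$overall$mp[1] else NA))
  }
  invisible(x)
}

#' Exposure-to-transcript MR scan
#'
#' For every region, estimates the causal effect of the exposure on each cis
#' (+/- `window` bp) transcript by univariable IVW over Steiger-filtered
#' exposure instruments, requiring at least `min_ivs` surviving instruments.
#' Pairs with fewer instruments are reported with `status =
#' "insufficient_ivs"`.
#'
#' @param regions list of regions (see [run_screen()]).
#' @param cfg a [screen_config()] (uses the `mediation` settings).
#' @param window cis half-window, bp (default 5e5).
#' @return data frame: `exposure`, `mediator_id`, `alpha_EM`, `se_EM`,
#'   `p_EM`, `n_ivs_EM`, `tss_distance`, `status`.
#' @export
run_dnam_transcript_scan <- function(regions, cfg = screen_config(),
                                     window = 5e5) {
  med <- cfg$mediation
  rows <- list()
  for (r in regions) {
    h <- .harmonize_region(r, af_tol = cfg$af_tol)
    exp_id <- attr(h$exposure, "trait_id")
    probe_chrom <- attr(h$exposure, "feature_chrom")
    probe_pos <- attr(h$exposure, "feature_pos")
    win <- if (!is.na(probe_pos)) probe_pos + c(-1, 1) * med$window_ivs else NULL
    ivs <- select_instruments(h$exposure, h$ld, med$p_iv, med$r2_iv,
                              window = win, chrom = probe_chrom)
    cands <- select_mediators(h$exposure, h$transcripts, h$ld, ivs,
                              window = window, p_em = med$p_em,
                              t_rev = med$t_rev,
                              min_ivs = med$min_ivs_post_steiger,
                              keep_all = TRUE)
    if (nrow(cands)) {
      cands$exposure <- exp_id
      cands$status <- "ok"
      rows[[exp_id]] <- cands
    }
    # cis transcripts skipped for lack of instruments are counted explicitly
    assessed <- cands$mediator_id
    for (id in names(h$transcripts)) {
      tss <- attr(h$transcripts[[id]], "feature_pos")
      if (!is.na(tss) && !is.na(probe_pos) && abs(tss - probe_pos) <= window &&
          !(id %in% assessed)) {
        rows[[paste0(exp_id, ".", id)]] <-
          data.frame(mediator_id = id, alpha_EM = NA_real_, se_EM = NA_real_,
                     p_EM = NA_real_, n_ivs_EM = NA_integer_,
                     tss_distance = abs(tss - probe_pos), selected = FALSE,
                     exposure = exp_id, status = "insufficient_ivs",
                     stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mediator_id = character(0), alpha_EM = numeric(0),
               se_EM = numeric(0), p_EM = numeric(0), n_ivs_EM = integer(0),
               tss_distance = numeric(0), selected = logical(0),
               exposure = character(0), status = character(0))
  rownames(out) <- NULL
  out
}
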
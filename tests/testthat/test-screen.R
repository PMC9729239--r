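cohort_cache <- new.env()

get_cohort <- function() {
  if (is.null(cohort_cache$regions)) {
    cohort_cache$regions <-
      suppressMessages(generate_region_cohort(n_regions = 30, seed = 42))
    cohort_cache$screen <- suppressMessages(suppressWarnings(
      run_screen(cohort_cache$regions,
                 screen_config(seed = 42, variants = "leave_top_iv"))))
  }
  cohort_cache
}

test_that("screen stage counts are consistent with the cohort construction", {
  cc <- get_cohort()
  regions <- cc$regions; scr <- cc$screen
  kinds <- vapply(regions, `[[`, character(1), "kind")
  counts <- scr$counts
  expect_equal(counts$tested, 30)
  expect_equal(counts$with_min_ivs + counts$insufficient_ivs, 30)
  # all constructed total effects are strong: every testable probe passes P_T
  expect_equal(counts$significant_total_effect, counts$with_min_ivs)
  # regions are > 1 Mb apart by construction: clumping removes nothing
  expect_equal(counts$after_distance_clump, counts$significant_total_effect)
  # ground-truth region kinds among the clumped survivors
  region_ids <- vapply(regions, function(r) r$blueprint$region_id, character(1))
  kept <- match(sub("_probe:trait$", "", scr$pairs$pair_id), region_ids)
  kept_kinds <- kinds[kept]
  expect_equal(counts$no_cis_transcript, sum(kept_kinds == "no_transcripts"))
  expect_equal(counts$detectable, sum(kept_kinds == "mediated"))
  expect_equal(counts$not_detectable_with_cis,
               sum(kept_kinds == "null_transcripts"))
})

test_that("detectable and overall MP aggregation covers the truth-implied slope", {
  cc <- get_cohort()
  regions <- cc$regions; scr <- cc$screen
  pairs <- scr$pairs
  region_of <- vapply(regions, function(r)
    paste0(attr(r$exposure, "trait_id"), ":trait"), character(1))
  det_ids <- pairs$pair_id[pairs$detectable & pairs$has_cis_transcript]
  truth <- t(vapply(regions[match(det_ids, region_of)], function(r)
    c(as.numeric(r$truth$theta_D), as.numeric(r$truth$theta_T)), numeric(2)))
  truth_mp <- 1 - sum(truth[, 1] * truth[, 2]) / sum(truth[, 2]^2)
  est <- scr$mp$detectable
  expect_equal(est$n_pairs, length(det_ids))
  expect_gt(truth_mp, est$ci_lo)
  expect_lt(truth_mp, est$ci_hi)
  # overall mode adds the null-transcript pairs and lowers the MP
  expect_gt(scr$mp$overall$n_pairs, est$n_pairs)
  expect_lt(scr$mp$overall$mp, est$mp)
})

test_that("every aggregated pair satisfies the printed gates", {
  cc <- get_cohort()
  pairs <- cc$screen$pairs
  used <- pairs[pairs$detectable & pairs$has_cis_transcript, ]
  expect_true(all(used$status == "ok"))
  expect_true(all(used$p_T < 1e-6))
  results <- cc$screen$results
  ms <- vapply(results, function(p) p$m_selected, numeric(1))
  mp <- vapply(results, function(p) p$m_post_steiger, numeric(1))
  expect_true(all(ms >= 5))
  expect_true(all(mp >= 3))
})

test_that("the leave-top-IV variant removes one instrument and stays concordant", {
  cc <- get_cohort()
  scr <- cc$screen
  vt <- scr$variants$leave_top_iv
  full <- scr$pairs
  shared <- intersect(vt$pair_id[vt$status == "ok"],
                      full$pair_id[full$status == "ok"])
  expect_gt(length(shared), 10)
  se_full <- full$se_T[match(shared, full$pair_id)]
  se_var <- vt$se_T[match(shared, vt$pair_id)]
  expect_gt(mean(se_var), mean(se_full))   # weaker instruments, noisier theta_T
  # effect directions stay concordant for strong pairs
  tt <- full$theta_T[match(shared, full$pair_id)]
  tv <- vt$theta_T[match(shared, vt$pair_id)]
  expect_gt(mean(sign(tt) == sign(tv)), 0.9)
})

test_that("the exposure-to-transcript scan respects windows and recovers effects", {
  tr <- data.frame(id = c("Tnear", "Tfar"), tss_offset = c(1e5, 7e5),
                   alpha_EM = c(-0.5, 0.4), alpha_MY = c(0.3, 0.2),
                   h2_direct = 0.05, n_qtls = 4)
  bp <- region_blueprint(region_id = "scan", transcripts = tr)
  reg <- generate_region(bp, seed = 51)
  scan <- run_dnam_transcript_scan(list(reg), screen_config())
  expect_true("Tnear" %in% scan$mediator_id)
  expect_false("Tfar" %in% scan$mediator_id)   # outside +/- 500 kb
  row <- scan[scan$mediator_id == "Tnear", ]
  expect_lt(abs(row$alpha_EM - (-0.5)), 2 * row$se_EM)
  expect_true(row$n_ivs_EM >= 3)
})
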
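test_that("the dilution correction follows the closed form", {
  # sum(SE^2) = 0.5 * sum(theta_T^2), gamma = 0.5
  theta_T <- c(1, 1)
  theta_D <- 0.5 * theta_T
  est <- mp_from_effects(theta_D, theta_T, se_T = c(sqrt(0.5), sqrt(0.5)))
  expect_equal(est$gamma, 0.5)
  expect_equal(est$gamma_cor, 0.5 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(est$mp, 1 - 0.70710678, tolerance = 1e-7)
})

test_that("no dilution and perfect identity give gamma_cor = gamma and MP = 0", {
  theta_T <- c(0.2, -0.1, 0.3, 0.15)
  est <- mp_from_effects(0.4 * theta_T + c(0.01, -0.02, 0, 0.01), theta_T,
                         se_T = rep(0, 4))
  expect_equal(est$gamma_cor, est$gamma)
  ident <- mp_from_effects(theta_T, theta_T, se_T = rep(0, 4))
  expect_equal(ident$mp, 0)
  expect_error(mp_from_effects(theta_T, theta_T, se_T = rep(1, 4)),
               "dilution correction undefined")
})

test_that("MP estimation is invariant to pair order and global sign flips", {
  set.seed(9)
  theta_T <- rnorm(20, 0, 0.2)
  theta_D <- 0.6 * theta_T + rnorm(20, 0, 0.02)
  se_T <- rep(0.01, 20)
  a <- mp_from_effects(theta_D, theta_T, se_T)
  p <- sample(20)
  b <- mp_from_effects(theta_D[p], theta_T[p], se_T[p])
  expect_equal(b$mp, a$mp)
  flip <- mp_from_effects(-theta_D, -theta_T, se_T)
  expect_equal(flip$mp, a$mp)
})

test_that("overall-mode MP is below detectable-mode MP when non-detectable pairs exist", {
  set.seed(10)
  n <- 30
  theta_T <- rnorm(n, 0, 0.2)
  theta_D <- 0.5 * theta_T + rnorm(n, 0, 0.01)
  det <- rep(c(TRUE, FALSE), c(20, 10))
  theta_D[!det] <- theta_T[!det]            # non-detectable rule
  pairs <- data.frame(theta_T = theta_T, se_T = 0.01, theta_D = theta_D,
                      detectable = det, has_cis_transcript = TRUE,
                      status = "ok")
  mp_det <- estimate_mp(pairs, min_pairs = 5, mode = "detectable")
  mp_all <- estimate_mp(pairs, min_pairs = 5, mode = "overall")
  expect_equal(mp_det$n_pairs, 20)
  expect_equal(mp_all$n_pairs, 30)
  expect_lt(mp_all$mp, mp_det$mp)
  # pairs without cis transcripts are excluded from both modes
  pairs$has_cis_transcript[1:5] <- FALSE
  expect_equal(estimate_mp(pairs, min_pairs = 5, mode = "overall")$n_pairs, 25)
})

test_that("MP comparison z-test behaves at its reference points", {
  a <- mp_from_effects(c(0.1, 0.2, 0.12), c(0.2, 0.4, 0.25), rep(0.001, 3))
  z0 <- compare_mp(a, a)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  b <- a
  b$gamma_cor <- a$gamma_cor + 1.96 * sqrt(2) * a$se_gamma_cor
  expect_equal(compare_mp(a, b)$p, 0.05, tolerance = 1e-3)
  ab <- compare_mp(a, b); ba <- compare_mp(b, a)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
})

test_that("product of coefficients sums per-mediator paths", {
  pair <- list(theta_T = 0.5,
               mediators = data.frame(mediator_id = c("a", "b", "c"),
                                      alpha_EM = c(0.5, -0.3, 0.2),
                                      alpha_MY = c(0.2, 0.4, -0.1)))
  pc <- product_of_coefficients(pair)
  expect_equal(pc$theta_M_alt, 0.5 * 0.2 - 0.3 * 0.4 - 0.2 * 0.1)
  expect_equal(pc$theta_D_alt, 0.5 - pc$theta_M_alt)
  one <- product_of_coefficients(list(theta_T = 0.3, mediators = data.frame(
    mediator_id = "a", alpha_EM = 0.5, alpha_MY = 0.2)))
  expect_equal(one$theta_M_alt, 0.1)
})

test_that("mediator clumping keeps the lowest-p representative of correlated sets", {
  eff <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("A", "B")))
  eff[, 2] <- eff[, 1] * 0.95 + rnorm(20, 0, 0.05)  # highly correlated
  cands <- data.frame(mediator_id = c("A", "B"), p_EM = c(1e-5, 1e-3))
  expect_equal(clump_mediators(cands, eff, 0.3)$mediator_id, "A")
  # uncorrelated mediators are all kept
  eff2 <- cbind(A = c(1, -1, 1, -1), B = c(1, 1, -1, -1))
  expect_equal(nrow(clump_mediators(cands, eff2, 0.3)), 2)
})

test_that("mediator clumping traces the greedy rule on exact correlations", {
  # orthonormal construction with exact sample correlations:
  # cor(1,2) = 0.5, cor(1,3) = 0.1, cor(2,3) = 0.1; p order 1 < 2 < 3
  e1 <- c(1, -1, 0, 0) / sqrt(2)
  e2 <- c(1, 1, -2, 0) / sqrt(6)
  e3 <- c(1, 1, 1, -3) / sqrt(12)
  x1 <- e1
  x2 <- 0.5 * e1 + sqrt(0.75) * e2
  c2 <- (0.1 - 0.05) / sqrt(0.75)
  x3 <- 0.1 * e1 + c2 * e2 + sqrt(1 - 0.01 - c2^2) * e3
  eff <- cbind(M1 = x1, M2 = x2, M3 = x3)
  expect_equal(cor(eff)[1, 2], 0.5, tolerance = 1e-12)
  cands <- data.frame(mediator_id = c("M1", "M2", "M3"),
                      p_EM = c(1e-6, 1e-5, 1e-4))
  kept <- clump_mediators(cands, eff, r_med = 0.3)
  expect_equal(kept$mediator_id, c("M1", "M3"))
})

test_that("mediator selection respects the cis window and the p_EM boundary", {
  tr_in <- data.frame(id = "Tin", tss_offset = 4e5, alpha_EM = 0.4,
                      alpha_MY = 0.3, h2_direct = 0.05, n_qtls = 4)
  tr_out <- data.frame(id = "Tout", tss_offset = 6e5, alpha_EM = 0.4,
                       alpha_MY = 0.3, h2_direct = 0.05, n_qtls = 4)
  bp <- region_blueprint(region_id = "w", transcripts = rbind(tr_in, tr_out),
                         n_snps = 120)
  reg <- generate_region(bp, seed = 21)
  ivs <- select_instruments(reg$exposure, reg$ld)
  cands <- select_mediators(reg$exposure, reg$transcripts, reg$ld, ivs,
                            keep_all = TRUE)
  expect_true("Tin" %in% cands$mediator_id)
  expect_false("Tout" %in% cands$mediator_id)   # TSS 600 kb away: excluded
  # boundary semantics: selected iff p_EM strictly below the threshold
  p_obs <- cands$p_EM[cands$mediator_id == "Tin"]
  above <- select_mediators(reg$exposure, reg$transcripts, reg$ld, ivs,
                            p_em = p_obs * 1.0001)
  below <- select_mediators(reg$exposure, reg$transcripts, reg$ld, ivs,
                            p_em = p_obs * 0.9999)
  expect_true("Tin" %in% above$mediator_id)
  expect_false("Tin" %in% below$mediator_id)
})

test_that("true mediators are recovered among null transcripts", {
  tr <- data.frame(id = c("T1", "T2", paste0("N", 1:4)),
                   tss_offset = c(2e4, 4e4, 6e4, 8e4, 1e5, 1.2e5),
                   alpha_EM = c(0.5, -0.4, 0, 0, 0, 0),
                   alpha_MY = c(0.3, 0.2, 0.1, -0.1, 0.2, 0.1),
                   h2_direct = 0.05, n_qtls = 3)
  bp <- region_blueprint(region_id = "rec", n_snps = 150, transcripts = tr,
                         n_exposure = 1e6, n_mediator = 1e6, n_outcome = 1e6)
  reg <- generate_region(bp, seed = 31)
  ivs <- select_instruments(reg$exposure, reg$ld)
  meds <- select_mediators(reg$exposure, reg$transcripts, reg$ld, ivs)
  expect_setequal(meds$mediator_id, c("T1", "T2"))
})

test_that("mediate_pair applies the non-detectable rule and reports unclamped MP", {
  # region whose transcripts have no causal link to the exposure
  tr <- data.frame(id = "N1", tss_offset = 5e4, alpha_EM = 0, alpha_MY = 0.3,
                   h2_direct = 0.05, n_qtls = 4)
  bp <- region_blueprint(region_id = "nd", transcripts = tr, theta_D = 0.15)
  reg <- generate_region(bp, seed = 41)
  h <- mrmediate:::.harmonize_region(reg)
  res <- mediate_pair(h$exposure, h$transcripts, h$outcome, h$ld)
  if (res$detectable) skip("null transcript passed selection at this seed")
  expect_false(res$detectable)
  expect_equal(res$theta_D, res$theta_T)
  expect_equal(res$mp_pair, 0)
  expect_true(res$has_cis_transcript)

  # detectable pair: MP is reported as 1 - theta_D/theta_T without clamping
  tr2 <- data.frame(id = "T1", tss_offset = 5e4, alpha_EM = 0.5,
                    alpha_MY = 0.4, h2_direct = 0.05, n_qtls = 4)
  bp2 <- region_blueprint(region_id = "det", transcripts = tr2, theta_D = 0.1)
  reg2 <- generate_region(bp2, seed = 42)
  h2 <- mrmediate:::.harmonize_region(reg2)
  res2 <- mediate_pair(h2$exposure, h2$transcripts, h2$outcome, h2$ld)
  expect_true(res2$detectable)
  expect_equal(res2$mp_pair, 1 - res2$theta_D / res2$theta_T)
  expect_true(res2$F_cond > 0)
})

test_that("pair stratification matches a constructed truth table", {
  mk <- function(id, signs, tT, tD) {
    list(pair_id = id, status = "ok", detectable = TRUE, theta_T = tT,
         se_T = 0.01, theta_D = tD, n_med = length(signs),
         mediators = data.frame(mediator_id = paste0("m", seq_along(signs)),
                                alpha_EM = signs * 0.4))
  }
  pairs <- list(
    mk("p1", -1, 0.2, 0.1), mk("p2", -1, 0.3, 0.15), mk("p3", 1, 0.2, 0.18),
    mk("p4", c(1, 1), 0.25, 0.1), mk("p5", c(-1, 1), 0.3, 0.1),
    mk("p6", c(-1, 1, -1), 0.2, 0.05), mk("p7", c(-1, -1), 0.4, 0.2))
  tab <- stratify_pairs(pairs)
  get_n <- function(s, m) tab$n[tab$sign == s & tab$multiplicity == m]
  expect_equal(get_n("Negative", "mono"), 2)
  expect_equal(get_n("Positive", "mono"), 1)
  expect_equal(get_n("Bivalent", "multi"), 2)
  expect_equal(get_n("Negative", "multi"), 1)
  expect_equal(get_n("Positive", "multi"), 1)
  expect_false(any(tab$sign == "Bivalent" & tab$multiplicity == "mono"))
  biv <- tab[tab$sign == "Bivalent" & tab$multiplicity == "multi", ]
  expect_equal(biv$mean_n_med, 2.5)
  expect_equal(biv$mp, 1 - mp_from_effects(c(0.1, 0.05), c(0.3, 0.2),
                                           c(0.01, 0.01))$gamma_cor,
               tolerance = 1e-12)
})
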
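test_that("z/n tables are converted to standardized beta/se on read", {
  path <- withr::local_tempfile(fileext = ".txt")
  write.table(data.frame(rsid = c("v1", "v2", "v3"), chr = 1,
                         bp = c(100, 200, 300), ea = "A", oa = "G",
                         freq = 0.3, zscore = c(3, -1, 0), N = 900),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_summary_stats(path, trait_id = "t", dialect = c(
    variant_id = "rsid", chrom = "chr", pos = "bp", effect_allele = "ea",
    other_allele = "oa", eaf = "freq", z = "zscore", n = "N"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$beta[1], 0.1)          # z = 3, n = 900
  expect_equal(tab$se, rep(1 / 30, 3))
  expect_equal(tab$beta[3], 0)            # z = 0 maps to 0 for any n
})

test_that("invalid rows are dropped and missing mandatory columns error", {
  d <- data.frame(variant_id = c("a", "b"), chrom = 1, pos = c(1, 2),
                  effect_allele = "A", other_allele = "C",
                  eaf = 0.2, beta = c(0.1, 0.2), se = c(0.01, 0), n = 100)
  expect_message(tab <- summary_stats(d, "t"), "dropped")
  expect_equal(tab$variant_id, "a")       # se = 0 row removed
  expect_error(summary_stats(d[, setdiff(names(d), "pos")], "t"),
               "pos")
  expect_error(summary_stats(d[d$se == 0, ], "t"), "no valid records")
})

test_that("standardization is z/sqrt(n) and idempotent", {
  tab <- make_ss(c("a", "b"), beta = c(0.4, -0.2), se = 0.2, n = 400)
  s1 <- standardize_effects(tab)          # z = 2 -> 0.1; z = -1 -> -0.05
  expect_equal(s1$beta, c(0.1, -0.05))
  expect_equal(s1$se, c(0.05, 0.05))
  s2 <- standardize_effects(s1)
  expect_equal(s2$beta, s1$beta)
  expect_equal(s2$se, s1$se)
})

test_that("harmonization flips swapped alleles, removes palindromes and AF outliers", {
  ids <- c("v1", "v2", "v3", "v4")
  R <- diag(4); dimnames(R) <- list(ids, ids)
  ld <- ld_panel(R, ids, chrom = rep(1, 4), pos = 1:4 * 1000)
  t1 <- summary_stats(data.frame(
    variant_id = ids, chrom = 1, pos = 1:4 * 1000,
    effect_allele = c("A", "A", "C", "A"), other_allele = c("G", "T", "T", "C"),
    eaf = c(0.30, 0.30, 0.30, 0.30), beta = c(0.1, 0.2, 0.3, 0.4),
    se = 0.01, n = 1e4), "t1")
  t2 <- summary_stats(data.frame(
    variant_id = ids, chrom = 1, pos = 1:4 * 1000,
    effect_allele = c("G", "A", "C", "A"), other_allele = c("A", "T", "T", "C"),
    eaf = c(0.70, 0.30, 0.34, 0.36), beta = c(-0.1, 0.2, 0.3, 0.4),
    se = 0.01, n = 1e4), "t2")
  h <- suppressMessages(harmonize(list(t1, t2), ld))
  # v2 is palindromic (A/T): removed regardless of AF agreement
  expect_false("v2" %in% h$tables[[1]]$variant_id)
  # v1 swapped in t2: sign flipped back, retained
  expect_true("v1" %in% h$tables[[2]]$variant_id)
  expect_equal(h$tables[[2]]$beta[h$tables[[2]]$variant_id == "v1"], 0.1)
  # AF difference 0.04 retained, 0.06 removed
  expect_true("v3" %in% h$tables[[1]]$variant_id)
  expect_false("v4" %in% h$tables[[1]]$variant_id)
})

test_that("harmonization is idempotent and invariant to a full allele flip", {
  bp <- region_blueprint(region_id = "hh", n_snps = 40, n_exposure_qtls = 3,
                         transcripts = data.frame(id = "T1", tss_offset = 2e4,
                                                  alpha_EM = 0.4, alpha_MY = 0.3,
                                                  h2_direct = 0.05, n_qtls = 3))
  reg <- generate_region(bp, seed = 3)
  tabs <- list(reg$outcome, reg$exposure)
  h1 <- suppressMessages(harmonize(tabs, reg$ld))
  h2 <- suppressMessages(harmonize(h1$tables, h1$ld))
  expect_equal(as.data.frame(h2$tables[[2]]), as.data.frame(h1$tables[[2]]))
  expect_equal(h2$ld$R, h1$ld$R)
  # flip all alleles/AF/signs of the second table: harmonized betas unchanged
  flipped <- as.data.frame(reg$exposure)
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  tf <- summary_stats(flipped, "exp_flipped", "exposure", validate = FALSE)
  h3 <- suppressMessages(harmonize(list(reg$outcome, tf), reg$ld))
  expect_equal(h3$tables[[2]]$beta, h1$tables[[2]]$beta)
})

test_that("read/write round trip preserves the table", {
  tab <- make_ss(c("a", "b", "c"), beta = c(0.1, -0.2, 0.05), se = 0.02)
  path <- withr::local_tempfile(fileext = ".txt")
  write_summary_stats(tab, path)
  back <- read_summary_stats(path, trait_id = "trait")
  expect_equal(back$beta, tab$beta)
  expect_equal(back$variant_id, tab$variant_id)
  expect_equal(back$se, tab$se)
})
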
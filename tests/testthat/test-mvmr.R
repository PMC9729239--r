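test_that("MVMR with no mediators reduces to univariable IVW", {
  set.seed(4)
  m <- 6
  C <- random_corr(m)
  bE <- rnorm(m, 0, 0.2); bY <- rnorm(m, 0, 0.1)
  uni <- ivw_correlated(bE, bY, 1e-4, 1e-4, C = C)
  mv <- mvmr_correlated(list(B = matrix(bE, ncol = 1), beta_Y = bY,
                             var_Y = 1e-4, C = C))
  expect_equal(mv$theta_D, uni$theta, tolerance = 1e-10)
  expect_equal(mv$se_D, uni$se, tolerance = 1e-10)
})

test_that("a noiseless full-mediation chain gives theta_D = 0 and exact alpha_MY", {
  alpha_EM <- 0.5; alpha_MY <- 0.2
  bE_exp <- c(0.2, -0.15, 0.3, 0.25)
  d <- c(0.3, 0.28, -0.26)
  bE <- c(bE_exp, rep(0, 3))                  # exposure effects, mediator IVs 0
  bM <- c(alpha_EM * bE_exp, d)
  bY <- alpha_MY * bM                          # full mediation: direct effect 0
  fit <- mvmr_correlated(list(B = cbind(bE, bM), beta_Y = bY, var_Y = 1e-6,
                              C = NULL, mediator_ids = "M1"))
  expect_equal(fit$theta_D, 0, tolerance = 1e-12)
  expect_equal(unname(fit$alpha_MY), alpha_MY, tolerance = 1e-12)
  # difference method equals product method exactly in the noiseless chain
  theta_T <- ivw_correlated(bE_exp, alpha_MY * alpha_EM * bE_exp, 1e-6, 1e-6)$theta
  expect_equal(theta_T - fit$theta_D, alpha_EM * alpha_MY, tolerance = 1e-12)
  q <- q_statistic_mvmr(fit)
  expect_equal(q$Q, 0, tolerance = 1e-20)
})

test_that("MVMR matches the brute-force GLS oracle on random problems", {
  set.seed(12)
  for (i in 1:100) {
    m <- sample(6:12, 1)
    k <- sample(1:4, 1)
    C <- random_corr(m)
    B <- matrix(rnorm(m * (k + 1), 0, 0.2), m)
    bY <- rnorm(m, 0, 0.1)
    fit <- mvmr_correlated(list(B = B, beta_Y = bY, var_Y = 1e-4, C = C))
    expect_equal(unname(fit$coef), gls_oracle(B, bY, C), tolerance = 1e-10)
  }
})

test_that("with C = I MVMR equals ordinary least squares", {
  set.seed(5)
  B <- matrix(rnorm(18, 0, 0.2), 6)
  bY <- rnorm(6, 0, 0.1)
  fit <- mvmr_correlated(list(B = B, beta_Y = bY, var_Y = 1e-4, C = NULL))
  expect_equal(unname(fit$coef), unname(coef(lm(bY ~ B - 1))),
               tolerance = 1e-10)
})

test_that("an all-zero mediator column is dropped without changing theta_D", {
  set.seed(6)
  bE <- rnorm(8, 0, 0.2); bM <- rnorm(8, 0, 0.2); bY <- rnorm(8, 0, 0.1)
  base <- mvmr_correlated(list(B = cbind(bE, bM), beta_Y = bY, var_Y = 1e-4,
                               C = NULL, mediator_ids = "M1"))
  wide <- mvmr_correlated(list(B = cbind(bE, bM, 0), beta_Y = bY, var_Y = 1e-4,
                               C = NULL, mediator_ids = c("M1", "Mzero")))
  expect_equal(wide$theta_D, base$theta_D, tolerance = 1e-12)
  expect_equal(wide$dropped_mediators, "Mzero")
  # duplicated mediator column also triggers rank handling
  dup <- mvmr_correlated(list(B = cbind(bE, bM, bM), beta_Y = bY, var_Y = 1e-4,
                              C = NULL, mediator_ids = c("M1", "M1copy")))
  expect_equal(dup$dropped_mediators, "M1copy")
  expect_equal(dup$theta_D, base$theta_D, tolerance = 1e-12)
})

test_that("rank-score clumping orders mediator IVs by summed rank", {
  ids <- c("e1", "a", "b", "x")
  R <- diag(4); dimnames(R) <- list(ids, ids)
  ld <- ld_panel(R, ids, chrom = rep(1, 4), pos = 1:4 * 1e3)
  # IV a ranks (1, 3) -> 4; IV b ranks (2, 1) -> 3: b precedes a
  cands <- list(
    M1 = data.frame(variant_id = c("a", "b", "x"), pvalue = c(1e-8, 1e-6, 1e-5),
                    pos = c(2e3, 3e3, 4e3)),
    M2 = data.frame(variant_id = c("b", "x", "a"), pvalue = c(1e-9, 1e-7, 1e-6),
                    pos = c(3e3, 4e3, 2e3)))
  pooled <- rank_score_clump("e1", cands, ld, r2_thresh = 0.05)
  expect_equal(pooled, c("e1", "b", "a", "x"))
})

test_that("rank-score clumping drops mediator IVs in LD with exposure IVs", {
  ids <- c("e1", "m1")
  R <- matrix(c(1, sqrt(0.9), sqrt(0.9), 1), 2, dimnames = list(ids, ids))
  ld <- ld_panel(R, ids, chrom = c(1, 1), pos = c(1e3, 2e3))
  cands <- list(M1 = data.frame(variant_id = "m1", pvalue = 1e-9, pos = 2e3))
  expect_equal(rank_score_clump("e1", cands, ld), "e1")
  # single mediator: pooled order equals that mediator's p-value order
  ids3 <- c("e1", "m1", "m2")
  ld3 <- ld_panel(diag(3), ids3, chrom = rep(1, 3), pos = 1:3 * 1e3)
  cands3 <- list(M1 = data.frame(variant_id = c("m2", "m1"),
                                 pvalue = c(1e-9, 1e-6), pos = c(3e3, 2e3)))
  expect_equal(rank_score_clump("e1", cands3, ld3), c("e1", "m2", "m1"))
})

test_that("design matrix fills reported effects and zeroes unreported ones", {
  exp_tab <- make_ss(c("e1", "e2"), beta = c(0.2, 0.3), se = 0.01,
                     trait_id = "probe")
  med_tab <- make_ss(c("e1", "m1"), beta = c(0.1, 0.4), se = 0.01,
                     trait_id = "T1", trait_role = "mediator")
  out_tab <- make_ss(c("e1", "e2", "m1"), beta = c(0.05, 0.06, 0.02),
                     se = 0.005, trait_id = "Y", trait_role = "outcome")
  prob <- build_design_matrix(exp_tab, list(T1 = med_tab), out_tab,
                              c("e1", "e2", "m1"))
  expect_equal(unname(prob$B[, 1]), c(0.2, 0.3, 0))   # m1 unreported in mQTL
  expect_equal(unname(prob$B[, 2]), c(0.1, 0, 0.4))   # e2 unreported in eQTL
  expect_equal(prob$beta_Y, c(0.05, 0.06, 0.02))
  expect_warning(
    build_design_matrix(exp_tab, list(T1 = med_tab), out_tab,
                        c("e1", "e2", "m1", "missing")),
    "missing from the outcome")
})

test_that("conditional F reduces to the mean instrument F without mediators", {
  bE <- c(0.2, 0.15, 0.25, 0.1, 0.3)
  n_E <- 10000
  f <- conditional_f(list(B = matrix(bE, ncol = 1), C = NULL), n_E)
  expect_equal(f, n_E * sum(bE^2) / 5, tolerance = 1e-12)
})

test_that("a collinear mediator drives the conditional F to zero", {
  bE <- c(0.2, 0.15, 0.25, 0.1, 0.3)
  f <- conditional_f(list(B = cbind(bE, 2 * bE), C = NULL), 1e4)
  expect_equal(f, 0, tolerance = 1e-20)
})

test_that("conditional F matches a manual weighted residual regression", {
  set.seed(7)
  m <- 5
  C <- random_corr(m)
  bE <- rnorm(m, 0, 0.2); bM <- 0.5 * bE + rnorm(m, 0, 0.1)
  n_E <- 30000
  f <- conditional_f(list(B = cbind(bE, bM), C = C), n_E)
  # manual: C^-1-weighted regression of bE on bM, residual strength
  Ci <- solve(C)
  g <- drop(solve(t(bM) %*% Ci %*% bM) %*% t(bM) %*% Ci %*% bE)
  delta <- bE - g * bM
  f_manual <- n_E * drop(t(delta) %*% Ci %*% delta) / (m * (1 + g^2))
  expect_equal(f, f_manual, tolerance = 1e-8)
  # supplying an identity phenotypic correlation matrix matches the default
  expect_equal(conditional_f(list(B = cbind(bE, bM), C = C), n_E,
                             pheno_corr = diag(2)), f, tolerance = 1e-10)
})

test_that("MVMR Q has m - k degrees of freedom and matches a brute-force sum", {
  set.seed(8)
  B <- matrix(rnorm(40, 0, 0.2), 10, 4)
  fit <- mvmr_correlated(list(B = B, beta_Y = rnorm(10, 0, 0.1), var_Y = 1e-3,
                              C = NULL))
  expect_equal(q_statistic_mvmr(fit)$df, 10 - 3)       # m = 10, k = 3
  # 4-IV, 1-mediator hand computation
  bE <- c(0.2, 0.25, 0.15, 0.3); bM <- c(0.1, 0.05, 0.2, 0.12)
  bY <- c(0.06, 0.07, 0.05, 0.1)
  var_Y <- rep(2e-3, 4)
  fit2 <- mvmr_correlated(list(B = cbind(bE, bM), beta_Y = bY, var_Y = var_Y,
                               C = NULL))
  theta <- qr.coef(qr(cbind(bE, bM)), bY)
  r <- bY - drop(cbind(bE, bM) %*% theta)
  sig <- pmax(sum(r^2) / (4 - 2), var_Y)
  q2 <- q_statistic_mvmr(fit2)
  expect_equal(q2$Q, sum(r^2 / sig), tolerance = 1e-10)
  expect_equal(q2$df, 3)
})
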
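#' Simulation scenario configuration
#'
#' Parameters of the generative model used to assess bias in estimated
#' mediation proportions. An exposure with cis heritability `h2_E` is
#' instrumented by `m_E` independent variants; each of the `N_med` relevant
#' mediators (out of `N_med_pot` potential ones) carries `m_M` own instruments
#' with direct heritability `h2_M_direct`. Exposure-to-mediator and
#' mediator-to-outcome causal effects are drawn from a bivariate normal with
#' variances `var_alpha_EM`/`var_alpha_MY` and correlation `rho`. The indirect
#' effect is `theta_M = sum(alpha_EM * alpha_MY)`, the direct effect
#' `theta_D = theta_M * (1/true_MP - 1)` and the total `theta_T = theta_D +
#' theta_M`. Summary statistics are observed with sampling noise of variance
#' `1/N` (per-dataset sample sizes `N_E`, `N_M`, `N_Y`), and exposure effects
#' of mediator instruments are zeroed to mimic sub-threshold unreported QTLs.
#'
#' @param m_E exposure instruments (default 10).
#' @param m_M instruments per relevant mediator (default 10).
#' @param N_med_pot potential mediators (default 12).
#' @param N_med relevant mediators (default 2).
#' @param h2_E exposure cis heritability (default 0.1).
#' @param h2_M_direct per-mediator direct heritability (default 0.1).
#' @param var_alpha_EM,var_alpha_MY causal-effect variances (default 0.05).
#' @param rho correlation between `alpha_EM` and `alpha_MY` (default 0).
#' @param true_MP generative mediation proportion (default 0.35).
#' @param theta_D direct effect used when `N_med = 0` (no mediation), where
#'   the MP identity is degenerate (default 0.1).
#' @param N_E,N_M,N_Y QTL/GWAS sample sizes (default 30000 each).
#' @param p_em mediator selection threshold (default 0.01).
#' @param reps replicates per scenario (default 500).
#' @param seed master seed (default 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m_E = 10, m_M = 10, N_med_pot = 12, N_med = 2,
                       h2_E = 0.1, h2_M_direct = 0.1, var_alpha_EM = 0.05,
                       var_alpha_MY = 0.05, rho = 0, true_MP = 0.35,
                       theta_D = 0.1, N_E = 30000, N_M = 30000, N_Y = 30000,
                       p_em = 0.01, reps = 500, seed = 1) {
  cfg <- list(m_E = m_E, m_M = m_M, N_med_pot = N_med_pot, N_med = N_med,
              h2_E = h2_E, h2_M_direct = h2_M_direct,
              var_alpha_EM = var_alpha_EM, var_alpha_MY = var_alpha_MY,
              rho = rho, true_MP = true_MP, theta_D = theta_D,
              N_E = N_E, N_M = N_M, N_Y = N_Y, p_em = p_em,
              reps = reps, seed = seed)
  stopifnot(cfg$h2_E > 0, cfg$h2_E < 1, cfg$h2_M_direct > 0,
            cfg$h2_M_direct < 1, abs(cfg$rho) <= 1,
            cfg$N_med <= cfg$N_med_pot, cfg$true_MP >= 0, cfg$true_MP <= 1)
  structure(cfg, class = "sim_config")
}

# draw m effects with sd sqrt(h2/m), rescaled so sum of squares is exactly h2
draw_rescaled <- function(m, h2) {
  b <- stats::rnorm(m, 0, sqrt(h2 / m))
  b * sqrt(h2 / sum(b^2))
}

#' Simulate one summary-statistics dataset
#'
#' Draws one replicate of the generative model in [sim_config()]: true
#' instrument effects, causal chain, and noisy observed summary statistics
#' over the `m_E + N_med * m_M` instrument grid (instruments are mutually
#' independent, C = I). Exposure effect estimates at mediator-instrument
#' positions are set to zero after adding noise, mimicking QTL datasets that
#' report only significant associations.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed for this draw.
#' @return list of class `sim_dataset` with `beta_E_hat` (length m), `beta_M_hat`
#'   (m x N_med_pot matrix), `beta_Y_hat` (length m), index vectors
#'   `exposure_idx` and `mediator_idx` (list), and `truth` (`alpha_EM`,
#'   `alpha_MY`, `theta_M`, `theta_D`, `theta_T`).
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m_tot <- cfg$m_E + cfg$N_med * cfg$m_M
  exposure_idx <- seq_len(cfg$m_E)
  mediator_idx <- lapply(seq_len(cfg$N_med), function(k) {
    cfg$m_E + (k - 1) * cfg$m_M + seq_len(cfg$m_M)
  })

  beta_E <- numeric(m_tot)
  beta_E[exposure_idx] <- draw_rescaled(cfg$m_E, cfg$h2_E)

  alpha_EM <- numeric(cfg$N_med_pot)
  alpha_MY <- numeric(cfg$N_med_pot)
  if (cfg$N_med > 0) {
    sd_em <- sqrt(cfg$var_alpha_EM); sd_my <- sqrt(cfg$var_alpha_MY)
    z1 <- stats::rnorm(cfg$N_med); z2 <- stats::rnorm(cfg$N_med)
    alpha_EM[seq_len(cfg$N_med)] <- sd_em * z1
    alpha_MY[seq_len(cfg$N_med)] <-
      sd_my * (cfg$rho * z1 + sqrt(1 - cfg$rho^2) * z2)
  }

  beta_M <- matrix(0, m_tot, cfg$N_med_pot)
  for (k in seq_len(cfg$N_med)) {
    beta_M[exposure_idx, k] <- beta_E[exposure_idx] * alpha_EM[k]
    beta_M[mediator_idx[[k]], k] <- draw_rescaled(cfg$m_M, cfg$h2_M_direct)
  }

  theta_M <- sum(alpha_EM * alpha_MY)
  if (cfg$true_MP == 0 && theta_M != 0) {
    stop("true_MP = 0 with non-zero mediated effect: theta_D undefined")
  }
  theta_D <- if (theta_M == 0) cfg$theta_D else theta_M * (1 / cfg$true_MP - 1)
  theta_T <- theta_D + theta_M
  beta_Y <- theta_D * beta_E + drop(beta_M %*% alpha_MY)

  beta_E_hat <- beta_E + stats::rnorm(m_tot, 0, sqrt(1 / cfg$N_E))
  beta_M_hat <- beta_M + matrix(stats::rnorm(m_tot * cfg$N_med_pot, 0,
                                             sqrt(1 / cfg$N_M)),
                                m_tot, cfg$N_med_pot)
  beta_Y_hat <- beta_Y + stats::rnorm(m_tot, 0, sqrt(1 / cfg$N_Y))
  # mediator-instrument exposure effects are sub-threshold: unreported, hence 0
  beta_E_hat[-exposure_idx] <- 0

  structure(list(beta_E_hat = beta_E_hat, beta_M_hat = beta_M_hat,
                 beta_Y_hat = beta_Y_hat, exposure_idx = exposure_idx,
                 mediator_idx = mediator_idx,
                 truth = list(alpha_EM = alpha_EM, alpha_MY = alpha_MY,
                              theta_M = theta_M, theta_D = theta_D,
                              theta_T = theta_T, beta_E = beta_E)),
            class = "sim_dataset")
}

#' Run the estimator chain on one simulated dataset
#'
#' Mirrors the real-data workflow: univariable IVW over the exposure
#' instruments for `theta_T`, mediator selection by exposure-to-mediator MR at
#' `p_em`, MVMR over the pooled instruments (exposure instruments plus own
#' instruments of selected relevant mediators) for `theta_D`, and the
#' conditional F-statistic of the exposure.
#'
#' @param dat a [simulate_dataset()] result.
#' @param cfg the matching [sim_config()].
#' @return list: `theta_T`, `se_T`, `theta_D`, `se_D`, `n_selected`,
#'   `n_med_sig` (relevant mediators selected), `F_cond`.
#' @export
fit_simulated <- function(dat, cfg) {
  ei <- dat$exposure_idx
  var_E <- 1 / cfg$N_E; var_M <- 1 / cfg$N_M; var_Y <- 1 / cfg$N_Y

  tot <- ivw_correlated(dat$beta_E_hat[ei], dat$beta_Y_hat[ei], var_E, var_Y)

  # exposure -> mediator MR per potential mediator over exposure instruments
  p_sel <- vapply(seq_len(cfg$N_med_pot), function(k) {
    ivw_correlated(dat$beta_E_hat[ei], dat$beta_M_hat[ei, k], var_E, var_M)$pvalue
  }, numeric(1))
  selected <- which(p_sel < cfg$p_em)
  relevant_selected <- selected[selected <= cfg$N_med]

  if (!length(selected)) {
    return(list(theta_T = tot$theta, se_T = tot$se, theta_D = tot$theta,
                se_D = tot$se, n_selected = 0L, n_med_sig = 0L,
                F_cond = cfg$N_E * sum(dat$beta_E_hat[ei]^2) / length(ei),
                detectable = FALSE))
  }
  rows <- c(ei, unlist(dat$mediator_idx[relevant_selected]))
  B <- cbind(dat$beta_E_hat[rows], dat$beta_M_hat[rows, selected, drop = FALSE])
  prob <- list(B = B, beta_Y = dat$beta_Y_hat[rows], var_Y = var_Y, C = NULL,
               mediator_ids = paste0("M", selected))
  fit <- mvmr_correlated(prob)
  list(theta_T = tot$theta, se_T = tot$se, theta_D = fit$theta_D,
       se_D = fit$se_D, n_selected = length(selected),
       n_med_sig = length(relevant_selected),
       F_cond = conditional_f(prob, cfg$N_E), detectable = TRUE)
}

#' Run a simulation scenario
#'
#' Simulates `reps` exposure-outcome pairs under one parameter setting, fits
#' the estimator chain to each, and aggregates the mediation proportion by the
#' dilution-corrected no-intercept regression of `theta_D` on `theta_T`
#' across replicates ([mp_from_effects()]). Per-replicate random streams are
#' derived deterministically from the master seed and replicate index, so
#' results are reproducible bit-for-bit.
#'
#' @param cfg a [sim_config()].
#' @return list of class `scenario_result`: `mp_hat`, `ci95`, `se`,
#'   `mean_n_med_sig`, `mean_n_selected`, `mean_F_cond`, `n_failed`,
#'   `replicates` (data frame), `cfg`.
#' @export
run_scenario <- function(cfg) {
  stopifnot(cfg$reps >= 2)
  recs <- vector("list", cfg$reps)
  for (r in seq_len(cfg$reps)) {
    rep_seed <- (cfg$seed %% 1000003) * 2048 + r
    dat <- simulate_dataset(cfg, seed = rep_seed)
    recs[[r]] <- tryCatch({
      fit <- fit_simulated(dat, cfg)
      data.frame(rep = r, theta_T = fit$theta_T, se_T = fit$se_T,
                 theta_D = fit$theta_D, se_D = fit$se_D,
                 n_selected = fit$n_selected, n_med_sig = fit$n_med_sig,
                 F_cond = fit$F_cond, true_theta_T = dat$truth$theta_T,
                 failed = FALSE)
    }, error = function(e) {
      data.frame(rep = r, theta_T = NA, se_T = NA, theta_D = NA, se_D = NA,
                 n_selected = NA, n_med_sig = NA, F_cond = NA,
                 true_theta_T = dat$truth$theta_T, failed = TRUE)
    })
  }
  reps <- do.call(rbind, recs)
  ok <- reps[!reps$failed, , drop = FALSE]
  est <- mp_from_effects(ok$theta_D, ok$theta_T, ok$se_T)
  structure(list(mp_hat = est$mp, ci95 = est$ci95, se = est$se_gamma_cor,
                 mean_n_med_sig = mean(ok$n_med_sig),
                 mean_n_selected = mean(ok$n_selected),
                 mean_F_cond = mean(ok$F_cond),
                 n_failed = sum(reps$failed), replicates = reps, cfg = cfg),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(paste0("Scenario: true MP = %.2f -> MP_hat = %.1f%% ",
                     "(95%% CI: [%.1f%%-%.1f%%]); mean N_med_sig = %.2f; ",
                     "mean F_cond = %.1f\n"),
              x$cfg$true_MP, 100 * x$mp_hat, 100 * x$ci95[1], 100 * x$ci95[2],
              x$mean_n_med_sig, x$mean_F_cond))
  invisible(x)
}

#' Sweep over simulation scenarios
#'
#' Runs [run_scenario()] for each configuration and returns a tidy table, one
#' row per scenario, keyed by the parameter(s) that vary.
#'
#' @param cfgs list of [sim_config()] objects.
#' @return data frame with the varied parameters and per-scenario summaries.
#' @export
sweep_scenarios <- function(cfgs) {
  results <- lapply(cfgs, run_scenario)
  par_names <- names(cfgs[[1]])
  par_names <- setdiff(par_names, c("seed"))
  varies <- par_names[vapply(par_names, function(p) {
    length(unique(vapply(cfgs, function(c) as.numeric(c[[p]]), numeric(1)))) > 1
  }, logical(1))]
  if (!length(varies)) varies <- "true_MP"
  rows <- Map(function(cfg, res) {
    cbind(as.data.frame(cfg[varies]),
          data.frame(mp_hat = res$mp_hat, ci_lo = res$ci95[1],
                     ci_hi = res$ci95[2], mean_n_med_sig = res$mean_n_med_sig,
                     mean_F_cond = res$mean_F_cond, n_failed = res$n_failed))
  }, cfgs, results)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
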
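# Independent brute-force oracles used to cross-check the estimators.

# generalized least squares by explicit normal equations and small-matrix
# inversion (no shared code with the package's fit paths)
gls_oracle <- function(X, y, C) {
  X <- as.matrix(X)
  Ci <- solve(C)
  drop(solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% y)
}

# textbook fixed-effect IVW (independent instruments, inverse-variance weights)
ivw_textbook <- function(beta_E, beta_Y, var_Y) {
  w <- 1 / var_Y
  theta <- sum(w * beta_E * beta_Y) / sum(w * beta_E^2)
  se <- sqrt(1 / sum(w * beta_E^2))
  list(theta = theta, se = se)
}

# random correlation matrix with unit diagonal (well-conditioned)
random_corr <- function(m) {
  A <- matrix(stats::rnorm(m * m), m)
  S <- A %*% t(A) + m * diag(m)
  stats::cov2cor(S)
}

# small in-code summary_stats builder
make_ss <- function(ids, beta, se, pos = seq_along(ids) * 1000, chrom = 1,
                    ea = "A", oa = "G", eaf = 0.3, n = 10000,
                    trait_id = "trait", trait_role = "exposure",
                    feature_pos = NA_integer_, feature_chrom = NA_integer_) {
  k <- length(ids)
  summary_stats(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                           effect_allele = rep_len(ea, k),
                           other_allele = rep_len(oa, k),
                           eaf = rep_len(eaf, k), beta = beta,
                           se = rep_len(se, k), n = rep_len(n, k),
                           stringsAsFactors = FALSE),
                trait_id = trait_id, trait_role = trait_role,
                feature_pos = feature_pos, feature_chrom = feature_chrom,
                validate = FALSE)
}
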
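# Independent oracles used across the suite. These stay deliberately dumb:
# brute-force enumeration and hand-derived closed forms, never calls into the
# code paths they check.

# Brute-force signed-rank oracle: centered statistic and exact two-sided p by
# enumerating all 2^m sign assignments on the observed mid-ranks.
oracle_signed_rank <- function(x, y) {
  d <- y - x
  nz <- d[d != 0]
  m <- length(nz)
  if (m == 0L) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(nz))
  center <- m * (m + 1) / 4
  s_obs <- sum(r[nz > 0]) - center
  s_all <- numeric(2^m)
  for (k in 0:(2^m - 1)) {
    signs <- as.integer(intToBits(k))[seq_len(m)]
    s_all[k + 1] <- sum(r[signs == 1L]) - center
  }
  list(statistic = s_obs,
       p_value = mean(abs(s_all) >= abs(s_obs) - 1e-12))
}

# Exact single-arm probability by enumerating every 0/1 sequence of length p.
oracle_single_arm_prob <- function(p) {
  seqs <- as.matrix(expand.grid(rep(list(0:1), p)))
  mean(rowSums(seqs) %in% c(0L, p))
}

# Closed-form sampling variances of the mean-effect estimator, derived from
# the generative model (no carryover, no period effects, balanced designs,
# residual shared between counterfactuals of a cell):
#
# RRD (constrained, p_T = p_C = p/2, tau_hat = mean_i d_hat_i):
#   d_hat_i = D_i + (mean of p/2 residuals) - (mean of p/2 other residuals)
#   Var(d_hat_i) = sigma2_D + 4 sigma2_e / p  =>  Var(tau_hat) = that / N.
#
# PGD (N/2 per arm, between-arm difference of per-subject means over p
# periods): Var(subject mean) = sigma2_a + sigma2_D x + sigma2_e / p, so
#   Var(tau_hat) = (4 sigma2_a + 2 sigma2_D + 4 sigma2_e / p) / N.
oracle_var_tau_rrd <- function(sigma2_trh, sigma2_resid, N, p) {
  (sigma2_trh + 4 * sigma2_resid / p) / N
}
oracle_var_tau_pgd <- function(sigma2_subject, sigma2_trh, sigma2_resid, N, p) {
  (4 * sigma2_subject + 2 * sigma2_trh + 4 * sigma2_resid / p) / N
}
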
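# Independent oracles used across tests.

# NB log-likelihood of one group with common mean m, size factors sf,
# dispersion alpha (size = 1/alpha; Poisson when alpha == 0)
nb_group_loglik <- function(m, y, sf, alpha) {
  mu <- sf * m
  if (alpha == 0) sum(dpois(y, mu, log = TRUE))
  else sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# brute-force likelihood-ratio test of group effect for one gene
nb_lrt_oracle <- function(y, sf, alpha, is_double) {
  mle <- function(y0, sf0) {
    optimize(function(m) -nb_group_loglik(m, y0, sf0, alpha),
             interval = c(1e-6, max(y0 / sf0) * 10 + 10))$minimum
  }
  m_all <- mle(y, sf)
  m0 <- mle(y[!is_double], sf[!is_double])
  m1 <- mle(y[is_double], sf[is_double])
  ll_null <- nb_group_loglik(m_all, y, sf, alpha)
  ll_full <- nb_group_loglik(m0, y[!is_double], sf[!is_double], alpha) +
    nb_group_loglik(m1, y[is_double], sf[is_double], alpha)
  stat <- 2 * (ll_full - ll_null)
  pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

# closed-form chi-squared (df = 3) upper tail, independent of pchisq
chi2_df3_upper <- function(x) {
  2 * (1 - pnorm(sqrt(x))) + sqrt(2 * x / pi) * exp(-x / 2)
}

# one-gene methylation summary computed by direct arithmetic
manual_gene_level <- function(sites, ctx) {
  s <- sites[sites$context == ctx & sites$total_reads >= 1, ]
  sum(s$methylated_reads) / sum(s$total_reads)
}
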
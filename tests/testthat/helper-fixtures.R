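# small study-condition configs used across tests; sizes chosen so that each
# test runs in seconds while keeping the statistical structure intact
tiny_config <- function(...) {
  defaults <- list(
    n_genes = 60, n_tsg = 8, n_normal = 40, n_cancer = c(40, 40),
    n_flipped_pairs = 10, frac_cis = 0.3, n_trans_targets = 15,
    seed = 11
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# simulate bivariate samples with correlation rho and return cor(x, y)
sample_cor <- function(n, rho) {
  f <- rnorm(n)
  x <- sqrt(abs(rho)) * f + sqrt(1 - abs(rho)) * rnorm(n)
  y <- sign(rho) * sqrt(abs(rho)) * f + sqrt(1 - abs(rho)) * rnorm(n)
  cor(x, y)
}

# p-value matrix with k columns sharing a latent factor (pairwise correlation
# rho between the underlying z-scores), uniform marginals under the null
correlated_null_pvalues <- function(n_rows, k = 3, rho = 0.5) {
  latent <- rnorm(n_rows)
  z <- sqrt(rho) * latent +
    sqrt(1 - rho) * matrix(rnorm(n_rows * k), n_rows, k)
  pnorm(z, lower.tail = FALSE)
}
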
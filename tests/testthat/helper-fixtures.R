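# Shared fixtures: a small study configuration and its derived objects,
# built once per test run.

small_config <- function(seed = 42L, n_genes = 300L, noise_log2_sd = 0.1,
                         ...) {
  sim_config(seed = seed, n_genes = n_genes,
             noise_log2_sd = noise_log2_sd, ...)
}

# Renewal-theory standard error of the simulated effective initiation
# rate (independent re-derivation used by the oracle tests): intervals
# between successes are tau + Exp(1/a).
renewal_rate_se <- function(a, tau, duration) {
  mu1 <- tau + 1 / a
  (1 / a) / sqrt(mu1^3 * duration)
}

# Exhaustive hypergeometric tail P(overlap >= k): enumerate every
# possible query draw of size n from a universe of size N in which the
# group is (WLOG, by exchangeability) the first K elements.
hyper_tail_enum <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(0 >= k))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Pearson correlation from the raw covariance formula (oracle for
# signature_correlation).
pearson_brute <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
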
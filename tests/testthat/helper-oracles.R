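# Independent oracles used across tests.

# Brute-force GLS ancestral states: for each internal node, the BLUP
# E[a_k | tips] with the phylogenetic mean estimated by GLS.  Built on
# the full covariance matrix, independent of the tree-Laplacian path
# used by ancestral_states_bm().
gls_asr_oracle <- function(tree, x) {
  x <- x[tree$tip.label]
  n <- length(x)
  C <- ape::vcv.phylo(tree)
  Ci <- solve(C)
  mu <- sum(Ci %*% x) / sum(Ci)
  depths <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  states <- vapply((n + 1):(n + tree$Nnode), function(k) {
    ck <- depths[mr[k, seq_len(n)]]
    mu + as.numeric(t(ck) %*% Ci %*% (x - mu))
  }, numeric(1))
  names(states) <- as.character((n + 1):(n + tree$Nnode))
  states
}

# Direct multivariate-normal log-density with mean mu*1 and covariance
# sigma2 * C (no profiling): oracle for the lambda likelihood.
mvn_loglik_oracle <- function(C, x, mu, sigma2) {
  n <- length(x)
  S <- sigma2 * C
  r <- x - mu
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                       t(r) %*% solve(S) %*% r))
}

# Closed-form simple-regression slope and SE (oracle for powerlaw_fit
# and the nested F-test pieces).
ols_slope_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  se <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  list(slope = b, intercept = a, se = se)
}

# Random valid Sharpe-Schoolfield parameter sets for property tests.
random_ss_params <- function() {
  E <- stats::runif(1, 0.3, 1.2)
  ss_params(B0 = stats::runif(1, 0.05, 2), E = E,
            ED = E + stats::runif(1, 1, 4),
            Tpk = celsius_to_kelvin(stats::runif(1, 15, 45)))
}
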
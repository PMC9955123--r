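# Seeded random valid parameter sets used across the oracle-path tests:
# unit-diagonal full-rank mixing matrix, at least `n0` pure nodes per
# community on each side, Dirichlet-interior mixed rows, theta bounded away
# from 0 and 1 so all edge probabilities stay in (0, 1).
random_valid_params <- function(seed, K = NULL, nr = NULL, nc = NULL,
                                mixed_frac = NULL) {
  set.seed(seed)
  if (is.null(K)) K <- sample(2:4, 1)
  if (is.null(nr)) nr <- sample(60:250, 1)
  if (is.null(nc)) nc <- sample(60:250, 1)
  if (is.null(mixed_frac)) mixed_frac <- runif(1, 0.1, 0.6)
  n0r <- max(2L, floor(nr * (1 - mixed_frac) / K))
  n0c <- max(2L, floor(nc * (1 - mixed_frac) / K))
  pi_r <- dimsc:::random_membership(nr, n0r, K)
  pi_c <- dimsc:::random_membership(nc, n0c, K)
  P <- matrix(runif(K * K, 0, 0.5), K, K)
  diag(P) <- 1
  theta <- runif(nr, 0.2, 0.9)
  didcmm_params(K, P, pi_r, pi_c, theta)
}

# Column permutation alignment helper for comparing matrices up to
# community relabelling.
align_to <- function(pi_hat, pi_true) {
  perm <- mixed_hamming(pi_hat, pi_true)$perm
  pi_hat %*% dimsc:::.perm_matrix(perm)
}
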
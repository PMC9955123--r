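#' Validate a membership matrix
#'
#' A membership matrix is an `n x K` matrix whose i-th row is the probability
#' mass function of node i over the K communities: entries lie in \[0, 1\] and
#' every row sums to one.  Row and column nodes of a directed network carry
#' separate membership matrices (often written \eqn{\Pi_r} and \eqn{\Pi_c}).
#'
#' @param pi numeric matrix, `n x K`.
#' @param tol tolerance on the row sums (default `1e-12`).
#' @param arg name used in error messages.
#' @return `pi`, invisibly, after validation.
#' @export
validate_membership <- function(pi, tol = 1e-12, arg = "pi") {
  if (!is.matrix(pi) || !is.numeric(pi)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (any(pi < -tol) || any(pi > 1 + tol)) {
    stop(sprintf("`%s` has entries outside [0, 1]", arg), call. = FALSE)
  }
  bad <- which(abs(rowSums(pi) - 1) > tol)
  if (length(bad)) {
    stop(sprintf("`%s` rows are not probability vectors (first offending row: %d)",
                 arg, bad[1]), call. = FALSE)
  }
  invisible(pi)
}

#' Pure-node index sets of a membership matrix
#'
#' A node is *pure* when its membership row is a standard basis vector (a
#' single community carries weight one); otherwise it is *mixed*.
#'
#' @param pi membership matrix (`n x K`, row-stochastic).
#' @param tol numerical tolerance for equality with 1.
#' @return A list with `is_pure` (logical length n), and `index` (list of K
#'   integer vectors: the pure nodes of each community).
#' @export
pure_nodes <- function(pi, tol = 1e-12) {
  K <- ncol(pi)
  is_pure <- apply(pi, 1L, function(r) any(abs(r - 1) <= tol))
  index <- lapply(seq_len(K), function(k) which(abs(pi[, k] - 1) <= tol))
  list(is_pure = is_pure, index = index)
}

#' Build a block membership matrix with pure and mixed nodes
#'
#' Lays out `n0` pure nodes per community (communities in order, pure blocks
#' first) followed by mixed nodes.  `mixed` may be a single probability vector
#' recycled over all mixed nodes (the uniform `1/K` pattern used throughout
#' the simulations) or a matrix of patterns cycled row by row, which covers
#' designs with no pure nodes and a small set of fixed mixed profiles such as
#' (0.9, 0.1)/(0.1, 0.9).
#'
#' @param n total number of nodes.
#' @param n0 number of pure nodes per community.
#' @param K number of communities.
#' @param mixed probability vector of length K, or a matrix with K columns.
#' @return an `n x K` row-stochastic matrix.
#' @export
build_membership <- function(n, n0, K, mixed = rep(1 / K, K)) {
  if (n0 * K > n) stop("n0 * K exceeds n", call. = FALSE)
  pi <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (n0 > 0) pi[((k - 1) * n0 + 1):(k * n0), k] <- 1
  }
  n_mixed <- n - n0 * K
  if (n_mixed > 0) {
    if (is.matrix(mixed)) {
      stopifnot(ncol(mixed) == K)
      idx <- rep(seq_len(nrow(mixed)), length.out = n_mixed)
      pi[(n0 * K + 1):n, ] <- mixed[idx, , drop = FALSE]
    } else {
      stopifnot(length(mixed) == K)
      pi[(n0 * K + 1):n, ] <- matrix(mixed, n_mixed, K, byrow = TRUE)
    }
  }
  validate_membership(pi, tol = 1e-9)
  pi
}

#' Draw random mixed membership rows on the simplex interior
#'
#' Used by the randomised oracle fixtures: `n0` pure nodes per community and
#' the remaining nodes drawn from a Dirichlet(1, ..., 1) distribution, which
#' puts them strictly inside the simplex with probability one.
#'
#' @param n,n0,K as in [build_membership()].
#' @return an `n x K` row-stochastic matrix.
#' @keywords internal
random_membership <- function(n, n0, K) {
  n_mixed <- n - n0 * K
  mixed <- NULL
  if (n_mixed > 0) {
    g <- matrix(stats::rexp(n_mixed * K), n_mixed, K)
    mixed <- g / rowSums(g)
  }
  pi <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (n0 > 0) pi[((k - 1) * n0 + 1):(k * n0), k] <- 1
  }
  if (n_mixed > 0) pi[(n0 * K + 1):n, ] <- mixed
  pi
}
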
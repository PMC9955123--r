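#' Top-K singular value decomposition
#'
#' Computes the leading K singular triplets (U, Lambda, V) of a population or
#' observed bi-adjacency matrix.  The sign of each singular-vector pair is
#' fixed by making the largest-magnitude entry of each column of U positive,
#' so repeated runs (and stored fixtures) are reproducible; the estimator
#' itself is invariant to sign flips.
#'
#' @param M numeric matrix, `nr x nc`.
#' @param K number of leading components, `K <= min(nr, nc)`.
#' @return an object of class `spectral_decomposition`: list with `U`
#'   (`nr x K`), `d` (length-K singular values, nonincreasing), `V`
#'   (`nc x K`); `U_star` and `row_norms` are filled by [row_normalize()].
#' @export
top_k_svd <- function(M, K) {
  stopifnot(is.matrix(M) || inherits(M, "Matrix"))
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("`M` must be finite", call. = FALSE)
  K <- as.integer(K)
  if (K > min(dim(M))) stop("K exceeds min(nr, nc)", call. = FALSE)
  s <- svd(M, nu = K, nv = K)
  d <- s$d[seq_len(K)]
  U <- s$u; V <- s$v
  for (k in seq_len(K)) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  if (d[K] < 1e-12 * d[1]) {
    warning("RankDeficiency: K-th singular value is numerically zero; ",
            "corner hunting downstream is unreliable", call. = FALSE)
  }
  structure(list(U = U, d = d, V = V, U_star = NULL, row_norms = NULL,
                 degenerate_rows = integer(0)),
            class = "spectral_decomposition")
}

#' Row-normalize the left singular vectors
#'
#' Scales every row of U to unit Euclidean norm, producing the matrix whose
#' rows live on the unit sphere and carry the cone structure: pure row nodes
#' sit at the K cone corners and mixed rows are scaled convex combinations of
#' them.  The normalization removes the row-node degree-heterogeneity
#' nuisance.  Rows with numerically zero norm (impossible on exact-rank
#' inputs after pruning, possible on pathological samples) are assigned the
#' first unit vector and recorded in `degenerate_rows`.
#'
#' @param dec a `spectral_decomposition` from [top_k_svd()].
#' @param eps norm threshold below which a row counts as degenerate.
#' @return the decomposition with `U_star` and `row_norms` filled.
#' @export
row_normalize <- function(dec, eps = 1e-12) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  nrm <- sqrt(rowSums(dec$U^2))
  degenerate <- which(nrm <= eps)
  U_star <- dec$U / pmax(nrm, eps)
  if (length(degenerate)) {
    U_star[degenerate, ] <- 0
    U_star[degenerate, 1] <- 1
  }
  dec$U_star <- U_star
  dec$row_norms <- nrm
  dec$degenerate_rows <- degenerate
  dec
}

# Moore-Penrose pseudo-inverse of a small K x K corner matrix with a
# condition-number guard; used for the corner-matrix inversions.
pinv_guarded <- function(B, cond_max = 1e10, what = "corner matrix") {
  s <- svd(B)
  d <- s$d
  if (d[1] <= 0 || d[1] / max(d[length(d)], .Machine$double.xmin) > cond_max) {
    stop(sprintf("SingularCornerMatrix: %s has condition number > %g", what, cond_max),
         call. = FALSE)
  }
  s$v %*% (t(s$u) / d)
}
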
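#' Oracle spectral recovery from the population matrix
#'
#' The ideal estimator: given the exact expectation `omega` of the adjacency
#' matrix (rank K under the identifiability conditions) it recovers the row
#' and column membership matrices exactly.  Pipeline: compact SVD
#' `omega = U Lambda V'`; row-normalize U into `U_star`; successive
#' projection on the rows of V finds the pure-column-node corner rows; the
#' SVM-cone hunt on `U_star` finds the pure-row-node corners; then
#' \deqn{J^* = diag(U^*(I_r,:)\,\Lambda\,V'(I_c,:)),\quad
#'       Z_r = U\,U^{*-1}(I_r,:)\,J^*,\quad Z_c = V\,V^{-1}(I_c,:),}
#' and row-wise L1 normalization of `Z_r`, `Z_c` gives the memberships.
#' The corner-block of the degree vector is identified as
#' `theta_r(I_r) = diag(U(I_r,:) Lambda V'(I_c,:))` (this is where the unit
#' diagonal of the mixing matrix is needed); the remaining entries follow
#' from the recovered memberships and mixing matrix.
#'
#' @param omega population matrix (`nr x nc`, rank K).
#' @param K number of communities.
#' @param seed seed for the k-means restarts inside the cone hunt.
#' @return a list of class `dimsc_fit` with elements `pi_r`, `pi_c`
#'   (membership estimates), `Z_r`, `Z_c` (pre-normalization scores),
#'   `corners_row`, `corners_col`, `theta_r` (recovered degree vector),
#'   `P` (recovered mixing matrix), `svd`, and diagnostic counts.
#' @export
ideal_dimsc <- function(omega, K, seed = 1L) {
  K <- as.integer(K)
  dec <- row_normalize(top_k_svd(omega, K))
  cc <- successive_projection(dec$V, K)
  cr <- svm_cone(dec$U_star, K, seed = seed)
  est <- .memberships_from_corners(dec, cr, cc, clip = FALSE)

  # degree vector: exact on the corner block, extended via the recovered
  # mixing matrix P = Theta_r(I_r,I_r)^{-1} Omega(I_r, I_c); uses the
  # community-aligned corner sets of the fit
  Ir <- est$corners_row$indices
  Ic <- est$corners_col$indices
  theta_corner <- diag(dec$U[Ir, , drop = FALSE] %*%
                         (dec$d * t(dec$V[Ic, , drop = FALSE])))
  P_hat <- omega[Ir, Ic, drop = FALSE] / theta_corner
  denom <- est$pi_r %*% P_hat %*% t(est$pi_c[Ic, , drop = FALSE])
  theta_full <- rowSums(omega[, Ic, drop = FALSE]) / rowSums(denom)

  structure(c(est,
              list(theta_r = theta_full, theta_r_corner = theta_corner,
                   P = P_hat, svd = dec, K = K, oracle = TRUE)),
            class = "dimsc_fit")
}

#' Fit DiMSC to an observed adjacency matrix
#'
#' The empirical estimator: runs the oracle pipeline on the top-K SVD of the
#' observed binary bi-adjacency matrix, then clips negative score entries to
#' zero (weights must be nonnegative; noise can push scores below zero)
#' before the row-wise L1 normalization.
#'
#' @param A binary `nr x nc` matrix, or an `adjacency_sample` from
#'   [sample_adjacency()].  Must contain no all-zero row or column (prune
#'   first).
#' @param K number of communities.
#' @param seed seed for the k-means restarts inside the cone hunt.
#' @return a `dimsc_fit`; see [ideal_dimsc()].  `clipped_row`/`clipped_col`
#'   count score entries set to zero, `rescued_rows`/`rescued_cols` count
#'   rows whose scores were entirely nonpositive (those are assigned the
#'   community of their largest pre-clip score).
#' @export
dimsc <- function(A, K, seed = 1L) {
  if (inherits(A, "adjacency_sample")) A <- A$A
  stopifnot(is.matrix(A))
  if (any(rowSums(A) == 0) || any(colSums(A) == 0)) {
    stop("`A` has all-zero rows or columns; prune before fitting", call. = FALSE)
  }
  K <- as.integer(K)
  dec <- row_normalize(top_k_svd(A, K))
  cc <- successive_projection(dec$V, K)
  cr <- svm_cone(dec$U_star, K, seed = seed)
  est <- .memberships_from_corners(dec, cr, cc, clip = TRUE)
  structure(c(est, list(svd = dec, K = K, oracle = FALSE)),
            class = "dimsc_fit")
}

# Shared corner-to-membership step (Z scores, clipping policy, L1 rows).
#
# The row and column corner sets are first brought into a common community
# order: diag(U*(Ir,:) Lambda V'(Ic,:)) identifies the degree factors only
# when the i-th row corner and the i-th column corner represent the same
# community (the ideal-case convention Pi_r(Ir,:) = Pi_c(Ic,:) = I_K).  The
# product matrix is N_U Theta_r P up to row/column permutations and P is
# diagonally dominant by the unit-diagonal identifiability condition, so a
# maximum-sum assignment on it recovers the pairing.
.memberships_from_corners <- function(dec, cr, cc, clip) {
  K <- length(cr$indices)
  Ur <- dec$U_star[cr$indices, , drop = FALSE]
  Vc <- dec$V[cc$indices, , drop = FALSE]
  M <- Ur %*% (dec$d * t(Vc))
  if (K > 1) {
    pairing <- hungarian_assignment(-M)
    cc$indices <- cc$indices[pairing]
    cc$corner_rows <- cc$corner_rows[pairing, , drop = FALSE]
    Vc <- dec$V[cc$indices, , drop = FALSE]
    M <- M[, pairing, drop = FALSE]
  }
  J_star <- diag(M)
  neg_J <- sum(J_star <= 0)
  if (neg_J > 0) J_star <- pmax(J_star, 1e-12)  # positive in the ideal case
  Y_star <- dec$U %*% pinv_guarded(Ur, what = "row corner matrix U*(Ir,:)")
  Z_r <- Y_star %*% diag(J_star, K)
  Z_c <- dec$V %*% pinv_guarded(Vc, what = "column corner matrix V(Ic,:)")

  norm_rows <- function(Z, do_clip) {
    rescued <- integer(0)
    Zc <- Z
    clipped <- 0L
    if (do_clip) {
      clipped <- sum(Z < 0)
      Zc <- pmax(Z, 0)
      dead <- which(rowSums(Zc) <= 0)
      if (length(dead)) {
        rescued <- dead
        for (i in dead) Zc[i, which.max(Z[i, ])] <- 1
      }
    }
    s <- rowSums(abs(Zc))
    list(pi = Zc / s, clipped = clipped, rescued = rescued)
  }
  nr_ <- norm_rows(Z_r, clip)
  nc_ <- norm_rows(Z_c, clip)
  list(pi_r = nr_$pi, pi_c = nc_$pi, Z_r = Z_r, Z_c = Z_c,
       corners_row = cr, corners_col = cc,
       clipped_row = nr_$clipped, clipped_col = nc_$clipped,
       rescued_rows = nr_$rescued, rescued_cols = nc_$rescued,
       negative_J_entries = neg_J)
}

#' @export
#' @method print dimsc_fit
print.dimsc_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d row nodes x %d column nodes, K = %d\n",
              if (isTRUE(x$oracle)) "Ideal DiMSC (population)" else "DiMSC",
              nrow(x$pi_r), nrow(x$pi_c), x$K))
  cat(sprintf("  leading singular values: %s\n",
              paste(signif(x$svd$d, 4), collapse = ", ")))
  cat(sprintf("  corner rows: %s | corner cols: %s\n",
              paste(x$corners_row$indices, collapse = ","),
              paste(x$corners_col$indices, collapse = ",")))
  if (!isTRUE(x$oracle)) {
    cat(sprintf("  clipped score entries: %d (row), %d (col)\n",
                x$clipped_row, x$clipped_col))
  }
  invisible(x)
}
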
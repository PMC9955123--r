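# All error metrics are permutation-aligned: community labels are only
# identified up to a relabelling, so distances are minimized over the K x K
# permutation matrices.  The entrywise L1 cost decomposes over matched column
# pairs, so the minimization is an assignment problem; it is solved by brute
# force over the K! permutations for K <= 6 and by the Hungarian algorithm
# beyond that, and the two routes agree exactly (tested).

# cost[k, l] = sum_i |pi_hat[i, k] - pi_true[i, l]|
.column_l1_cost <- function(pi_hat, pi_true) {
  K <- ncol(pi_hat)
  cost <- matrix(0, K, K)
  for (k in seq_len(K)) {
    cost[k, ] <- colSums(abs(pi_hat[, k] - pi_true))
  }
  cost
}

.all_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(K - 1L)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], K,
                   sub[, seq(pos, K - 1)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  out
}

# Hungarian algorithm (O(K^3) shortest augmenting path) for the minimum-cost
# assignment; perm[k] = column of pi_true matched to column k of pi_hat.
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n)) perm[p[j + 1L]] <- j
  perm
}

# Best permutation for a cost matrix; method switch for the oracle
# equivalence test.
.best_permutation <- function(cost, method = c("auto", "brute", "hungarian")) {
  method <- match.arg(method)
  K <- nrow(cost)
  if (method == "hungarian" || (method == "auto" && K > 6)) {
    perm <- hungarian_assignment(cost)
    return(list(perm = perm, cost = sum(cost[cbind(seq_len(K), perm)])))
  }
  perms <- .all_permutations(K)
  best <- Inf; best_perm <- seq_len(K)
  for (r in seq_len(nrow(perms))) {
    s <- sum(cost[cbind(seq_len(K), perms[r, ])])
    if (s < best) { best <- s; best_perm <- perms[r, ] }
  }
  list(perm = best_perm, cost = best)
}

#' Permutation-aligned mixed Hamming error (one side)
#'
#' `min_P ||pi_hat P - pi_true||_1 / n` over K x K permutation matrices P,
#' with the entrywise absolute-sum norm: the average per-node L1 membership
#' error under the best community relabelling.
#'
#' @param pi_hat,pi_true row-stochastic `n x K` matrices of the same shape.
#' @param method permutation search: `"auto"` (brute force for K <= 6,
#'   Hungarian assignment above), `"brute"`, or `"hungarian"`.
#' @return list with `error` and `perm` (the permutation: estimated column k
#'   is matched to true column `perm[k]`).
#' @export
mixed_hamming <- function(pi_hat, pi_true, method = "auto") {
  if (!all(dim(pi_hat) == dim(pi_true))) {
    stop("ShapeMismatch: membership matrices differ in shape", call. = FALSE)
  }
  bp <- .best_permutation(.column_l1_cost(pi_hat, pi_true), method)
  list(error = bp$cost / nrow(pi_hat), perm = bp$perm)
}

#' Mixed Hamming error of a two-sided fit
#'
#' The maximum of the row-side and column-side permutation-aligned errors,
#' each minimized over its own permutation.
#'
#' @param pi_hat_r,pi_r row-side estimate and truth.
#' @param pi_hat_c,pi_c column-side estimate and truth.
#' @return a single number in \[0, 2\].
#' @export
mhamm <- function(pi_hat_r, pi_r, pi_hat_c, pi_c) {
  max(mixed_hamming(pi_hat_r, pi_r)$error,
      mixed_hamming(pi_hat_c, pi_c)$error)
}

#' Worst per-node membership error
#'
#' Under the permutation that minimizes the total L1 error (the same
#' alignment as [mixed_hamming()]), the maximum over nodes of the L1
#' deviation between estimated and true membership rows.
#'
#' @inheritParams mixed_hamming
#' @return list with `error` (the max per-node L1 deviation) and `perm`.
#' @export
per_node_max_error <- function(pi_hat, pi_true) {
  if (!all(dim(pi_hat) == dim(pi_true))) {
    stop("ShapeMismatch: membership matrices differ in shape", call. = FALSE)
  }
  al <- mixed_hamming(pi_hat, pi_true)
  aligned <- pi_hat %*% .perm_matrix(al$perm)
  list(error = max(rowSums(abs(aligned - pi_true))), perm = al$perm)
}

.perm_matrix <- function(perm) {
  K <- length(perm)
  P <- matrix(0, K, K)
  P[cbind(seq_len(K), perm)] <- 1
  P
}

#' Shannon node-membership entropy
#'
#' The entropy of each node's membership PMF, in nats: 0 for pure nodes,
#' `log(K)` for a uniform membership; `0 log 0` counts as 0.
#'
#' @param pi row-stochastic membership matrix.
#' @return nonnegative numeric vector of length `nrow(pi)`.
#' @export
node_membership_entropy <- function(pi) {
  validate_membership(pi, tol = 1e-8)
  apply(pi, 1L, function(r) {
    r <- r[r > 0]
    -sum(r * log(r))
  })
}

#' Fraction of highly mixed nodes
#'
#' A node is *highly mixed* when its largest membership weight is at most
#' `threshold` (inclusive): no single community claims it convincingly.
#'
#' @param pi_hat row-stochastic membership matrix.
#' @param threshold inclusive cut on the row maximum (default 0.8).
#' @return list with `tau` (flagged fraction) and `flags` (logical vector).
#' @export
highly_mixed_fraction <- function(pi_hat, threshold = 0.8) {
  mx <- apply(pi_hat, 1L, max)
  flags <- mx <= threshold
  list(tau = mean(flags), flags = flags)
}

#' Hard community labels
#'
#' The home-base community of every node: the argmax of its membership row,
#' ties broken by the smallest community index.
#'
#' @param pi_hat row-stochastic membership matrix.
#' @return integer vector of labels in `1..K`.
#' @export
hard_labels <- function(pi_hat) {
  apply(pi_hat, 1L, which.max)
}

#' Row/column community asymmetry
#'
#' Permutation-minimized entrywise L1 distance between the two estimated
#' membership matrices of the *same* node set (row side vs column side),
#' divided by n.  Large values mean the sending-side community structure
#' differs from the receiving-side structure.
#'
#' @param pi_hat_r,pi_hat_c `n x K` row-stochastic matrices over one node set.
#' @return a single number.
#' @export
row_col_asymmetry <- function(pi_hat_r, pi_hat_c) {
  if (!all(dim(pi_hat_r) == dim(pi_hat_c))) {
    stop("ShapeMismatch: row and column estimates must cover the same nodes",
         call. = FALSE)
  }
  mixed_hamming(pi_hat_c, pi_hat_r)$error
}

#' Full recovery report for a two-sided fit
#'
#' @param fit a `dimsc_fit`.
#' @param pi_r,pi_c true membership matrices (already subset to the surviving
#'   nodes if the sample was pruned).
#' @param threshold highly-mixed cut, see [highly_mixed_fraction()].
#' @return a one-row tibble with `mhamm`, per-side errors, worst per-node
#'   errors, highly-mixed fractions and (for square fits) the row/column
#'   asymmetry.
#' @export
recovery_report <- function(fit, pi_r, pi_c, threshold = 0.8) {
  er <- mixed_hamming(fit$pi_r, pi_r)
  ec <- mixed_hamming(fit$pi_c, pi_c)
  tibble::tibble(
    mhamm = max(er$error, ec$error),
    mhamm_row = er$error,
    mhamm_col = ec$error,
    f_r_max = per_node_max_error(fit$pi_r, pi_r)$error,
    f_c_max = per_node_max_error(fit$pi_c, pi_c)$error,
    tau_r = highly_mixed_fraction(fit$pi_r, threshold)$tau,
    tau_c = highly_mixed_fraction(fit$pi_c, threshold)$tau,
    hamm_rc = if (nrow(fit$pi_r) == nrow(fit$pi_c))
      row_col_asymmetry(fit$pi_r, fit$pi_c) else NA_real_
  )
}
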
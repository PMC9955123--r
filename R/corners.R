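#' Successive projection vertex hunting
#'
#' Greedy simplex vertex hunting on the rows of a point matrix: K times,
#' select the row with maximal Euclidean norm in the current residual matrix,
#' then project every row onto the orthogonal complement of the selected
#' residual row.  On separable data — every row a convex combination of K
#' vertex rows that are themselves present — the selected indices are exactly
#' vertex rows, which is how the pure column nodes are found from the right
#' singular vectors.
#'
#' @param points `n x K` numeric matrix.
#' @param K number of vertices to hunt.
#' @return an object of class `corner_set`: list with `indices` (selection
#'   order), `corner_rows` (`K x K`, the corresponding rows of `points`), and
#'   `side = "column"`.
#' @export
successive_projection <- function(points, K) {
  stopifnot(is.matrix(points), nrow(points) >= K)
  R <- points
  idx <- integer(K)
  for (k in seq_len(K)) {
    nrm2 <- rowSums(R^2)
    j <- which.max(nrm2)           # ties: which.max takes the smallest index
    if (nrm2[j] <= 1e-24) {
      stop("DegenerateGeometry: residual norms vanished before K vertices were found",
           call. = FALSE)
    }
    idx[k] <- j
    u <- R[j, ] / sqrt(nrm2[j])
    R <- R - (R %*% u) %*% t(u)
  }
  corner_rows <- points[idx, , drop = FALSE]
  structure(list(indices = idx, corner_rows = corner_rows, side = "column"),
            class = "corner_set")
}

# Hard-margin one-class linear separator: unit w and offset b maximising the
# margin subject to w'x_i >= b for all rows.  Primary route is a one-class
# SVM in the hard-margin limit (tiny nu); if the solver degenerates the dual
# is solved directly as a minimum-norm point over the convex hull by
# Frank-Wolfe (w* = m/||m||, b* = ||m|| for the minimiser m).
.supporting_hyperplane <- function(X) {
  w <- NULL
  fit <- tryCatch(
    e1071::svm(X, type = "one-classification", kernel = "linear",
               nu = min(0.5, 1 / nrow(X)), scale = FALSE),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    w_raw <- drop(t(fit$coefs) %*% fit$SV)
    if (sqrt(sum(w_raw^2)) > 1e-10) w <- w_raw / sqrt(sum(w_raw^2))
  }
  if (is.null(w) || min(X %*% w) <= 0) {
    m <- .min_norm_point(X)
    if (sqrt(sum(m^2)) > 1e-12) w <- m / sqrt(sum(m^2))
  }
  if (is.null(w)) {
    stop("ConeCollapse: no supporting hyperplane with positive margin found",
         call. = FALSE)
  }
  margins <- drop(X %*% w)
  list(w = w, b = min(margins), margins = margins)
}

# Frank-Wolfe minimum-norm point in the convex hull of the rows of X.
.min_norm_point <- function(X, iters = 500L) {
  m <- colMeans(X)
  for (t in seq_len(iters)) {
    g <- drop(X %*% m)            # gradient direction scores
    j <- which.min(g)
    d <- X[j, ] - m
    denom <- sum(d^2)
    if (denom < 1e-30) break
    gamma <- min(1, max(0, -sum(m * d) / denom))
    if (gamma <= 0) break
    m <- m + gamma * d
  }
  m
}

#' SVM-cone corner hunting
#'
#' Finds the K corners of the cone spanned by unit-norm rows: (1) fit the
#' maximum-margin supporting hyperplane `w'x = b` of the point cloud with a
#' one-class linear SVM; (2) keep as candidates the points within a relative
#' margin `margin_tol` of the hyperplane (cone corners attain the minimal
#' margin, mixed rows sit strictly above); (3) cluster the candidates into K
#' groups by k-means (k-means++-style multiple restarts, seeded); (4) return
#' per group the candidate closest to its centre.  When fewer than K
#' distinguishable candidate clusters exist the margin tolerance escalates
#' tenfold up to `max_tol` before failing.
#'
#' @param points_unit `n x K` matrix with (approximately) unit-norm rows.
#' @param K number of corners.
#' @param margin_tol initial relative margin tolerance.
#' @param max_tol largest tolerance tried under escalation.
#' @param seed integer seed for the k-means restarts.
#' @return a `corner_set` (with `side = "row"`, plus the fitted `w`, `b`,
#'   the tolerance finally `used_tol`, and the `candidates` kept).
#' @export
svm_cone <- function(points_unit, K, margin_tol = 1e-3, max_tol = 1e-1,
                     seed = 1L) {
  stopifnot(is.matrix(points_unit), nrow(points_unit) >= K)
  hp <- .supporting_hyperplane(points_unit)
  tol <- margin_tol
  last_err <- NULL
  while (tol <= max_tol * (1 + 1e-12)) {
    res <- tryCatch(
      .cone_corners_at_tol(points_unit, K, hp, tol, seed),
      error = function(e) e
    )
    if (!inherits(res, "error")) {
      res$used_tol <- tol
      return(res)
    }
    last_err <- res
    tol <- tol * 10
  }
  stop(last_err)
}

.cone_corners_at_tol <- function(X, K, hp, tol, seed) {
  # cone data has b > 0 (positive-margin feasibility); the additive branch
  # only fires on degenerate inputs where the relative rule would be empty
  thr <- if (hp$b > 0) hp$b * (1 + tol) else hp$b + tol * (max(hp$margins) - hp$b)
  cand <- which(hp$margins <= thr)
  if (length(cand) < K) {
    stop("ConeCollapse: fewer than K candidate corners at this margin tolerance",
         call. = FALSE)
  }
  Xc <- X[cand, , drop = FALSE]
  n_distinct <- nrow(unique(round(Xc, 12)))
  if (n_distinct < K) {
    stop("ConeCollapse: fewer than K distinct candidate points", call. = FALSE)
  }
  if (length(cand) == K) {
    corner_rows <- X[cand, , drop = FALSE]
    sv <- svd(corner_rows, nu = 0, nv = 0)$d
    if (sv[K] < 1e-10 * sv[1]) {
      stop("ConeCollapse: corner matrix is rank deficient", call. = FALSE)
    }
    return(structure(list(indices = cand, corner_rows = corner_rows,
                          side = "row", w = hp$w, b = hp$b, candidates = cand),
                     class = "corner_set"))
  }
  set.seed(as.integer(seed))
  km <- suppressWarnings(stats::kmeans(Xc, centers = K, nstart = 10, iter.max = 100))
  centers <- km$centers
  cd <- as.matrix(stats::dist(centers))
  diag(cd) <- Inf
  if (min(cd) < 1e-8) {
    stop("ConeCollapse: candidate clusters are not distinguishable", call. = FALSE)
  }
  # clusters ordered by descending size, ties by smallest member index
  first_member <- vapply(seq_len(K), function(g) min(which(km$cluster == g)), 1L)
  ord <- order(-km$size, first_member)
  idx <- integer(K)
  for (pos in seq_len(K)) {
    g <- ord[pos]
    members <- which(km$cluster == g)
    d2 <- rowSums((Xc[members, , drop = FALSE] -
                     matrix(centers[g, ], length(members), K, byrow = TRUE))^2)
    idx[pos] <- cand[members[which.min(d2)]]  # ties: smallest index
  }
  corner_rows <- X[idx, , drop = FALSE]
  sv <- svd(corner_rows, nu = 0, nv = 0)$d
  if (sv[K] < 1e-10 * sv[1]) {
    stop("ConeCollapse: corner matrix is rank deficient", call. = FALSE)
  }
  structure(list(indices = idx, corner_rows = corner_rows, side = "row",
                 w = hp$w, b = hp$b, candidates = cand),
            class = "corner_set")
}

#' @export
#' @method print corner_set
print.corner_set <- function(x, ...) {
  cat(sprintf("%s-side corner set: K = %d, indices: %s\n",
              x$side, length(x$indices), paste(x$indices, collapse = ", ")))
  invisible(x)
}
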
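#' Bundle DiDCMM parameters
#'
#' The directed degree-corrected mixed-membership (DiDCMM) model generates a
#' binary `nr x nc` bi-adjacency matrix A with independent Bernoulli entries
#' \deqn{P(A(i,j)=1) = \theta_r(i)\,\Pi_r(i,:)\,P\,\Pi_c(j,:)',}
#' where `pi_r` (`nr x K`) and `pi_c` (`nc x K`) are row-stochastic membership
#' matrices, `P` (`K x K`, nonnegative, possibly asymmetric) sets the
#' community-to-community connection strength, and `theta_r` is the positive
#' degree-heterogeneity vector of the row nodes (column nodes carry none:
#' allowing heterogeneity on both sides makes the model unidentifiable).
#'
#' @param K number of communities (row side and column side share K).
#' @param P `K x K` nonnegative mixing matrix.
#' @param pi_r,pi_c membership matrices for row and column nodes.
#' @param theta_r positive numeric vector of length `nrow(pi_r)`.
#' @param check_probability reject parameter sets whose expected adjacency
#'   has entries above 1 (default `TRUE`).
#' @return an object of class `didcmm_params`.
#' @seealso [validate_identifiability()], [population_matrix()],
#'   [sample_adjacency()]
#' @export
didcmm_params <- function(K, P, pi_r, pi_c, theta_r, check_probability = TRUE) {
  stopifnot(is.numeric(K), length(K) == 1, K >= 1)
  K <- as.integer(K)
  if (!is.matrix(P) || nrow(P) != K || ncol(P) != K) {
    stop("`P` must be a K x K matrix", call. = FALSE)
  }
  if (any(P < 0)) stop("`P` must be nonnegative", call. = FALSE)
  validate_membership(pi_r, tol = 1e-9, arg = "pi_r")
  validate_membership(pi_c, tol = 1e-9, arg = "pi_c")
  if (ncol(pi_r) != K || ncol(pi_c) != K) {
    stop("membership matrices must have K columns", call. = FALSE)
  }
  theta_r <- as.numeric(theta_r)
  if (length(theta_r) != nrow(pi_r)) {
    stop("`theta_r` must have one entry per row node", call. = FALSE)
  }
  if (any(theta_r <= 0)) stop("`theta_r` must be strictly positive", call. = FALSE)
  params <- structure(
    list(K = K, P = P, pi_r = pi_r, pi_c = pi_c, theta_r = theta_r,
         nr = nrow(pi_r), nc = nrow(pi_c)),
    class = "didcmm_params"
  )
  if (check_probability) {
    om_max <- max(sweep(pi_r %*% P %*% t(pi_c), 1, theta_r, `*`))
    if (om_max > 1 + 1e-12) {
      stop(sprintf("OutOfRangeProbability: max expected edge probability %.4f > 1; rescale theta_r or P",
                   om_max), call. = FALSE)
    }
  }
  params
}

#' @export
#' @method print didcmm_params
print.didcmm_params <- function(x, ...) {
  cat(sprintf("DiDCMM parameters: nr = %d, nc = %d, K = %d\n", x$nr, x$nc, x$K))
  pr <- pure_nodes(x$pi_r); pc <- pure_nodes(x$pi_c)
  cat(sprintf("  pure row nodes: %d / %d; pure column nodes: %d / %d\n",
              sum(pr$is_pure), x$nr, sum(pc$is_pure), x$nc))
  cat(sprintf("  theta_r in [%.4g, %.4g]\n", min(x$theta_r), max(x$theta_r)))
  invisible(x)
}

#' Identifiability report for DiDCMM parameters
#'
#' Checks the two sufficient identifiability conditions: the mixing matrix has
#' full rank K and unit diagonal, and every row community and every column
#' community contains at least one pure node.  This is a pure inspection: it
#' never errors on a violation, it reports flags so callers can decide.
#'
#' @param params a [didcmm_params()] object.
#' @return a one-row tibble with logical flags `rank_full`, `unit_diagonal`,
#'   `pure_rows`, `pure_cols`, overall `identifiable`, and list-columns
#'   `violating_row_communities` / `violating_col_communities`.
#' @export
validate_identifiability <- function(params) {
  stopifnot(inherits(params, "didcmm_params"))
  P <- params$P
  sv <- svd(P, nu = 0, nv = 0)$d
  rank_full <- sum(sv >= 1e-10 * max(sv, .Machine$double.eps)) == params$K
  unit_diag <- all(abs(diag(P) - 1) <= 1e-10)
  pr <- pure_nodes(params$pi_r)
  pc <- pure_nodes(params$pi_c)
  viol_r <- which(vapply(pr$index, length, 1L) == 0L)
  viol_c <- which(vapply(pc$index, length, 1L) == 0L)
  tibble::tibble(
    rank_full = rank_full,
    unit_diagonal = unit_diag,
    pure_rows = length(viol_r) == 0L,
    pure_cols = length(viol_c) == 0L,
    identifiable = rank_full && unit_diag && length(viol_r) == 0L && length(viol_c) == 0L,
    violating_row_communities = list(viol_r),
    violating_col_communities = list(viol_c)
  )
}

#' Expected adjacency (population) matrix
#'
#' Builds \eqn{\Omega = \Theta_r \Pi_r P \Pi_c'}, the entrywise expectation of
#' the bi-adjacency matrix.  Under the identifiability conditions its rank is
#' exactly K, the low-dimensional structure the spectral estimator exploits.
#'
#' @param params a [didcmm_params()] object.
#' @return `nr x nc` numeric matrix with entries in \[0, 1\].
#' @export
population_matrix <- function(params) {
  stopifnot(inherits(params, "didcmm_params"))
  omega <- sweep(params$pi_r %*% params$P %*% t(params$pi_c), 1, params$theta_r, `*`)
  if (min(omega) < -1e-12 || max(omega) > 1 + 1e-12) {
    stop("OutOfRangeProbability: population matrix entries outside [0, 1]", call. = FALSE)
  }
  pmin(pmax(omega, 0), 1)
}

#' Sample a Bernoulli adjacency matrix from a population matrix
#'
#' Draws `A(i,j) ~ Bernoulli(omega(i,j))` independently.  With `prune = TRUE`
#' the rows with zero out-degree and the columns with zero in-degree are
#' removed in one pass (the pruning step of the simulation protocol: an
#' isolated node contributes nothing to the spectral factors), and
#' `kept_rows`/`kept_cols` record the survivors so ground-truth membership
#' matrices can be subset identically.
#'
#' @param omega population matrix with entries in \[0, 1\].
#' @param seed integer seed for the Bernoulli draws (optional).
#' @param prune drop zero-out-degree rows / zero-in-degree columns.
#' @return a list of class `adjacency_sample` with `A`, `kept_rows`,
#'   `kept_cols`.
#' @export
sample_adjacency <- function(omega, seed = NULL, prune = FALSE) {
  stopifnot(is.matrix(omega), min(omega) >= 0, max(omega) <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  A <- matrix(as.numeric(stats::runif(length(omega)) < omega),
              nrow(omega), ncol(omega))
  kept_rows <- seq_len(nrow(A))
  kept_cols <- seq_len(ncol(A))
  if (prune) {
    kept_rows <- which(rowSums(A) > 0)
    kept_cols <- which(colSums(A) > 0)
    A <- A[kept_rows, kept_cols, drop = FALSE]
  }
  structure(list(A = A, kept_rows = kept_rows, kept_cols = kept_cols),
            class = "adjacency_sample")
}

#' Planted-partition DiDCMM parameters
#'
#' The planted-partition special case on `n = nr = nc` nodes: within-community
#' edge probability `pin = alpha_in * log(n) / n`, across-community
#' `pout = alpha_out * log(n) / n`, no degree heterogeneity (`theta_r = 1`).
#' The recoverability statistic `|alpha_in - alpha_out| / max(alpha_in,
#' alpha_out)` governs the phase transition of membership estimation.
#'
#' @param n number of nodes per side.
#' @param K number of communities.
#' @param pi_r,pi_c membership matrices (`n x K`).
#' @param alpha_in,alpha_out positive signal levels.
#' @return a [didcmm_params()] object (the `pin`/`pout` scale is folded into
#'   the mixing matrix, the equivalent of factoring a sparsity scalar out of
#'   a unit-diagonal mixing matrix).
#' @export
make_planted_partition <- function(n, K, pi_r, pi_c, alpha_in, alpha_out) {
  stopifnot(alpha_in > 0, alpha_out > 0)
  pin <- alpha_in * log(n) / n
  pout <- alpha_out * log(n) / n
  if (max(pin, pout) > 1) {
    stop(sprintf("ProbabilityOverflow: max(pin, pout) = %.3f > 1", max(pin, pout)),
         call. = FALSE)
  }
  P <- matrix(pout, K, K)
  diag(P) <- pin
  didcmm_params(K, P, pi_r, pi_c, theta_r = rep(1, n))
}

# --- scenario registry ------------------------------------------------------

# Mixing matrices printed in the simulation studies.
.P1 <- matrix(c(1, 0.1, 0.2, 1), 2, 2, byrow = TRUE)
.P2 <- matrix(c(0.8, 0.1, 0.2, 0.9), 2, 2, byrow = TRUE)
.P3 <- matrix(c(1, 0.1, 0.3, 0.2, 1, 0.4, 0.5, 0.2, 1), 3, 3, byrow = TRUE)
.P4 <- matrix(c(0.8, 0.1, 0.3, 0.2, 0.9, 0.4, 0.5, 0.2, 1), 3, 3, byrow = TRUE)
.Pa <- matrix(c(0.9, 0.05, 0.1, 0.95), 2, 2, byrow = TRUE)
.Pb <- matrix(c(0.1, 0.95, 0.9, 0.05), 2, 2, byrow = TRUE)
# Row-major reading of the sparse small-network mixing matrices, scaled by
# log(nr)/nr; the printed source is typeset ambiguously, so the constructor
# below keeps them overridable.
.Pc_unscaled <- matrix(c(1 / 2, 1, 0, 1 / 2), 2, 2, byrow = TRUE)
.Pd_unscaled <- matrix(c(0, 1 / 2, 1 / 2, 1), 2, 2, byrow = TRUE)
.Pe_unscaled <- matrix(c(1 / 2, 1, 0, 0, 1 / 2, 0, 1, 0, 1 / 2), 3, 3, byrow = TRUE)
.Pf_unscaled <- matrix(c(1, 0, 1 / 2, 1 / 2, 0, 0, 0, 1 / 2, 1), 3, 3, byrow = TRUE)

#' Mild polynomial degree-heterogeneity profile of the small-network setups
#'
#' `theta_r(i) = 0.9 + i^2 / (9 nr^2)`, an increasing profile confined to
#' roughly \[0.9, 1.011\].
#'
#' @param nr number of row nodes.
#' @return numeric vector of length `nr`.
#' @export
setup_theta <- function(nr) 0.9 + (seq_len(nr))^2 / (9 * nr^2)

# Reciprocal-uniform degree draws: 1/theta_bar ~ U(1, z), theta = rho * theta_bar.
.theta_reciprocal_uniform <- function(nr, z, rho) {
  rho / stats::runif(nr, 1, z)
}

.experiment_base <- list(
  small2 = list(nr = 200, nc = 300, K = 2),
  large3 = list(nr = 600, nc = 900, K = 3)
)

# Mixed-membership patterns with no pure nodes used by several experiments.
.mixed2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
.mixed3 <- matrix(c(0.8, 0.1, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.8), 3, 3, byrow = TRUE)

#' Construct the parameters of a registered simulation scenario
#'
#' Reproduces the printed simulation configurations: the degree-heterogeneity,
#' pure-node-fraction, connectivity, sparsity and phase-transition experiment
#' families on networks of 200x300 / 600x900 nodes, and the eight small
#' illustrative setups on networks of 16-100 nodes.  Each scenario fixes
#' (K, P, membership layout, degree scheme); `overrides` moves the grid
#' parameter of the family (`n0`, `z`, `rho`, `beta`, `alpha_in`,
#' `alpha_out`) or swaps the degree profile (`theta_fun`).
#'
#' Registered names: `experiment1a`-`1d`, `experiment2a`-`2h`,
#' `experiment3a`-`3h`, `experiment4a`-`4h`, `experiment5a`, `experiment5b`,
#' `experiment6`, `setup1`-`setup8`.
#'
#' Whenever the mixing matrix of a connectivity scenario has entries above 1,
#' the drawn degree vector is rescaled by `1/max(P)` before validation so that
#' all edge probabilities remain in \[0, 1\].
#'
#' @param name scenario identifier.
#' @param overrides named list of parameter overrides.
#' @param seed integer seed used for the random parts of parameter generation
#'   (the reciprocal-uniform degree draws); deterministic scenarios ignore it.
#' @return a [didcmm_params()] object.
#' @export
make_scenario <- function(name, overrides = list(), seed = 1L) {
  ov <- function(key, default) if (!is.null(overrides[[key]])) overrides[[key]] else default
  set.seed(as.integer(seed))

  exp_family <- function(base, P, n0, z, rho, mixed_r = NULL, mixed_c = NULL) {
    nr <- ov("nr", base$nr); nc <- ov("nc", base$nc); K <- base$K
    n0 <- ov("n0", n0); z <- ov("z", z); rho <- ov("rho", rho)
    mr <- if (is.null(mixed_r)) rep(1 / K, K) else mixed_r
    mc <- if (is.null(mixed_c)) rep(1 / K, K) else mixed_c
    pi_r <- build_membership(nr, n0, K, mr)
    pi_c <- build_membership(nc, n0, K, mc)
    theta_fun <- ov("theta_fun", function(n) .theta_reciprocal_uniform(n, z, rho))
    theta <- theta_fun(nr)
    if (max(P) > 1) theta <- theta / max(P)  # connectivity-family rescaling rule
    didcmm_params(K, P, pi_r, pi_c, theta)
  }

  beta_P <- function(beta, diag_entries) {
    K <- length(diag_entries)
    P <- matrix(beta - 1, K, K)
    diag(P) <- diag_entries
    P
  }

  setup_family <- function(nr, nr0, nc, nc0, P, K) {
    nr <- ov("nr", nr); nc <- ov("nc", nc)
    nr0 <- ov("nr0", nr0); nc0 <- ov("nc0", nc0)
    pi_r <- build_membership(nr, nr0, K, rep(1 / K, K))
    pi_c <- build_membership(nc, nc0, K, rep(1 / K, K))
    theta_fun <- ov("theta_fun", setup_theta)
    didcmm_params(K, P, pi_r, pi_c, theta_fun(nr))
  }

  phase_family <- function(n, K, n0_row, n0_col, alpha_in, alpha_out) {
    n <- ov("n", n)
    alpha_in <- ov("alpha_in", alpha_in); alpha_out <- ov("alpha_out", alpha_out)
    pi_r <- build_membership(n, ov("n0_row", n0_row), K, rep(1 / K, K))
    pi_c <- build_membership(n, ov("n0_col", n0_col), K, rep(1 / K, K))
    make_planted_partition(n, K, pi_r, pi_c, alpha_in, alpha_out)
  }

  sb <- .experiment_base$small2; lg <- .experiment_base$large3
  switch(name,
    # Pure-node fraction family (default grid value n0 = 80 / 200-node side).
    experiment1a = exp_family(sb, .P1, n0 = 80, z = 5, rho = 1),
    experiment1b = exp_family(sb, .P2, n0 = 80, z = 5, rho = 1),
    experiment1c = exp_family(lg, .P3, n0 = 150, z = 5, rho = 1),
    experiment1d = exp_family(lg, .P4, n0 = 150, z = 5, rho = 1),
    # Degree-heterogeneity family (grid parameter z).
    experiment2a = exp_family(sb, .P1, n0 = 80, z = 5, rho = 1),
    experiment2b = exp_family(sb, .P2, n0 = 80, z = 5, rho = 1),
    experiment2c = exp_family(lg, .P3, n0 = 150, z = 5, rho = 1),
    experiment2d = exp_family(lg, .P4, n0 = 150, z = 5, rho = 1),
    experiment2e = exp_family(sb, .P1, n0 = 0, z = 5, rho = 1, .mixed2, .mixed2),
    experiment2f = exp_family(sb, .P2, n0 = 0, z = 5, rho = 1, .mixed2, .mixed2),
    experiment2g = exp_family(lg, .P3, n0 = 0, z = 5, rho = 1, .mixed3, .mixed3),
    experiment2h = exp_family(lg, .P4, n0 = 0, z = 5, rho = 1, .mixed3, .mixed3),
    # Connectivity family (grid parameter beta; off-diagonals beta - 1).
    experiment3a = exp_family(sb, beta_P(ov("beta", 1), c(1, 1)), 80, 5, 1),
    experiment3b = exp_family(sb, beta_P(ov("beta", 1), c(0.8, 0.9)), 80, 5, 1),
    experiment3c = exp_family(lg, beta_P(ov("beta", 1), c(1, 1, 1)), 150, 5, 1),
    experiment3d = exp_family(lg, beta_P(ov("beta", 1), c(0.8, 0.9, 1)), 150, 5, 1),
    experiment3e = exp_family(sb, beta_P(ov("beta", 1), c(1, 1)), 0, 5, 1, .mixed2, .mixed2),
    experiment3f = exp_family(sb, beta_P(ov("beta", 1), c(0.8, 0.9)), 0, 5, 1, .mixed2, .mixed2),
    experiment3g = exp_family(lg, beta_P(ov("beta", 1), c(1, 1, 1)), 0, 5, 1, .mixed3, .mixed3),
    experiment3h = exp_family(lg, beta_P(ov("beta", 1), c(0.8, 0.9, 1)), 0, 5, 1, .mixed3, .mixed3),
    # Sparsity family (grid parameter rho).
    experiment4a = exp_family(sb, .P1, n0 = 80, z = 5, rho = ov("rho", 1)),
    experiment4b = exp_family(sb, .P2, n0 = 80, z = 5, rho = ov("rho", 1)),
    experiment4c = exp_family(lg, .P3, n0 = 150, z = 5, rho = ov("rho", 1)),
    experiment4d = exp_family(lg, .P4, n0 = 150, z = 5, rho = ov("rho", 1)),
    # Phase-transition family.
    experiment5a = phase_family(300, 2, 100, 120, 25, 25),
    experiment5b = phase_family(300, 3, 60, 80, 25, 25),
    # Growing-network planted partition, far inside the recoverable region.
    experiment6 = {
      n <- ov("n", 1000)
      pi <- build_membership(n, n %/% 2, 2, c(0.5, 0.5))
      make_planted_partition(n, 2, pi, pi,
                             ov("alpha_in", 2), ov("alpha_out", 0.0001))
    },
    # Small illustrative directed / bipartite networks.
    setup1 = setup_family(16, 6, 16, 7, .Pa, 2),
    setup2 = setup_family(16, 6, 16, 7, .Pb, 2),
    setup3 = setup_family(32, 14, 28, 12, .Pa, 2),
    setup4 = setup_family(32, 14, 28, 12, .Pb, 2),
    setup5 = setup_family(100, 48, 100, 45, .Pc_unscaled * log(100) / 100, 2),
    setup6 = setup_family(100, 48, 100, 45, .Pd_unscaled * log(100) / 100, 2),
    setup7 = setup_family(100, 30, 100, 32, .Pe_unscaled * log(100) / 100, 3),
    setup8 = setup_family(100, 30, 100, 32, .Pf_unscaled * log(100) / 100, 3),
    stop(sprintf("UnknownScenario: '%s'", name), call. = FALSE)
  )
}

#' List registered scenario names
#' @return character vector.
#' @export
scenario_names <- function() {
  c(paste0("experiment1", letters[1:4]),
    paste0("experiment2", letters[1:8]),
    paste0("experiment3", letters[1:8]),
    paste0("experiment4", letters[1:4]),
    "experiment5a", "experiment5b", "experiment6",
    paste0("setup", 1:8))
}
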
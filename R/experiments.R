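# Deterministic per-replicate seed derivation: a fixed mixing of the base
# seed, the grid-point index and the replicate index, kept below 2^31.
derive_seed <- function(base, i, j = 0L) {
  as.integer((as.double(base) * 7919 + as.double(i) * 104729 +
                as.double(j) * 1299709) %% 2147483629) + 1L
}

# One Monte-Carlo replicate: sample, prune, subset the truth, fit, score.
.one_replicate <- function(params, K, seed) {
  omega <- population_matrix(params)
  smp <- sample_adjacency(omega, seed = seed, prune = TRUE)
  if (length(smp$kept_rows) < K || length(smp$kept_cols) < K) {
    stop("sample too sparse after pruning", call. = FALSE)
  }
  pi_r <- params$pi_r[smp$kept_rows, , drop = FALSE]
  pi_c <- params$pi_c[smp$kept_cols, , drop = FALSE]
  t0 <- proc.time()[["elapsed"]]
  fit <- dimsc(smp$A, K, seed = seed)
  elapsed <- proc.time()[["elapsed"]] - t0
  list(mhamm = mhamm(fit$pi_r, pi_r, fit$pi_c, pi_c), runtime = elapsed)
}

#' Run a Monte-Carlo experiment over a parameter grid
#'
#' For each grid point: build the scenario parameters (once, including any
#' random degree draws), then repeatedly sample an adjacency matrix, prune
#' zero-degree nodes (subsetting the ground truth identically), fit DiMSC and
#' record the mixed Hamming error.  Replicate seeds are deterministic
#' functions of (base seed, grid point, replicate), so a run is exactly
#' reproducible.  Failed replicates (e.g. a rank-collapsed sample) are
#' excluded and counted.
#'
#' @param scenario registered scenario name, see [make_scenario()].
#' @param grid named list with at most one entry: the grid parameter and its
#'   values (e.g. `list(n0 = c(10, 50, 100))`).  `NULL` runs the scenario at
#'   its registered defaults.
#' @param replicates Monte-Carlo replicates per grid point.
#' @param seed base seed.
#' @param overrides extra fixed overrides passed to [make_scenario()].
#' @return a tibble with one row per grid point: the grid value, mean and sd
#'   of the mixed Hamming error, mean fit runtime (seconds, informational),
#'   and the number of failed replicates.
#' @export
run_monte_carlo <- function(scenario, grid = NULL, replicates = 50L, seed = 1L,
                            overrides = list()) {
  stopifnot(replicates >= 1)
  if (is.null(grid)) grid <- list(.default = NA)
  stopifnot(length(grid) == 1L)
  par_name <- names(grid)
  values <- grid[[1L]]

  purrr::map_dfr(seq_along(values), function(gi) {
    ov <- overrides
    if (par_name != ".default") ov[[par_name]] <- values[[gi]]
    params <- make_scenario(scenario, overrides = ov,
                            seed = derive_seed(seed, gi))
    res <- purrr::map(seq_len(replicates), function(r) {
      tryCatch(.one_replicate(params, params$K, derive_seed(seed, gi, r)),
               error = function(e) NULL)
    })
    ok <- !vapply(res, is.null, TRUE)
    errs <- vapply(res[ok], `[[`, 0, "mhamm")
    times <- vapply(res[ok], `[[`, 0, "runtime")
    tibble::tibble(
      scenario = scenario,
      parameter = if (par_name == ".default") NA_character_ else par_name,
      value = if (par_name == ".default") NA_real_ else as.numeric(values[[gi]]),
      mean_mhamm = mean(errs),
      sd_mhamm = stats::sd(errs),
      mean_runtime = mean(times),
      replicates = sum(ok),
      failed = sum(!ok)
    )
  })
}

#' Phase-transition grid over planted-partition signal levels
#'
#' Mean mixed Hamming error of DiMSC on planted-partition networks over a
#' grid of within/across signal levels `(alpha_in, alpha_out)`.  Each cell
#' also reports the recoverability statistic
#' `|alpha_in - alpha_out| / max(alpha_in, alpha_out)`; estimation succeeds
#' where that statistic is well above zero and fails near the diagonal.
#' Cells whose edge probabilities overflow 1 are recorded as missing.
#'
#' @param n nodes per side.
#' @param K communities.
#' @param pure_rows,pure_cols pure nodes per community on each side.
#' @param alpha_grid numeric vector of signal levels (used for both axes).
#' @param replicates Monte-Carlo replicates per cell.
#' @param seed base seed.
#' @return tibble with columns `alpha_in`, `alpha_out`, `statistic`,
#'   `mean_mhamm`, `replicates`, `failed`; class `phase_grid` for plotting.
#' @export
phase_transition_grid <- function(n, K, pure_rows, pure_cols, alpha_grid,
                                  replicates = 25L, seed = 1L) {
  cells <- expand.grid(alpha_in = alpha_grid, alpha_out = alpha_grid)
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    a_in <- cells$alpha_in[ci]; a_out <- cells$alpha_out[ci]
    stat <- abs(a_in - a_out) / max(a_in, a_out)
    params <- tryCatch(
      make_scenario(if (K == 2) "experiment5a" else "experiment5b",
                    overrides = list(n = n, n0_row = pure_rows,
                                     n0_col = pure_cols,
                                     alpha_in = a_in, alpha_out = a_out),
                    seed = derive_seed(seed, ci)),
      error = function(e) NULL
    )
    if (is.null(params)) {
      return(tibble::tibble(alpha_in = a_in, alpha_out = a_out,
                            statistic = stat, mean_mhamm = NA_real_,
                            replicates = 0L, failed = replicates))
    }
    res <- purrr::map(seq_len(replicates), function(r) {
      tryCatch(.one_replicate(params, K, derive_seed(seed, ci, r))$mhamm,
               error = function(e) NULL)
    })
    ok <- !vapply(res, is.null, TRUE)
    tibble::tibble(alpha_in = a_in, alpha_out = a_out, statistic = stat,
                   mean_mhamm = mean(unlist(res[ok])),
                   replicates = sum(ok), failed = sum(!ok))
  })
  class(out) <- c("phase_grid", class(out))
  out
}

#' Heatmap of a phase-transition grid
#'
#' @param object a `phase_grid` tibble from [phase_transition_grid()].
#' @param ... unused.
#' @return a ggplot object (tiles shaded by mean error, the no-recovery
#'   diagonal appearing as the bright band).
#' @export
autoplot.phase_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$alpha_in, y = .data$alpha_out,
                               fill = .data$mean_mhamm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "mean MHamm") +
    ggplot2::labs(x = expression(alpha["in"]), y = expression(alpha["out"])) +
    ggplot2::theme_minimal()
}

#' Iterative degree/connectivity core of a real directed network
#'
#' Restricts a square adjacency matrix to its largest subgraph in which every
#' node has in-degree and out-degree at least `m` and the underlying
#' undirected graph is connected: iteratively removes under-degree nodes,
#' restricts to the largest weakly connected component, and repeats until
#' both conditions hold.  This is the standard pre-processing for real
#' directed networks, which carry many zero-in- or zero-out-degree nodes.
#'
#' @param A square binary adjacency matrix.
#' @param m minimum in- and out-degree (`m = 0` keeps only the connectivity
#'   restriction).
#' @return list of class `pruned_network` with `A_m`, `m`, `kept_nodes`
#'   (indices into the original matrix).
#' @export
prune_to_m_core <- function(A, m) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), m >= 0)
  keep <- seq_len(nrow(A))
  repeat {
    if (!length(keep)) stop("EmptyCore: no nodes satisfy the degree/connectivity constraints",
                            call. = FALSE)
    B <- A[keep, keep, drop = FALSE]
    deg_ok <- rowSums(B) >= m & colSums(B) >= m
    if (!all(deg_ok)) {
      keep <- keep[deg_ok]
      next
    }
    g <- igraph::graph_from_adjacency_matrix(B, mode = "directed")
    comp <- igraph::components(g, mode = "weak")
    if (comp$no > 1L) {
      big <- which.max(comp$csize)
      keep <- keep[comp$membership == big]
      next
    }
    break
  }
  structure(list(A_m = A[keep, keep, drop = FALSE], m = m, kept_nodes = keep),
            class = "pruned_network")
}
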
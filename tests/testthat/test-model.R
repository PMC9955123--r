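test_that("identifiability report flags rank, diagonal and pure-node conditions", {
  pi2 <- build_membership(6, 3, 2)
  p_id <- didcmm_params(2, diag(2), pi2, pi2, rep(0.5, 6))
  rep_id <- validate_identifiability(p_id)
  expect_true(rep_id$identifiable)

  P2 <- matrix(c(0.8, 0.1, 0.2, 0.9), 2, 2, byrow = TRUE)
  rep_p2 <- validate_identifiability(didcmm_params(2, P2, pi2, pi2, rep(0.5, 6)))
  expect_false(rep_p2$unit_diagonal)
  expect_true(rep_p2$rank_full)

  # no pure node in row community 1
  pi_nopure <- rbind(matrix(c(0.6, 0.4), 3, 2, byrow = TRUE),
                     matrix(c(0, 1), 3, 2, byrow = TRUE))
  rep_np <- validate_identifiability(didcmm_params(2, diag(2), pi_nopure, pi2, rep(0.5, 6)))
  expect_false(rep_np$pure_rows)
  expect_identical(rep_np$violating_row_communities[[1]], 1L)
  # report never mutates
  expect_equal(pi_nopure[1, ], c(0.6, 0.4))
})

test_that("population matrix equals theta-weighted bilinear form and has rank K", {
  # rank-1 constant case
  p1 <- didcmm_params(1, matrix(1, 1, 1), matrix(1, 5, 1), matrix(1, 4, 1),
                      rep(0.3, 5))
  expect_equal(population_matrix(p1), matrix(0.3, 5, 4))

  # direct evaluation on pure nodes
  P <- matrix(c(1, 0.1, 0.2, 1), 2, 2, byrow = TRUE)
  p2 <- didcmm_params(2, P, diag(2), diag(2), c(0.5, 1))
  expect_equal(population_matrix(p2),
               matrix(c(0.5, 0.05, 0.2, 1.0), 2, 2, byrow = TRUE))

  # numerical rank K on a seeded random instance
  params <- random_valid_params(31, K = 3)
  omega <- population_matrix(params)
  d <- svd(omega, nu = 0, nv = 0)$d
  expect_identical(sum(d > 1e-8 * d[1]), 3L)
  expect_equal(omega, sweep(params$pi_r %*% params$P %*% t(params$pi_c),
                            1, params$theta_r, `*`))
})

test_that("overscaled parameters are rejected rather than clipped", {
  pi2 <- build_membership(4, 2, 2)
  expect_error(didcmm_params(2, 2 * diag(2), pi2, pi2, rep(0.9, 4)),
               "OutOfRangeProbability")
})

test_that("adjacency sampling is Bernoulli with the population mean and prunes exactly", {
  expect_equal(sample_adjacency(matrix(0, 3, 3), seed = 1)$A, matrix(0, 3, 3))
  smp0 <- sample_adjacency(matrix(0, 3, 3), seed = 1, prune = TRUE)
  expect_identical(smp0$kept_rows, integer(0))
  smp1 <- sample_adjacency(matrix(1, 3, 3), seed = 1, prune = TRUE)
  expect_equal(smp1$A, matrix(1, 3, 3))
  expect_identical(smp1$kept_rows, 1:3)

  # empirical mean within 3 binomial standard errors, entrywise
  omega <- matrix(c(0.5, 0.05, 0.2, 1.0), 2, 2, byrow = TRUE)
  B <- 4000
  acc <- matrix(0, 2, 2)
  for (b in seq_len(B)) acc <- acc + sample_adjacency(omega, seed = b)$A
  se <- sqrt(omega * (1 - omega) / B)
  expect_true(all(abs(acc / B - omega) <= 3 * se + 1e-12))

  # pruning removes exactly the zero-degree rows/columns
  om <- matrix(0.6, 6, 6)
  om[2, ] <- 0; om[, 5] <- 0
  smp <- sample_adjacency(om, seed = 7, prune = TRUE)
  expect_false(2 %in% smp$kept_rows)
  expect_false(5 %in% smp$kept_cols)
  expect_true(all(rowSums(smp$A) > 0) && all(colSums(smp$A) > 0))
})

test_that("planted partition encodes pin/pout and rejects overflow", {
  n <- 300
  pi <- build_membership(n, 100, 2)
  pp <- make_planted_partition(n, 2, pi, pi, 50, 2.5)
  expect_equal(diag(pp$P), rep(50 * log(n) / n, 2))
  expect_equal(pp$P[1, 2], 2.5 * log(n) / n)
  expect_equal(abs(50 - 2.5) / max(50, 2.5), 0.95)
  # no-signal limit: constant population matrix
  pp0 <- make_planted_partition(n, 2, pi, pi, 10, 10)
  expect_lt(diff(range(population_matrix(pp0))), 1e-12)
  expect_error(make_planted_partition(20, 2, build_membership(20, 10, 2),
                                      build_membership(20, 10, 2), 50, 2.5),
               "ProbabilityOverflow")
})

test_that("scenario registry reproduces the printed configurations", {
  p1 <- make_scenario("experiment1a", seed = 3)
  expect_identical(c(p1$nr, p1$nc, p1$K), c(200L, 300L, 2L))
  expect_equal(p1$P, matrix(c(1, 0.1, 0.2, 1), 2, 2, byrow = TRUE))
  expect_true(all(1 / p1$theta_r >= 1 & 1 / p1$theta_r <= 5))

  s1 <- make_scenario("setup1")
  expect_identical(c(s1$nr, s1$nc), c(16L, 16L))
  expect_equal(s1$P, matrix(c(0.9, 0.05, 0.1, 0.95), 2, 2, byrow = TRUE))
  expect_identical(sum(pure_nodes(s1$pi_r)$is_pure), 12L)
  expect_identical(sum(pure_nodes(s1$pi_c)$is_pure), 14L)
  expect_equal(s1$theta_r, 0.9 + (1:16)^2 / (9 * 16^2))

  e5 <- make_scenario("experiment5a")
  expect_identical(c(e5$nr, e5$nc, e5$K), c(300L, 300L, 2L))
  expect_identical(sum(pure_nodes(e5$pi_r)$is_pure), 200L)
  expect_identical(sum(pure_nodes(e5$pi_c)$is_pure), 240L)
  expect_equal(unique(e5$pi_r[!pure_nodes(e5$pi_r)$is_pure, 1]), 0.5)

  # connectivity family rescales theta when P has entries above 1
  e3 <- make_scenario("experiment3a", overrides = list(beta = 4), seed = 2)
  expect_lte(max(population_matrix(e3)), 1)

  expect_error(make_scenario("not-a-scenario"), "UnknownScenario")
})

test_that("oracle reconstruction certifies identifiability on random instances", {
  # two parameter sets sharing the same population matrix must be identical:
  # exercised constructively by recovering the generator's parameters
  params <- random_valid_params(7, K = 3)
  fit <- ideal_dimsc(population_matrix(params), 3, seed = 7)
  pr <- mixed_hamming(fit$pi_r, params$pi_r)$perm
  pc <- mixed_hamming(fit$pi_c, params$pi_c)$perm
  Pm <- dimsc:::.perm_matrix(pr); Pcm <- dimsc:::.perm_matrix(pc)
  expect_lt(max(abs(align_to(fit$pi_r, params$pi_r) - params$pi_r)), 1e-8)
  expect_lt(max(abs(align_to(fit$pi_c, params$pi_c) - params$pi_c)), 1e-8)
  expect_lt(max(abs(t(Pm) %*% fit$P %*% Pcm - params$P)), 1e-8)
  expect_lt(max(abs(fit$theta_r - params$theta_r)), 1e-8)
})
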
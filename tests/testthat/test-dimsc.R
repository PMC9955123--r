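test_that("oracle recovery is exact on valid parameter draws", {
  for (s in 101:106) {
    params <- random_valid_params(s)
    K <- params$K
    omega <- population_matrix(params)
    fit <- ideal_dimsc(omega, K, seed = s)
    expect_lt(mhamm(fit$pi_r, params$pi_r, fit$pi_c, params$pi_c), 1e-8)
    expect_lt(max(abs(fit$theta_r - params$theta_r)), 1e-8)
    # corner-block identity for the degree vector
    expect_lt(max(abs(fit$theta_r_corner -
                        params$theta_r[fit$corners_row$indices])), 1e-8)
  }
})

test_that("single-community fits return all-ones memberships", {
  p1 <- didcmm_params(1, matrix(1, 1, 1), matrix(1, 8, 1), matrix(1, 6, 1),
                      rep(0.4, 8))
  fit <- ideal_dimsc(population_matrix(p1), 1)
  expect_equal(fit$pi_r, matrix(1, 8, 1))
  expect_equal(fit$pi_c, matrix(1, 6, 1))
})

test_that("matrix-inverse identities hold pre-clip", {
  params <- random_valid_params(55, K = 3)
  omega <- population_matrix(params)
  smp <- sample_adjacency(omega, seed = 3, prune = TRUE)
  fit <- dimsc(smp$A, 3, seed = 3)
  dec <- fit$svd
  Ur <- dec$U_star[fit$corners_row$indices, ]
  Vc <- dec$V[fit$corners_col$indices, ]
  Y_star <- dec$U %*% dimsc:::pinv_guarded(Ur)
  expect_lt(max(abs(Y_star %*% Ur - dec$U)), 1e-8)
  Zc <- dec$V %*% dimsc:::pinv_guarded(Vc)
  expect_lt(max(abs(Zc %*% Vc - dec$V)), 1e-8)
})

test_that("a noiseless block observable is recovered exactly", {
  # population matrix with entries in {0,1}: the sample equals it a.s.
  pi_r <- build_membership(12, 6, 2)
  pi_c <- build_membership(10, 5, 2)
  P <- diag(2)
  params <- didcmm_params(2, P, pi_r, pi_c, rep(1, 12))
  A <- population_matrix(params)
  expect_true(all(A %in% c(0, 1)))
  fit <- dimsc(A, 2, seed = 1)
  expect_lt(mhamm(fit$pi_r, pi_r, fit$pi_c, pi_c), 1e-8)
})

test_that("column-side recovery is invariant to rescaling the degree vector", {
  params <- random_valid_params(77, K = 2)
  omega <- population_matrix(params)
  fit1 <- ideal_dimsc(omega, 2, seed = 5)
  fit2 <- ideal_dimsc(0.5 * omega, 2, seed = 5)  # theta -> theta/2
  expect_lt(max(abs(align_to(fit2$pi_c, fit1$pi_c) - fit1$pi_c)), 1e-10)
  expect_lt(max(abs(align_to(fit2$pi_r, fit1$pi_r) - fit1$pi_r)), 1e-10)
})

test_that("fits reject unpruned input and expose clipping diagnostics", {
  A <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_error(dimsc(A, 1), "all-zero")
  params <- make_scenario("setup3")
  smp <- sample_adjacency(population_matrix(params), seed = 8, prune = TRUE)
  fit <- dimsc(smp$A, 2, seed = 8)
  expect_gte(fit$clipped_row, 0)
  expect_true(all(abs(rowSums(fit$pi_r) - 1) < 1e-12))
  expect_true(all(fit$pi_r >= 0))
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_identical(g$K, 2L)
})

test_that("estimation error shrinks with the planted-partition signal", {
  # paired seeds: strong-signal cells beat the no-signal diagonal
  params_hi <- make_scenario("experiment5a",
                             overrides = list(alpha_in = 50, alpha_out = 2.5))
  params_no <- make_scenario("experiment5a",
                             overrides = list(alpha_in = 25, alpha_out = 25))
  err <- function(params, s) {
    smp <- sample_adjacency(population_matrix(params), seed = s, prune = TRUE)
    fit <- dimsc(smp$A, 2, seed = s)
    mhamm(fit$pi_r, params$pi_r[smp$kept_rows, ], fit$pi_c,
          params$pi_c[smp$kept_cols, ])
  }
  e_hi <- vapply(1:5, function(s) err(params_hi, s), 0)
  e_no <- vapply(1:5, function(s) err(params_no, s), 0)
  expect_true(all(e_hi < e_no))
})
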
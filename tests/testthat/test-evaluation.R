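test_that("mixed Hamming error is permutation-minimized entrywise L1 per node", {
  pi <- diag(2)
  expect_equal(mixed_hamming(pi, pi)$error, 0)
  expect_identical(mixed_hamming(pi, pi)$perm, 1:2)
  expect_equal(mixed_hamming(pi[, 2:1], pi)$error, 0)
  expect_identical(mixed_hamming(pi[, 2:1], pi)$perm, c(2L, 1L))
  # frozen brute-force value: identity cost 0.2/2, swap cost 3.8/2
  ph <- rbind(c(0.9, 0.1), c(0, 1))
  expect_equal(mixed_hamming(ph, diag(2))$error, 0.1)
  expect_error(mixed_hamming(diag(2), diag(3)), "ShapeMismatch")
  # pseudo-metric symmetry and joint-permutation invariance
  params <- random_valid_params(41, K = 3)
  set.seed(1)
  noise <- matrix(rexp(nrow(params$pi_r) * 3), ncol = 3)
  ph2 <- 0.8 * params$pi_r + 0.2 * noise / rowSums(noise)
  expect_equal(mixed_hamming(ph2, params$pi_r)$error,
               mixed_hamming(params$pi_r, ph2)$error)
  prm <- c(3, 1, 2)
  expect_equal(mixed_hamming(ph2[, prm], params$pi_r[, prm])$error,
               mixed_hamming(ph2, params$pi_r)$error)
})

test_that("two-sided error is the max of the per-side minima", {
  pi <- build_membership(10, 5, 2)
  expect_equal(mhamm(pi, pi, pi, pi), 0)
  ph_r <- pi; ph_r[1, ] <- c(0.9, 0.1)  # row side error 0.2/10
  ph_c <- pi; ph_c[1, ] <- c(0.95, 0.05)
  expect_equal(mhamm(ph_r, pi, ph_c, pi), 0.02)
})

test_that("brute-force and Hungarian alignment agree on random instances", {
  set.seed(99)
  for (r in 1:100) {
    K <- sample(2:6, 1)
    n <- sample(5:30, 1)
    g1 <- matrix(rexp(n * K), n); p1 <- g1 / rowSums(g1)
    g2 <- matrix(rexp(n * K), n); p2 <- g2 / rowSums(g2)
    eb <- mixed_hamming(p1, p2, method = "brute")$error
    eh <- mixed_hamming(p1, p2, method = "hungarian")$error
    expect_equal(eb, eh, tolerance = 1e-12)
  }
})

test_that("worst per-node error uses the global alignment", {
  pi <- build_membership(10, 5, 2)
  expect_equal(per_node_max_error(pi, pi)$error, 0)
  ph <- pi; ph[3, ] <- ph[3, ] + c(-0.1, 0.1)
  expect_equal(per_node_max_error(ph, pi)$error, 0.2)
})

test_that("node membership entropy matches its closed-form corner cases", {
  pi <- rbind(c(1, 0, 0), c(0.5, 0.5, 0), c(1 / 3, 1 / 3, 1 / 3))
  nme <- node_membership_entropy(pi)
  expect_equal(nme, c(0, log(2), log(3)))
  # bounds on random memberships
  set.seed(12)
  g <- matrix(rexp(40), ncol = 4); p <- g / rowSums(g)
  v <- node_membership_entropy(p)
  expect_true(all(v >= 0 & v <= log(4) + 1e-12))
})

test_that("highly-mixed flags use the inclusive threshold", {
  expect_equal(highly_mixed_fraction(diag(2))$tau, 0)
  hm <- highly_mixed_fraction(rbind(c(0.8, 0.2), c(0.9, 0.1)))
  expect_identical(hm$flags, c(TRUE, FALSE))  # 0.8 >= max holds with equality
  expect_equal(highly_mixed_fraction(rbind(c(1, 0), c(0.5, 0.5)))$tau, 0.5)
})

test_that("hard labels take the argmax with smallest-index ties", {
  expect_identical(hard_labels(rbind(c(0.9, 0.1), c(0.5, 0.5))), c(1L, 1L))
  expect_identical(hard_labels(matrix(c(0, 0, 1), 1, 3)), 3L)
})

test_that("row/column asymmetry is the aligned L1 distance between sides", {
  pi <- build_membership(8, 4, 2)
  expect_equal(row_col_asymmetry(pi, pi), 0)
  expect_equal(row_col_asymmetry(pi, pi[, 2:1]), 0)
  expect_equal(row_col_asymmetry(diag(2), rbind(c(0.5, 0.5), c(0, 1))), 0.5)
  expect_error(row_col_asymmetry(diag(2), build_membership(3, 1, 2)),
               "ShapeMismatch")
})

test_that("recovery reports aggregate the metrics coherently", {
  params <- random_valid_params(61, K = 2, nr = 80, nc = 80)
  fit <- ideal_dimsc(population_matrix(params), 2, seed = 6)
  rp <- recovery_report(fit, params$pi_r, params$pi_c)
  expect_equal(rp$mhamm, max(rp$mhamm_row, rp$mhamm_col))
  expect_lt(rp$mhamm, 1e-8)
  expect_lt(rp$f_r_max, 1e-8)
  expect_false(is.na(rp$hamm_rc))
})
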
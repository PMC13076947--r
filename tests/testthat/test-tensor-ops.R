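test_that("mode-n products match the scalar triple-loop definition", {
  set.seed(100)
  for (case in 1:50) {
    dims <- sample(2:4, 3, replace = TRUE)
    dims[3] <- min(dims[3], 3)
    tens <- array(stats::rnorm(prod(dims)), dim = dims)
    mode <- sample(1:3, 1)
    mat <- matrix(stats::rnorm(3 * dims[mode]), 3, dims[mode])
    expect_lt(max(abs(mode_n_product(tens, mat, mode) -
                        mode_n_oracle(tens, mat, mode))), 1e-10)
  }
})

test_that("identity and zero matrices act as identity and annihilator", {
  set.seed(5)
  tens <- array(stats::rnorm(3 * 4 * 2), dim = c(3, 4, 2))
  expect_equal(mode_n_product(tens, diag(4), 2), tens)
  expect_true(all(mode_n_product(tens, matrix(0, 5, 3), 1) == 0))
  expect_error(mode_n_product(tens, matrix(0, 5, 7), 1), "mismatch")
})

test_that("mode products along distinct modes commute", {
  set.seed(6)
  for (case in 1:5) {
    tens <- array(stats::rnorm(24), dim = c(3, 4, 2))
    a <- matrix(stats::rnorm(6), 2, 3)
    b <- matrix(stats::rnorm(20), 5, 4)
    lhs <- mode_n_product(mode_n_product(tens, a, 1), b, 2)
    rhs <- mode_n_product(mode_n_product(tens, b, 2), a, 1)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }
})

test_that("unfold/fold are mutually inverse in every mode", {
  set.seed(8)
  tens <- array(stats::rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  for (m in 1:3) {
    expect_equal(fold_tensor(unfold_tensor(tens, m), m, dim(tens)), tens)
  }
  # fixed layout: A(i, j, k) -> row i, column j + n (k - 1)
  u <- unfold_tensor(tens, 1)
  expect_equal(u[2, 3 + 4 * 1], tens[2, 3, 2])
})

test_that("full-rank decomposition reconstructs exactly", {
  set.seed(10)
  tens <- array(stats::rnorm(6 * 6 * 3), dim = c(6, 6, 3))
  tf <- tucker_decompose(tens, c(6, 6, 3))
  rel <- sqrt(sum((tucker_reconstruct(tf) - tens)^2) / sum(tens^2))
  expect_lt(rel, 1e-8)
  for (f in tf$factors) {
    expect_lt(max(abs(crossprod(f) - diag(ncol(f)))), 1e-10)
  }
})

test_that("a rank-1 outer product is recovered exactly at rank (1,1,1)", {
  set.seed(11)
  a <- stats::rnorm(5); b <- stats::rnorm(5); c <- stats::rnorm(3)
  tens <- outer(outer(a, b), c)
  tf <- tucker_decompose(tens, c(1, 1, 1))
  expect_lt(sqrt(sum((tucker_reconstruct(tf) - tens)^2) / sum(tens^2)), 1e-10)
  expect_lt(subspace_angle(tf$factors$U, matrix(a)), 1e-6)
})

test_that("reconstruction error is non-increasing in each rank", {
  set.seed(12)
  tens <- array(stats::rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  err <- function(ranks) {
    sqrt(sum((tucker_reconstruct(tucker_decompose(tens, ranks)) - tens)^2))
  }
  errs_r1 <- vapply(2:8, function(r) err(c(r, 4, 2)), numeric(1))
  expect_true(all(diff(errs_r1) <= 1e-10))
  errs_r3 <- vapply(1:3, function(r) err(c(4, 4, r)), numeric(1))
  expect_true(all(diff(errs_r3) <= 1e-10))
})

test_that("rank validation and non-finite rejection work", {
  tens <- array(1, dim = c(3, 3, 3))
  expect_error(tucker_decompose(tens, c(4, 3, 3)), "exceed")
  tens[1] <- NA
  expect_error(tucker_decompose(tens, c(2, 2, 2)), "non-finite")
  expect_error(global_features(array(0, c(3, 3, 3)), 4), "R1")
})

test_that("decomposition is deterministic, bitwise", {
  set.seed(13)
  tens <- array(stats::rnorm(7 * 7 * 3), dim = c(7, 7, 3))
  a <- tucker_decompose(tens, c(3, 3, 2))
  b <- tucker_decompose(tens, c(3, 3, 2))
  expect_identical(a, b)
})

test_that("global features match a dense SVD oracle of the mode-1 unfolding", {
  set.seed(14)
  tens <- array(stats::rnorm(10 * 10 * 3), dim = c(10, 10, 3))
  u <- global_features(tens, 3)
  u_oracle <- svd(unfold_tensor(tens, 1))$u[, 1:3]
  # projector agreement (well-posed where the tiny angle itself is not)
  expect_lt(max(abs(tcrossprod(u) - tcrossprod(u_oracle))), 1e-8)
  expect_lt(max(abs(crossprod(u) - diag(3))), 1e-10)
})

test_that("symmetric slices force equal mode-1 and mode-2 spans", {
  planted <- make_planted_tensor(12, c(3, 3, 2), sigma = 0, seed = 4)
  tf <- tucker_decompose(planted$tensor, c(3, 3, 2))
  expect_lt(subspace_angle(tf$factors$U, tf$factors$V), 1e-6)
})

test_that("the zero tensor yields deterministic canonical features", {
  u <- global_features(array(0, c(5, 5, 3)), 2)
  expect_equal(u, diag(5)[, 1:2])
})

test_that("planted mode-1 subspace is recovered under light noise", {
  planted <- make_planted_tensor(30, c(4, 4, 3), sigma = 0.01, seed = 7)
  u <- global_features(planted$tensor, 4)
  expect_lt(subspace_angle(u, planted$truth$U), 5)
})

test_that("alternating refinement does not degrade the HOSVD fit", {
  set.seed(15)
  tens <- make_planted_tensor(10, c(3, 3, 2), sigma = 0.1, seed = 2)$tensor
  e_hosvd <- sum((tucker_reconstruct(tucker_decompose(tens, c(3, 3, 2))) - tens)^2)
  e_hooi <- sum((tucker_reconstruct(
    tucker_decompose(tens, c(3, 3, 2), method = "hooi")) - tens)^2)
  expect_lte(e_hooi, e_hosvd + 1e-10)
})
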
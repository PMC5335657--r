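test_that("z_normalize centers and scales with sample sd, and is idempotent", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  z <- z_normalize(x)
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(as.numeric(z_normalize(z)), as.numeric(z), tolerance = 1e-12)

  # held-out rows use the stored training statistics
  tr <- matrix(rnorm(40), 10, 4)
  ztr <- z_normalize(tr)
  held <- matrix(attr(ztr, "center"), 1, 4)
  zheld <- z_normalize(held, stats = norm_stats(ztr))
  expect_equal(as.numeric(zheld), rep(0, 4))
})

test_that("z_normalize rejects zero-variance columns by name", {
  x <- cbind(a = rnorm(5), b = rep(2, 5))
  expect_error(z_normalize(x), "zero-variance.*b")
})

test_that("similarity constructors match the pairwise double-loop oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:20, 1)
    m <- sample(2:8, 1)
    M <- matrix(rnorm(n * m), n, m)
    expect_equal(feature_similarity(M), oracle_similarity_cols(M),
                 tolerance = 1e-12)
    expect_equal(subject_similarity(M), oracle_similarity_cols(t(M)),
                 tolerance = 1e-12)
    expect_equal(score_similarity(M), oracle_similarity_cols(M),
                 tolerance = 1e-12)
  }
  # bandwidth override
  M <- matrix(rnorm(12), 4, 3)
  expect_equal(feature_similarity(M, sigma = 2),
               oracle_similarity_cols(M, sigma = 2), tolerance = 1e-12)
})

test_that("similarity closed forms and invariants", {
  # identical columns -> 1; unit-distance columns -> exp(-1)
  x <- cbind(c(1, 0, 0), c(1, 0, 0), c(0, 0, 0))
  s <- feature_similarity(x)
  expect_equal(s[1, 2], 1)
  expect_equal(s[1, 3], exp(-1))
  # rows at squared distance 4 -> exp(-4)
  xs <- rbind(c(0, 0), c(2, 0), c(0, 0))
  ss <- subject_similarity(xs)
  expect_equal(ss[1, 2], exp(-4))
  expect_equal(ss[1, 3], 1)
  # transpose identity
  set.seed(4)
  M <- matrix(rnorm(24), 6, 4)
  expect_equal(subject_similarity(M), feature_similarity(t(M)))
  # C = 1 score graph
  expect_equal(score_similarity(matrix(1:5, ncol = 1)), matrix(1, 1, 1))
  # symmetry, unit diagonal, positivity
  expect_true(isSymmetric(s))
  expect_true(all(diag(feature_similarity(M)) == 1))
  expect_true(all(feature_similarity(M) > 0))
})

test_that("scaling a column up moves its similarities monotonically down", {
  set.seed(9)
  M <- matrix(rnorm(20), 5, 4)
  s1 <- feature_similarity(M)
  M2 <- M
  M2[, 1] <- 3 * M2[, 1]
  s2 <- feature_similarity(M2)
  # column 1 moved away from all others
  expect_true(all(s2[1, -1] <= s1[1, -1] + 1e-12))
})

test_that("graph_laplacian closed form, zero row sums, PSD, quadratic identity", {
  s <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  L <- graph_laplacian(s)
  expect_equal(L, matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))

  set.seed(21)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    sim <- feature_similarity(matrix(rnorm(n * 4), 4, n))
    L <- graph_laplacian(sim)
    expect_equal(max(abs(rowSums(L))), 0, tolerance = 1e-10)
    expect_true(all(L[row(L) != col(L)] <= 0))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9)
    for (k in 1:20) {
      v <- rnorm(n)
      expect_lte(abs(drop(crossprod(v, L %*% v)) -
                       oracle_laplacian_quadform(sim, v)), 1e-10)
    }
  }
  expect_error(graph_laplacian(matrix(c(1, 0.2, 0.8, 1), 2, 2)), "symmetric")
})

test_that("l21_reweight_diag formula and fixed-point identity", {
  w <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 4, 0))
  d <- l21_reweight_diag(w, epsilon = 1e-8)
  expect_equal(diag(d), c(1 / (2e-8), 0.5, 0.1))
  expect_true(all(d[row(d) != col(d)] == 0))
  # at a fixed point, 2 * D_ii * ||w_i|| = 1 for non-degenerate rows
  rn <- sqrt(rowSums(w^2))
  ok <- rn > 1e-8
  expect_equal(unname(2 * diag(d)[ok] * rn[ok]), rep(1, sum(ok)))
  expect_error(l21_reweight_diag(w, epsilon = 0), "positive")
})
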
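test_that("regularizers: smoothness of constants and closed forms", {
  # identical weight rows cost nothing under the feature graph
  sim <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  L <- graph_laplacian(sim)
  W_const <- rbind(c(1, 2), c(1, 2))
  expect_equal(regularizer_feature(W_const, L), 0)
  # two rows differing by a unit vector with f12 = 0.5: half double sum = 0.5
  W <- rbind(c(1, 0), c(0, 0))
  expect_equal(regularizer_feature(W, L), 0.5)
  # zero weights cost nothing on the subject graph
  X <- matrix(rnorm(8), 4, 2)
  Ls <- graph_laplacian(subject_similarity(X))
  expect_equal(regularizer_subject(matrix(0, 2, 2), X, Ls), 0)
  # identical subject rows contribute zero whatever the weights
  X2 <- rbind(c(1, 2), c(1, 2))
  L2 <- graph_laplacian(subject_similarity(X2))
  expect_equal(regularizer_subject(matrix(rnorm(4), 2, 2), X2, L2), 0,
               tolerance = 1e-12)
  # single score column, and identical weight columns
  expect_equal(regularizer_score(matrix(1:3, 3, 1), matrix(0, 1, 1)), 0)
  Lc <- graph_laplacian(matrix(c(1, 0.3, 0.3, 1), 2, 2))
  expect_equal(regularizer_score(cbind(1:3, 1:3), Lc), 0, tolerance = 1e-12)
})

test_that("trace forms equal half the explicit pairwise double sums", {
  set.seed(41)
  for (rep in 1:10) {
    S <- sample(4:8, 1); F_ <- sample(3:7, 1); C <- sample(2:4, 1)
    X <- matrix(rnorm(S * F_), S, F_)
    W <- matrix(rnorm(F_ * C), F_, C)
    sf <- feature_similarity(X)
    ss <- subject_similarity(X)
    Yt <- X %*% W + matrix(rnorm(S * C), S, C)
    sc <- score_similarity(Yt)
    expect_lte(abs(regularizer_feature(W, graph_laplacian(sf)) -
                     oracle_pairwise_half_sum(sf, W)), 1e-10)
    expect_lte(abs(regularizer_subject(W, X, graph_laplacian(ss)) -
                     oracle_pairwise_half_sum(ss, X %*% W)), 1e-10)
    expect_lte(abs(regularizer_score(W, graph_laplacian(sc)) -
                     oracle_pairwise_half_sum(sc, t(W))), 1e-10)
  }
})

test_that("smtl_objective equals the scalar-loop oracle", {
  inst <- random_instance(42)
  graphs <- smtl_graphs(inst$X, inst$Y)
  sim_f <- feature_similarity(inst$X)
  sim_s <- subject_similarity(inst$X)
  sim_c <- lapply(inst$Y, score_similarity)
  for (l in list(c(0, 0), c(0.7, 0), c(0, 1.3), c(0.5, 2))) {
    expect_equal(
      smtl_objective(inst$X, inst$Y, inst$W, l[1], l[2], graphs),
      oracle_objective(inst$X, inst$Y, inst$W, l[1], l[2],
                       sim_f, sim_s, sim_c),
      tolerance = 1e-9)
  }
  # W = 0 gives the total sum of squared scores; lambda = 0 the pure loss
  W0 <- lapply(inst$W, function(w) w * 0)
  expect_equal(smtl_objective(inst$X, inst$Y, W0, 1, 0, graphs),
               sum(vapply(inst$Y, function(Yt) sum(Yt^2), 0)))
  expect_equal(smtl_objective(inst$X, inst$Y, inst$W, 0, 0, graphs),
               sum(vapply(seq_along(inst$Y), function(t)
                 sum((inst$Y[[t]] - inst$X %*% inst$W[[t]])^2), 0)))
})
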
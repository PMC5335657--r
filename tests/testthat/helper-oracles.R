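# Independent brute-force oracles. These deliberately use scalar loops and
# never call the code paths they check.

# element-by-element heat kernel over columns of M
oracle_similarity_cols <- function(M, sigma = NULL) {
  n <- ncol(M)
  s <- matrix(NA_real_, n, n)
  for (u in seq_len(n))
    for (v in seq_len(n)) {
      d2 <- sum((M[, u] - M[, v])^2)
      if (!is.null(sigma)) d2 <- d2 / (2 * sigma^2)
      s[u, v] <- exp(-d2)
    }
  s
}

# quadratic form of the Laplacian via the pairwise identity
oracle_laplacian_quadform <- function(sim, x) {
  n <- nrow(sim)
  tot <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      tot <- tot + sim[i, j] * (x[i] - x[j])^2
  tot / 2
}

# trace-form regularizer as half the explicit pairwise double sum over rows
oracle_pairwise_half_sum <- function(sim, rows) {
  n <- nrow(sim)
  tot <- 0
  for (u in seq_len(n))
    for (v in seq_len(n))
      tot <- tot + sim[u, v] * sum((rows[u, ] - rows[v, ])^2)
  tot / 2
}

# dense Kronecker-vectorized Sylvester solve: vec(AW + WB) = (I(x)A + B'(x)I)vec(W)
oracle_sylvester <- function(A, B, Q) {
  Fn <- nrow(A); Cn <- nrow(B)
  M <- kronecker(diag(Cn), A) + kronecker(t(B), diag(Fn))
  matrix(solve(M, as.vector(Q)), Fn, Cn)
}

# full scalar-loop evaluation of the multi-task objective
oracle_objective <- function(X, Y_list, W_list, lambda1, lambda2,
                             sim_f, sim_s, sim_c_list) {
  loss <- 0
  for (t in seq_along(Y_list)) {
    R <- Y_list[[t]] - X %*% W_list[[t]]
    for (i in seq_len(nrow(R)))
      for (j in seq_len(ncol(R)))
        loss <- loss + R[i, j]^2
  }
  reg <- 0
  for (t in seq_along(Y_list)) {
    Wt <- W_list[[t]]
    reg <- reg + oracle_pairwise_half_sum(sim_f, Wt)
    reg <- reg + oracle_pairwise_half_sum(sim_s, X %*% Wt)
    reg <- reg + oracle_pairwise_half_sum(sim_c_list[[t]], t(Wt))
  }
  what <- do.call(cbind, W_list)
  l21 <- 0
  for (i in seq_len(nrow(what))) l21 <- l21 + sqrt(sum(what[i, ]^2))
  loss + lambda1 * reg + lambda2 * l21
}

# small random problem shared by several tests
random_instance <- function(seed, S = 12, F_ = 6, C = 2, Tn = 3,
                            noise_sd = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(S * F_), S, F_)
  W <- lapply(seq_len(Tn), function(t) matrix(rnorm(F_ * C), F_, C))
  Y <- lapply(W, function(w) X %*% w + matrix(rnorm(S * C, sd = noise_sd), S, C))
  list(X = X, W = W, Y = Y)
}

make_test_cohort <- function(seed = 1, ...) {
  spec <- simulation_spec(...)
  simulate_cohort(spec, seed = seed)
}
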
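# Independent oracles used across the suite. These recompute quantities by a
# different route than the package (dense matrices, brute-force optimization,
# closed forms) and must stay independent of the code paths they check.

# Penalized REML criterion computed with dense n x n covariance matrices:
# V* = I + Z Delta Z' (block-diagonal by cluster), profiled over beta and
# sigma^2. Same criterion definition as the package, different arithmetic
# route (no sufficient statistics, no Woodbury).
dense_reml_criterion <- function(y, X, Z, cluster, Delta, penalty_df = 1.5) {
  n <- length(y)
  p <- ncol(X)
  Vstar <- diag(n)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    Zi <- Z[idx, , drop = FALSE]
    Vstar[idx, idx] <- Vstar[idx, idx] + Zi %*% Delta %*% t(Zi)
  }
  Vinv <- solve(Vstar)
  A <- t(X) %*% Vinv %*% X
  beta <- solve(A, t(X) %*% Vinv %*% y)
  resid <- y - X %*% beta
  r <- drop(t(resid) %*% Vinv %*% resid)
  as.numeric((n - p) * (1 + log(2 * pi * r / (n - p))) +
    determinant(Vstar, logarithm = TRUE)$modulus +
    determinant(A, logarithm = TRUE)$modulus -
    penalty_df * determinant(Delta, logarithm = TRUE)$modulus)
}

dense_delta <- function(par, q) {
  if (q == 1L) return(matrix(exp(2 * par[1]), 1, 1))
  L <- matrix(c(exp(par[1]), par[3], 0, exp(par[2])), 2, 2)
  tcrossprod(L)
}

# Brute-force maximizer of the (penalized) restricted likelihood over the
# dense criterion, from several fixed starts.
dense_reml_fit <- function(y, X, Z, cluster, penalty_df = 1.5) {
  q <- ncol(Z)
  npar <- if (q == 1L) 1L else 3L
  obj <- function(par) {
    dense_reml_criterion(y, X, Z, cluster, dense_delta(par, q), penalty_df)
  }
  starts <- if (q == 1L) list(-2, 0, 1) else {
    list(c(0, 0, 0), c(-1, -1, 0), c(1, 0.5, 0.3))
  }
  best <- NULL
  for (s in starts) {
    o <- if (npar == 1L) {
      stats::optim(s, obj, method = "Brent", lower = -12, upper = 6)
    } else {
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-13))
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  Delta <- dense_delta(best$par, q)
  n <- length(y)
  p <- ncol(X)
  Vstar <- diag(n)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    Zi <- Z[idx, , drop = FALSE]
    Vstar[idx, idx] <- Vstar[idx, idx] + Zi %*% Delta %*% t(Zi)
  }
  Vinv <- solve(Vstar)
  A <- t(X) %*% Vinv %*% X
  beta <- drop(solve(A, t(X) %*% Vinv %*% y))
  resid <- y - X %*% beta
  sigma_sq <- drop(t(resid) %*% Vinv %*% resid) / (n - p)
  list(criterion = best$value, Delta = Delta, beta = beta,
       sigma_sq = sigma_sq, G = sigma_sq * Delta)
}

# Small clustered dataset generator for fitter tests (not the package's
# population generator: plain normals, explicit effects).
toy_clustered <- function(n_per = 8, m = 4, tau0 = 1, tau1 = 0,
                          sigma = 0.7, beta = c(0.5, 1), seed = 1) {
  set.seed(seed)
  cl <- rep(seq_len(m), each = n_per)
  b0 <- rnorm(m, 0, tau0)
  b1 <- if (tau1 > 0) rnorm(m, 0, tau1) else rep(0, m)
  x1 <- rnorm(m * n_per)
  y <- beta[1] + b0[cl] + (beta[2] + b1[cl]) * x1 + rnorm(m * n_per, 0, sigma)
  data.frame(clinic_id = cl, x1 = x1, y = y, quintile = 1L)
}

# Base-combination population cached per test run (generation is cheap but
# several files reuse it).
base_pop <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache) || cache$seed != seed) {
      cache <<- generate_population(sim_params(), seed = seed)
    }
    cache
  }
})
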
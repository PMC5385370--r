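# Independent oracles used across the suite. These deliberately avoid the
# package's dual-system / downdate code paths.

# Primal ridge-form LSSVM oracle: with equality constraints eliminated,
# minimizing 0.5 w'w + 0.5 gamma sum(xi^2) over (w, b) is an unconstrained
# quadratic; solve its normal equations directly.
oracle_lssvm_primal <- function(X, y, gamma) {
  X <- as.matrix(X)
  n <- nrow(X)
  B <- cbind(X, 1)
  C <- diag(y) %*% B
  J <- diag(c(rep(1, ncol(X)), 0))
  theta <- solve(J + gamma * crossprod(C), gamma * crossprod(C, rep(1, n)))
  list(w = theta[seq_len(ncol(X))], b = theta[ncol(X) + 1L])
}

oracle_lssvm_objective <- function(X, y, gamma, w, b) {
  xi <- 1 - y * (drop(as.matrix(X) %*% w) + b)
  0.5 * sum(w^2) + 0.5 * gamma * sum(xi^2)
}

# Brute-force RFE oracle: at each step retrain after removing each candidate
# feature (with the primal oracle solver) and remove the feature whose
# removal changes ||w||^2 least; ties broken by lowest original index.
oracle_rfe_order <- function(X, y, gamma) {
  X <- as.matrix(X)
  surviving <- seq_len(ncol(X))
  order_out <- integer(0)
  while (length(surviving) > 1L) {
    w_full <- oracle_lssvm_primal(X[, surviving, drop = FALSE], y, gamma)$w
    full_norm <- sum(w_full^2)
    delta <- vapply(seq_along(surviving), function(j) {
      wk <- oracle_lssvm_primal(X[, surviving[-j], drop = FALSE], y, gamma)$w
      abs(full_norm - sum(wk^2))
    }, numeric(1))
    drop_j <- order(delta, surviving)[1L]
    order_out <- c(order_out, surviving[drop_j])
    surviving <- surviving[-drop_j]
  }
  c(order_out, surviving)
}

# Exhaustive 2-means oracle: best 2-partition by within-cluster SS over all
# nontrivial assignments (feasible only for tiny point sets).
oracle_two_means <- function(z) {
  z <- as.matrix(z)
  n <- nrow(z)
  best <- NULL
  best_ss <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    c1 <- colMeans(z[grp, , drop = FALSE])
    c2 <- colMeans(z[!grp, , drop = FALSE])
    ss <- sum(sweep(z[grp, , drop = FALSE], 2, c1)^2) +
      sum(sweep(z[!grp, , drop = FALSE], 2, c2)^2)
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- list(c1 = c1, c2 = c2)
    }
  }
  best
}

# Linearly separable two-class Gaussian blobs.
make_separable <- function(n = 20, d = 3, gap = 6, seed = 1) {
  set.seed(seed)
  y <- sample(rep(c(1L, -1L), length.out = n))
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + y * gap / 2
  list(X = X, y = y)
}

# Standardized copy of a synthetic population (the pipeline's per-subject
# z-scoring step applied to both segments).
standardize_population <- function(pop) {
  pop$subjects <- lapply(pop$subjects, function(s) {
    s$V <- standardize_by_subject(s$V)
    s$W <- standardize_by_subject(s$W)
    s
  })
  pop
}
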
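make_V <- function(seed = 7, n = 40, d = 10, sep = 1.2) {
  set.seed(seed)
  y <- rep(c(1L, -1L), n / 2)[sample(n)]
  V <- matrix(rnorm(n * d), n, d)
  V[, 1:3] <- V[, 1:3] + y * sep / 2  # planted overlap, not separable
  list(V = V, y = y)
}

test_that("the candidate grid is 2^-4 .. 2^10 with 15 values", {
  g <- gamma_grid(15)
  expect_equal(g, 2^(-4:10))
  expect_length(g, 15L)
})

test_that("gamma selection tie-breaks toward the smallest candidate on separable data", {
  d <- make_separable(n = 40, d = 5, gap = 8, seed = 2)
  g <- select_gamma(d$X, d$y)
  expect_equal(as.numeric(g), 2^-4)
  expect_true(all(attr(g, "scores") == 1))
})

test_that("gamma selection matches an exhaustive independent grid oracle", {
  dat <- make_V(seed = 7)
  for (rule in c("heldout", "literal")) {
    g <- select_gamma(dat$V, dat$y, rule = rule)
    # oracle: independent primal-solver retrain and score over the grid
    idx_r <- seq(1, nrow(dat$V), by = 2)
    Vr <- dat$V[idx_r, ]; yr <- dat$y[idx_r]
    if (rule == "heldout") {
      Ve <- dat$V[-idx_r, ]; ye <- dat$y[-idx_r]
    } else {
      Ve <- Vr; ye <- yr
    }
    escore <- sapply(gamma_grid(15), function(gg) {
      o <- oracle_lssvm_primal(Vr, yr, gg)
      pred <- ifelse(drop(Ve %*% o$w) + o$b >= 0, 1L, -1L)
      tp <- sum(ye == 1 & pred == 1); fn <- sum(ye == 1 & pred == -1)
      tn <- sum(ye == -1 & pred == -1); fp <- sum(ye == -1 & pred == 1)
      pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
      sen <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (pre + sen == 0) 0 else 2 * pre * sen / (pre + sen)
      ((tp + tn) / length(ye) + f1) / 2
    })
    expect_equal(as.numeric(g), gamma_grid(15)[which.max(escore)])
    expect_equal(unname(attr(g, "scores")), escore, tolerance = 1e-9)
  }
})

test_that("gamma selection rejects degenerate splits", {
  X <- matrix(rnorm(12), 6, 2)
  # alternating labels put one class at every odd position
  expect_error(select_gamma(X, c(1, -1, 1, -1, 1, -1)), "degenerate split")
})

test_that("class centers are componentwise class means", {
  V <- rbind(c(0, 0), c(2, 2), c(10, 10))
  cc <- class_centers(V, c(1, 1, -1))
  expect_equal(unname(cc$v_P), c(1, 1))
  expect_equal(unname(cc$v_N), c(10, 10))
  expect_equal(c(cc$n_P, cc$n_N), c(2L, 1L))
  # single row per class: centers equal those rows
  cc1 <- class_centers(V[2:3, ], c(1, -1))
  expect_equal(unname(cc1$v_P), c(2, 2))
  set.seed(12)
  Vr <- matrix(rnorm(60), 20, 3)
  yr <- rep(c(1L, -1L), 10)
  ccr <- class_centers(Vr, yr)
  expect_equal(unname(ccr$v_P), unname(colMeans(Vr[yr == 1, ])),
               tolerance = 1e-12)
  expect_error(class_centers(Vr, rep(1L, 20)), "both classes")
})

test_that("instance selection keeps strictly-below-mean distances only", {
  cc <- structure(list(v_P = c(0, 0), v_N = c(100, 0)), class = "class_centers")
  O_P <- rbind(c(1, 0), c(2, 0), c(3, 0))  # distances 1, 2, 3; mean 2
  O_N <- rbind(c(99, 0), c(101, 0))
  sel <- select_instances(O_P, O_N, cc)
  expect_equal(sel$P, 1L)  # distance 2 is not < mean 2
  # all equidistant: none kept
  eq <- rbind(c(5, 0), c(-5, 0), c(0, 5))
  expect_length(select_instances(eq, O_N, cc)$P, 0L)
  expect_warning(select_instances(O_P[0, , drop = FALSE], O_N, cc), "empty")
})

test_that("instance selection separates a near from a far subpopulation", {
  set.seed(3)
  n <- 200; d <- 8
  near_frac <- 0.6
  is_near <- c(rep(TRUE, n * near_frac), rep(FALSE, n * (1 - near_frac)))
  O_P <- matrix(rnorm(n * d), n, d) +
    outer(ifelse(is_near, 0, 20), rep(1, d))
  cc <- structure(list(v_P = rep(0, d), v_N = rep(0, d)),
                  class = "class_centers")
  sel <- select_instances(O_P, O_P, cc)
  kept <- sel$P
  expect_equal(length(kept) / n, near_frac, tolerance = 0.1)
  d_all <- sqrt(rowSums(O_P^2))
  expect_lt(max(d_all[kept]), min(d_all[!is_near]))
})

test_that("the adaptive training set concatenates target and selected source rows", {
  set.seed(5)
  V <- matrix(rnorm(40 * 6), 40, 6)
  yV <- rep(c(1L, -1L), 20)
  O <- matrix(rnorm(300 * 6), 300, 6)
  yO <- rep(c(1L, -1L), 150)
  ts <- build_training_set(V, yV, O, yO, gamma_o = 2)
  expect_equal(nrow(ts$X), 340L)
  expect_equal(ts$n_target, 40L)
  expect_equal(ts$gamma_o, 2)
  expect_warning(ts0 <- build_training_set(V, yV, O[0, ], integer(0), 2),
                 "empty source")
  expect_equal(nrow(ts0$X), 40L)
  # a row present in both V and the selection is retained twice
  tsdup <- build_training_set(V, yV, V[1, , drop = FALSE], yV[1], 2)
  expect_equal(nrow(tsdup$X), 41L)
  expect_equal(tsdup$X[41, ], V[1, ])
  expect_error(build_training_set(V, yV, matrix(0, 2, 5), c(1L, -1L), 2),
               "mismatch")
})

test_that("kappa scaling centers to zero sum and unit norm", {
  expect_equal(kappa_scale(c(1, 2, 3)), c(-1, 0, 1) / sqrt(2))
  expect_equal(round(kappa_scale(c(1, 2, 3)), 4), c(-0.7071, 0, 0.7071))
  expect_equal(kappa_scale(c(5, 5, 5)), c(0, 0, 0))
  set.seed(8)
  for (i in 1:5) {
    s <- rnorm(sample(2:50, 1))
    k <- kappa_scale(s)
    expect_equal(sum(k), 0, tolerance = 1e-12)
    expect_equal(sum(k^2), 1, tolerance = 1e-12)
  }
  expect_error(kappa_scale(1), "at least 2")
})

test_that("the domain-distance downdate is the exact Pythagorean identity", {
  cc <- structure(list(v_P = c(3, 4), v_N = c(0, 0)), class = "class_centers")
  O_P <- matrix(0, 2, 2)  # mean 0 -> gap = v_P = (3, 4), full distance 5
  O_N <- matrix(0, 2, 2)  # gap 0: contributes 0 beyond itself
  expect_equal(domain_distance_after_removal(cc, O_P, O_N, 1), 4)
  expect_equal(domain_distance_after_removal(cc, O_P, O_N, 2), 3)
  # a zero-gap feature leaves the full distance unchanged
  cc2 <- structure(list(v_P = c(0, 3, 4), v_N = rep(0, 3)),
                   class = "class_centers")
  expect_equal(domain_distance_after_removal(cc2, matrix(0, 2, 3),
                                             matrix(0, 2, 3), 1), 5)
})

test_that("downdate agrees with explicit recomputation in 50 dimensions", {
  set.seed(13)
  d <- 50
  v_P <- rnorm(d); v_N <- rnorm(d)
  O_P <- matrix(rnorm(30 * d), 30, d)
  O_N <- matrix(rnorm(25 * d), 25, d)
  cc <- structure(list(v_P = v_P, v_N = v_N), class = "class_centers")
  for (k in seq_len(d)) {
    explicit <- sqrt(sum((v_P[-k] - colMeans(O_P)[-k])^2)) +
      sqrt(sum((v_N[-k] - colMeans(O_N)[-k])^2))
    expect_equal(domain_distance_after_removal(cc, O_P, O_N, k), explicit,
                 tolerance = 1e-10)
  }
})

test_that("T-RFE with lambda2 = 0 reduces to classical RFE bit-for-bit", {
  set.seed(21)
  pop <- make_feature_population(population_spec(n_subjects = 4, D = 30,
                                                 n_trials = 24), seed = 21)
  s1 <- pop$subjects[[1]]
  O <- do.call(rbind, lapply(pop$subjects[-1], function(s) s$W))
  yO <- unlist(lapply(pop$subjects[-1], function(s) s$labels))
  init <- trfe_init(s1$V, s1$labels, O, yO)
  r_trfe <- trfe_rank(init$A, init$yA, s1$V, s1$labels, init$O_P, init$O_N,
                      init$gamma_o, lambda1 = 1, lambda2 = 0, q = 7)
  r_rfe <- rfe_rank(init$A, init$yA, init$gamma_o, q = 7)
  expect_identical(r_trfe$elimination_order, r_rfe$elimination_order)
  expect_identical(r_trfe$batches, r_rfe$batches)
})

test_that("T-RFE with lambda1 = 0 eliminates by descending center gap", {
  set.seed(22)
  d <- 20; nV <- 30
  yV <- rep(c(1L, -1L), nV / 2)
  V <- matrix(rnorm(nV * d), nV, d)
  O_P <- matrix(rnorm(40 * d), 40, d) + 0.3
  O_N <- matrix(rnorm(40 * d), 40, d) - 0.3
  A <- rbind(V, O_P, O_N)
  yA <- c(yV, rep(1L, 40), rep(-1L, 40))
  r <- trfe_rank(A, yA, V, yV, O_P, O_N, gamma_o = 1,
                 lambda1 = 0, lambda2 = 1, q = 1)
  # oracle: explicit per-iteration recomputation of d_P(k) + d_N(k),
  # eliminating the arg-min (the largest-gap feature) each time
  gap_P <- colMeans(V[yV == 1, ]) - colMeans(O_P)
  gap_N <- colMeans(V[yV == -1, ]) - colMeans(O_N)
  surviving <- seq_len(d)
  expected <- integer(0)
  while (length(surviving) > 0) {
    dvec <- vapply(seq_along(surviving), function(j) {
      keep <- surviving[-j]
      sqrt(sum(gap_P[keep]^2)) + sqrt(sum(gap_N[keep]^2))
    }, numeric(1))
    pick <- order(dvec, surviving)[1]
    expected <- c(expected, surviving[pick])
    surviving <- surviving[-pick]
  }
  expect_identical(r$elimination_order, expected)
})

test_that("T-RFE ranking is deterministic and survives an emptied source class", {
  set.seed(23)
  d <- 12
  yV <- rep(c(1L, -1L), 10)
  V <- matrix(rnorm(20 * d), 20, d) + yV * 0.5
  O_N <- matrix(rnorm(30 * d), 30, d) - 0.5
  A <- rbind(V, O_N)
  yA <- c(yV, rep(-1L, 30))
  expect_warning(
    r <- trfe_rank(A, yA, V, yV, O_N[0, , drop = FALSE], O_N, 2, q = 4),
    "empty")
  expect_setequal(r$elimination_order, seq_len(d))
  r2 <- suppressWarnings(
    trfe_rank(A, yA, V, yV, O_N[0, , drop = FALSE], O_N, 2, q = 4))
  expect_identical(r$elimination_order, r2$elimination_order)
})

test_that("end-to-end trfe() logs selection sizes and returns a full ranking", {
  pop <- make_feature_population(population_spec(n_subjects = 4, D = 20,
                                                 n_trials = 20), seed = 31)
  s1 <- pop$subjects[[1]]
  O <- do.call(rbind, lapply(pop$subjects[-1], function(s) s$W))
  yO <- unlist(lapply(pop$subjects[-1], function(s) s$labels))
  res <- trfe(s1$V, s1$labels, O, yO, q = 5)
  expect_s3_class(res$ranking, "feature_ranking")
  expect_equal(res$ranking$D, 20L)
  expect_true(res$init$gamma_o %in% gamma_grid(15))
  expect_equal(nrow(res$init$A), 20 + res$init$n_sel_P + res$init$n_sel_N)
  expect_lt(res$init$n_sel_P, sum(yO == 1))  # kept fraction < 1
})
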
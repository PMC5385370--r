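#' Candidate regularization grid
#'
#' The geometric grid `gamma_j = 2^(-5+j)`, `j = 1..p`; the default `p = 15`
#' spans `2^-4 .. 2^10`.
#'
#' @param p Grid size.
#' @return Numeric vector of length `p`, ascending.
#' @export
gamma_grid <- function(p = 15) 2^(-5 + seq_len(p))

#' Select the LSSVM regularization parameter on the validating set
#'
#' Evenly selects 50% of the validating instances (the odd 1-based positions
#' 1, 3, 5, ...) as `V_r`, trains an LSSVM on `V_r` for every candidate
#' `gamma` in [gamma_grid()], scores each fit by `E = (P_acc + P_f) / 2`, and
#' returns the `gamma` with the highest score (ties broken toward the
#' smallest `gamma`).
#'
#' Under the default `rule = "heldout"` the score is computed on the
#' complement `V \ V_r`, so the selection generalizes rather than rewarding
#' self-fit; `rule = "literal"` scores on `V_r` itself (train-set scoring),
#' preserved for auditability.
#'
#' @param V Numeric validating feature matrix (>= 4 rows, both classes).
#' @param y Labels in `{-1, +1}`.
#' @param p Grid size (default 15).
#' @param rule `"heldout"` (default) or `"literal"`.
#' @return The selected `gamma` (scalar), with the per-candidate scores and
#'   the grid attached as attributes `scores` and `grid`.
#' @export
select_gamma <- function(V, y, p = 15, rule = c("heldout", "literal")) {
  rule <- match.arg(rule)
  V <- as.matrix(V)
  y <- .as_pm1(y)
  n <- nrow(V)
  if (n < 4L) stop("need at least 4 validating instances", call. = FALSE)
  idx_r <- seq(1L, n, by = 2L)
  Vr <- V[idx_r, , drop = FALSE]
  yr <- y[idx_r]
  if (rule == "heldout") {
    Ve <- V[-idx_r, , drop = FALSE]
    ye <- y[-idx_r]
  } else {
    Ve <- Vr
    ye <- yr
  }
  if (length(unique(yr)) < 2L || length(unique(ye)) < 2L)
    stop("degenerate split: a class is absent from the selection or evaluation half",
         call. = FALSE)
  grid <- gamma_grid(p)
  scores <- vapply(grid, function(g) {
    m <- lssvm_train(Vr, yr, g)
    met <- compute_metrics(ye, predict(m, Ve))
    (met$P_acc + met$P_f) / 2
  }, numeric(1))
  out <- grid[which.max(scores)]  # which.max takes the first (smallest gamma)
  attr(out, "scores") <- scores
  attr(out, "grid") <- grid
  out
}

#' Target-domain class centers
#'
#' Componentwise means of the validating set's low-class (`+1`, "P") and
#' high-class (`-1`, "N") rows. These anchor both source-instance selection
#' and the domain-distance term of the T-RFE objective.
#'
#' @param V Validating feature matrix.
#' @param y Labels in `{-1, +1}`; both classes must be present.
#' @return Object of class `class_centers`: list with `v_P`, `v_N`, `n_P`,
#'   `n_N`.
#' @export
class_centers <- function(V, y) {
  V <- as.matrix(V)
  y <- .as_pm1(y)
  if (!all(c(-1L, 1L) %in% y))
    stop("both classes must be present in the validating set", call. = FALSE)
  structure(list(v_P = colMeans(V[y == 1L, , drop = FALSE]),
                 v_N = colMeans(V[y == -1L, , drop = FALSE]),
                 n_P = sum(y == 1L), n_N = sum(y == -1L)),
            class = "class_centers")
}

.keep_near_center <- function(M, v) {
  if (nrow(M) == 0L) return(integer(0))
  d <- sqrt(rowSums(sweep(M, 2L, v)^2))
  which(d < mean(d))
}

#' Select source instances near the target class centers
#'
#' Keeps a source instance of class C iff its Euclidean distance to the
#' target-domain center `v_C` is strictly below the mean of those distances
#' over all class-C source instances. This is the sign rule of the
#' instance-selection criterion H (its printed normalization is a positive
#' scaling that cannot change the sign), so the kept fraction is always < 1
#' for non-degenerate inputs; if every instance is equidistant, none is kept.
#'
#' @param O_P,O_N Source feature matrices of the low (`+1`) and high (`-1`)
#'   classes.
#' @param centers A [class_centers()] object from the validating set.
#' @return List with integer index vectors `P` and `N` (row indices into
#'   `O_P` / `O_N` of the kept instances).
#' @export
select_instances <- function(O_P, O_N, centers) {
  stopifnot(inherits(centers, "class_centers"))
  O_P <- as.matrix(O_P)
  O_N <- as.matrix(O_N)
  if (nrow(O_P) == 0L || nrow(O_N) == 0L)
    warning("a source class subset is empty; returning empty selection for it",
            call. = FALSE)
  list(P = .keep_near_center(O_P, centers$v_P),
       N = .keep_near_center(O_N, centers$v_N))
}

#' Assemble the adaptive T-RFE training set
#'
#' Concatenates the target-domain validating rows with the selected source
#' rows (duplicates, should they occur, are retained: the set union of the
#' initialization algorithm is over instances, and repeated rows simply
#' up-weight them in the least-squares fit). Records the selected
#' regularization parameter.
#'
#' @param V,yV Validating features and labels.
#' @param O_sel,yO_sel Selected source features and labels (possibly empty).
#' @param gamma_o Selected regularization parameter.
#' @return List with `X`, `y`, `gamma_o` and `n_target` (= `nrow(V)`).
#' @export
build_training_set <- function(V, yV, O_sel, yO_sel, gamma_o) {
  V <- as.matrix(V)
  O_sel <- as.matrix(O_sel)
  if (nrow(O_sel) > 0L && ncol(O_sel) != ncol(V))
    stop("feature-dimension mismatch between V and selected source set",
         call. = FALSE)
  if (nrow(O_sel) == 0L)
    warning("empty source selection: training set falls back to the target validating data",
            call. = FALSE)
  list(X = rbind(V, O_sel), y = c(.as_pm1(yV),
                                  if (nrow(O_sel)) .as_pm1(yO_sel) else integer(0)),
       gamma_o = gamma_o, n_target = nrow(V))
}

#' Center-and-normalize scaling of a score vector
#'
#' The scaling applied to both T-RFE score components before they are
#' combined: subtract the mean and divide by the L2 norm of the centered
#' vector, `kappa(s)_k = (s_k - mean(s)) / ||s - mean(s)||_2`. The output is
#' zero-sum with unit L2 norm; an all-equal input maps to the zero vector
#' (that component then contributes nothing to the combined score).
#'
#' @param scores Numeric vector, length >= 2.
#' @return Numeric vector of the same length.
#' @examples
#' kappa_scale(c(1, 2, 3))  # -0.7071 0 0.7071
#' @export
kappa_scale <- function(scores) {
  s <- as.numeric(scores)
  if (length(s) < 2L) stop("need at least 2 scores", call. = FALSE)
  c0 <- s - mean(s)
  nrm <- sqrt(sum(c0^2))
  if (nrm == 0) return(numeric(length(s)))
  c0 / nrm
}

# Per-feature source-target distances after single-feature removal, for all
# surviving features at once. gap = v_C - colMeans(O_C) over surviving
# columns; d_C(k) = sqrt(sum(gap^2) - gap_k^2) by the Pythagorean downdate.
.distance_after_removal_all <- function(gap) {
  tot <- sum(gap^2)
  sqrt(pmax(tot - gap^2, 0))
}

#' Source-target domain distance after removing one feature
#'
#' `d_P(k) + d_N(k)`: for each class C, the Euclidean distance between the
#' target center `v_C` and the mean of the selected source instances,
#' computed over all surviving features except `k`. Implemented through the
#' exact downdate `d_C(k)^2 = d_C^2 - delta_k^2`, where `delta_k` is the
#' per-feature center gap. An empty source class contributes 0 with a
#' warning.
#'
#' @param centers [class_centers()] over the surviving features.
#' @param O_P_sel,O_N_sel Selected source matrices over the surviving
#'   features.
#' @param k Index (into the surviving-feature columns) of the removed
#'   feature.
#' @return Scalar `d_P(k) + d_N(k)`.
#' @export
domain_distance_after_removal <- function(centers, O_P_sel, O_N_sel, k) {
  stopifnot(inherits(centers, "class_centers"))
  one <- function(M, v) {
    M <- as.matrix(M)
    if (nrow(M) == 0L) {
      warning("empty selected source class contributes 0 to the domain distance",
              call. = FALSE)
      return(0)
    }
    gap <- v - colMeans(M)
    .distance_after_removal_all(gap)[k]
  }
  one(O_P_sel, centers$v_P) + one(O_N_sel, centers$v_N)
}

#' T-RFE feature ranking
#'
#' Transfer recursive feature elimination: like classical RFE, but each
#' surviving feature `k` is scored by a weighted combination of two
#' kappa-scaled terms,
#' \deqn{\Delta\tilde\Phi(k) = \lambda_1 \,\kappa(w_k^2) +
#'   \lambda_2 \,\kappa(d_P(k) + d_N(k)),}
#' the margin-loss surrogate and the source-target domain distance that
#' would remain after removing `k`. Eliminating the smallest scores removes
#' features that are both non-discriminative and responsible for
#' source-target discrepancy. Per iteration the LSSVM is retrained on the
#' adaptive training set `A` (surviving features, fixed `gamma_o`), the
#' target centers are recomputed from `V`'s surviving features, the selected
#' source means from `O_P` / `O_N`, and the `q` lowest-scoring features are
#' removed from all of them.
#'
#' When one weight is zero the surviving term alone drives elimination and
#' the ordering is computed from that term's raw scores (the kappa scaling is
#' strictly increasing, so this is the same ordering, made exact in floating
#' point); with `lambda2 = 0` the elimination order therefore reproduces
#' [rfe_rank()] on identical inputs exactly. If a kappa input is all-equal
#' (e.g. after the selected source set empties), that term is the zero
#' vector and contributes nothing.
#'
#' @param A,yA Adaptive training set (target validating rows plus selected
#'   source rows) and labels.
#' @param V,yV Target-domain validating set and labels (drives the centers).
#' @param O_P,O_N Selected source instances of the low / high class.
#' @param gamma_o Regularization parameter, fixed across iterations.
#' @param lambda1,lambda2 Non-negative weights of the margin and the
#'   domain-distance terms; defaults 0.5 and 0.5. Their sum must be > 0.
#' @param q Elimination step length. Default 10.
#' @return A `feature_ranking` (see [rfe_rank()]).
#' @export
trfe_rank <- function(A, yA, V, yV, O_P, O_N, gamma_o,
                      lambda1 = 0.5, lambda2 = 0.5, q = 10) {
  A <- as.matrix(A)
  V <- as.matrix(V)
  O_P <- as.matrix(O_P)
  O_N <- as.matrix(O_N)
  yA <- .as_pm1(yA)
  yV <- .as_pm1(yV)
  D <- ncol(A)
  if (ncol(V) != D || (nrow(O_P) && ncol(O_P) != D) ||
      (nrow(O_N) && ncol(O_N) != D))
    stop("feature-dimension mismatch across A, V, O_P, O_N", call. = FALSE)
  if (lambda1 < 0 || lambda2 < 0 || lambda1 + lambda2 <= 0)
    stop("need lambda1, lambda2 >= 0 with lambda1 + lambda2 > 0", call. = FALSE)
  if (!is.numeric(q) || q < 1 || q > D)
    stop("need 1 <= q <= D", call. = FALSE)
  q <- as.integer(q)
  if (nrow(O_P) == 0L || nrow(O_N) == 0L)
    warning("an empty selected source class contributes 0 to the domain distance",
            call. = FALSE)

  mu_P_V <- colMeans(V[yV == 1L, , drop = FALSE])
  mu_N_V <- colMeans(V[yV == -1L, , drop = FALSE])
  mu_P_O <- if (nrow(O_P)) colMeans(O_P) else NULL
  mu_N_O <- if (nrow(O_N)) colMeans(O_N) else NULL

  surviving <- seq_len(D)
  batches <- list()
  while (length(surviving) > 0L) {
    m <- length(surviving)
    fit <- tryCatch(lssvm_train(A[, surviving, drop = FALSE], yA, gamma_o),
                    error = function(e) .partial_ranking_error(e, batches))
    sw <- fit$w^2
    dist_k <- numeric(m)
    if (!is.null(mu_P_O))
      dist_k <- dist_k +
        .distance_after_removal_all(mu_P_V[surviving] - mu_P_O[surviving])
    if (!is.null(mu_N_O))
      dist_k <- dist_k +
        .distance_after_removal_all(mu_N_V[surviving] - mu_N_O[surviving])

    score <- if (lambda2 == 0) {
      sw          # single-term ordering: identical to kappa-scaled ordering
    } else if (lambda1 == 0) {
      dist_k
    } else if (m == 1L) {
      0
    } else {
      lambda1 * kappa_scale(sw) + lambda2 * kappa_scale(dist_k)
    }
    batch <- .pick_batch(score, surviving, min(q, m))
    batches[[length(batches) + 1L]] <- batch
    surviving <- setdiff(surviving, batch)
  }
  .new_ranking(batches, D, q)
}

#' Initialize the T-RFE training set and model
#'
#' The full initialization pass for one testing subject: select the
#' regularization parameter on the validating set ([select_gamma()]),
#' compute the target class centers ([class_centers()]), select source
#' instances near those centers ([select_instances()]), and assemble the
#' adaptive training set `A = V` union selected source rows
#' ([build_training_set()]).
#'
#' @param V,yV Target-domain validating features and labels.
#' @param O,yO Source-domain working features (all other subjects, stacked)
#'   and labels.
#' @param p Gamma grid size.
#' @param rule Gamma selection rule, see [select_gamma()].
#' @return Object of class `trfe_init`: `gamma_o`, `centers`, `O_P`, `O_N`
#'   (the selected source matrices), `yO_P`, `yO_N`, `A`, `yA`, `n_target`,
#'   and the selection sizes `n_sel_P`, `n_sel_N`.
#' @export
trfe_init <- function(V, yV, O, yO, p = 15, rule = c("heldout", "literal")) {
  V <- as.matrix(V)
  O <- as.matrix(O)
  yV <- .as_pm1(yV)
  yO <- .as_pm1(yO)
  gamma_o <- as.numeric(select_gamma(V, yV, p = p, rule = match.arg(rule)))
  centers <- class_centers(V, yV)
  O_P <- O[yO == 1L, , drop = FALSE]
  O_N <- O[yO == -1L, , drop = FALSE]
  sel <- select_instances(O_P, O_N, centers)
  O_P_sel <- O_P[sel$P, , drop = FALSE]
  O_N_sel <- O_N[sel$N, , drop = FALSE]
  O_sel <- rbind(O_P_sel, O_N_sel)
  yO_sel <- c(rep(1L, nrow(O_P_sel)), rep(-1L, nrow(O_N_sel)))
  ts <- build_training_set(V, yV, O_sel, yO_sel, gamma_o)
  structure(list(gamma_o = gamma_o, centers = centers,
                 O_P = O_P_sel, O_N = O_N_sel,
                 A = ts$X, yA = ts$y, n_target = ts$n_target,
                 n_sel_P = nrow(O_P_sel), n_sel_N = nrow(O_N_sel)),
            class = "trfe_init")
}

#' @export
print.trfe_init <- function(x, ...) {
  cat(sprintf("<trfe_init> gamma_o = %g, |A| = %d (target %d + selected source %d P / %d N)\n",
              x$gamma_o, nrow(x$A), x$n_target, x$n_sel_P, x$n_sel_N))
  invisible(x)
}

#' End-to-end T-RFE for one testing subject
#'
#' Convenience wrapper running [trfe_init()] followed by [trfe_rank()].
#'
#' @inheritParams trfe_init
#' @inheritParams trfe_rank
#' @return List with elements `init` (a `trfe_init`) and `ranking` (a
#'   `feature_ranking`).
#' @export
trfe <- function(V, yV, O, yO, lambda1 = 0.5, lambda2 = 0.5, q = 10,
                 p = 15, rule = c("heldout", "literal")) {
  init <- trfe_init(V, yV, O, yO, p = p, rule = rule)
  ranking <- trfe_rank(init$A, init$yA, V, yV, init$O_P, init$O_N,
                       init$gamma_o, lambda1 = lambda1, lambda2 = lambda2,
                       q = q)
  list(init = init, ranking = ranking)
}

#' Tune the T-RFE term weights on the validating set
#'
#' Optional grid search over the weight pairs `(0.1, 0.9), ..., (0.9, 0.1)`:
#' for each pair the T-RFE ranking is recomputed and an LSSVM on the top
#' `k_eval` features of the adaptive training set is scored by
#' `(P_acc + P_f) / 2` on the validating set. The default weights (0.5, 0.5)
#' treat margin loss and domain distance as equally important; this tuner is
#' for users who prefer a data-driven choice.
#'
#' @inheritParams trfe_rank
#' @param k_eval Number of top-ranked features the scoring classifier uses.
#'   Default 10.
#' @return The best `(lambda1, lambda2)` pair (named numeric vector) with
#'   the per-pair scores attached as attribute `scores`.
#' @export
tune_lambda <- function(A, yA, V, yV, O_P, O_N, gamma_o, q = 10,
                        k_eval = 10) {
  grid <- seq(0.1, 0.9, by = 0.1)
  scores <- vapply(grid, function(l1) {
    r <- trfe_rank(A, yA, V, yV, O_P, O_N, gamma_o,
                   lambda1 = l1, lambda2 = 1 - l1, q = q)
    feats <- top_features(r, k_eval)
    m <- lssvm_train(A[, feats, drop = FALSE], yA, gamma_o)
    met <- compute_metrics(yV, predict(m, as.matrix(V)[, feats, drop = FALSE]))
    (met$P_acc + met$P_f) / 2
  }, numeric(1))
  best <- grid[which.max(scores)]
  out <- c(lambda1 = best, lambda2 = 1 - best)
  attr(out, "scores") <- scores
  out
}
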
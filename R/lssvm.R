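.as_pm1 <- function(y) {
  y <- as.integer(round(as.numeric(y)))
  if (!all(y %in% c(-1L, 1L)))
    stop("labels must be coded -1 / +1", call. = FALSE)
  y
}

#' Train a linear least-squares SVM
#'
#' Solves the LSSVM training problem
#' \deqn{\min_{w,b,\xi} \tfrac12 w^T w + \tfrac12 \gamma \sum_i \xi_i^2
#'   \quad \mathrm{s.t.}\quad y_i (w \cdot x_i + b) = 1 - \xi_i}
#' through its dual KKT conditions, rearranged as the single
#' `(n+1) x (n+1)` linear system
#' \deqn{\begin{bmatrix} 0 & -y^T \\ y & K \circ yy^T + \gamma^{-1} I
#'   \end{bmatrix} \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'   \begin{bmatrix} 0 \\ \mathbf{1} \end{bmatrix}}
#' with the linear kernel `K_ij = x_i . x_j` and an `n x n` identity block.
#' The primal weight vector is recovered as `w = sum_i alpha_i y_i x_i`.
#'
#' The system is solved by a dense direct solve with partial pivoting; a
#' warning reports the reciprocal condition number when it falls below
#' `1e-10`, and a singular system raises an error carrying the condition
#' estimate.
#'
#' @param X Numeric matrix `n x d` of training instances (rows).
#' @param y Labels in `{-1, +1}`; both classes must be present.
#' @param gamma Regularization parameter, > 0. Larger values penalize slack
#'   harder (less regularization of `w`).
#' @return Object of class `lssvm`: list with `alphas`, `b`, `gamma`, `X`,
#'   `y`, the derived weight vector `w` and slacks `xi`.
#' @examples
#' m <- lssvm_train(matrix(c(1, -1)), c(1, -1), gamma = 1)
#' m$alphas  # 1/3, 1/3
#' m$w       # 2/3
#' @export
lssvm_train <- function(X, y, gamma) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- .as_pm1(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training instances", call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("invalid input: both classes must be present in y", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("gamma must be a positive scalar", call. = FALSE)
  if (!all(is.finite(X))) stop("X contains non-finite entries", call. = FALSE)

  K <- tcrossprod(X)
  H <- K * tcrossprod(y) + diag(n) / gamma
  M <- rbind(c(0, -y), cbind(y, H))
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-15)
    stop(sprintf("singular KKT system (reciprocal condition %.3e)", rc),
         call. = FALSE)
  if (rc < 1e-10)
    warning(sprintf("ill-conditioned KKT system (reciprocal condition %.3e)", rc),
            call. = FALSE)
  sol <- unname(solve(M, c(0, rep(1, n))))
  b <- sol[1L]
  alpha <- sol[-1L]
  w <- drop(crossprod(X, alpha * y))
  xi <- 1 - y * (drop(X %*% w) + b)
  structure(list(alphas = alpha, b = b, gamma = gamma, X = X, y = y,
                 w = w, xi = xi),
            class = "lssvm")
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf("<lssvm> n = %d, d = %d, gamma = %g, |w| = %.4g, b = %.4g\n",
              nrow(x$X), ncol(x$X), x$gamma, sqrt(sum(x$w^2)), x$b))
  invisible(x)
}

#' Decision values of an LSSVM
#'
#' Computes `w . x + b` for new instances, either from the primal weight
#' vector or from the dual expansion `sum_i alpha_i y_i K(x_i, x) + b`. The
#' two formulations agree to machine precision and are both exposed so tests
#' can assert the identity.
#'
#' @param model An [lssvm_train()] model.
#' @param X_new Numeric matrix (or vector, one instance) of new data.
#' @param formulation `"primal"` or `"dual"`.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, X_new, formulation = c("primal", "dual")) {
  formulation <- match.arg(formulation)
  stopifnot(inherits(model, "lssvm"))
  Xn <- if (is.matrix(X_new)) X_new else matrix(X_new, nrow = 1L)
  if (ncol(Xn) != ncol(model$X))
    stop("feature dimension mismatch: model has ", ncol(model$X),
         ", newdata has ", ncol(Xn), call. = FALSE)
  if (formulation == "primal") {
    drop(Xn %*% model$w) + model$b
  } else {
    drop(Xn %*% crossprod(model$X, model$alphas * model$y)) + model$b
  }
}

#' Predict emotion classes with an LSSVM
#'
#' Labels are `sign(w . x + b)` with the tie convention `sign(0) := +1`.
#'
#' @param object An `lssvm` model.
#' @param newdata Matrix (or single-instance vector) of features.
#' @param ... Unused.
#' @return Integer labels in `{-1, +1}`.
#' @export
predict.lssvm <- function(object, newdata, ...) {
  f <- decision_values(object, newdata, "primal")
  ifelse(f >= 0, 1L, -1L)
}

#' Squared norm of the LSSVM weight vector
#'
#' Computes `||w||^2 = alpha^T (Psi Psi^T) alpha` with
#' `(Psi Psi^T)_{ij} = y_i y_j x_i . x_j`, the dual-side expression of the
#' squared margin normal. Identical (to rounding) to `sum(w^2)` from the
#' primal weight vector.
#'
#' @param model An `lssvm` model.
#' @return Non-negative scalar.
#' @export
margin_norm <- function(model) {
  stopifnot(inherits(model, "lssvm"))
  av <- model$alphas * model$y
  drop(crossprod(av, tcrossprod(model$X) %*% av))
}

#' Binary classification metrics
#'
#' Confusion counts and the six rates used throughout: sensitivity (recall of
#' the low class, which is the positive class `+1`), specificity, precision,
#' accuracy, F1-score of the low class, and negative predictive value. A rate
#' whose denominator is zero is reported as 0 and flagged in `undefined`
#' rather than raising, so sweeps over feature-step curves never abort.
#'
#' @param y_true,y_pred Equal-length label vectors in `{-1, +1}`; `+1` is the
#'   low-emotion (positive) class.
#' @return Object of class `metrics_report`: counts `n_TP`, `n_FN`, `n_TN`,
#'   `n_FP`; rates `P_sen`, `P_spe`, `P_pre`, `P_acc`, `P_f`, `P_npv`; and
#'   `undefined`, the names of any zero-denominator rates.
#' @export
compute_metrics <- function(y_true, y_pred) {
  y_true <- .as_pm1(y_true)
  y_pred <- .as_pm1(y_pred)
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ", call. = FALSE)
  tp <- sum(y_true == 1L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == -1L)
  tn <- sum(y_true == -1L & y_pred == -1L)
  fp <- sum(y_true == -1L & y_pred == 1L)
  undefined <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else num / den
  }
  p_sen <- rate(tp, tp + fn, "P_sen")
  p_spe <- rate(tn, tn + fp, "P_spe")
  p_pre <- rate(tp, tp + fp, "P_pre")
  p_acc <- (tn + tp) / (tn + fn + tp + fp)
  p_f <- rate(2 * p_pre * p_sen, p_pre + p_sen, "P_f")
  p_npv <- rate(tn, tn + fn, "P_npv")
  structure(list(n_TP = tp, n_FN = fn, n_TN = tn, n_FP = fp,
                 P_sen = p_sen, P_spe = p_spe, P_pre = p_pre,
                 P_acc = p_acc, P_f = p_f, P_npv = p_npv,
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics> acc %.4f | sen %.4f spe %.4f pre %.4f f1 %.4f npv %.4f (TP %d FN %d TN %d FP %d)\n",
              x$P_acc, x$P_sen, x$P_spe, x$P_pre, x$P_f, x$P_npv,
              x$n_TP, x$n_FN, x$n_TN, x$n_FP))
  if (length(x$undefined))
    cat("  undefined (0/0 -> 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
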
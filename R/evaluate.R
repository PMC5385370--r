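.scheme_names <- c("trfe-sg", "rfe-sg", "lssvm-sg", "rfe-ss", "lssvm-ss")

.stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# Pooled-prediction cross-validation over a fixed feature subset.
.cv_predict <- function(X, y, gamma, folds) {
  pred <- integer(length(y))
  for (f in unique(folds)) {
    te <- folds == f
    m <- lssvm_train(X[!te, , drop = FALSE], y[!te], gamma)
    pred[te] <- predict(m, X[te, , drop = FALSE])
  }
  pred
}

.metrics_row <- function(met) {
  data.frame(P_sen = met$P_sen, P_spe = met$P_spe, P_pre = met$P_pre,
             P_acc = met$P_acc, P_f = met$P_f, P_npv = met$P_npv)
}

# Optimal step: maximize P_acc, ties toward fewer features, then higher P_f.
.optimal_step <- function(steps_df) {
  steps_df[order(-steps_df$P_acc, steps_df$n_features, -steps_df$P_f)[1L], ]
}

#' Leave-one-subject-out evaluation of a feature-selection scheme
#'
#' Runs one of five emotion-classification schemes over every subject of a
#' dataset, holding each subject out in turn:
#' \describe{
#'   \item{`lssvm-ss`}{subject-specific LSSVM, no feature selection; 10-fold
#'     stratified cross-validation on the subject's working data.}
#'   \item{`rfe-ss`}{subject-specific: RFE ranking computed once from the
#'     subject's validating data, then a step curve of 10-fold CV metrics on
#'     the working data (the single validating-data ranking is reused across
#'     folds).}
#'   \item{`lssvm-sg`}{subject-generic LSSVM: train on all other subjects'
#'     working data, all features, test on the held-out subject's working
#'     data.}
#'   \item{`rfe-sg`}{subject-generic RFE: ranking from the pooled source
#'     working data; step classifiers trained on the source pool.}
#'   \item{`trfe-sg`}{the transfer scheme: T-RFE initialization (gamma
#'     selection on the subject's validating data, instance selection,
#'     adaptive training set A) and T-RFE ranking; step classifiers trained
#'     on A.}
#' }
#' In every scheme the regularization parameter is selected on the held-out
#' subject's validating data via [select_gamma()], and the held-out subject's
#' working data never enters ranking or training of the subject-generic
#' schemes. Step `s` of a step curve uses exactly the `s * q` top-ranked
#' features (truncated at D); schemes without selection emit a single row
#' with `step = 0` and all features. Subjects whose labels contain a single
#' class are excluded with a warning.
#'
#' @param dataset A [make_feature_population()] object, or any list with a
#'   `subjects` element of per-subject records `list(subject_id, labels, V,
#'   W)` (V = validating features, W = working features, rows = trials).
#' @param scheme One of `"trfe-sg"`, `"rfe-sg"`, `"lssvm-sg"`, `"rfe-ss"`,
#'   `"lssvm-ss"`.
#' @param q Elimination step length / step-curve block size. Default 10.
#' @param p Gamma grid size. Default 15.
#' @param rule Gamma selection rule, see [select_gamma()].
#' @param lambda1,lambda2 T-RFE term weights (used by `trfe-sg` only).
#' @param n_folds CV folds for the subject-specific schemes. Default 10.
#' @param seed Seed for the CV fold assignment.
#' @param standardize Apply [standardize_by_subject()] to each subject's
#'   validating and working features before evaluation (the pipeline's
#'   per-subject z-scoring step). Default TRUE; set FALSE if the features
#'   are already standardized.
#' @return Object of class `scheme_result`: `scheme`; `steps`, a tidy data
#'   frame (subject, scheme, step, n_features, six metrics); `optimal`, one
#'   row per subject at its optimal step; `rankings`, per-subject
#'   `feature_ranking` objects (NULL for the no-selection schemes); `gamma`,
#'   the per-subject selected regularization; `init`, per-subject
#'   `trfe_init` objects for `trfe-sg`.
#' @export
loso_evaluate <- function(dataset, scheme = .scheme_names, q = 10, p = 15,
                          rule = c("heldout", "literal"), lambda1 = 0.5,
                          lambda2 = 0.5, n_folds = 10, seed = 1,
                          standardize = TRUE) {
  scheme <- match.arg(scheme, .scheme_names)
  rule <- match.arg(rule)
  subjects <- dataset$subjects
  if (length(subjects) < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (standardize)
    subjects <- lapply(subjects, function(s) {
      s$V <- standardize_by_subject(s$V)
      s$W <- standardize_by_subject(s$W)
      s
    })
  D <- ncol(subjects[[1L]]$W)
  n_steps <- ceiling(D / q)

  steps_all <- list()
  optimal_all <- list()
  rankings <- list()
  inits <- list()
  gammas <- numeric(0)

  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    sid <- as.character(sub$subject_id)
    y <- .as_pm1(sub$labels)
    if (length(unique(y)) < 2L) {
      warning("subject ", sid, " has a single class; excluded", call. = FALSE)
      next
    }
    V <- as.matrix(sub$V)
    W <- as.matrix(sub$W)
    gamma_o <- as.numeric(select_gamma(V, y, p = p, rule = rule))
    ranking <- NULL
    init <- NULL

    if (scheme %in% c("lssvm-sg", "rfe-sg", "trfe-sg")) {
      others <- subjects[-i]
      O <- do.call(rbind, lapply(others, function(s) as.matrix(s$W)))
      yO <- unlist(lapply(others, function(s) .as_pm1(s$labels)))
    }

    rows <- switch(scheme,
      "lssvm-ss" = {
        folds <- .stratified_folds(y, n_folds, seed + i)
        met <- compute_metrics(y, .cv_predict(W, y, gamma_o, folds))
        cbind(data.frame(step = 0L, n_features = D), .metrics_row(met))
      },
      "rfe-ss" = {
        ranking <- rfe_rank(V, y, gamma_o, q = q)
        folds <- .stratified_folds(y, n_folds, seed + i)
        do.call(rbind, lapply(seq_len(n_steps), function(s) {
          feats <- top_features(ranking, min(s * q, D))
          met <- compute_metrics(
            y, .cv_predict(W[, feats, drop = FALSE], y, gamma_o, folds))
          cbind(data.frame(step = s, n_features = length(feats)),
                .metrics_row(met))
        }))
      },
      "lssvm-sg" = {
        m <- lssvm_train(O, yO, gamma_o)
        met <- compute_metrics(y, predict(m, W))
        cbind(data.frame(step = 0L, n_features = D), .metrics_row(met))
      },
      "rfe-sg" = {
        ranking <- rfe_rank(O, yO, gamma_o, q = q)
        do.call(rbind, lapply(seq_len(n_steps), function(s) {
          feats <- top_features(ranking, min(s * q, D))
          m <- lssvm_train(O[, feats, drop = FALSE], yO, gamma_o)
          met <- compute_metrics(y, predict(m, W[, feats, drop = FALSE]))
          cbind(data.frame(step = s, n_features = length(feats)),
                .metrics_row(met))
        }))
      },
      "trfe-sg" = {
        init <- trfe_init(V, y, O, yO, p = p, rule = rule)
        ranking <- trfe_rank(init$A, init$yA, V, y, init$O_P, init$O_N,
                             init$gamma_o, lambda1 = lambda1,
                             lambda2 = lambda2, q = q)
        do.call(rbind, lapply(seq_len(n_steps), function(s) {
          feats <- top_features(ranking, min(s * q, D))
          m <- lssvm_train(init$A[, feats, drop = FALSE], init$yA,
                           init$gamma_o)
          met <- compute_metrics(y, predict(m, W[, feats, drop = FALSE]))
          cbind(data.frame(step = s, n_features = length(feats)),
                .metrics_row(met))
        }))
      })

    rows <- cbind(data.frame(subject = sid, scheme = scheme), rows)
    steps_all[[sid]] <- rows
    optimal_all[[sid]] <- .optimal_step(rows)
    rankings[[sid]] <- ranking
    inits[[sid]] <- init
    gammas[sid] <- if (!is.null(init)) init$gamma_o else gamma_o
  }

  if (length(steps_all) == 0L)
    stop("no evaluable subject (all single-class)", call. = FALSE)
  steps <- do.call(rbind, steps_all)
  optimal <- do.call(rbind, optimal_all)
  rownames(steps) <- rownames(optimal) <- NULL
  structure(list(scheme = scheme, steps = steps, optimal = optimal,
                 rankings = rankings, gamma = gammas, init = inits),
            class = "scheme_result")
}

#' @export
print.scheme_result <- function(x, ...) {
  cat(sprintf("<scheme_result> %s: %d subjects, mean optimal P_acc = %.4f, P_f = %.4f\n",
              x$scheme, nrow(x$optimal), mean(x$optimal$P_acc),
              mean(x$optimal$P_f)))
  invisible(x)
}

#' Summarize scheme results across subjects
#'
#' Median, quartiles and mean of the per-subject optimal-step accuracy and
#' F1-score of each scheme, plus the median optimal feature count - the
#' descriptive cross-scheme comparison.
#'
#' @param results A `scheme_result` or a list of them.
#' @return Data frame, one row per scheme.
#' @export
summarize_schemes <- function(results) {
  if (inherits(results, "scheme_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    o <- r$optimal
    data.frame(scheme = r$scheme, n_subjects = nrow(o),
               P_acc_median = stats::median(o$P_acc),
               P_acc_q1 = unname(stats::quantile(o$P_acc, 0.25)),
               P_acc_q3 = unname(stats::quantile(o$P_acc, 0.75)),
               P_acc_mean = mean(o$P_acc),
               P_f_median = stats::median(o$P_f),
               P_f_mean = mean(o$P_f),
               n_features_median = stats::median(o$n_features))
  }))
}

#' Recall of a planted feature set in the top ranks
#'
#' Fraction of the planted indices found among the `k` top-ranked features.
#'
#' @param ranking A `feature_ranking`.
#' @param planted Integer vector of planted feature indices.
#' @param k Number of top ranks examined. Default 10.
#' @return Scalar in `[0, 1]`.
#' @export
top_k_recall <- function(ranking, planted, k = 10) {
  mean(planted %in% top_features(ranking, k))
}

#' Box-plot comparison of schemes
#'
#' Per-subject optimal-step metric distributions by scheme. Requires
#' ggplot2.
#'
#' @param results List of `scheme_result` objects.
#' @param metric Metric column to plot. Default `"P_acc"`.
#' @return A ggplot object.
#' @export
plot_scheme_comparison <- function(results, metric = "P_acc") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  if (inherits(results, "scheme_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, `[[`, "optimal"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme, y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Step-curve plot for one scheme result
#'
#' Classification metrics against the step index (number of top-ranked
#' feature blocks supplied to the classifier). Requires ggplot2.
#'
#' @param result A `scheme_result` with a step curve.
#' @param metrics Metric columns to draw.
#' @return A ggplot object.
#' @export
plot_step_curve <- function(result,
                            metrics = c("P_sen", "P_spe", "P_acc", "P_f")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- result$steps
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(subject = df$subject, step = df$step, metric = m,
               value = df[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     color = .data$metric)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::labs(x = "step index", y = NULL) +
    ggplot2::theme_minimal()
}
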
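.new_ranking <- function(batches, D, q) {
  elim <- unlist(batches, use.names = FALSE)
  stopifnot(length(elim) == D, !anyDuplicated(elim))
  rank_of <- integer(D)
  rank_of[elim] <- seq_len(D)
  structure(list(batches = batches, elimination_order = elim,
                 rank = rank_of, q = q, D = D),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> D = %d, step q = %d, %d elimination batches\n",
              x$D, x$q, length(x$batches)))
  cat("  top features:", paste(utils::head(top_features(x, min(10L, x$D)), 10L),
                               collapse = " "), "\n")
  invisible(x)
}

#' Most salient features of a ranking
#'
#' Features eliminated last are the most salient. Returns the `k` top-ranked
#' original feature indices, most salient first.
#'
#' @param ranking A `feature_ranking`.
#' @param k Number of features.
#' @return Integer vector of length `min(k, D)`.
#' @export
top_features <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  k <- min(k, ranking$D)
  rev(utils::tail(ranking$elimination_order, k))
}

# One elimination pass shared by rfe_rank and trfe_rank: pick n_pick features
# by successive arg-min over `score`, ties broken by lowest original index.
# Scores are fixed within the batch, so the q successive picks equal the q
# smallest (score, index) pairs.
.pick_batch <- function(score, surviving, n_pick) {
  surviving[order(score, surviving)[seq_len(n_pick)]]
}

.partial_ranking_error <- function(e, batches) {
  stop(errorCondition(
    paste0("ranking aborted mid-loop: ", conditionMessage(e)),
    class = c("trfe_partial_ranking", "error"),
    partial_batches = batches))
}

#' Classical LSSVM-based recursive feature elimination
#'
#' Produces a full feature ranking by iteratively training a linear LSSVM on
#' the surviving features, scoring each surviving feature `k` by the squared
#' weight `w_k^2` - the margin-loss surrogate for the change in `||w||^2`
#' when `k` is removed - and eliminating the `q` lowest-scoring features per
#' iteration. Features eliminated later are more salient.
#'
#' Within a batch, features are removed by `q` successive arg-min picks with
#' ties broken by lowest original index, so the elimination order is fully
#' deterministic. `gamma` is held fixed across iterations. Reported indices
#' always refer to original catalog positions.
#'
#' @param X Numeric matrix `n x D`.
#' @param y Labels in `{-1, +1}`, both classes present.
#' @param gamma LSSVM regularization parameter.
#' @param q Elimination step length (features removed per iteration),
#'   `1 <= q <= D`. Default 10, matching the step length used in the
#'   evaluation sweeps.
#' @return Object of class `feature_ranking`: `batches` (list of index
#'   vectors, first batch eliminated first), `elimination_order`, `rank`
#'   (position in elimination order; higher = more salient), `q`, `D`.
#' @export
rfe_rank <- function(X, y, gamma, q = 10) {
  X <- as.matrix(X)
  D <- ncol(X)
  if (!is.numeric(q) || q < 1 || q > D)
    stop("need 1 <= q <= ncol(X)", call. = FALSE)
  q <- as.integer(q)
  surviving <- seq_len(D)
  batches <- list()
  while (length(surviving) > 0L) {
    fit <- tryCatch(lssvm_train(X[, surviving, drop = FALSE], y, gamma),
                    error = function(e) .partial_ranking_error(e, batches))
    batch <- .pick_batch(fit$w^2, surviving, min(q, length(surviving)))
    batches[[length(batches) + 1L]] <- batch
    surviving <- setdiff(surviving, batch)
  }
  .new_ranking(batches, D, q)
}

#' @describeIn rfe_rank Coerce a ranking to a data frame with columns
#'   `feature_index`, `catalog_name` (if a catalog is supplied via
#'   `catalog`), `batch` and `rank`.
#' @param x A `feature_ranking`.
#' @param row.names,optional Ignored (data-frame method signature).
#' @param catalog Optional [feature_catalog()] used to name features.
#' @param ... Unused.
#' @export
as.data.frame.feature_ranking <- function(x, row.names = NULL,
                                          optional = FALSE, catalog = NULL,
                                          ...) {
  batch_of <- integer(x$D)
  for (j in seq_along(x$batches)) batch_of[x$batches[[j]]] <- j
  out <- data.frame(feature_index = seq_len(x$D),
                    batch = batch_of,
                    rank = x$rank)
  if (!is.null(catalog))
    out$catalog_name <- catalog_names(catalog)[out$feature_index]
  out[c("feature_index", intersect("catalog_name", names(out)), "batch",
        "rank")]
}
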
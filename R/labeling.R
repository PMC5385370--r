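.restore_seed <- function() {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  }
}

with_seed <- function(seed, code) {
  restore <- .restore_seed()
  on.exit(restore())
  set.seed(seed)
  force(code)
}

#' Adaptive valence/arousal thresholds by 2-means clustering
#'
#' Fits k = 2 clusters to a subject's 2-D self-assessment ratings (valence,
#' arousal; each on the 1-9 scale) by repeated k-means, keeping the solution
#' with the lowest within-cluster sum of squares, and returns the midpoint of
#' the two cluster centers as the per-subject threshold pair. The midpoint
#' adapts the low/high class boundary to each rater's personal use of the
#' scale instead of the conventional fixed cut at 5.
#'
#' @param ratings Numeric matrix `n_trials x 2`, columns (valence, arousal),
#'   values in `[1, 9]`, at least 4 rows with at least 2 distinct points.
#' @param n_restarts Number of random k-means initializations. Default 10.
#' @param seed Integer seed controlling the restarts (the global RNG state is
#'   restored afterwards).
#' @return Object of class `threshold_pair`: list with `tau` (named vector
#'   `valence`, `arousal`), `centers` (2 x 2 matrix) and `tot_withinss`.
#' @examples
#' r <- rbind(matrix(2, 20, 2), matrix(8, 20, 2)) + 0
#' fit_thresholds(r, seed = 1)$tau  # c(5, 5)
#' @export
fit_thresholds <- function(ratings, n_restarts = 10, seed = 0) {
  z <- as.matrix(ratings)
  if (ncol(z) != 2L) stop("`ratings` must have 2 columns (valence, arousal)",
                          call. = FALSE)
  if (nrow(z) < 4L) stop("need at least 4 rating points", call. = FALSE)
  if (!all(is.finite(z)) || any(z < 1) || any(z > 9))
    stop("ratings must be finite values in [1, 9]", call. = FALSE)
  if (nrow(unique(z)) < 2L)
    stop("degenerate clustering: all rating points identical", call. = FALSE)
  km <- with_seed(seed,
    stats::kmeans(z, centers = 2L, nstart = n_restarts, iter.max = 100L))
  centers <- km$centers[order(km$centers[, 1], km$centers[, 2]), , drop = FALSE]
  tau <- colMeans(centers)
  names(tau) <- c("valence", "arousal")
  colnames(centers) <- c("valence", "arousal")
  structure(list(tau = tau, centers = centers,
                 tot_withinss = km$tot.withinss),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("<threshold_pair> tau = (valence %.4f, arousal %.4f)\n",
              x$tau["valence"], x$tau["arousal"]))
  invisible(x)
}

#' Assign binary emotion classes from ratings and a threshold
#'
#' Ratings strictly below the threshold are the low class, coded `+1` (the
#' positive class in all classification metrics); ratings at or above the
#' threshold are the high class, coded `-1`. The boundary convention mirrors
#' the conventional fixed-threshold split into low (< 5) and high (>= 5)
#' states.
#'
#' @param ratings Numeric matrix `n x 2` (valence, arousal) or, when
#'   `dimension` is given and `ratings` is a vector, the ratings of that
#'   dimension alone.
#' @param tau A `threshold_pair` from [fit_thresholds()], or a numeric
#'   threshold scalar when `ratings` is a vector.
#' @param dimension `"valence"` or `"arousal"`.
#' @return Integer vector of labels in `{-1, +1}`.
#' @export
assign_labels <- function(ratings, tau, dimension = c("valence", "arousal")) {
  dimension <- match.arg(dimension)
  if (inherits(tau, "threshold_pair")) tau <- tau$tau[dimension]
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau))
    stop("threshold must be a finite scalar", call. = FALSE)
  r <- if (is.matrix(ratings) || is.data.frame(ratings)) {
    as.matrix(ratings)[, match(dimension, c("valence", "arousal"))]
  } else as.numeric(ratings)
  ifelse(r < tau, 1L, -1L)
}
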
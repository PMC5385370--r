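#' Write / read a feature matrix as CSV
#'
#' Delimited-text interchange for trials-by-features matrices, with a header
#' row naming the catalog entries.
#'
#' @param X Numeric matrix, trials x features.
#' @param path Output file.
#' @param catalog Optional [feature_catalog()] supplying column names.
#' @return `write_feature_csv`: the path, invisibly. `read_feature_csv`: a
#'   numeric matrix with column names.
#' @export
write_feature_csv <- function(X, path, catalog = NULL) {
  X <- as.matrix(X)
  if (!is.null(catalog)) colnames(X) <- catalog_names(catalog)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  utils::write.csv(as.data.frame(X), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Write a feature ranking as CSV
#'
#' Columns: `feature_index`, optionally `catalog_name`, `batch`, `rank`.
#'
#' @param ranking A `feature_ranking`.
#' @param path Output file.
#' @param catalog Optional [feature_catalog()].
#' @return The path, invisibly.
#' @export
write_ranking_csv <- function(ranking, path, catalog = NULL) {
  utils::write.csv(as.data.frame(ranking, catalog = catalog), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a ratings CSV
#'
#' Expects columns `subject`, `trial`, `valence`, `arousal`.
#'
#' @param path Input file.
#' @return Data frame with those columns.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "trial", "valence", "arousal")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ratings file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df[need]
}

#' Serialize an LSSVM model to JSON
#'
#' Self-describing JSON carrying the dual coefficients, bias, regularization
#' parameter and primal weight vector (enough to predict with the primal
#' form).
#'
#' @param model An `lssvm` model.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_lssvm_json <- function(model, path) {
  stopifnot(inherits(model, "lssvm"))
  jsonlite::write_json(
    list(type = "lssvm_linear", alphas = model$alphas, b = model$b,
         gamma = model$gamma, w = model$w, n = nrow(model$X),
         d = ncol(model$X)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized LSSVM for prediction
#'
#' Restores a primal-form predictor from [write_lssvm_json()] output.
#'
#' @param path Input file.
#' @return A function `f(X_new)` returning labels in `{-1, +1}`.
#' @export
read_lssvm_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$type, "lssvm_linear"))
    stop("not a serialized linear LSSVM", call. = FALSE)
  w <- as.numeric(m$w)
  b <- as.numeric(m$b)
  function(X_new) {
    Xn <- if (is.matrix(X_new)) X_new else matrix(X_new, nrow = 1L)
    ifelse(drop(Xn %*% w) + b >= 0, 1L, -1L)
  }
}
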
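#' Multichannel EEG trial segment
#'
#' Container for one trial's EEG recording: a channels-by-samples matrix with
#' its sampling rate and channel labels. All feature-extraction functions in
#' the package consume this object.
#'
#' @param data Numeric matrix, `n_channels x n_samples`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of channel labels, one per row of
#'   `data`. Defaults to the standard 32-channel montage ([deap_channels()])
#'   when `data` has 32 rows.
#' @param subject_id Subject identifier (any scalar).
#' @param trial_index Non-negative integer trial index.
#' @return An object of class `trial_signal`.
#' @seealso [split_trial()], [bandpass_filter()], [extract_features()]
#' @export
trial_signal <- function(data, fs, channel_names = NULL, subject_id = NA,
                         trial_index = 0L) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  if (is.null(channel_names)) {
    channel_names <- if (nrow(data) == 32L) deap_channels()
                     else paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one entry per data row", call. = FALSE)
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         subject_id = subject_id, trial_index = as.integer(trial_index)),
    class = "trial_signal"
  )
}

#' @export
print.trial_signal <- function(x, ...) {
  cat(sprintf("<trial_signal> %d channels x %d samples @ %g Hz (%.1f s), subject %s trial %d\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              as.character(x$subject_id), x$trial_index))
  invisible(x)
}

#' Duration of a trial in seconds
#' @param signal A [trial_signal()].
#' @return Scalar duration in seconds.
#' @export
trial_duration <- function(signal) {
  stopifnot(inherits(signal, "trial_signal"))
  ncol(signal$data) / signal$fs
}

#' Split a trial into validating and working segments
#'
#' Partitions a trial at `validate_seconds`: the first segment drives model
#' selection (hyper-parameter choice, target-domain anchoring), the remainder
#' drives classifier training and testing. The two segments partition the
#' samples exactly, with no overlap and no loss.
#'
#' @param signal A [trial_signal()].
#' @param validate_seconds Length of the leading validating segment in
#'   seconds; must be strictly shorter than the trial. Default 10.
#' @return List with elements `validating` and `working`, both `trial_signal`.
#' @examples
#' tr <- trial_signal(matrix(rnorm(2 * 128 * 12), 2), fs = 128)
#' sp <- split_trial(tr, 6)
#' ncol(sp$validating$data)  # 768
#' @export
split_trial <- function(signal, validate_seconds = 10) {
  stopifnot(inherits(signal, "trial_signal"))
  if (!is.numeric(validate_seconds) || length(validate_seconds) != 1L ||
      !is.finite(validate_seconds) || validate_seconds <= 0)
    stop("`validate_seconds` must be a positive scalar", call. = FALSE)
  n <- ncol(signal$data)
  n_val <- as.integer(round(validate_seconds * signal$fs))
  if (n_val >= n)
    stop("trial too short: validating segment must leave a non-empty working segment",
         call. = FALSE)
  seg <- function(cols) {
    out <- signal
    out$data <- signal$data[, cols, drop = FALSE]
    out
  }
  list(validating = seg(seq_len(n_val)),
       working = seg(seq.int(n_val + 1L, n)))
}
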
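.periodogram <- function(x) {
  # one-sided periodogram without doubling: P(f_j) = |X_j|^2 / n at
  # f_j = j * fs / n, j = 1..floor(n/2) (DC excluded).
  n <- length(x)
  X <- stats::fft(x)
  j <- seq_len(floor(n / 2))
  list(power = Mod(X[j + 1L])^2 / n, freq = j / n)  # freq in cycles/sample
}

#' Per-channel spectral band power
#'
#' Power of each channel in a frequency band, computed from a single
#' periodogram of the full segment (plain FFT, no windowing): the sum of
#' `|X_j|^2 / n` over frequency bins with `low_hz <= f_j < high_hz`. For a
#' bin-aligned sinusoid of amplitude A this equals `A^2 * n / 4`.
#'
#' @param signal A [trial_signal()]; the segment must be at least 2 s long.
#' @param band Numeric length-2 vector `c(low_hz, high_hz)` within
#'   `(0, fs/2)`.
#' @return Numeric vector of non-negative powers, one per channel, named by
#'   channel.
#' @export
band_power <- function(signal, band) {
  stopifnot(inherits(signal, "trial_signal"))
  fs <- signal$fs
  if (length(band) != 2L || !all(is.finite(band)) ||
      band[1] <= 0 || band[2] <= band[1] || band[2] > fs / 2)
    stop("invalid band: need 0 < low < high <= fs/2", call. = FALSE)
  n <- ncol(signal$data)
  if (n < 2 * fs)
    stop("segment too short for spectral estimation (need >= 2 s)", call. = FALSE)
  j <- seq_len(floor(n / 2))
  f <- j * fs / n
  sel <- f >= band[1] & f < band[2]
  if (!any(sel))
    stop("invalid band: no frequency bins fall in [low, high)", call. = FALSE)
  X <- stats::mvfft(t(signal$data))
  P <- Mod(X[j + 1L, , drop = FALSE])^2 / n
  out <- colSums(P[sel, , drop = FALSE])
  names(out) <- signal$channel_names
  out
}

#' Seven time-domain statistics of a single channel
#'
#' Returns, in this fixed order: mean, variance (population convention,
#' divide by n), zero-crossing rate, Shannon entropy of the amplitude
#' histogram, spectral entropy of the normalized periodogram, kurtosis
#' (non-excess, normal = 3), and skewness.
#'
#' Conventions (fixed for reproducibility, since several are underdetermined
#' by their common names):
#' \itemize{
#'   \item zero-crossing rate = sign changes between consecutive samples
#'     divided by `n - 1`; exact zeros inherit the previous sample's sign
#'     (leading zeros count as positive);
#'   \item Shannon entropy: 16 equal-width histogram bins over
#'     `[min(x), max(x)]`, probabilities from counts, natural log,
#'     `0 * log 0 := 0`;
#'   \item spectral entropy: natural-log Shannon entropy of the periodogram
#'     normalized to sum 1 over the bins in `[4, 45)` Hz (the filter
#'     pass-band);
#'   \item degenerate (constant) input: variance, ZCR, both entropies,
#'     kurtosis and skewness are all defined as 0 - never an error.
#' }
#'
#' @param channel_signal Numeric vector, length >= 16.
#' @param fs Sampling rate in Hz (needed to place the spectral-entropy band).
#'   Default 128.
#' @param spectral_band Band (Hz) over which spectral entropy is computed.
#' @return Named numeric vector of length 7.
#' @export
time_domain_stats <- function(channel_signal, fs = 128,
                              spectral_band = c(4, 45)) {
  x <- as.numeric(channel_signal)
  n <- length(x)
  if (n < 16L) stop("need at least 16 samples", call. = FALSE)
  if (!all(is.finite(x)))
    stop("invalid input: non-finite samples", call. = FALSE)
  m <- mean(x)
  v <- mean((x - m)^2)

  if (v == 0) {
    out <- c(m, 0, 0, 0, 0, 0, 0)
    names(out) <- .time_stat_names()
    return(out)
  }

  s <- sign(x)
  if (s[1] == 0) s[1] <- 1
  for (i in which(s == 0)) s[i] <- s[i - 1L]  # zeros inherit previous sign
  zcr <- sum(s[-1] != s[-n]) / (n - 1)

  cnt <- tabulate(
    pmin(pmax(findInterval(x, seq(min(x), max(x), length.out = 17L),
                           rightmost.closed = TRUE), 1L), 16L),
    nbins = 16L)
  p <- cnt / n
  p <- p[p > 0]
  sh_ent <- -sum(p * log(p))

  pg <- .periodogram(x)
  f <- pg$freq * fs
  sel <- f >= spectral_band[1] & f < spectral_band[2]
  pw <- pg$power[sel]
  sp_ent <- if (length(pw) == 0 || sum(pw) <= 0) 0 else {
    q <- pw / sum(pw)
    q <- q[q > 0]
    -sum(q * log(q))
  }

  kur <- mean((x - m)^4) / v^2
  ske <- mean((x - m)^3) / v^1.5
  out <- c(m, v, zcr, sh_ent, sp_ent, kur, ske)
  names(out) <- .time_stat_names()
  out
}

#' Extract the full feature vector of a trial segment
#'
#' Computes all catalog features from a 32-channel segment: per-channel band
#' powers in the five bands, right-minus-left band-power differences over the
#' 14 asymmetry pairs in four bands, and seven time-domain statistics per
#' channel - 440 features in the catalog's fixed order.
#'
#' @param trial A [trial_signal()] carrying all montage channels (matched by
#'   name; order is irrelevant).
#' @param catalog A [feature_catalog()].
#' @return Numeric vector with one entry per catalog row, named by
#'   [catalog_names()].
#' @export
extract_features <- function(trial, catalog = feature_catalog()) {
  stopifnot(inherits(trial, "trial_signal"))
  ch_names <- unique(catalog$channel_or_pair[catalog$family == "band_power"])
  miss <- setdiff(ch_names, trial$channel_names)
  if (length(miss) > 0)
    stop("catalog channels missing from trial: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bands <- eeg_bands()
  bp <- sapply(seq_len(nrow(bands)), function(b)
    band_power(trial, c(bands$low[b], bands$high[b])))
  colnames(bp) <- bands$band  # channels x bands, rows named by channel
  td <- sapply(trial$channel_names, function(cn)
    time_domain_stats(trial$data[match(cn, trial$channel_names), ],
                      fs = trial$fs))  # 7 x channels

  vals <- numeric(nrow(catalog))
  for (i in seq_len(nrow(catalog))) {
    fam <- catalog$family[i]
    if (fam == "band_power") {
      vals[i] <- bp[catalog$channel_or_pair[i], catalog$band[i]]
    } else if (fam == "asymmetry") {
      pr <- strsplit(catalog$channel_or_pair[i], "-", fixed = TRUE)[[1]]
      vals[i] <- bp[pr[1], catalog$band[i]] - bp[pr[2], catalog$band[i]]
    } else {
      vals[i] <- td[catalog$statistic[i], catalog$channel_or_pair[i]]
    }
  }
  names(vals) <- catalog_names(catalog)
  vals
}

#' Standardize a subject's feature matrix
#'
#' Column-wise z-scoring across one subject's trials (sample standard
#' deviation, divide by n - 1, matching R's `sd()`), so each feature has
#' mean 0 and s.d. 1 over that subject: the column `c(1, 2, 3)` maps to
#' `c(-1, 0, 1)`. Zero-variance columns map to 0. Standardization is always applied
#' within subject, never across subjects, so that between-subject scale
#' differences cannot leak into cross-subject training.
#'
#' @param features Numeric matrix, trials x features, for a single subject
#'   (>= 2 rows).
#' @return Matrix of the same shape.
#' @export
standardize_by_subject <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) < 2L)
    stop("need at least 2 trials to standardize", call. = FALSE)
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  Z <- sweep(X, 2L, mu)
  nz <- s > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2L, s[nz], "/")
  Z[, !nz] <- 0
  Z
}
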
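#' Standard 32-channel EEG montage
#'
#' Channel labels in the fixed order used throughout the package (the montage
#' of the DEAP recording setup).
#'
#' @return Character vector of 32 channel names.
#' @export
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
    "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
    "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
    "PO4", "O2")
}

#' Hemispheric asymmetry channel pairs
#'
#' The 14 right-left channel pairs whose band-power differences form the
#' asymmetry features. Each asymmetry feature is right-channel band power
#' minus left-channel band power.
#'
#' @return Data frame with columns `right` and `left`.
#' @export
asymmetry_pairs <- function() {
  data.frame(
    right = c("Fp2", "AF4", "F4", "F8", "FC6", "FC2", "C4", "T8", "CP6",
              "CP2", "P4", "P8", "PO4", "O2"),
    left  = c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5",
              "CP1", "P3", "P7", "PO3", "O1"),
    stringsAsFactors = FALSE
  )
}

#' Frequency band definitions
#'
#' Band edges in Hz. Intervals are half-open, `[low, high)`, so bands sharing
#' a printed edge (theta 4-8 and alpha 8-12) never double-count a frequency
#' bin.
#'
#' @return Data frame with columns `band`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("theta", "slow_alpha", "alpha", "beta", "gamma"),
    low  = c(4, 8, 8, 12, 30),
    high = c(8, 10, 12, 30, 45),
    stringsAsFactors = FALSE
  )
}

.time_stat_names <- function() {
  c("mean", "variance", "zcr", "shannon_entropy", "spectral_entropy",
    "kurtosis", "skewness")
}

#' Build the 440-entry feature catalog
#'
#' Fixed, documented ordering of the 440 features extracted per trial
#' segment:
#' \enumerate{
#'   \item 160 band-power entries: for each of the 32 montage channels (in
#'     [deap_channels()] order), the five bands theta, slow_alpha, alpha,
#'     beta, gamma;
#'   \item 56 asymmetry entries: for each of the 14 pairs (in
#'     [asymmetry_pairs()] order), the four bands theta, alpha, beta, gamma
#'     (slow_alpha excluded);
#'   \item 224 time-domain entries: for each channel, the seven statistics
#'     mean, variance, zero-crossing rate, Shannon entropy, spectral entropy,
#'     kurtosis, skewness.
#' }
#' So feature index `k` is reproducible from this table alone.
#'
#' @return A data frame of class `feature_catalog` with columns `family`
#'   (`band_power`/`asymmetry`/`time_domain`), `channel_or_pair`, `band`
#'   (`none` for time-domain entries) and `statistic`.
#' @export
feature_catalog <- function() {
  ch <- deap_channels()
  pairs <- asymmetry_pairs()
  bands5 <- eeg_bands()$band
  bands4 <- setdiff(bands5, "slow_alpha")
  bp <- data.frame(
    family = "band_power",
    channel_or_pair = rep(ch, each = length(bands5)),
    band = rep(bands5, times = length(ch)),
    statistic = "power",
    stringsAsFactors = FALSE
  )
  asy <- data.frame(
    family = "asymmetry",
    channel_or_pair = rep(paste0(pairs$right, "-", pairs$left),
                          each = length(bands4)),
    band = rep(bands4, times = nrow(pairs)),
    statistic = "power_difference",
    stringsAsFactors = FALSE
  )
  td <- data.frame(
    family = "time_domain",
    channel_or_pair = rep(ch, each = 7L),
    band = "none",
    statistic = rep(.time_stat_names(), times = length(ch)),
    stringsAsFactors = FALSE
  )
  cat <- rbind(bp, asy, td)
  # feature-count conservation for the standard montage
  stopifnot(sum(cat$family == "band_power") == 160L,
            sum(cat$family == "asymmetry") == 56L,
            sum(cat$family == "time_domain") == 224L,
            nrow(cat) == 440L)
  rownames(cat) <- NULL
  class(cat) <- c("feature_catalog", "data.frame")
  cat
}

#' Human-readable catalog entry names
#' @param catalog A [feature_catalog()].
#' @return Character vector, one name per catalog entry.
#' @export
catalog_names <- function(catalog = feature_catalog()) {
  ifelse(catalog$family == "time_domain",
         paste(catalog$channel_or_pair, catalog$statistic, sep = "."),
         paste(catalog$channel_or_pair, catalog$band, sep = "."))
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat(sprintf("<feature_catalog> %d entries: %d band_power, %d asymmetry, %d time_domain\n",
              nrow(x), sum(x$family == "band_power"),
              sum(x$family == "asymmetry"), sum(x$family == "time_domain")))
  invisible(x)
}
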
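#' Specification of a synthetic multi-subject feature population
#'
#' Defines the statistical structure of a planted multi-subject population of
#' trial feature vectors: a subset of "transferable" discriminative features
#' whose class association is consistent across subjects, a subset of
#' subject-specific discriminative features whose class-association sign is
#' re-drawn per subject (a coin flip per subject-feature), per-subject mean
#' shifts on every feature, and equicorrelated unit-Gaussian noise within
#' feature families. This is the heterogeneity structure - features that
#' transfer across subjects vs. features that only discriminate within a
#' subject - that transfer feature selection is designed to exploit.
#'
#' Defaults are the planted-population study conditions used throughout the
#' package's evaluation: 8 subjects of 40 trials, 50 features, 5 transferable
#' and 5 subject-specific discriminative features with class-mean separation
#' 1.5 noise s.d., subject shift s.d. 1.0. Feature families default to
#' consecutive blocks of 10 features with within-family noise correlation
#' 0.2, a modest dependence mimicking band-power features from neighboring
#' channels.
#'
#' @param n_subjects,n_trials Number of subjects and trials per subject.
#' @param D Feature dimensionality.
#' @param idx_transfer,idx_specific Disjoint index sets (within `1..D`) of
#'   the transferable and subject-specific discriminative features.
#' @param effect Class-mean separation in noise-s.d. units (class means sit
#'   at `+/- effect/2`).
#' @param shift_scale S.d. of the per-subject, per-feature mean shifts.
#' @param rho Equicorrelation of the noise within a family, in `[0, 1)`.
#' @param families Integer vector of length `D` assigning features to
#'   families; default consecutive blocks of 10.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 8, n_trials = 40, D = 50,
                            idx_transfer = 1:5, idx_specific = 6:10,
                            effect = 1.5, shift_scale = 1.0, rho = 0.2,
                            families = NULL) {
  idx_transfer <- as.integer(idx_transfer)
  idx_specific <- as.integer(idx_specific)
  if (length(intersect(idx_transfer, idx_specific)) > 0)
    stop("idx_transfer and idx_specific must be disjoint", call. = FALSE)
  if (any(c(idx_transfer, idx_specific) > D) ||
      any(c(idx_transfer, idx_specific) < 1))
    stop("feature indices must lie in 1..D", call. = FALSE)
  if (effect < 0) stop("effect must be >= 0", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (is.null(families))
    families <- rep(seq_len(ceiling(D / 10)), each = 10L)[seq_len(D)]
  stopifnot(length(families) == D)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), D = as.integer(D),
                 idx_transfer = idx_transfer, idx_specific = idx_specific,
                 effect = effect, shift_scale = shift_scale, rho = rho,
                 families = as.integer(families)),
            class = "population_spec")
}

.equicorr_noise <- function(n, families, rho) {
  D <- length(families)
  Z <- matrix(stats::rnorm(n * D), n, D)
  if (rho == 0) return(Z)
  Zc <- matrix(stats::rnorm(n * max(families)), n, max(families))
  sqrt(1 - rho) * Z + sqrt(rho) * Zc[, families, drop = FALSE]
}

#' Generate a planted multi-subject feature population
#'
#' Draws, for every subject and trial, a balanced binary label and two
#' feature vectors (a "validating" and a "working" draw, emulating the two
#' segments of one trial: same trial label and mean structure, independent
#' noise). Per subject `s`, trial with label `y`, the mean of feature `k` is
#' `shift_s[k] + y * effect/2 * (1 if k transferable; sign_s[k] if k
#' subject-specific; 0 otherwise)`, where `shift_s ~ N(0, shift_scale^2)`
#' i.i.d. over features and `sign_s[k]` is a per-subject coin flip. Noise is
#' unit Gaussian with equicorrelation `rho` within families. The generator
#' is fully determined by `(spec, seed)`.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed.
#' @return Object of class `feature_population`: list with `subjects` (each
#'   a list `subject_id`, `labels`, `V`, `W`, `shift`, `specific_signs`),
#'   `idx_transfer`, `idx_specific` (the planted ground truth), and `spec`.
#' @export
make_feature_population <- function(spec = population_spec(), seed = 1) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
      nt <- spec$n_trials
      labels <- sample(rep(c(1L, -1L), length.out = nt))
      shift <- stats::rnorm(spec$D, 0, spec$shift_scale)
      signs <- sample(c(-1, 1), length(spec$idx_specific), replace = TRUE)
      beta <- numeric(spec$D)
      beta[spec$idx_transfer] <- spec$effect / 2
      beta[spec$idx_specific] <- signs * spec$effect / 2
      mu <- outer(labels, beta) + matrix(shift, nt, spec$D, byrow = TRUE)
      list(subject_id = s, labels = labels,
           V = mu + .equicorr_noise(nt, spec$families, spec$rho),
           W = mu + .equicorr_noise(nt, spec$families, spec$rho),
           shift = shift, specific_signs = signs)
    })
    structure(list(subjects = subjects, idx_transfer = spec$idx_transfer,
                   idx_specific = spec$idx_specific, spec = spec),
              class = "feature_population")
  })
}

#' @export
print.feature_population <- function(x, ...) {
  cat(sprintf("<feature_population> %d subjects x %d trials, D = %d (%d transferable + %d subject-specific planted)\n",
              length(x$subjects), x$spec$n_trials, x$spec$D,
              length(x$idx_transfer), length(x$idx_specific)))
  invisible(x)
}

#' Generate a bimodal synthetic rating cloud
#'
#' Two clipped-Gaussian clusters in the valence-arousal square `[1, 9]^2`
#' with known generating midpoint, emulating the bimodal structure of
#' per-subject self-assessment ratings. Values are clipped (not resampled)
#' to `[1, 9]`.
#'
#' @param n_trials Number of rating points.
#' @param c_low,c_high Cluster centers, each within `[1, 9]^2`.
#' @param spread Cluster s.d. (> 0).
#' @param mix Probability of the low cluster, in `(0, 1)`.
#' @param seed Integer seed.
#' @return Numeric `n_trials x 2` matrix (columns valence, arousal) with the
#'   generating midpoint `(c_low + c_high) / 2` attached as attribute
#'   `midpoint` and the cluster memberships as attribute `cluster`.
#' @export
make_ratings <- function(n_trials = 40, c_low = c(3, 3.5),
                         c_high = c(7, 6.5), spread = 0.5, mix = 0.5,
                         seed = 1) {
  if (spread <= 0) stop("spread must be > 0", call. = FALSE)
  if (mix <= 0 || mix >= 1) stop("mix must be in (0, 1)", call. = FALSE)
  if (any(c(c_low, c_high) < 1) || any(c(c_low, c_high) > 9))
    stop("cluster centers must lie within [1, 9]^2", call. = FALSE)
  with_seed(seed, {
    low <- stats::runif(n_trials) < mix
    ctr <- rbind(c_high, c_low)[low + 1L, , drop = FALSE]
    z <- ctr + matrix(stats::rnorm(2 * n_trials, 0, spread), n_trials, 2)
    z <- pmin(pmax(z, 1), 9)
    colnames(z) <- c("valence", "arousal")
    attr(z, "midpoint") <- (c_low + c_high) / 2
    attr(z, "cluster") <- ifelse(low, "low", "high")
    z
  })
}

#' Generate sinusoid-plus-noise EEG-like trials
#'
#' Each channel is a sum of sinusoids at stated in-band frequencies with
#' stated amplitudes (random phases) plus white Gaussian noise, so per-trial
#' ground-truth band powers are derivable in closed form: a bin-aligned tone
#' of amplitude A contributes `A^2 * n / 4` to its band's periodogram power.
#'
#' @param freqs Tone frequencies in Hz (all `< fs/2`).
#' @param amplitudes `n_channels x length(freqs)` matrix of amplitudes (a
#'   vector is recycled across channels).
#' @param noise_sd White-noise s.d. (>= 0).
#' @param fs Sampling rate in Hz (>= 128).
#' @param duration Trial length in seconds (>= 12, so the 10 s validating
#'   split leaves a working segment).
#' @param n_trials Number of trials.
#' @param channel_names Channel labels; default the 32-channel montage.
#' @param subject_id Subject identifier stored in each trial.
#' @param seed Integer seed (controls phases and noise).
#' @return List of [trial_signal()] objects.
#' @export
make_signal_trials <- function(freqs, amplitudes, noise_sd = 0, fs = 128,
                               duration = 60, n_trials = 1,
                               channel_names = deap_channels(),
                               subject_id = 1, seed = 1) {
  if (any(freqs >= fs / 2))
    stop("tone frequencies must be below fs/2", call. = FALSE)
  if (fs < 128) stop("fs must be >= 128", call. = FALSE)
  if (duration < 12) stop("duration must be >= 12 s", call. = FALSE)
  n_ch <- length(channel_names)
  A <- if (is.matrix(amplitudes)) amplitudes
       else matrix(amplitudes, n_ch, length(freqs), byrow = TRUE)
  stopifnot(nrow(A) == n_ch, ncol(A) == length(freqs))
  n <- as.integer(round(duration * fs))
  tt <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    lapply(seq_len(n_trials), function(tr) {
      dat <- matrix(0, n_ch, n)
      for (f in seq_along(freqs)) {
        ph <- stats::runif(n_ch, 0, 2 * pi)
        dat <- dat + A[, f] *
          t(sin(outer(tt, rep(2 * pi * freqs[f], n_ch)) +
                  matrix(ph, n, n_ch, byrow = TRUE)))
      }
      if (noise_sd > 0)
        dat <- dat + matrix(stats::rnorm(n_ch * n, 0, noise_sd), n_ch, n)
      trial_signal(dat, fs, channel_names, subject_id = subject_id,
                   trial_index = tr - 1L)
    })
  })
}
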
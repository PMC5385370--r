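make_noise_trial <- function(n_ch = 1, fs = 128, duration = 50, seed = 1,
                             sd = 1) {
  set.seed(seed)
  trial_signal(matrix(rnorm(n_ch * fs * duration, 0, sd), n_ch), fs,
               channel_names = paste0("ch", seq_len(n_ch)))
}

test_that("band-pass filter attenuates stop-band tones and DC", {
  fs <- 128
  tt <- (0:(fs * 20 - 1)) / fs
  tone50 <- trial_signal(matrix(sin(2 * pi * 50 * tt), 1), fs)
  out <- bandpass_filter(tone50)
  # drop the transient, compare steady-state power at 50 Hz
  keep <- seq(5 * fs, length(tt))
  p_in <- mean(tone50$data[1, keep]^2)
  p_out <- mean(out$data[1, keep]^2)
  expect_lt(10 * log10(p_out / p_in), -10)

  dc <- trial_signal(matrix(1, 1, fs * 20), fs)
  out_dc <- bandpass_filter(dc)
  expect_lt(max(abs(out_dc$data[1, keep])), 1e-4)
})

test_that("white-noise energy transfer matches the analytic Butterworth response", {
  fs <- 128
  # oracle: E[var_out / var_in] = integral of |H(f)|^2 over (0, fs/2] / (fs/2)
  f <- seq(0.01, fs / 2, length.out = 20000)
  expected <- mean(butterworth_response(f, 4, 45, 3))
  ratios <- vapply(1:8, function(s) {
    tr <- make_noise_trial(fs = fs, duration = 60, seed = s)
    out <- bandpass_filter(tr)
    keep <- seq(5 * fs, ncol(tr$data))
    mean(out$data[1, keep]^2) / mean(tr$data[1, keep]^2)
  }, numeric(1))
  expect_equal(mean(ratios), expected, tolerance = 0.1)
})

test_that("filter rejects invalid parameters and non-finite input", {
  tr <- make_noise_trial(duration = 12)
  expect_error(bandpass_filter(tr, low_hz = 0), "invalid filter band")
  expect_error(bandpass_filter(tr, low_hz = 50, high_hz = 45), "invalid filter band")
  expect_error(bandpass_filter(tr, high_hz = 70), "invalid filter band")
  tr$data[1, 5] <- NA
  expect_error(bandpass_filter(tr), "non-finite")
})

test_that("split_trial partitions samples exactly", {
  tr <- make_noise_trial(n_ch = 2, duration = 60)
  sp <- split_trial(tr, 10)
  expect_equal(ncol(sp$validating$data), 1280L)
  expect_equal(ncol(sp$working$data), 6400L)
  expect_identical(cbind(sp$validating$data, sp$working$data), tr$data)

  tr12 <- make_noise_trial(duration = 12)
  sp12 <- split_trial(tr12, 6)
  expect_equal(ncol(sp12$validating$data), ncol(sp12$working$data))

  expect_error(split_trial(tr12, 12), "too short")
  expect_error(split_trial(tr12, 15), "too short")
})

test_that("band power isolates an in-band tone and is zero for silence", {
  tr <- make_signal_trials(freqs = 6, amplitudes = 1, noise_sd = 0,
                           duration = 50, seed = 2)[[1]]
  bands <- eeg_bands()
  pw <- sapply(seq_len(nrow(bands)), function(i)
    band_power(tr, c(bands$low[i], bands$high[i]))[1])
  names(pw) <- bands$band
  total <- sum(pw[c("theta", "alpha", "beta", "gamma")])
  expect_gt(pw["theta"] / total, 0.95)
  expect_lt(pw["alpha"] / total, 0.02)
  expect_lt(pw["beta"] / total, 0.02)
  expect_lt(pw["gamma"] / total, 0.02)

  silent <- trial_signal(matrix(0, 1, 128 * 10), 128)
  expect_equal(unname(band_power(silent, c(4, 8))), 0)
  expect_error(band_power(tr, c(45, 4)), "invalid band")
  expect_error(band_power(tr, c(6.001, 6.002)), "no frequency bins")
})

test_that("white-noise band powers are proportional to band widths", {
  # flat-spectrum oracle: theta:alpha:beta:gamma = 4:4:18:15
  widths <- c(theta = 4, alpha = 4, beta = 18, gamma = 15)
  lims <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30),
               gamma = c(30, 45))
  acc <- c(theta = 0, alpha = 0, beta = 0, gamma = 0)
  for (s in 1:20) {
    tr <- make_noise_trial(duration = 50, seed = 100 + s)
    for (b in names(lims)) acc[b] <- acc[b] + band_power(tr, lims[[b]])[1]
  }
  expect_equal(unname(acc / sum(acc)), unname(widths / sum(widths)),
               tolerance = 0.15)
})

test_that("time-domain statistics match their definitions", {
  alt <- rep(c(1, -1), 64)
  st <- time_domain_stats(alt)
  expect_equal(unname(st["mean"]), 0)
  expect_equal(unname(st["zcr"]), 1.0)

  const <- time_domain_stats(rep(5, 100))
  expect_equal(unname(const),
               c(5, 0, 0, 0, 0, 0, 0))

  set.seed(11)
  x <- rnorm(6400)
  st2 <- time_domain_stats(x)
  # moment-formula oracle on the drawn sample
  m <- mean(x); v <- mean((x - m)^2)
  expect_equal(unname(st2["kurtosis"]), mean((x - m)^4) / v^2, tolerance = 1e-12)
  expect_equal(unname(st2["kurtosis"]), 3, tolerance = 0.2)
  expect_equal(unname(st2["skewness"]), 0, tolerance = 0.1)
  expect_equal(unname(st2["variance"]), v)
  expect_error(time_domain_stats(1:8), "16 samples")
})

test_that("zeros inherit the previous sign in the zero-crossing rate", {
  # 1, 0, -1: the zero takes sign +, so there is exactly one sign change
  x <- c(rep(c(1, 0, -1, -1), 8))
  st <- time_domain_stats(x)
  # per 4-sample block: 1(+) 0(+) -1(-) -1(-): one change; block joins add one
  # change back to +1: count = 8 changes down + 7 up = 15 over 31 gaps
  expect_equal(unname(st["zcr"]), 15 / 31)
})

test_that("extract_features returns the catalog layout with consistent values", {
  cat <- feature_catalog()
  tr <- make_signal_trials(freqs = c(6, 10, 20), amplitudes = c(1, 0.5, 0.25),
                           noise_sd = 0.5, duration = 12, seed = 3)[[1]]
  fv <- extract_features(tr, cat)
  expect_length(fv, 440L)
  expect_named(fv, catalog_names(cat))

  # symmetric signals: all asymmetry features are zero
  half <- tr$data[1:16, ]
  sym <- trial_signal(rbind(half, half), tr$fs,
                      c(asymmetry_pairs()$left, "Oz", "Pz",
                        asymmetry_pairs()$right, "Fz", "Cz"))
  fv_sym <- extract_features(sym, cat)
  expect_equal(max(abs(fv_sym[cat$family == "asymmetry"])), 0)

  # tone only on Fp2: asymmetry(Fp2-Fp1, alpha) equals Fp2 alpha power
  A <- matrix(0, 32, 1)
  A[match("Fp2", deap_channels()), 1] <- 1
  tone <- make_signal_trials(freqs = 10, amplitudes = A, noise_sd = 0,
                             duration = 12, seed = 4)[[1]]
  fv_t <- extract_features(tone, cat)
  asym_idx <- which(cat$channel_or_pair == "Fp2-Fp1" & cat$band == "alpha")
  expect_equal(unname(fv_t[asym_idx]),
               unname(band_power(tone, c(8, 12))["Fp2"]), tolerance = 1e-9)
  expect_gt(fv_t[asym_idx], 0)

  # missing channel is named in the error
  bad <- trial_signal(tr$data[1:31, ], tr$fs, deap_channels()[1:31])
  expect_error(extract_features(bad, cat), "O2")
})

test_that("asymmetry features are antisymmetric under channel swap", {
  cat <- feature_catalog()
  tr <- make_noise_trial(n_ch = 32, duration = 12, seed = 9)
  tr$channel_names <- deap_channels()
  fv <- extract_features(tr, cat)
  swapped <- tr
  prs <- asymmetry_pairs()
  for (i in seq_len(nrow(prs))) {
    a <- match(prs$right[i], deap_channels())
    b <- match(prs$left[i], deap_channels())
    swapped$data[c(a, b), ] <- tr$data[c(b, a), ]
  }
  fv_sw <- extract_features(swapped, cat)
  asym <- cat$family == "asymmetry"
  expect_equal(fv_sw[asym], -fv[asym], tolerance = 1e-12)
})

test_that("standardization z-scores per column with zero-variance guard", {
  X <- cbind(c(1, 2, 3), c(7, 7, 7), c(0, 10, 20))
  Z <- standardize_by_subject(X)
  expect_equal(Z[, 1], c(-1, 0, 1))
  expect_equal(Z[, 2], c(0, 0, 0))
  set.seed(21)
  Y <- matrix(rnorm(40 * 15, 5, 3), 40)
  Zy <- standardize_by_subject(Y)
  expect_equal(max(abs(colMeans(Zy))), 0, tolerance = 1e-9)
  expect_equal(unname(apply(Zy, 2, sd)), rep(1, 15), tolerance = 1e-9)
  expect_error(standardize_by_subject(Y[1, , drop = FALSE]), "at least 2")
})
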
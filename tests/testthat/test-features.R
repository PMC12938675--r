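# Feature extraction: Welch PSD, band powers, temporal/Hjorth/entropy
# features, and the feature-matrix construction modes.

test_that("Welch PSD integrates to the variance and localizes tones", {
  set.seed(21)
  x <- stats::rnorm(256 * 60, sd = 3)
  w <- welch_psd(x, 256, window_s = 2)
  df <- w$frequencies[2] - w$frequencies[1]
  expect_equal(sum(w$psd) * df, stats::var(x), tolerance = 0.05)
  expect_equal(df, 0.5)

  tt <- seq(0, 60 - 1 / 256, by = 1 / 256)
  ws <- welch_psd(sin(2 * pi * 10 * tt), 256, window_s = 2)
  expect_lte(abs(ws$frequencies[which.max(ws$psd)] - 10), df)

  wz <- welch_psd(rep(0, 1024), 256)
  expect_true(all(wz$psd == 0))
  expect_error(welch_psd(stats::rnorm(100), 256, window_s = 2), "shorter")
})

test_that("band power follows the mean-square convention and relative powers normalize", {
  expect_equal(band_power(rep(0, 100)), 0)
  tt <- seq(0, 20 - 1 / 256, by = 1 / 256)
  expect_equal(band_power(5 * sin(2 * pi * 7 * tt)), 25 / 2, tolerance = 1e-3)
  expect_equal(unname(rel_power(c(1, 1, 1, 1, 1))), rep(0.2, 5))
  expect_error(rel_power(c(0, 0, 0, 0, 0)), "undefined")
})

test_that("PSD band features: peaks, ratios and the 45-55 Hz exclusion", {
  freqs <- seq(0, 128, by = 0.5)
  psd <- rep(0, length(freqs))
  psd[freqs == 6] <- 4   # theta tone
  psd[freqs == 10] <- 4  # alpha tone of equal power
  psd[freqs == 20] <- 2  # beta
  psd[freqs == 50] <- 100 # mains: must not leak into any band
  psd[freqs == 2] <- 1
  psd[freqs == 35] <- 1
  out <- psd_band_features(freqs, psd)
  expect_equal(unname(out$peak_frequency[c("Theta", "Alpha", "Beta")]),
               c(6, 10, 20))
  expect_equal(unname(out$ratios[["theta_alpha"]]), 1)
  expect_equal(unname(out$ratios[["beta_alpha"]]), 0.5)
  expect_equal(unname(out$peak_frequency[["Gamma"]]), 35)

  flat <- rep(1, length(freqs))
  tie <- psd_band_features(freqs, flat)
  expect_equal(unname(tie$peak_frequency[["Theta"]]), 4) # lowest bin on ties
  zero_beta <- psd; zero_beta[freqs >= 15 & freqs <= 30] <- 0
  expect_error(psd_band_features(freqs, zero_beta), "denominator")
})

test_that("temporal moments use population conventions", {
  x <- rep(c(-1, 1), 500)
  ts <- temporal_stats(x)
  expect_equal(unname(ts[c("skewness", "kurtosis")]), c(0, 1))
  expect_equal(unname(ts[c("min", "max")]), c(-1, 1))
  set.seed(22)
  g <- stats::rnorm(1e5)
  expect_equal(unname(temporal_stats(g)[["kurtosis"]]), 3, tolerance = 0.1)
  expect_error(temporal_stats(rep(2, 10)), "constant")
})

test_that("Hjorth parameters: frequency ordering, sinusoid complexity, scale behaviour", {
  set.seed(23)
  w <- stats::rnorm(5000)
  expect_gt(hjorth(w)[["mobility"]], hjorth(cumsum(w))[["mobility"]])
  tt <- seq(0, 40, by = 1 / 256) # 25.6 samples/cycle at 10 Hz
  s <- sin(2 * pi * 10 * tt)
  expect_equal(unname(hjorth(s)[["complexity"]]), 1, tolerance = 0.02)
  h1 <- hjorth(w); h2 <- hjorth(7 * w)
  expect_equal(h2[["activity"]], 49 * h1[["activity"]])
  expect_equal(h2[["mobility"]], h1[["mobility"]])
  expect_equal(h2[["complexity"]], h1[["complexity"]])
  expect_error(hjorth(rep(1, 10)), "variance")
})

test_that("Shannon entropy matches an independent histogram computation", {
  expect_equal(shannon_entropy(rep(5, 100)), 0)
  x <- rep(seq(0, 1, length.out = 64), each = 10) # equal occupancy
  expect_equal(shannon_entropy(x, 64), 6, tolerance = 1e-9)
  set.seed(24)
  g <- stats::rnorm(5000)
  # independent oracle via hist()
  br <- seq(min(g), max(g), length.out = 65)
  cnt <- graphics::hist(g, breaks = br, plot = FALSE, right = TRUE,
                        include.lowest = TRUE)$counts
  p <- cnt[cnt > 0] / length(g)
  expect_equal(shannon_entropy(g, 64), -sum(p * log2(p)), tolerance = 1e-10)
})

test_that("spectral entropy separates tones from noise and ignores amplitude", {
  tt <- seq(0, 60 - 1 / 256, by = 1 / 256)
  tone <- sin(2 * pi * 10 * tt)
  expect_lt(spectral_entropy(tone, 256), 0.3)
  set.seed(25)
  noise <- stats::rnorm(length(tt))
  expect_gt(spectral_entropy(noise, 256), 0.9)
  expect_equal(spectral_entropy(13 * noise, 256), spectral_entropy(noise, 256))
  expect_error(spectral_entropy(rep(0, 1024), 256), "spectral mass")
})

test_that("feature matrices are complete, finite and consistently named", {
  fm <- small_feature_matrix()
  expect_equal(nrow(fm), 8)
  expect_equal(length(attr(fm, "feature_names")), 156)
  X <- feature_values(fm)
  expect_true(all(is.finite(X)))
  relsum_o1 <- rowSums(X[, grepl("^O1_.*_RelPower$", colnames(X))])
  relsum_o2 <- rowSums(X[, grepl("^O2_.*_RelPower$", colnames(X))])
  expect_equal(relsum_o1, rep(1, 8), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(relsum_o2, rep(1, 8), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("scaling a recording by c scales power features by c^2 and leaves shape features invariant", {
  rec <- small_clean_cohort()$clean[[1]]
  scaled <- rec
  scaled$samples <- 3 * rec$samples
  f1 <- subject_features(rec)
  f2 <- subject_features(scaled)
  pow <- grepl("_(AbsPower|Activity)$", names(f1))
  lin <- grepl("_(Std|Mean|Min|Max)$", names(f1))
  inv <- grepl("_(RelPower|Skewness|Kurtosis|Mobility|Complexity|ShannonEntropy|SpectralEntropy|PeakFrequency)$|Ratio$",
               names(f1))
  expect_equal(f2[pow], 9 * f1[pow], tolerance = 1e-9)
  expect_equal(f2[lin], 3 * f1[lin], tolerance = 1e-9)
  expect_equal(f2[inv], f1[inv], tolerance = 1e-6)
})

test_that("segment-wise and concatenated aggregation agree on stationary signals", {
  specs <- lapply(default_band_specs(), function(s) {
    band_spec(s$band_name, s$f_lo, s$f_hi, s$mean_amp, amp_cv = 0,
              entropy_knob = s$entropy_knob)
  })
  rec <- simulate_subject(specs, NULL, duration = 120, seed = 26)
  fc <- subject_features(rec, "concatenated")
  fs_ <- subject_features(rec, "segmentwise")
  expect_identical(names(fc), names(fs_))
  ap <- grepl("_AbsPower$", names(fc))
  expect_equal(fs_[ap], fc[ap], tolerance = 0.05)
})

test_that("composite O1+O2 powers are the channel means", {
  fm <- small_feature_matrix()
  X <- feature_values(fm)
  for (b in c("Delta", "Beta")) {
    expect_equal(X[, paste0("O1O2_", b, "_AbsPower")],
                 (X[, paste0("O1_", b, "_AbsPower")] +
                    X[, paste0("O2_", b, "_AbsPower")]) / 2)
  }
})
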
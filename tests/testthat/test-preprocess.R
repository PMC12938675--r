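# Filtering, boundary trimming, artifact rejection and retention tables.

test_that("the filter chain notches 50 Hz, passes 10 Hz, and removes DC with zero lag", {
  r50 <- apply_filters(tone_recording(50, amp = 10))
  expect_lte(rms(r50$samples[1, ]) / (10 / sqrt(2)), 0.1)

  x10 <- tone_recording(10, amp = 1)
  r10 <- apply_filters(x10)
  gain_db <- 20 * log10(rms(r10$samples[1, ]) / rms(x10$samples[1, ]))
  expect_gte(gain_db, -1)
  cc <- stats::ccf(r10$samples[1, ], x10$samples[1, ], lag.max = 5, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)

  rdc <- apply_filters(as_recording(rep(100, 256 * 120)))
  expect_lt(abs(mean(rdc$samples[1, ])), 0.5)

  rz <- apply_filters(as_recording(rep(0, 256 * 120)))
  expect_true(all(rz$samples == 0))

  expect_error(apply_filters(tone_recording(10), filter_spec(lp_cutoff = 200)),
               "Nyquist")
})

test_that("filtering twice changes in-band (2-40 Hz) power by < 5%", {
  rec <- simulate_subject(default_band_specs(), NULL, duration = 120, seed = 6)
  band_rms <- function(r) {
    w <- welch_psd(r$samples[1, ], r$fs, window_s = 2)
    sqrt(sum(w$psd[w$frequencies >= 2 & w$frequencies <= 40]))
  }
  once <- apply_filters(rec)
  twice <- apply_filters(once)
  expect_lt(abs(band_rms(twice) - band_rms(once)) / band_rms(once), 0.05)
})

test_that("boundary trimming removes exactly 2 x trim_s seconds", {
  rec <- simulate_subject(default_band_specs(), NULL, duration = 600, seed = 8)
  expect_equal(trim_boundaries(rec, 20)$duration, 560)
  rec100 <- simulate_subject(default_band_specs(), NULL, duration = 100, seed = 8)
  expect_identical(trim_boundaries(rec100, 0), rec100)
  rec60 <- simulate_subject(default_band_specs(), NULL, duration = 60, seed = 8)
  expect_error(trim_boundaries(rec60, 30), "too short")
})

test_that("epoch rejection flags exactly the epochs that violate the criterion", {
  set.seed(31)
  n <- 256 * 560
  x <- stats::rnorm(n, 0, 5)
  x[256 * 25] <- 150 # one spike in the third 10-s epoch
  rec <- as_recording(rbind(O1 = x, O2 = rep(0, n)))
  res <- reject_artifacts(rec, 100, 10)
  expect_equal(res$report$rejected_s, 10)
  expect_equal(res$report$rejected_pct, 10 / 560 * 100)
  expect_equal(sum(!res$report$keep_mask), 1L)

  quiet <- as_recording(matrix(stats::runif(2 * n, -50, 50), 2))
  res2 <- reject_artifacts(quiet, 100, 10)
  expect_equal(res2$report$rejected_s, 0)
  expect_equal(res2$report$retained_pct, 100)
})

test_that("either-channel violations reject the epoch; ties at threshold are retained", {
  n <- 2560L
  a <- rep(0, n); b <- rep(0, n)
  b[100] <- 150 # only O2 violates
  res <- reject_artifacts(as_recording(rbind(O1 = a, O2 = b)), 100, 10)
  expect_equal(res$report$rejected_s, 10)
  tie <- rep(0, n); tie[100] <- 100 # exactly at threshold
  res2 <- reject_artifacts(as_recording(rbind(O1 = tie, O2 = a)), 100, 10)
  expect_equal(res2$report$rejected_s, 0)
  # literal peak-to-peak reading: range > 2 * threshold
  pp <- rep(0, n); pp[100] <- 150; pp[200] <- -150
  res3 <- reject_artifacts(as_recording(rbind(O1 = pp, O2 = a)), 160,
                           10, criterion = "peak_to_peak")
  expect_equal(res3$report$rejected_s, 0) # range 300 < 320
  res4 <- reject_artifacts(as_recording(rbind(O1 = pp, O2 = a)), 140,
                           10, criterion = "peak_to_peak")
  expect_equal(res4$report$rejected_s, 10) # range 300 > 280
})

test_that("duration accounting is exact and retained samples preserve order", {
  rec <- simulate_subject(default_band_specs(), artifact_spec(),
                          duration = 120, seed = 10)
  rec <- trim_boundaries(apply_filters(rec), 20)
  for (thr in c(75, 100, 125)) {
    res <- reject_artifacts(rec, thr, 10)
    expect_identical(res$report$rejected_s + res$report$retained_s,
                     res$report$analyzed_s)
  }
  # order preservation: tag the signal with its sample index
  n <- 256L * 60L
  idx_rec <- as_recording(rbind(O1 = seq_len(n) / n * 10, O2 = rep(0, n)))
  idx_rec$samples[1, 5000] <- 1e4
  res <- reject_artifacts(idx_rec, 100, 10)
  expect_false(is.unsorted(res$clean$samples[1, res$clean$samples[1, ] < 1e3]))
})

test_that("the calibrated transient rate lands cohort-mean rejection in a 5-20% band", {
  coh <- simulate_cohort(4, artifact_spec = artifact_spec(),
                         duration = 120, seed = 314)
  pp <- preprocess_cohort(coh)
  pct <- vapply(pp$reports, function(r) r$rejected_pct, 0)
  expect_gte(mean(pct), 5)
  expect_lte(mean(pct), 20)
})

test_that("rejected duration is monotonically non-increasing in the threshold", {
  coh <- lapply(1:3, function(i) {
    simulate_subject(default_band_specs(), artifact_spec(),
                     duration = 120, seed = 40 + i)
  })
  for (rec in coh) {
    rec <- trim_boundaries(apply_filters(rec), 20)
    rej <- vapply(c(75, 100, 125),
                  function(t) reject_artifacts(rec, t, 10)$report$rejected_s, 0)
    expect_true(all(diff(rej) <= 0))
  }
})

fake_report <- function(rejected_s, group, analyzed_s = 560) {
  structure(list(subject_id = "X", group = group, threshold = 100,
                 epoch_s = 10, criterion = "absolute", keep_mask = logical(),
                 analyzed_s = analyzed_s,
                 retained_s = analyzed_s - rejected_s, rejected_s = rejected_s,
                 retained_pct = 100 * (analyzed_s - rejected_s) / analyzed_s,
                 rejected_pct = 100 * rejected_s / analyzed_s),
            class = "artifact_report")
}

test_that("retention summary reproduces group statistics and the Welch comparison", {
  gd <- lapply(c(55, 63, 71), fake_report, group = "GD")
  hc <- lapply(c(50, 60, 70), fake_report, group = "HC")
  tab <- retention_summary(list(GD = gd, HC = hc))
  expect_equal(tab$rejected_s_mean, c(63, 60))
  expect_equal(tab$rejected_pct_mean, c(63, 60) / 560 * 100)
  oracle <- stats::t.test(c(55, 63, 71), c(50, 60, 70))
  expect_equal(tab$welch_t[1], unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(tab$welch_df[1], unname(oracle$parameter), tolerance = 1e-12)
  # same group values on both sides -> t = 0; constant group -> CV = 0
  same <- retention_summary(list(GD = hc, HC = hc))
  expect_equal(same$welch_t[1], 0)
  const_gd <- lapply(c(60, 60, 60), fake_report, group = "GD")
  tab2 <- retention_summary(list(GD = const_gd, HC = hc))
  expect_equal(tab2$cv_pct[1], 0)
})

test_that("threshold sensitivity tables are monotone and collapse to the single summary", {
  coh <- simulate_cohort(3, artifact_spec = artifact_spec(),
                         duration = 120, seed = 77)
  filtered <- lapply(coh, function(r) trim_boundaries(apply_filters(r), 20))
  tab <- threshold_sensitivity(filtered, c(75, 100, 125), 10)
  for (g in c("GD", "HC")) {
    rows <- tab[tab$group == g, ]
    expect_true(all(diff(rows$rejected_pct_mean[order(rows$threshold)]) <= 0))
  }
  single <- threshold_sensitivity(filtered, 100, 10)
  reports <- lapply(filtered, function(r) reject_artifacts(r, 100, 10)$report)
  by_group <- split(reports, vapply(filtered, `[[`, "", "group"))
  expect_equal(single, retention_summary(by_group[c("GD", "HC")]))
  expect_error(threshold_sensitivity(filtered, c(100, 100)), "distinct")
})
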
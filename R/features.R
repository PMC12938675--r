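# Feature extraction: band power, Welch PSD features, temporal moments,
# Hjorth parameters, entropies, and the subjects x features matrix.

#' Welch power spectral density
#'
#' Hamming-tapered segments with 50% overlap; each segment is mean-removed
#' before tapering. One-sided density scaling, so the integral of the PSD
#' over frequency approximates the signal variance.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length in seconds (frequency resolution
#'   `1/window_s`).
#' @param overlap Fractional overlap between segments.
#' @return List with `frequencies` (Hz) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  nw <- round(window_s * fs)
  n <- length(x)
  if (n < nw) stop("signal shorter than one Welch window", call. = FALSE)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nw - 1) / (nw - 1)) # Hamming
  U <- sum(w^2)
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  nfreq <- nw %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + (Mod(X)^2)
  }
  psd <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when nw even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nw %% 2 == 0) dbl[nfreq] <- 1
  list(frequencies = seq(0, nfreq - 1) * fs / nw, psd = psd * dbl)
}

#' Absolute and relative band power
#'
#' Absolute power is the mean squared amplitude (uV^2) of a band-limited
#' signal; relative power is each band's share of the five-band total.
#'
#' @param band_signal One band-limited signal.
#' @return Scalar absolute power.
#' @export
band_power <- function(band_signal) {
  if (length(band_signal) == 0) stop("empty signal", call. = FALSE)
  mean(band_signal^2)
}

#' @rdname band_power
#' @param abs_powers Named vector of the five bands' absolute powers.
#' @return `rel_power()`: vector of relative powers summing to 1.
#' @export
rel_power <- function(abs_powers) {
  tot <- sum(abs_powers)
  if (tot == 0) stop("all five band powers are zero; relative power undefined", call. = FALSE)
  abs_powers / tot
}

#' PSD-derived band features
#'
#' Peak frequency per band (frequency of maximum PSD inside the band,
#' lowest-frequency bin on ties) and the Theta/Alpha, Theta/Beta and
#' Beta/Alpha ratios of band-integrated PSD power. Spectral bins in the
#' 45-55 Hz mains guard band are excluded from all integrations.
#'
#' @param frequencies,psd A Welch PSD (see [welch_psd()]).
#' @param ranges Named list of band ranges (defaults to the nominal bands).
#' @return List with `peak_frequency` (named vector) and `ratios`.
#' @export
psd_band_features <- function(frequencies, psd, ranges = band_ranges()) {
  guard <- frequencies >= 45 & frequencies <= 55
  band_ix <- lapply(ranges, function(r) {
    which(frequencies >= r[1] & frequencies <= r[2] & !guard)
  })
  peak <- vapply(band_ix, function(ix) {
    if (!length(ix)) return(NA_real_)
    frequencies[ix[which.max(psd[ix])]]
  }, 0)
  bp <- vapply(band_ix, function(ix) sum(psd[ix]), 0)
  ratio <- function(num, den) {
    if (bp[[den]] == 0) stop(sprintf("zero %s band power in ratio denominator", den), call. = FALSE)
    bp[[num]] / bp[[den]]
  }
  list(peak_frequency = peak,
       ratios = c(theta_alpha = ratio("Theta", "Alpha"),
                  theta_beta = ratio("Theta", "Beta"),
                  beta_alpha = ratio("Beta", "Alpha")))
}

#' Temporal moment statistics
#'
#' Population-convention moments: skewness `mean((x - mu)^3) / sd^3` and
#' kurtosis as the raw fourth-moment ratio (a Gaussian gives ~3, not 0).
#'
#' @param x Numeric signal.
#' @return Named vector: mean, std, min, max, skewness, kurtosis.
#' @export
temporal_stats <- function(x) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  if (v == 0) stop("constant signal: skewness/kurtosis undefined (sd = 0)", call. = FALSE)
  c(mean = mu, std = sqrt(v), min = min(x), max = max(x),
    skewness = mean((x - mu)^3) / v^1.5,
    kurtosis = mean((x - mu)^4) / v^2)
}

#' Hjorth parameters
#'
#' Activity is the population variance (uV^2); mobility the root variance
#' ratio of the first difference to the signal; complexity the mobility
#' ratio of the first difference to the signal.
#'
#' @param x Numeric signal (length >= 3).
#' @return Named vector: activity, mobility, complexity.
#' @export
hjorth <- function(x) {
  if (length(x) < 3) stop("need >= 3 samples", call. = FALSE)
  dx <- diff(x)
  ddx <- diff(dx)
  v0 <- pop_var(x); v1 <- pop_var(dx); v2 <- pop_var(ddx)
  if (v0 == 0 || v1 == 0) stop("zero variance: Hjorth parameters undefined", call. = FALSE)
  mob <- sqrt(v1 / v0)
  c(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Shannon entropy of the amplitude histogram
#'
#' Amplitudes are binned into `n_bins` equal-width bins spanning the
#' per-signal \[min, max\] range; probabilities are bin counts / N and
#' empty bins contribute nothing. A constant signal occupies one bin and
#' returns 0 by convention.
#'
#' @param x Numeric signal.
#' @param n_bins Number of histogram bins.
#' @return Entropy in bits, in \[0, log2(n_bins)\].
#' @export
shannon_entropy <- function(x, n_bins = 64) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = n_bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the Welch PSD normalized to a probability
#' distribution, divided by the log of the number of spectral bins; near 0
#' for a pure tone, near 1 for white noise, invariant to amplitude scale.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate.
#' @param window_s Welch window (s).
#' @return Entropy in \[0, 1\].
#' @export
spectral_entropy <- function(x, fs, window_s = 2) {
  w <- welch_psd(x, fs, window_s = window_s)
  tot <- sum(w$psd)
  if (tot == 0) stop("zero signal: no spectral mass", call. = FALSE)
  p <- w$psd / tot
  p <- p[p > 0]
  (-sum(p * log2(p))) / log2(length(w$psd))
}

BAND_FEATURES <- c("AbsPower", "RelPower", "Mean", "Std", "Min", "Max",
                   "Skewness", "Kurtosis", "Activity", "Mobility",
                   "Complexity", "ShannonEntropy", "SpectralEntropy",
                   "PeakFrequency")

# Feature vector for one channel given its band signals and broadband
# cleaned signal.
channel_features <- function(band_signals, broadband, fs,
                             welch_window_s = 2, entropy_bins = 64) {
  absp <- vapply(band_signals, band_power, 0)
  relp <- rel_power(absp)
  wb <- welch_psd(broadband, fs, window_s = welch_window_s)
  psdf <- psd_band_features(wb$frequencies, wb$psd)
  out <- c()
  for (b in names(band_signals)) {
    x <- band_signals[[b]]
    ts <- temporal_stats(x)
    hj <- hjorth(x)
    vals <- c(absp[[b]], relp[[b]], ts[["mean"]], ts[["std"]], ts[["min"]],
              ts[["max"]], ts[["skewness"]], ts[["kurtosis"]],
              hj[["activity"]], hj[["mobility"]], hj[["complexity"]],
              shannon_entropy(x, entropy_bins),
              spectral_entropy(x, fs, window_s = welch_window_s),
              psdf$peak_frequency[[b]])
    names(vals) <- paste(b, BAND_FEATURES, sep = "_")
    out <- c(out, vals)
  }
  ratios <- psdf$ratios
  names(ratios) <- c("ThetaAlphaRatio", "ThetaBetaRatio", "BetaAlphaRatio")
  c(out, ratios)
}

#' Feature vector for one cleaned recording
#'
#' Computes the per-channel, per-band feature set plus channel-level PSD
#' ratios and O1+O2 composite band powers (arithmetic mean of the two
#' channels' powers). In `"concatenated"` mode every feature is evaluated
#' once on the full cleaned signal; in `"segmentwise"` mode the cleaned
#' band-limited signals are cut into `segment_s`-second segments, features
#' are computed per segment (with a shorter Welch window) and averaged
#' within subject.
#'
#' @param rec Cleaned `eeg_recording`.
#' @param mode Aggregation mode.
#' @param segment_s Segment length for segment-wise mode (s).
#' @param welch_window_s Welch window for concatenated mode (s).
#' @param entropy_bins Histogram bins for Shannon entropy.
#' @param levels Wavelet depth.
#' @return Named numeric feature vector.
#' @export
subject_features <- function(rec, mode = c("concatenated", "segmentwise"),
                             segment_s = 10, welch_window_s = 2,
                             entropy_bins = 64, levels = 6L) {
  mode <- match.arg(mode)
  bands_by_ch <- decompose_recording(rec, levels)
  fs <- rec$fs
  per_channel <- function(ch) {
    bands <- bands_by_ch[[ch]]
    broad <- rec$samples[ch, ]
    if (mode == "concatenated") {
      channel_features(bands, broad, fs, welch_window_s, entropy_bins)
    } else {
      seg_len <- round(segment_s * fs)
      n_seg <- length(broad) %/% seg_len
      if (n_seg < 1) stop(sprintf("subject %s: no full %g-s segment retained", rec$subject_id, segment_s), call. = FALSE)
      segs <- lapply(seq_len(n_seg), function(k) {
        idx <- ((k - 1) * seg_len + 1):(k * seg_len)
        channel_features(lapply(bands, `[`, idx), broad[idx], fs,
                         welch_window_s = min(welch_window_s, segment_s / 10),
                         entropy_bins = entropy_bins)
      })
      colMeans(do.call(rbind, segs))
    }
  }
  f1 <- per_channel("O1"); f2 <- per_channel("O2")
  names(f1) <- paste0("O1_", names(f1))
  names(f2) <- paste0("O2_", names(f2))
  comp <- c()
  for (b in EEG_BANDS) {
    for (p in c("AbsPower", "RelPower")) {
      comp[paste0("O1O2_", b, "_", p)] <-
        (f1[[paste0("O1_", b, "_", p)]] + f2[[paste0("O2_", b, "_", p)]]) / 2
    }
  }
  c(f1, f2, comp)
}

#' Build the subjects x features matrix
#'
#' @param cohort_clean List of cleaned `eeg_recording`s.
#' @param mode,segment_s,welch_window_s,entropy_bins,levels Passed to
#'   [subject_features()].
#' @return A `feature_matrix`: tibble with `subject_id`, `group`,
#'   `aggregation_mode`, then one column per feature; attribute
#'   `feature_names` holds the registry order.
#' @export
build_feature_matrix <- function(cohort_clean,
                                 mode = c("concatenated", "segmentwise"),
                                 segment_s = 10, welch_window_s = 2,
                                 entropy_bins = 64, levels = 6L) {
  mode <- match.arg(mode)
  rows <- lapply(cohort_clean, subject_features, mode = mode,
                 segment_s = segment_s, welch_window_s = welch_window_s,
                 entropy_bins = entropy_bins, levels = levels)
  feats <- do.call(rbind, rows)
  if (anyNA(feats) || any(!is.finite(feats))) {
    stop("non-finite feature values produced", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(feats))
  out <- tibble::add_column(
    out,
    subject_id = vapply(cohort_clean, function(r) r$subject_id, ""),
    group = vapply(cohort_clean, function(r) r$group, ""),
    aggregation_mode = mode,
    .before = 1
  )
  attr(out, "feature_names") <- colnames(feats)
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Assemble a feature matrix from precomputed values
#'
#' Wraps an existing subjects x features value matrix (e.g. loaded from a
#' CSV export, or simulated directly for calibration studies) in the
#' `feature_matrix` container used by the statistics and evaluation
#' modules.
#'
#' @param values Numeric matrix, one row per subject, named columns.
#' @param groups Character vector of `"GD"`/`"HC"` labels.
#' @param subject_ids Optional ids (defaults to `S01`, `S02`, ...).
#' @param mode Aggregation-mode tag to record.
#' @return A `feature_matrix` tibble.
#' @export
feature_matrix_from_values <- function(values, groups, subject_ids = NULL,
                                       mode = "concatenated") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("F%03d", seq_len(ncol(values)))
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("S%02d", seq_len(nrow(values)))
  stopifnot(length(groups) == nrow(values))
  out <- tibble::as_tibble(as.data.frame(values))
  out <- tibble::add_column(out, subject_id = subject_ids, group = groups,
                            aggregation_mode = mode, .before = 1)
  attr(out, "feature_names") <- colnames(values)
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Feature columns of a feature matrix as a plain matrix
#' @param fm A `feature_matrix`.
#' @return Numeric matrix (subjects x features).
#' @export
feature_values <- function(fm) {
  meta <- c("subject_id", "group", "aggregation_mode")
  as.matrix(fm[, setdiff(names(fm), meta)])
}

#' End-to-end preprocessing of a cohort
#'
#' Applies the standard filter chain, boundary trims and artifact
#' rejection to every recording.
#'
#' @param cohort List of raw `eeg_recording`s.
#' @param fspec A [filter_spec()].
#' @param trim_s Boundary trim (s).
#' @param threshold_uV,epoch_s Artifact rejection parameters.
#' @return List with `clean` (cleaned recordings) and `reports`
#'   (artifact reports).
#' @export
preprocess_cohort <- function(cohort, fspec = filter_spec(), trim_s = 20,
                              threshold_uV = 100, epoch_s = 10) {
  res <- lapply(cohort, function(rec) {
    reject_artifacts(trim_boundaries(apply_filters(rec, fspec), trim_s),
                     threshold_uV = threshold_uV, epoch_s = epoch_s)
  })
  list(clean = lapply(res, `[[`, "clean"),
       reports = lapply(res, `[[`, "report"))
}
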
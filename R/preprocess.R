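# Preprocessing: zero-phase band-limiting + 50 Hz notch, boundary trimming,
# epoch-wise amplitude artifact rejection, and retention accounting.

#' Filter specification
#'
#' Defaults implement the standard pipeline: 4th-order zero-phase
#' (forward-backward) Butterworth high-pass at 0.5 Hz and low-pass at
#' 50 Hz, with a second-order IIR notch at 50 Hz (quality factor 30,
#' ~1.7 Hz bandwidth) applied before the final low-pass.
#'
#' @param hp_cutoff,lp_cutoff High-/low-pass cutoffs in Hz.
#' @param order Butterworth order (even, forward-backward symmetric).
#' @param notch_freq Notch centre frequency (Hz); `NA` disables the notch.
#' @param notch_q Notch quality factor (centre / -3 dB bandwidth).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(hp_cutoff = 0.5, lp_cutoff = 50, order = 4,
                        notch_freq = 50, notch_q = 30) {
  if (hp_cutoff >= lp_cutoff) stop("hp_cutoff must be < lp_cutoff", call. = FALSE)
  if (order %% 2 != 0) stop("order must be even", call. = FALSE)
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff, order = order,
                 notch_freq = notch_freq, notch_q = notch_q),
            class = "filter_spec")
}

# Forward-backward filtering with odd-reflective padding (>= 3 filter
# lengths, capped at 3 s) so start-up transients never reach the data.
filtfilt_refl <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L) * 10L, 768L))
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  ext <- c(pre, x, post)
  y <- rev(signal::filter(b, a, rev(signal::filter(b, a, ext))))
  y[(npad + 1):(npad + n)]
}

# RBJ-cookbook second-order IIR notch.
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Apply zero-phase band-limiting and notch filters
#'
#' Stage order: high-pass, notch, low-pass (the notch precedes the final
#' low-pass). Each stage is applied forward-backward, so the net response
#' has no group delay and the effective attenuation is the squared
#' single-pass magnitude.
#'
#' @param rec An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @return Filtered `eeg_recording`.
#' @export
apply_filters <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  if (spec$lp_cutoff >= nyq) stop("lp_cutoff must be below Nyquist", call. = FALSE)
  if (ncol(rec$samples) <= 6 * spec$order) stop("signal too short to filter", call. = FALSE)
  hp <- signal::butter(spec$order, spec$hp_cutoff / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$lp_cutoff / nyq, type = "low")
  nt <- if (is.finite(spec$notch_freq %||% NA)) notch_coefs(spec$notch_freq, rec$fs, spec$notch_q)
  out <- rec
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    x <- filtfilt_refl(hp$b, hp$a, x)
    if (!is.null(nt)) x <- filtfilt_refl(nt$b, nt$a, x)
    x <- filtfilt_refl(lp$b, lp$a, x)
    out$samples[ch, ] <- x
  }
  out
}

#' Discard recording boundaries
#'
#' Removes `trim_s` seconds from each end (impedance stabilization at the
#' start, filter edge effects at the end); a 600 s recording with the
#' default 20 s trim leaves 560 s of analyzable data.
#'
#' @param rec An `eeg_recording`.
#' @param trim_s Seconds trimmed from each boundary.
#' @return Trimmed `eeg_recording`.
#' @export
trim_boundaries <- function(rec, trim_s = 20) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (trim_s < 0) stop("trim_s must be >= 0", call. = FALSE)
  if (trim_s == 0) return(rec)
  n <- ncol(rec$samples)
  k <- round(trim_s * rec$fs)
  if (n <= 2 * k) {
    stop(sprintf("recording (%g s) too short for a %g s trim at each end",
                 rec$duration, trim_s), call. = FALSE)
  }
  out <- rec
  out$samples <- rec$samples[, (k + 1):(n - k), drop = FALSE]
  out$duration <- ncol(out$samples) / rec$fs
  out
}

#' Epoch-wise amplitude artifact rejection
#'
#' Splits the recording into consecutive non-overlapping epochs of
#' `epoch_s` seconds and rejects an epoch when either channel violates the
#' amplitude criterion; surviving epochs are concatenated in temporal
#' order. The caller is expected to pass high-pass-filtered data (the
#' criterion reflects post-filter excursions, not raw voltage).
#'
#' @param rec An `eeg_recording` (already high-pass filtered).
#' @param threshold_uV Amplitude threshold in uV.
#' @param epoch_s Epoch length in seconds.
#' @param criterion `"absolute"` rejects when `max(|x|) > threshold`
#'   (strict: an extreme exactly at threshold is retained); the literal
#'   `"peak_to_peak"` reading rejects when `max(x) - min(x) > 2 * threshold`.
#' @return List with `clean` (concatenated `eeg_recording`) and `report`
#'   (an `artifact_report`: keep mask, retained/rejected seconds and
#'   percentages against the analyzed duration).
#' @export
reject_artifacts <- function(rec, threshold_uV = 100, epoch_s = 10,
                             criterion = c("absolute", "peak_to_peak")) {
  stopifnot(inherits(rec, "eeg_recording"))
  criterion <- match.arg(criterion)
  if (threshold_uV <= 0) stop("threshold_uV must be > 0", call. = FALSE)
  if (epoch_s <= 0) stop("epoch_s must be > 0", call. = FALSE)
  n <- ncol(rec$samples)
  len <- round(epoch_s * rec$fs)
  starts <- seq(1L, n, by = len)
  keep <- logical(length(starts))
  for (e in seq_along(starts)) {
    idx <- starts[e]:min(n, starts[e] + len - 1L)
    seg <- rec$samples[, idx, drop = FALSE]
    bad <- if (criterion == "absolute") {
      any(apply(abs(seg), 1, max) > threshold_uV)
    } else {
      any(apply(seg, 1, function(v) max(v) - min(v)) > 2 * threshold_uV)
    }
    keep[e] <- !bad
  }
  keep_idx <- unlist(lapply(which(keep), function(e) {
    starts[e]:min(n, starts[e] + len - 1L)
  }), use.names = FALSE)
  clean <- rec
  clean$samples <- rec$samples[, keep_idx, drop = FALSE]
  clean$duration <- length(keep_idx) / rec$fs
  analyzed_s <- n / rec$fs
  retained_s <- length(keep_idx) / rec$fs
  rejected_s <- analyzed_s - retained_s
  report <- structure(list(
    subject_id = rec$subject_id, group = rec$group,
    threshold = threshold_uV, epoch_s = epoch_s, criterion = criterion,
    keep_mask = keep,
    analyzed_s = analyzed_s, retained_s = retained_s, rejected_s = rejected_s,
    retained_pct = 100 * retained_s / analyzed_s,
    rejected_pct = 100 * rejected_s / analyzed_s
  ), class = "artifact_report")
  list(clean = clean, report = report)
}

#' Group-level retention summary
#'
#' Per group: mean and SD of retained/rejected seconds and percentages,
#' the coefficient of variation of rejected seconds, and a two-sided Welch
#' t-test comparing rejected seconds between the two groups.
#'
#' @param reports_by_group Named list (`GD`, `HC`) of lists of
#'   `artifact_report`s.
#' @return A tibble, one row per group, with the Welch test replicated on
#'   both rows (`welch_t`, `welch_df`, `welch_p`).
#' @export
retention_summary <- function(reports_by_group) {
  stopifnot(is.list(reports_by_group), length(reports_by_group) == 2)
  grab <- function(reports, f) vapply(reports, function(r) r[[f]], 0)
  for (g in names(reports_by_group)) {
    if (length(reports_by_group[[g]]) < 2) {
      stop(sprintf("group %s needs >= 2 reports", g), call. = FALSE)
    }
  }
  rej <- lapply(reports_by_group, grab, "rejected_s")
  wt <- welch_ttest_samples(rej[[1]], rej[[2]])
  rows <- lapply(names(reports_by_group), function(g) {
    rp <- reports_by_group[[g]]
    rs <- grab(rp, "rejected_s")
    tibble::tibble(
      group = g, n = length(rp),
      threshold = rp[[1]]$threshold,
      retained_s_mean = mean(grab(rp, "retained_s")),
      retained_s_sd = stats::sd(grab(rp, "retained_s")),
      retained_pct_mean = mean(grab(rp, "retained_pct")),
      retained_pct_sd = stats::sd(grab(rp, "retained_pct")),
      rejected_s_mean = mean(rs), rejected_s_sd = stats::sd(rs),
      rejected_pct_mean = mean(grab(rp, "rejected_pct")),
      rejected_pct_sd = stats::sd(grab(rp, "rejected_pct")),
      cv_pct = if (mean(rs) > 0) 100 * stats::sd(rs) / mean(rs) else 0,
      welch_t = wt$t, welch_df = wt$df, welch_p = wt$p
    )
  })
  do.call(rbind, rows)
}

#' Artifact-threshold sensitivity analysis
#'
#' Re-runs rejection and the group retention summary at each threshold
#' (default the strict/standard/permissive +/-75, 100, 125 uV set).
#'
#' @param recs Cohort: list of high-pass-filtered `eeg_recording`s with
#'   `GD`/`HC` group labels.
#' @param thresholds Amplitude thresholds in uV.
#' @param epoch_s Epoch length in seconds.
#' @return A tibble with one row per group x threshold.
#' @export
threshold_sensitivity <- function(recs, thresholds = c(75, 100, 125),
                                  epoch_s = 10) {
  if (any(thresholds <= 0) || anyDuplicated(thresholds)) {
    stop("thresholds must be positive and distinct", call. = FALSE)
  }
  rows <- lapply(sort(thresholds), function(thr) {
    reports <- lapply(recs, function(r) reject_artifacts(r, thr, epoch_s)$report)
    by_group <- split(reports, vapply(recs, function(r) r$group, ""))
    retention_summary(by_group[c("GD", "HC")])
  })
  do.call(rbind, rows)
}
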
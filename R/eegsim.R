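# Synthetic two-channel occipital EEG cohort generator.
#
# Each recording is built additively from five band-limited oscillatory
# processes (Delta..Gamma), a slow drift, a 50 Hz line component, and
# Poisson-timed high-amplitude transients. O2 shares each band's slow
# amplitude envelope with O1 but has partially independent innovations, so
# the inter-channel correlation is positive but below 1.

EEG_BANDS <- c("Delta", "Theta", "Alpha", "Beta", "Gamma")

#' Specification of one oscillatory band component
#'
#' @param band_name One of `"Delta"`, `"Theta"`, `"Alpha"`, `"Beta"`,
#'   `"Gamma"`.
#' @param f_lo,f_hi Band edges in Hz. Defaults are the nominal analysis
#'   bands: Delta 0-4, Theta 4-8, Alpha 8-15, Beta 15-30, Gamma 30-45 Hz.
#' @param mean_amp Root-mean-square amplitude of the band component in uV.
#' @param amp_cv Coefficient of variation of the slow (about 0.1 Hz)
#'   log-normal amplitude envelope; 0 switches modulation off.
#' @param entropy_knob Number in \[0, 1\] controlling within-band spectral
#'   flatness: 0 produces a pure tone at the band centre, 1 noise spanning
#'   the whole band; intermediate values produce proportionally narrower
#'   band-limited noise centred on the band centre.
#' @return A `band_spec` list.
#' @export
band_spec <- function(band_name, f_lo, f_hi, mean_amp,
                      amp_cv = 0.3, entropy_knob = 0.5) {
  band_name <- match.arg(band_name, EEG_BANDS)
  assert_scalar_number(f_lo, "f_lo", lo = 0)
  assert_scalar_number(f_hi, "f_hi", lo = 0)
  if (f_lo >= f_hi) {
    stop(sprintf("band %s: f_lo (%g) must be < f_hi (%g)", band_name, f_lo, f_hi),
         call. = FALSE)
  }
  assert_scalar_number(mean_amp, "mean_amp", lo = 0)
  assert_scalar_number(amp_cv, "amp_cv", lo = 0)
  assert_scalar_number(entropy_knob, "entropy_knob", lo = 0, hi = 1)
  structure(list(band_name = band_name, f_lo = f_lo, f_hi = f_hi,
                 mean_amp = mean_amp, amp_cv = amp_cv,
                 entropy_knob = entropy_knob),
            class = "band_spec")
}

#' Default healthy-control band specifications
#'
#' Amplitudes are conventional occipital magnitudes during a visual task
#' (alpha-dominant, a few to ~10 uV RMS per band); the amplitude scale of
#' the emulated recordings is not pinned by any published value, only the
#' +/-100 uV artifact bound, so these defaults are chosen to sit well inside
#' that bound while leaving injected transients clearly above it.
#'
#' @param fs Sampling rate in Hz (band edges must stay below `fs/2`).
#' @return List of five [band_spec()] objects named by band.
#' @export
default_band_specs <- function(fs = 256) {
  specs <- list(
    Delta = band_spec("Delta", 0,  4,  mean_amp = 8,  amp_cv = 0.30, entropy_knob = 0.8),
    Theta = band_spec("Theta", 4,  8,  mean_amp = 6,  amp_cv = 0.30, entropy_knob = 0.7),
    Alpha = band_spec("Alpha", 8,  15, mean_amp = 10, amp_cv = 0.30, entropy_knob = 0.3),
    Beta  = band_spec("Beta",  15, 30, mean_amp = 4,  amp_cv = 0.30, entropy_knob = 0.6),
    Gamma = band_spec("Gamma", 30, 45, mean_amp = 2,  amp_cv = 0.30, entropy_knob = 0.9)
  )
  for (s in specs) {
    if (s$f_hi > fs / 2) {
      stop(sprintf("band %s: upper edge %g Hz is at or above Nyquist (%g Hz)",
                   s$band_name, s$f_hi, fs / 2), call. = FALSE)
    }
  }
  specs
}

#' Artifact model specification
#'
#' @param transient_rate Sporadic high-amplitude transients per minute
#'   (Poisson). The default 0.7/min yields roughly 6-7 events per 10-min
#'   recording, i.e. about 10-12% of 10-s epochs rejected at +/-100 uV,
#'   matching a realistic dry-electrode artifact burden.
#' @param transient_amp Peak amplitude of a transient in uV.
#' @param drift_amp Amplitude of the slow electrode drift (uV).
#' @param drift_f Drift frequency in Hz (< 0.5).
#' @param line_noise_amp Amplitude of the 50 Hz mains component (uV).
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(transient_rate = 0.7, transient_amp = 180,
                          drift_amp = 30, drift_f = 0.1, line_noise_amp = 5) {
  assert_scalar_number(transient_rate, "transient_rate", lo = 0)
  assert_scalar_number(transient_amp, "transient_amp", lo = 0)
  assert_scalar_number(drift_amp, "drift_amp", lo = 0)
  assert_scalar_number(drift_f, "drift_f", lo = 0, hi = 0.5)
  assert_scalar_number(line_noise_amp, "line_noise_amp", lo = 0)
  structure(list(transient_rate = transient_rate, transient_amp = transient_amp,
                 drift_amp = drift_amp, drift_f = drift_f,
                 line_noise_amp = line_noise_amp),
            class = "artifact_spec")
}

#' Group effect profile applied to the GD group
#'
#' Per-band multiplicative offsets on `mean_amp`, `amp_cv` and
#' `entropy_knob` relative to the healthy-control specifications. The
#' identity profile (all multipliers 1) is the HC/null profile.
#'
#' @param amp_mult,cv_mult,entropy_mult Named numeric vectors (names from
#'   `Delta`..`Gamma`); missing bands default to 1. All values must be > 0;
#'   effective entropy knobs are clipped to \[0, 1\].
#' @return A `group_effect_profile` list.
#' @export
group_effect_profile <- function(amp_mult = NULL, cv_mult = NULL,
                                 entropy_mult = NULL) {
  fill <- function(x) {
    out <- stats::setNames(rep(1, 5), EEG_BANDS)
    if (!is.null(x)) {
      if (is.null(names(x)) || !all(names(x) %in% EEG_BANDS)) {
        stop("effect multipliers must be named by band", call. = FALSE)
      }
      if (any(x <= 0)) stop("effect multipliers must be > 0", call. = FALSE)
      out[names(x)] <- x
    }
    out
  }
  structure(list(amp_mult = fill(amp_mult), cv_mult = fill(cv_mult),
                 entropy_mult = fill(entropy_mult)),
            class = "group_effect_profile")
}

#' Amplitude multiplier achieving a target Cohen's d on band power
#'
#' Solves for the GD/HC band-amplitude ratio m such that the expected
#' Cohen's d of mean-square band power between groups equals `target_d`,
#' under the generator's log-normal between-subject amplitude jitter.
#' With amplitude jitter `exp(N(0, s^2))` (where
#' `s^2 = log(1 + subject_amp_cv^2)`), band power is log-normal with log-SD
#' `2s`, giving
#' `d(m) = (m^2 - 1) / (sqrt(exp(4 s^2) - 1) * sqrt((1 + m^4) / 2))`.
#' The returned multiplier ignores the (small) within-subject estimation
#' noise of band power over a 10-min recording, so realized effects run
#' marginally below the target.
#'
#' @param target_d Desired population Cohen's d (> 0).
#' @param subject_amp_cv Between-subject coefficient of variation of band
#'   amplitude (see [simulate_cohort()]).
#' @return Scalar multiplier m > 1.
#' @export
calibrate_amp_multiplier <- function(target_d, subject_amp_cv = 0.25) {
  assert_scalar_number(target_d, "target_d", lo = 1e-6)
  assert_scalar_number(subject_amp_cv, "subject_amp_cv", lo = 1e-6)
  s2 <- log(1 + subject_amp_cv^2)
  f <- function(m) {
    (m^2 - 1) / (sqrt(exp(4 * s2) - 1) * sqrt((1 + m^4) / 2)) - target_d
  }
  # d(m) is increasing then saturates at sqrt(2)/sqrt(exp(4 s^2) - 1)
  d_max <- sqrt(2) / sqrt(exp(4 * s2) - 1)
  if (target_d >= d_max) {
    stop(sprintf("target_d = %g unreachable: amplitude jitter caps d at %.3g",
                 target_d, d_max), call. = FALSE)
  }
  stats::uniroot(f, c(1 + 1e-9, 1e3), tol = 1e-10)$root
}

#' Default Gaming-Disorder effect profile (spectral slowing)
#'
#' Encodes the qualitative GD/HC contrast the analysis is designed to
#' detect: elevated Delta/Theta/Alpha power with increased Delta
#' variability, mildly reduced Beta power with increased Beta variability,
#' and reduced Gamma irregularity. The Delta amplitude multiplier is
#' calibrated so the expected Cohen's d of Delta band power is
#' `delta_target_d` at the given between-subject jitter.
#'
#' @param delta_target_d Target Cohen's d for Delta band power (default 0.9).
#' @param subject_amp_cv Between-subject amplitude CV used for calibration;
#'   must match the value passed to [simulate_cohort()].
#' @param hc_delta_amp_cv Healthy-control Delta envelope CV (the
#'   [default_band_specs()] value); the GD envelope-CV multiplier also
#'   raises mean band power by `(1 + cv_GD^2) / (1 + cv_HC^2)`, and the
#'   amplitude multiplier is corrected for that factor so the realized d
#'   stays on target.
#' @return A [group_effect_profile()].
#' @export
default_gd_effect <- function(delta_target_d = 0.9, subject_amp_cv = 0.25,
                              hc_delta_amp_cv = 0.30) {
  m_delta <- calibrate_amp_multiplier(delta_target_d, subject_amp_cv)
  delta_cv_mult <- 1.30
  env_power_ratio <- (1 + (hc_delta_amp_cv * delta_cv_mult)^2) /
    (1 + hc_delta_amp_cv^2)
  group_effect_profile(
    amp_mult = c(Delta = m_delta / sqrt(env_power_ratio), Theta = 1.20,
                 Alpha = 1.20, Beta = 0.85, Gamma = 1.05),
    cv_mult = c(Delta = delta_cv_mult, Beta = 1.30),
    entropy_mult = c(Gamma = 0.80)
  )
}

# Band-limited unit-RMS core process via FFT synthesis. entropy_knob
# interpolates the occupied bandwidth from a pure centre-frequency tone
# (knob = 0) to noise spanning the full band (knob = 1).
band_core <- function(n, fs, f_lo, f_hi, entropy_knob) {
  fc <- (f_lo + f_hi) / 2
  width <- entropy_knob * (f_hi - f_lo)
  df <- fs / n
  if (width < df) { # effectively a tone
    phase <- stats::runif(1, 0, 2 * pi)
    x <- sin(2 * pi * fc * seq(0, n - 1) / fs + phase)
  } else {
    lo <- max(f_lo, fc - width / 2)
    hi <- min(f_hi, fc + width / 2)
    z <- stats::rnorm(n)
    X <- stats::fft(z)
    freq <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * df
    X[freq < lo | freq > hi] <- 0
    X[1] <- 0
    x <- Re(stats::fft(X, inverse = TRUE)) / n
  }
  r <- rms(x)
  if (r == 0) rep(0, n) else x / r
}

# Slow multiplicative log-normal envelope with unit mean and the requested
# coefficient of variation; spectral content below env_f Hz.
slow_envelope <- function(n, fs, amp_cv, env_f = 0.1) {
  if (amp_cv <= 0) return(rep(1, n))
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  df <- fs / n
  freq <- c(seq(0, floor(n / 2)), seq(ceiling(n / 2) - 1, 1)) * df
  keep <- freq > 0 & freq <= max(env_f, df)
  Z[!keep] <- 0
  g <- Re(stats::fft(Z, inverse = TRUE)) / n
  sdg <- stats::sd(g)
  if (sdg == 0) return(rep(1, n))
  g <- g / sdg
  s <- sqrt(log(1 + amp_cv^2))
  exp(s * g - s^2 / 2)
}

# Raised-cosine transient pulse of the given peak amplitude and width (s).
transient_pulse <- function(width_s, fs, amp) {
  m <- max(3L, round(width_s * fs))
  amp * 0.5 * (1 - cos(2 * pi * seq_len(m) / (m + 1)))
}

#' Simulate one two-channel occipital EEG recording
#'
#' @param band_specs List of [band_spec()] objects (any subset of the five
#'   bands).
#' @param artifact_spec An [artifact_spec()]; `NULL` for artifact-free.
#' @param fs Sampling rate (Hz).
#' @param duration Recording length in seconds (>= 60).
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param subject_id,group Metadata stored on the recording.
#' @param channel_rho Correlation of the band innovations between O1 and O2
#'   (band envelopes are fully shared).
#' @return An `eeg_recording`: list with `subject_id`, `group`, `fs`,
#'   `duration`, `channels`, `samples` (2 x n matrix, uV), `provenance`.
#' @export
simulate_subject <- function(band_specs, artifact_spec = NULL, fs = 256,
                             duration = 600, seed = 1L,
                             subject_id = "S01", group = "HC",
                             channel_rho = 0.6) {
  if (duration < 60) stop("duration must be >= 60 s", call. = FALSE)
  for (s in band_specs) {
    if (!inherits(s, "band_spec")) stop("band_specs must be band_spec objects", call. = FALSE)
    if (s$f_hi >= fs / 2) {
      stop(sprintf("band %s: upper edge %g Hz is at or above Nyquist (%g Hz)",
                   s$band_name, s$f_hi, fs / 2), call. = FALSE)
    }
  }
  n <- round(fs * duration)
  set.seed(seed)
  o1 <- numeric(n)
  o2 <- numeric(n)
  for (s in band_specs) {
    if (s$mean_amp == 0) next
    env <- slow_envelope(n, fs, s$amp_cv)
    core1 <- band_core(n, fs, s$f_lo, s$f_hi, s$entropy_knob)
    core2i <- band_core(n, fs, s$f_lo, s$f_hi, s$entropy_knob)
    core2 <- channel_rho * core1 + sqrt(1 - channel_rho^2) * core2i
    o1 <- o1 + s$mean_amp * env * core1
    o2 <- o2 + s$mean_amp * env * core2
  }
  if (!is.null(artifact_spec)) {
    a <- artifact_spec
    tt <- seq(0, n - 1) / fs
    if (a$drift_amp > 0 && a$drift_f > 0) {
      o1 <- o1 + a$drift_amp * sin(2 * pi * a$drift_f * tt + stats::runif(1, 0, 2 * pi))
      o2 <- o2 + a$drift_amp * sin(2 * pi * a$drift_f * tt + stats::runif(1, 0, 2 * pi))
    }
    if (a$line_noise_amp > 0) {
      ph <- stats::runif(1, 0, 2 * pi)
      o1 <- o1 + a$line_noise_amp * sin(2 * pi * 50 * tt + ph)
      o2 <- o2 + a$line_noise_amp * sin(2 * pi * 50 * tt + ph + stats::runif(1, -0.3, 0.3))
    }
    if (a$transient_rate > 0 && a$transient_amp > 0) {
      n_ev <- stats::rpois(1, a$transient_rate * duration / 60)
      if (n_ev > 0) {
        starts <- sort(stats::runif(n_ev, 0, duration - 1))
        for (t0 in starts) {
          pulse <- transient_pulse(0.25, fs, a$transient_amp * sign(stats::runif(1) - 0.3))
          i0 <- round(t0 * fs) + 1L
          idx <- i0:min(n, i0 + length(pulse) - 1L)
          seg <- seq_along(idx)
          # shared event, channel-specific severity
          o1[idx] <- o1[idx] + pulse[seg] * stats::runif(1, 0.7, 1.3)
          o2[idx] <- o2[idx] + pulse[seg] * stats::runif(1, 0.7, 1.3)
        }
      }
    }
  }
  samples <- rbind(O1 = o1, O2 = o2)
  structure(list(subject_id = subject_id, group = group, fs = fs,
                 duration = duration, channels = c("O1", "O2"),
                 samples = samples, provenance = "simulated"),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]  %g Hz, %g s, channels: %s (%s)\n",
              x$subject_id, x$group, x$fs, x$duration,
              paste(x$channels, collapse = "/"), x$provenance))
  invisible(x)
}

#' Simulate a labelled GD/HC cohort
#'
#' Generates `2 * n_per_group` recordings with balanced labels and unique
#' subject ids. Each subject's band amplitudes are jittered log-normally
#' (between-subject variability, coefficient of variation
#' `subject_amp_cv`); GD subjects additionally receive the multiplicative
#' `effect` profile before jitter. Per-subject RNG streams are derived from
#' the master seed by counter offset, so the cohort is reproducible
#' subject-by-subject.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param hc_band_specs Healthy-control band specs ([default_band_specs()]).
#' @param effect A [group_effect_profile()] for the GD group; identity for
#'   a null cohort.
#' @param artifact_spec Shared [artifact_spec()] (or `NULL`).
#' @param fs,duration Sampling rate and duration passed to
#'   [simulate_subject()].
#' @param seed Master integer seed.
#' @param subject_amp_cv Between-subject log-normal amplitude CV.
#' @param subject_entropy_sd Between-subject additive jitter (SD) of each
#'   band's entropy knob, clipped to \[0, 1\]; gives shape-type features
#'   (entropies, complexity, peak frequency) realistic within-group
#'   variability so group contrasts on them are not near-deterministic.
#' @return List of `eeg_recording`s (GD first, then HC).
#' @export
simulate_cohort <- function(n_per_group = 15,
                            hc_band_specs = default_band_specs(fs),
                            effect = group_effect_profile(),
                            artifact_spec = NULL,
                            fs = 256, duration = 600, seed = 1L,
                            subject_amp_cv = 0.25,
                            subject_entropy_sd = 0.05) {
  if (n_per_group < 2) stop("n_per_group must be >= 2 (group statistics undefined)", call. = FALSE)
  stopifnot(inherits(effect, "group_effect_profile"))
  groups <- rep(c("GD", "HC"), each = n_per_group)
  ids <- sprintf("%s%02d", groups, c(seq_len(n_per_group), seq_len(n_per_group)))
  out <- vector("list", 2L * n_per_group)
  # all subjects' amplitude jitters come from one sequential stream (rather
  # than one short stream per subject), so they are exchangeable across the
  # GD/HC split by construction; the heavy per-recording streams are then
  # derived per subject from a disjoint counter block
  set.seed(derive_seed(seed, 424243L))
  jit_mat <- matrix(exp(stats::rnorm(5L * length(ids), 0,
                                     sqrt(log(1 + subject_amp_cv^2)))),
                    ncol = 5L, byrow = TRUE,
                    dimnames = list(NULL, EEG_BANDS))
  set.seed(derive_seed(seed, 424247L))
  ent_jit <- matrix(stats::rnorm(5L * length(ids), 0, subject_entropy_sd),
                    ncol = 5L, byrow = TRUE,
                    dimnames = list(NULL, EEG_BANDS))
  for (i in seq_along(ids)) {
    jitter <- jit_mat[i, ]
    specs <- lapply(hc_band_specs, function(s) {
      b <- s$band_name
      amp <- s$mean_amp
      cv <- s$amp_cv
      ent <- s$entropy_knob
      if (groups[i] == "GD") {
        amp <- amp * effect$amp_mult[[b]]
        cv <- cv * effect$cv_mult[[b]]
        ent <- ent * effect$entropy_mult[[b]]
      }
      ent <- min(1, max(0, ent + ent_jit[i, b]))
      band_spec(b, s$f_lo, s$f_hi, amp * jitter[[b]], cv, ent)
    })
    out[[i]] <- simulate_subject(specs, artifact_spec, fs = fs,
                                 duration = duration,
                                 seed = derive_seed(seed, 100003L + i),
                                 subject_id = ids[i], group = groups[i])
  }
  out
}
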
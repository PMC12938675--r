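# Shared fixture builders. Everything is generated in code; heavier shared
# objects are memoized so independent test files do not re-simulate them.

.fixture_cache <- new.env(parent = emptyenv())

rms <- function(x) sqrt(mean(x^2))

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Wrap a raw signal (vector, or 2 x n matrix) as an eeg_recording.
as_recording <- function(x, fs = 256, subject_id = "T01", group = "HC") {
  samples <- if (is.matrix(x)) x else rbind(O1 = x, O2 = x)
  rownames(samples) <- c("O1", "O2")
  structure(list(subject_id = subject_id, group = group, fs = fs,
                 duration = ncol(samples) / fs, channels = c("O1", "O2"),
                 samples = samples, provenance = "simulated"),
            class = "eeg_recording")
}

tone_recording <- function(freq, amp = 10, duration = 120, fs = 256,
                           phase = 0, ...) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  as_recording(amp * sin(2 * pi * freq * tt + phase), fs = fs, ...)
}

# A small preprocessed cohort with the default GD effect, reused by the
# feature/statistics/evaluation tests (n = 4/group keeps it light).
small_clean_cohort <- function() {
  memo("small_clean_cohort", function() {
    coh <- simulate_cohort(4, effect = default_gd_effect(),
                           artifact_spec = artifact_spec(),
                           duration = 120, seed = 20260101)
    preprocess_cohort(coh)
  })
}

small_feature_matrix <- function() {
  memo("small_feature_matrix", function() {
    build_feature_matrix(small_clean_cohort()$clean)
  })
}

# Gaussian feature matrix with labels independent of features (null), or
# with `n_informative` features shifted by `delta` in the GD group.
gaussian_feature_matrix <- function(n_per_group = 6, p = 12, seed = 1,
                                    n_informative = 0, delta = 0) {
  set.seed(seed)
  X <- matrix(stats::rnorm(2 * n_per_group * p), 2 * n_per_group, p)
  groups <- rep(c("GD", "HC"), each = n_per_group)
  if (n_informative > 0) {
    X[groups == "GD", seq_len(n_informative)] <-
      X[groups == "GD", seq_len(n_informative)] + delta
  }
  feature_matrix_from_values(X, groups)
}
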
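# Shared fixtures, built once per test run and cached in this
# environment. All synthetic, all seeded.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A tiny cohort (2 subjects x 2 sessions + 1 external) with features;
# enough for structural and determinism checks.
tiny_cohort <- function() {
  cached("tiny_cohort", make_cohort(cohort_config(
    n_subjects = 2, n_sessions = 2, n_external = 1, seed = 42)))
}

tiny_features <- function() {
  cached("tiny_features", cohort_features(tiny_cohort()))
}

# Strong-session-drift condition used for the leakage-gap checks:
# day-to-day band-power shifts (e^1.2 ~ 3x) and peak jitter (2 Hz sd)
# on the order of the between-subject separation, with moderate
# segment noise, so the session drift dominates within-session noise.
strong_drift_cohort_config <- function(seed) {
  cohort_config(n_subjects = 8, n_sessions = 8, n_external = 0,
                sigma_session = 1.2, sigma_freq = 2.0,
                segment_noise = 1.0, seed = seed)
}

# Pure multichannel test signal: one sinusoid per channel.
sine_segment <- function(freqs, fs = 500, n = 3750, amps = NULL) {
  if (is.null(amps)) amps <- rep(1, length(freqs))
  tt <- seq_len(n) / fs
  samples <- t(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * tt),
                      numeric(n)))
  rownames(samples) <- paste0("ch", seq_along(freqs))
  list(fs = fs, samples = samples, subject_id = "T", session_id = 1L,
       segment_index = 0L)
}

# Provenance table of a synthetic subject: n_sessions x n_segments.
fake_prov <- function(subject, n_sessions, n_segments = 24) {
  expand.grid(subject_id = subject,
              session_id = seq_len(n_sessions),
              segment_index = seq_len(n_segments) - 1L,
              stringsAsFactors = FALSE)[, c("subject_id", "session_id",
                                            "segment_index")]
}

# Linearly separable 2-D toy training set; separability is witnessed by
# the axis rule x1 > 0 which classifies it perfectly.
separable_toy <- function(n_per_class = 20, seed = 5) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n_per_class, 3, 0.5), rnorm(n_per_class, 0, 1)),
             cbind(rnorm(n_per_class, -3, 0.5), rnorm(n_per_class, 0, 1)))
  labels <- rep(c("genuine", "impostor"), each = n_per_class)
  stopifnot(all((X[, 1] > 0) == (labels == "genuine")))
  list(X = X, labels = labels)
}
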
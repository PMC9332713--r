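#' Configuration of a synthetic EEG verification cohort
#'
#' Describes a resting-state EEG study: a panel of genuine subjects
#' recorded over many sessions on different days, plus a set of external
#' impostors contributing a single session each. Defaults reproduce the
#' reference study design: 29 genuine subjects with 20 sessions each
#' (580 examinations) and 23 single-session external impostors (603
#' recordings in total), 19-channel 10-20 montage, 500 Hz sampling,
#' 3 minutes per session.
#'
#' Noise parameters control the three sources of variability the
#' generator emulates:
#' \describe{
#'   \item{`sigma_session`}{standard deviation of per-band log-power
#'     offsets drawn fresh every session (dimensionless, on the log
#'     scale of power). This is the day-to-day drift that makes
#'     session-disjoint testing harder than within-session testing.}
#'   \item{`sigma_freq`}{standard deviation (Hz) of per-session jitter
#'     of each band's oscillation center frequency.}
#'   \item{`segment_noise`}{standard deviation (microvolts) of white
#'     noise added to every sample; the within-session variability
#'     between 7.5 s segments.}
#'   \item{`subject_spread`}{between-subject dispersion of the
#'     identity-carrying signature parameters (oscillation amplitudes
#'     and center frequencies). Larger values make subjects easier to
#'     tell apart.}
#' }
#'
#' @param n_subjects number of genuine subjects (default 29).
#' @param n_sessions sessions per genuine subject (default 20).
#' @param n_external number of single-session external impostors
#'   (default 23; may be 0).
#' @param sigma_session session-to-session band log-power drift sd.
#' @param sigma_freq session-to-session peak-frequency jitter sd (Hz).
#' @param segment_noise white-noise sd in microvolts.
#' @param subject_spread between-subject signature dispersion in (0, 1].
#' @param fs sampling rate in Hz.
#' @param duration_s recording length in seconds.
#' @param montage character vector of electrode labels.
#' @param seed integer master seed; together with the other fields it
#'   fully determines the cohort.
#' @return An object of class `cohort_config`.
#' @seealso [make_cohort()]
#' @export
cohort_config <- function(n_subjects = 29, n_sessions = 20, n_external = 23,
                          sigma_session = 0.4, sigma_freq = 0.3,
                          segment_noise = 1.0, subject_spread = 0.5,
                          fs = 500, duration_s = 180,
                          montage = default_montage(), seed = 1) {
  stopifnot_scalar_count(n_subjects, "n_subjects")
  stopifnot_scalar_count(n_sessions, "n_sessions")
  stopifnot_scalar_count(n_external, "n_external", min = 0L)
  stopifnot_nonneg(sigma_session, "sigma_session")
  stopifnot_nonneg(sigma_freq, "sigma_freq")
  stopifnot_nonneg(segment_noise, "segment_noise")
  stopifnot_nonneg(subject_spread, "subject_spread")
  if (subject_spread > 1) stop("`subject_spread` must lie in (0, 1]")
  if (anyDuplicated(montage)) stop("montage labels must be unique")
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_sessions = as.integer(n_sessions),
    n_external = as.integer(n_external),
    sigma_session = sigma_session,
    sigma_freq = sigma_freq,
    segment_noise = segment_noise,
    subject_spread = subject_spread,
    fs = fs, duration_s = duration_s,
    montage = montage,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Draw one subject's spectral signature
#'
#' Per (band, channel): an oscillation center frequency and amplitude,
#' plus a 1/f^chi background exponent and scale. The spread parameter
#' scales both the amplitude dispersion (lognormal sdlog) and how far
#' centers may sit from the band midpoint; identity information lives
#' entirely in these draws.
#'
#' @param subject_id identifier stamped on the signature.
#' @param montage electrode labels.
#' @param spread between-subject dispersion in (0, 1].
#' @param seed integer seed.
#' @return Signature list: `centers` and `amplitudes` (bands x channels
#'   matrices), `chi`, `bg_scale`.
#' @export
draw_signature <- function(subject_id, montage, spread, seed) {
  bands <- eeg_bands()
  nb <- nrow(bands); nc <- length(montage)
  with_seed(seed, {
    mid <- (bands$lo_hz + bands$hi_hz) / 2
    halfw <- (bands$hi_hz - bands$lo_hz) / 2
    # centers strictly inside the band: at most 85% of the half-width
    # away from the midpoint
    off <- matrix(stats::runif(nb * nc, -1, 1), nb, nc)
    centers <- mid + off * 0.85 * halfw * max(spread, 0.05)
    amps <- matrix(exp(log(5) + stats::rnorm(nb * nc, 0, spread)), nb, nc)
    list(
      subject_id = subject_id,
      centers = centers,            # bands x channels, Hz
      amplitudes = amps,            # bands x channels, microvolts
      chi = stats::runif(1, 0.8, 1.4),
      bg_scale = stats::runif(1, 1.5, 3.0)
    )
  })
}

#' Draw one session's effect
#'
#' Per-band log-power offsets, per-band peak-frequency jitter, and a
#' mild global gain whose spread is tied to the session drift level.
#' With `sigma_session = sigma_freq = 0` this is exactly the identity
#' effect.
#'
#' @param session_id identifier stamped on the effect.
#' @param sigma_session band log-power offset sd.
#' @param sigma_freq peak-frequency jitter sd (Hz).
#' @param seed integer seed.
#' @return Session-effect list: `band_offsets`, `freq_jitter`, `gain`.
#' @export
draw_session_effect <- function(session_id, sigma_session, sigma_freq, seed) {
  nb <- nrow(eeg_bands())
  with_seed(seed, {
    list(
      session_id = session_id,
      band_offsets = stats::rnorm(nb, 0, sigma_session),
      freq_jitter = stats::rnorm(nb, 0, sigma_freq),
      gain = exp(stats::rnorm(1, 0, 0.2 * sigma_session))
    )
  })
}

#' @rdname draw_session_effect
#' @export
identity_session_effect <- function(session_id = 1L) {
  nb <- nrow(eeg_bands())
  list(session_id = session_id, band_offsets = rep(0, nb),
       freq_jitter = rep(0, nb), gain = 1)
}

#' Generate a synthetic EEG cohort
#'
#' Builds the full study: one spectral signature per subject (genuine
#' and external impostor), one session effect per (subject, session),
#' and a manifest of all recordings. Recordings themselves are rendered
#' on demand by [get_recording()] — each is a pure function of the
#' config seed and its (subject, session) coordinates — so arbitrarily
#' large cohorts never have to be held in memory at once.
#'
#' Genuine subjects are labelled `S01, S02, ...`; external impostors
#' `X01, X02, ...` and carry exactly one session. External impostors are
#' drawn from the same population distribution as genuine subjects, the
#' harder and fairer attack condition.
#'
#' @param config a [cohort_config()].
#' @return An object of class `eeg_cohort` with elements `config`,
#'   `signatures` (named list), `session_effects` (named list keyed
#'   `subject|session`), and `manifest` (data.frame with columns
#'   `subject_id`, `session_id`, `role`).
#' @examples
#' co <- make_cohort(cohort_config(n_subjects = 2, n_sessions = 2,
#'                                 n_external = 1, seed = 7))
#' table(co$manifest$role)
#' @export
make_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  genuine_ids <- sprintf("S%02d", seq_len(config$n_subjects))
  external_ids <- if (config$n_external > 0) {
    sprintf("X%02d", seq_len(config$n_external))
  } else character(0)

  all_ids <- c(genuine_ids, external_ids)
  signatures <- lapply(all_ids, function(id) {
    draw_signature(id, config$montage, config$subject_spread,
                   derive_seed(config$seed, "signature", id))
  })
  names(signatures) <- all_ids

  manifest <- rbind(
    if (length(genuine_ids) > 0) expand.grid(
      subject_id = genuine_ids,
      session_id = seq_len(config$n_sessions),
      stringsAsFactors = FALSE
    ),
    if (length(external_ids) > 0) data.frame(
      subject_id = external_ids, session_id = 1L,
      stringsAsFactors = FALSE
    )
  )
  manifest <- manifest[order(manifest$subject_id, manifest$session_id), ]
  rownames(manifest) <- NULL
  manifest$role <- ifelse(manifest$subject_id %in% genuine_ids,
                          "genuine", "external")

  effects <- vector("list", nrow(manifest))
  names(effects) <- paste(manifest$subject_id, manifest$session_id, sep = "|")
  for (i in seq_len(nrow(manifest))) {
    effects[[i]] <- draw_session_effect(
      manifest$session_id[i], config$sigma_session, config$sigma_freq,
      derive_seed(config$seed, "session", manifest$subject_id[i],
                  manifest$session_id[i])
    )
  }

  structure(list(config = config, signatures = signatures,
                 session_effects = effects, manifest = manifest),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<eeg_cohort> %d genuine subjects x %d sessions (%d recordings), %d external impostors; %d recordings total\n",
    x$config$n_subjects, x$config$n_sessions, sum(m$role == "genuine"),
    x$config$n_external, nrow(m)))
  invisible(x)
}

#' Render one multichannel EEG recording from a signature
#'
#' Synthesizes a channels-by-time microvolt matrix: per (band, channel)
#' a sinusoidal oscillation at the signature's center frequency (plus
#' the session's frequency jitter), with amplitude scaled by the
#' session's band log-power offset and global gain, superimposed on
#' 1/f^chi background noise and white segment noise. Oscillation phases
#' are random per (band, channel, session); phase carries no identity
#' information, consistent with the downstream power-only features.
#'
#' @param signature subject signature as produced inside [make_cohort()].
#' @param effect session effect (see [make_cohort()]); use
#'   `sigma_session = sigma_freq = 0` in the config for the identity
#'   effect.
#' @param seed integer seed for phases and noise.
#' @param fs sampling rate (Hz).
#' @param duration_s recording length (seconds).
#' @param montage electrode labels; its length fixes the channel count.
#' @param segment_noise white-noise sd in microvolts.
#' @param session_id,subject_id identifiers stamped on the result.
#' @return An `eeg_recording`: list with `subject_id`, `session_id`,
#'   `channel_names`, `fs`, `duration_s` and `samples` (channels x time
#'   matrix, microvolts).
#' @export
render_recording <- function(signature, effect, seed,
                             fs = 500, duration_s = 180,
                             montage = default_montage(),
                             segment_noise = 1.0,
                             subject_id = signature$subject_id,
                             session_id = effect$session_id) {
  bands <- eeg_bands()
  nb <- nrow(bands)
  nc <- length(montage)
  n <- round(duration_s * fs)
  tt <- seq_len(n) / fs

  stopifnot(nrow(signature$centers) == nb, ncol(signature$centers) == nc)

  samples <- with_seed(seed, {
    out <- matrix(0, nc, n)
    phases <- matrix(stats::runif(nb * nc, 0, 2 * pi), nb, nc)
    amp_mult <- exp(effect$band_offsets / 2)
    for (ch in seq_len(nc)) {
      x <- numeric(n)
      for (b in seq_len(nb)) {
        f <- signature$centers[b, ch] + effect$freq_jitter[b]
        # keep the jittered peak strictly inside its band
        f <- min(max(f, bands$lo_hz[b] + 0.1), bands$hi_hz[b] - 0.1)
        a <- signature$amplitudes[b, ch] * amp_mult[b]
        x <- x + a * sin(2 * pi * f * tt + phases[b, ch])
      }
      out[ch, ] <- x * effect$gain
    }
    # 1/f^chi background: complex Gaussian spectrum drawn directly in
    # the frequency domain with amplitude f^(-chi/2) (flat below 1 Hz,
    # zero DC), one inverse FFT per channel batch; rescaled afterwards
    # to the signature's background sd
    nh <- floor(n / 2) - 1 # strictly positive, non-Nyquist bins
    shape_h <- pmax(seq_len(nh) * (fs / n), 1)^(-signature$chi / 2)
    re <- matrix(stats::rnorm(nh * nc), nh, nc) * shape_h
    im <- matrix(stats::rnorm(nh * nc), nh, nc) * shape_h
    z <- matrix(0+0i, n, nc)
    z[2:(nh + 1), ] <- complex(real = re, imaginary = im)
    if (n %% 2 == 0) {
      z[n / 2 + 1, ] <- stats::rnorm(nc) *
        pmax(fs / 2, 1)^(-signature$chi / 2)
    }
    z[n:(n - nh + 1), ] <- Conj(z[2:(nh + 1), ])
    bg <- Re(stats::mvfft(z, inverse = TRUE)) / n
    bg_sd <- apply(bg, 2, stats::sd)
    bg <- sweep(bg, 2, ifelse(bg_sd > 0, signature$bg_scale / bg_sd, 0), "*")
    out <- out + t(bg)
    if (segment_noise > 0) {
      out <- out + matrix(stats::rnorm(nc * n, 0, segment_noise), nc, n)
    }
    out
  })
  dimnames(samples) <- list(montage, NULL)

  structure(list(subject_id = subject_id, session_id = session_id,
                 channel_names = montage, fs = fs, duration_s = duration_s,
                 samples = samples),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s session %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$session_id, nrow(x$samples), ncol(x$samples),
              x$fs))
  invisible(x)
}

#' Render one recording of a cohort
#'
#' Deterministically renders the recording for `(subject_id,
#' session_id)`; repeated calls return bit-identical signals.
#'
#' @param cohort an `eeg_cohort` from [make_cohort()].
#' @param subject_id subject label as in the cohort manifest.
#' @param session_id integer session index.
#' @return An `eeg_recording` (see [render_recording()]).
#' @export
get_recording <- function(cohort, subject_id, session_id) {
  key <- paste(subject_id, session_id, sep = "|")
  eff <- cohort$session_effects[[key]]
  sig <- cohort$signatures[[subject_id]]
  if (is.null(eff) || is.null(sig)) {
    stop("no such recording in cohort: ", key)
  }
  cfg <- cohort$config
  render_recording(sig, eff,
                   seed = derive_seed(cfg$seed, "render", subject_id,
                                      session_id),
                   fs = cfg$fs, duration_s = cfg$duration_s,
                   montage = cfg$montage,
                   segment_noise = cfg$segment_noise,
                   subject_id = subject_id, session_id = session_id)
}

#' Export cohort signatures as a JSON sidecar
#'
#' Writes the per-subject signature parameters (centers, amplitudes,
#' background exponent and scale) to JSON so downstream checks can use
#' the generating truth as an oracle.
#'
#' @param cohort an `eeg_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signatures_json <- function(cohort, path) {
  sigs <- lapply(cohort$signatures, function(s) {
    list(subject_id = s$subject_id, chi = s$chi, bg_scale = s$bg_scale,
         centers_hz = s$centers, amplitudes_uv = s$amplitudes)
  })
  jsonlite::write_json(sigs, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
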
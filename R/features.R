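#' Common average reference
#'
#' Re-references a recording by subtracting, at every time sample, the
#' mean across all channels. After CAR the across-channel mean is zero
#' everywhere. This is the only preprocessing applied before feature
#' extraction: no filtering and no artifact removal, imitating the
#' conditions of a practical verification system.
#'
#' @param recording an `eeg_recording` (or bare channels x time matrix).
#' @return Same type as the input, re-referenced.
#' @export
apply_car <- function(recording) {
  samples <- if (inherits(recording, "eeg_recording")) {
    recording$samples
  } else recording
  if (!is.matrix(samples) || nrow(samples) < 2) {
    stop("CAR requires at least 2 channels")
  }
  out <- sweep(samples, 2, colMeans(samples), "-")
  if (inherits(recording, "eeg_recording")) {
    recording$samples <- out
    recording
  } else out
}

#' Split a recording into fixed-length segments
#'
#' Cuts the recording into non-overlapping consecutive segments of
#' `seg_len_s` seconds; a trailing remainder shorter than one segment is
#' discarded. At the defaults (180 s at 500 Hz, 7.5 s segments) this
#' yields 24 segments of 3750 samples.
#'
#' @param recording an `eeg_recording`.
#' @param seg_len_s segment length in seconds (default 7.5).
#' @return List of segments; each is a list with `subject_id`,
#'   `session_id`, `segment_index` (0-based) and `samples`
#'   (channels x samples matrix).
#' @export
segment_recording <- function(recording, seg_len_s = 7.5) {
  stopifnot(inherits(recording, "eeg_recording"))
  seg_n <- round(seg_len_s * recording$fs)
  total <- ncol(recording$samples)
  n_seg <- floor(total / seg_n)
  if (n_seg < 1) stop("recording shorter than one segment")
  lapply(seq_len(n_seg), function(k) {
    idx <- ((k - 1) * seg_n + 1):(k * seg_n)
    list(subject_id = recording$subject_id,
         session_id = recording$session_id,
         segment_index = k - 1L,
         fs = recording$fs,
         samples = recording$samples[, idx, drop = FALSE])
  })
}

#' Welch power spectral density of one segment
#'
#' Averaged modified periodogram per channel: sliding Hamming windows of
#' `window_s` seconds with `overlap_s` seconds of overlap (defaults 1 s
#' and 0.5 s, i.e. 500-sample windows stepped by 250 samples, giving 14
#' windows per 7.5 s segment and a 1 Hz bin spacing). Density scaling:
#' power per Hz, one-sided, so that summing `power * df` over the grid
#' approximates the signal variance.
#'
#' @param segment a segment from [segment_recording()], or an
#'   `eeg_recording` (treated as one long segment), or a bare
#'   channels x time matrix together with `fs`.
#' @param window_s,overlap_s window length and overlap in seconds.
#' @param fs sampling rate; taken from the segment when available.
#' @return List of class `psd_estimate` with `freq` (Hz, from 0 to the
#'   Nyquist frequency) and `power` (channels x frequency matrix,
#'   microvolts squared per Hz), plus `fs` and `n_windows`.
#' @export
welch_psd <- function(segment, window_s = 1, overlap_s = 0.5, fs = NULL) {
  samples <- if (is.matrix(segment)) segment else segment$samples
  if (is.null(fs)) fs <- segment$fs
  if (is.null(fs)) stop("sampling rate `fs` required")
  nwin <- round(window_s * fs)
  step <- nwin - round(overlap_s * fs)
  if (step < 1) stop("overlap must be shorter than the window")
  n <- ncol(samples)
  if (n < nwin) stop("segment shorter than one window")
  starts <- seq(1, n - nwin + 1, by = step)
  nw <- length(starts)
  nch <- nrow(samples)
  w <- as.numeric(signal::hamming(nwin))
  scale <- 1 / (fs * sum(w^2)) # density normalization
  nfreq <- floor(nwin / 2) + 1

  # gather all (window, channel) slices into one nwin x (nw * nch)
  # matrix, window index varying fastest, and FFT them in one batch
  ridx <- as.vector(outer(seq_len(nwin), starts - 1L, "+"))
  M <- t(samples)[ridx, , drop = FALSE] # (nwin * nw) x nch
  dim(M) <- c(nwin, nw * nch)
  M <- M - rep(.colMeans(M, nwin, nw * nch), each = nwin) # demean window
  z <- stats::mvfft(M * w)
  p <- Mod(z[seq_len(nfreq), , drop = FALSE])^2 * scale
  # one-sided: double everything except DC (and Nyquist when nwin even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nwin %% 2 == 0) dbl[nfreq] <- 1
  p <- p * dbl
  # average the nw windows of each channel
  dim(p) <- c(nfreq * nw, nch)
  pow <- t(vapply(seq_len(nch), function(ch) {
    .rowMeans(matrix(p[, ch], nfreq, nw), nfreq, nw)
  }, numeric(nfreq)))
  rownames(pow) <- rownames(samples)
  structure(list(freq = (seq_len(nfreq) - 1) * fs / nwin,
                 power = pow,
                 fs = fs, n_windows = nw),
            class = "psd_estimate")
}

# Frequency-bin indices of a band under the half-open [lo, hi)
# convention; boundary bins (4, 8, 12, 30 Hz) belong to the band whose
# lower edge they equal.
band_bin_idx <- function(freq, lo_hz, hi_hz) {
  which(freq >= lo_hz & freq < hi_hz)
}

#' Spectral features of one band
#'
#' The three per-channel features computed from a PSD estimate for one
#' frequency band:
#' \enumerate{
#'   \item normalized peak frequency: the band's argmax frequency
#'     divided by the sampling frequency (bin-center argmax, no
#'     interpolation; ties broken toward the lowest frequency);
#'   \item peak-to-mean power ratio: maximum bin power in the band
#'     divided by the mean bin power in the band (1 for a flat PSD);
#'   \item relative band power: summed band power divided by the total
#'     power over the analysis range `total_range` (default 1--45 Hz,
#'     the union of the five canonical bands, which excludes DC drift
#'     and the power-line region).
#' }
#'
#' @param psd a `psd_estimate` from [welch_psd()].
#' @param band one-row data.frame with `lo_hz`, `hi_hz` (see
#'   [eeg_bands()]).
#' @param total_range length-2 numeric: half-open analysis range for the
#'   relative-power denominator. Use `c(0, Inf)` for the full spectrum
#'   convention.
#' @return Matrix channels x 3 with columns `npf`, `p2m`, `rbp`.
#' @export
band_features <- function(psd, band, total_range = c(1, 45)) {
  idx <- band_bin_idx(psd$freq, band$lo_hz, band$hi_hz)
  if (length(idx) == 0) stop("band contains no frequency bins")
  tot_idx <- band_bin_idx(psd$freq, total_range[1], total_range[2])
  bp <- psd$power[, idx, drop = FALSE]
  peak_pos <- apply(bp, 1, which.max) # ties -> lowest frequency
  peak_pow <- bp[cbind(seq_len(nrow(bp)), peak_pos)]
  mean_pow <- rowMeans(bp)
  tot_pow <- rowSums(psd$power[, tot_idx, drop = FALSE])
  band_pow <- rowSums(bp)
  out <- cbind(
    npf = psd$freq[idx[peak_pos]] / psd$fs,
    p2m = ifelse(mean_pow > 0, peak_pow / mean_pow, 1),
    rbp = ifelse(tot_pow > 0, band_pow / tot_pow, 0)
  )
  rownames(out) <- rownames(psd$power)
  out
}

# Feature column names in canonical (band, channel, feature) order.
feature_names <- function(bands, montage) {
  unlist(lapply(bands, function(b) {
    unlist(lapply(montage, function(ch) {
      paste(b, ch, c("npf", "p2m", "rbp"), sep = ".")
    }))
  }))
}

#' Build the ordered feature vector of one segment
#'
#' Concatenates the three band features over bands (canonical order
#' delta, theta, alpha, beta, gamma restricted to `band_set`), then
#' channels in montage order, then the three features. With 19 channels
#' this yields 57 values per band and 285 for all five bands. CAR is
#' assumed to have been applied upstream.
#'
#' @param segment a segment from [segment_recording()].
#' @param band_set character vector of band names (nonempty).
#' @param total_range see [band_features()].
#' @return Named numeric vector of length `57 * length(band_set)` for a
#'   19-channel montage.
#' @export
build_feature_vector <- function(segment, band_set = eeg_bands()$name,
                                 total_range = c(1, 45)) {
  if (length(band_set) == 0) stop("band_set must be nonempty")
  bands <- eeg_bands(band_set) # canonical order enforced here
  psd <- welch_psd(segment)
  vals <- unlist(lapply(seq_len(nrow(bands)), function(b) {
    as.vector(t(band_features(psd, bands[b, ], total_range)))
  }))
  names(vals) <- feature_names(bands$name, rownames(segment$samples))
  vals
}

#' Extract the feature table of a whole cohort
#'
#' Renders every recording in the manifest (or the subset given), applies
#' CAR, segments it, and computes all-band feature vectors. Recordings
#' are rendered and discarded one at a time, so memory stays bounded by
#' one recording plus the feature matrix.
#'
#' @param cohort an `eeg_cohort`.
#' @param manifest optional subset of `cohort$manifest` rows to process.
#' @param seg_len_s segment length in seconds.
#' @param total_range denominator range for relative band power.
#' @param verbose print one line per 50 recordings.
#' @return List of class `feature_table`: `features` (segments x 285
#'   matrix, rows keyed by `subject|session|segment`), `provenance`
#'   (data.frame with `subject_id`, `session_id`, `segment_index`,
#'   `role`) and `montage`.
#' @export
cohort_features <- function(cohort, manifest = cohort$manifest,
                            seg_len_s = 7.5, total_range = c(1, 45),
                            verbose = FALSE) {
  all_bands <- eeg_bands()$name
  rows <- list(); prov <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- get_recording(cohort, manifest$subject_id[i],
                         manifest$session_id[i])
    rec <- apply_car(rec)
    segs <- segment_recording(rec, seg_len_s)
    nfeat <- 3L * length(cohort$config$montage) * length(all_bands)
    mat <- t(vapply(segs, build_feature_vector, numeric(nfeat),
                    band_set = all_bands, total_range = total_range))
    rows[[i]] <- mat
    prov[[i]] <- data.frame(
      subject_id = manifest$subject_id[i],
      session_id = manifest$session_id[i],
      segment_index = vapply(segs, `[[`, integer(1), "segment_index"),
      role = manifest$role[i],
      stringsAsFactors = FALSE
    )
    if (verbose && i %% 50 == 0) {
      message(sprintf("features: %d/%d recordings", i, nrow(manifest)))
    }
  }
  features <- do.call(rbind, rows)
  provenance <- do.call(rbind, prov)
  rownames(features) <- prov_key(provenance$subject_id,
                                 provenance$session_id,
                                 provenance$segment_index)
  structure(list(features = features, provenance = provenance,
                 montage = cohort$config$montage),
            class = "feature_table")
}

#' Column indices of a band subset in an all-band feature matrix
#'
#' Selecting a band subset preserves the canonical (band, channel,
#' feature) block layout: the returned columns, in order, form exactly
#' the vector [build_feature_vector()] would produce for that
#' `band_set`.
#'
#' @param band_set character vector of band names.
#' @param montage electrode labels (defaults to the standard 19).
#' @return Integer vector of column indices into the 285-column layout.
#' @export
band_set_columns <- function(band_set, montage = default_montage()) {
  all_bands <- eeg_bands()$name
  per_band <- 3L * length(montage)
  keep <- which(all_bands %in% band_set)
  unlist(lapply(keep, function(b) ((b - 1L) * per_band + 1L):(b * per_band)))
}

#' Write a feature table to CSV
#'
#' Long format with one row per (segment, feature) or wide format with
#' one row per segment.
#'
#' @param ft a `feature_table` from [cohort_features()].
#' @param path output path.
#' @param format `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(ft, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    utils::write.csv(cbind(ft$provenance, as.data.frame(ft$features)),
                     path, row.names = FALSE)
  } else {
    nm <- colnames(ft$features)
    parts <- do.call(rbind, strsplit(nm, ".", fixed = TRUE))
    long <- data.frame(
      ft$provenance[rep(seq_len(nrow(ft$provenance)), each = length(nm)),
                    c("subject_id", "session_id", "segment_index")],
      band = rep(parts[, 1], nrow(ft$features)),
      channel = rep(parts[, 2], nrow(ft$features)),
      feature_name = rep(parts[, 3], nrow(ft$features)),
      value = as.vector(t(ft$features)),
      row.names = NULL
    )
    utils::write.csv(long, path, row.names = FALSE)
  }
  invisible(path)
}
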
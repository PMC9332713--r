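#' Canonical EEG frequency bands
#'
#' The five canonical scalp EEG bands used throughout the package:
#' delta (1--4 Hz), theta (4--8 Hz), alpha (8--12 Hz), beta (12--30 Hz)
#' and gamma (30--45 Hz). The gamma upper edge stops at 45 Hz so that the
#' analysis range stays clear of 50 Hz power-line interference. Band
#' membership on the 1 Hz Welch grid follows the half-open convention
#' `[lo, hi)`, so adjacent bands never share a frequency bin.
#'
#' @param names optional character vector restricting the result to a
#'   subset of `c("delta", "theta", "alpha", "beta", "gamma")`; the
#'   canonical order is always preserved regardless of the order given.
#' @return A data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @examples
#' eeg_bands()
#' eeg_bands(c("beta", "alpha"))  # returned in canonical order
#' @export
eeg_bands <- function(names = NULL) {
  bands <- data.frame(
    name  = c("delta", "theta", "alpha", "beta", "gamma"),
    lo_hz = c(1, 4, 8, 12, 30),
    hi_hz = c(4, 8, 12, 30, 45),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) return(bands)
  bad <- setdiff(names, bands$name)
  if (length(bad) > 0) {
    stop("unknown band name(s): ", paste(bad, collapse = ", "))
  }
  bands[bands$name %in% names, , drop = FALSE]
}

#' Standard 19-channel 10-20 scalp montage
#'
#' Electrode labels of the 19 standard scalp positions of the 10-20
#' international placement system, in the fixed order used for feature
#' vector layout.
#'
#' @return Character vector of 19 unique electrode labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Band sets analysed in the experiment grid
#'
#' The ten band sets of the full experiment: the five single bands, the
#' beta band combined with its neighbours (beta+gamma, alpha+beta,
#' alpha+beta+gamma, delta+alpha+beta+gamma) and all five bands.
#'
#' @return Named list; each element is a character vector of band names.
#' @export
canonical_band_sets <- function() {
  list(
    delta = "delta",
    theta = "theta",
    alpha = "alpha",
    beta  = "beta",
    gamma = "gamma",
    "beta+gamma" = c("beta", "gamma"),
    "alpha+beta" = c("alpha", "beta"),
    "alpha+beta+gamma" = c("alpha", "beta", "gamma"),
    "delta+alpha+beta+gamma" = c("delta", "alpha", "beta", "gamma"),
    all = c("delta", "theta", "alpha", "beta", "gamma")
  )
}
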
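test_that("band definitions tile 1-45 Hz without overlap", {
  b <- eeg_bands()
  expect_equal(b$name, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_true(all(b$lo_hz < b$hi_hz))
  expect_equal(b$lo_hz[-1], b$hi_hz[-5]) # adjacent edges meet exactly
  expect_equal(b$lo_hz[1], 1)
  expect_equal(b$hi_hz[5], 45)
  # half-open bins never shared between adjacent bands on the 1 Hz grid
  freq <- 0:250
  owners <- lapply(seq_len(5), function(i) {
    freq[freq >= b$lo_hz[i] & freq < b$hi_hz[i]]
  })
  expect_equal(sum(lengths(owners)), length(unique(unlist(owners))))
  expect_error(eeg_bands("mu"), "unknown band")
})

test_that("common average reference zeroes the across-channel mean", {
  x <- rbind(c(1, 3), c(3, 1))
  expect_equal(apply_car(x), rbind(c(-1, 1), c(1, -1)))
  same <- matrix(5, 4, 10)
  expect_equal(apply_car(same), matrix(0, 4, 10))
  set.seed(1)
  r <- matrix(rnorm(5 * 100), 5, 100)
  expect_equal(colMeans(apply_car(r)), rep(0, 100), tolerance = 1e-12)
  expect_error(apply_car(matrix(1, 1, 10)), "2 channels")
})

test_that("segmentation yields floor(duration / 7.5 s) consecutive segments", {
  rec <- get_recording(tiny_cohort(), "S01", 1)
  segs <- segment_recording(rec)
  expect_length(segs, 24)
  expect_true(all(vapply(segs, function(s) ncol(s$samples), numeric(1)) ==
                  3750))
  expect_equal(vapply(segs, `[[`, integer(1), "segment_index"), 0:23)
  # consecutive and non-overlapping: segment k starts where k-1 ended
  expect_identical(segs[[2]]$samples[, 1], rec$samples[, 3751])
  # short recordings: remainder dropped / error below one segment
  rec10 <- rec; rec10$samples <- rec$samples[, 1:5000]
  expect_length(segment_recording(rec10), 1)
  rec3 <- rec; rec3$samples <- rec$samples[, 1:3000]
  expect_error(segment_recording(rec3), "shorter")
})

test_that("Welch PSD recovers sinusoid peaks with 14 windows and 1 Hz bins", {
  seg <- sine_segment(c(10, 25))
  psd <- welch_psd(seg)
  expect_equal(psd$n_windows, 14)
  expect_equal(diff(psd$freq)[1], 1)
  expect_equal(max(psd$freq), 250)
  expect_true(all(psd$power >= 0))
  expect_equal(psd$freq[which.max(psd$power[1, ])], 10)
  expect_equal(psd$freq[which.max(psd$power[2, ])], 25)
  # zero signal -> all-zero PSD
  z <- welch_psd(matrix(0, 2, 3750), fs = 500)
  expect_equal(max(z$power), 0)
  expect_error(welch_psd(matrix(0, 2, 400), fs = 500), "shorter")
})

test_that("Welch PSD integrates to the white-noise variance (Parseval)", {
  set.seed(99)
  ratios <- replicate(50, {
    x <- matrix(rnorm(3750, sd = 1.7), 1)
    psd <- welch_psd(x, fs = 500)
    sum(psd$power) * 1 / stats::var(x[1, ]) # df = 1 Hz
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("band features match their definitions on a known sinusoid", {
  seg <- sine_segment(10)
  psd <- welch_psd(seg)
  f <- band_features(psd, eeg_bands("alpha"))
  expect_equal(f[1, "npf"], 10 / 500) # normalized peak frequency = 0.02
  expect_gt(f[1, "p2m"], 1)
  expect_gt(f[1, "rbp"], 0.95) # nearly all 1-45 Hz power inside alpha
  # flat PSD in band -> peak/mean ratio exactly 1
  flat <- structure(list(freq = 0:250,
                         power = matrix(1, 1, 251), fs = 500),
                    class = "psd_estimate")
  expect_equal(unname(band_features(flat, eeg_bands("beta"))[1, "p2m"]), 1)
  expect_error(band_features(psd, data.frame(lo_hz = 30.2, hi_hz = 30.4)),
               "no frequency bins")
})

test_that("feature vectors have the documented length and order", {
  seg <- segment_recording(apply_car(get_recording(tiny_cohort(),
                                                   "S01", 1)))[[1]]
  v1 <- build_feature_vector(seg, "beta")
  expect_length(v1, 57)
  v5 <- build_feature_vector(seg)
  expect_length(v5, 285)
  v2 <- build_feature_vector(seg, c("gamma", "beta")) # canonical order
  expect_length(v2, 114)
  expect_equal(names(v2)[1], "beta.Fp1.npf")
  # band-subset columns of the all-band matrix equal the direct build
  cols <- band_set_columns(c("beta", "gamma"))
  expect_equal(unname(v5[cols]), unname(v2))
  expect_error(build_feature_vector(seg, character(0)), "nonempty")
})

test_that("peak frequency always lies inside its half-open band", {
  ft <- tiny_features()
  for (b in seq_len(5)) {
    def <- eeg_bands()[b, ]
    npf <- ft$features[, band_set_columns(def$name)[seq(1, 57, by = 3)]]
    expect_true(all(npf >= def$lo_hz / 500 & npf < def$hi_hz / 500))
  }
})

test_that("relative band powers sum to 1 over the analysis range", {
  ft <- tiny_features()
  rbp_cols <- grep("\\.rbp$", colnames(ft$features))
  # per segment and channel: the five bands partition 1-45 Hz
  rbp <- ft$features[, rbp_cols]
  per_channel <- sapply(default_montage(), function(ch) {
    rowSums(rbp[, grep(paste0("\\.", ch, "\\."), colnames(rbp))])
  })
  expect_equal(unname(as.vector(per_channel)),
               rep(1, length(per_channel)), tolerance = 1e-9)
})

test_that("all three features are invariant to a global gain", {
  seg <- segment_recording(apply_car(get_recording(tiny_cohort(),
                                                   "S02", 1)))[[3]]
  v <- build_feature_vector(seg)
  seg_scaled <- seg
  seg_scaled$samples <- seg$samples * 7.3
  expect_equal(build_feature_vector(seg_scaled), v, tolerance = 1e-12)
})

test_that("feature extraction is deterministic", {
  seg <- segment_recording(apply_car(get_recording(tiny_cohort(),
                                                   "S01", 2)))[[5]]
  expect_identical(build_feature_vector(seg), build_feature_vector(seg))
})

test_that("total-power denominator convention is switchable", {
  seg <- sine_segment(10)
  psd <- welch_psd(seg)
  narrow <- band_features(psd, eeg_bands("alpha"), total_range = c(1, 45))
  full <- band_features(psd, eeg_bands("alpha"), total_range = c(0, Inf))
  expect_gte(narrow[1, "rbp"], full[1, "rbp"])
  # npf and p2m do not depend on the denominator convention
  expect_equal(narrow[1, c("npf", "p2m")], full[1, c("npf", "p2m")])
})

test_that("feature CSV export round-trips the wide table", {
  ft <- tiny_features()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(ft$features))
  expect_equal(back$delta.Fp1.npf, unname(ft$features[, "delta.Fp1.npf"]),
               tolerance = 1e-9)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, path2, format = "long")
  long <- utils::read.csv(path2)
  expect_equal(nrow(long), nrow(ft$features) * 285)
  expect_setequal(unique(long$feature_name), c("npf", "p2m", "rbp"))
})
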
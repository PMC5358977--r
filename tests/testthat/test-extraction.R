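test_that("DPSS tapers are orthonormal with positive even-taper sums", {
  tap <- dpss_tapers(125, 3, 5)
  expect_equal(dim(tap), c(125L, 5L))
  expect_equal(crossprod(tap), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
  expect_gt(sum(tap[, 1]), 0)
  expect_error(dpss_tapers(64, 2, 5), "<=")
  expect_error(extraction_params(n_tapers = 8), "<=")
})

test_that("a strong tone is detected at its frequency, silence is not", {
  sr <- 250000
  tone <- frequency_contour(rep(70, 41), hop = 0.001, "t")
  set.seed(2)
  wav <- synthesize_audio(tone, sr)
  wav <- wav + rnorm(length(wav), 0, 0.01)
  attr(wav, "sample_rate") <- sr
  pts <- detect_tf_points(wav, sr)
  expect_gt(nrow(pts), 20)
  expect_lt(median(abs(pts$freq_khz - 70)), 2)
  expect_true(all(pts$p < 0.01))
  expect_true(all(pts$freq_khz >= 35 & pts$freq_khz <= 115))

  silent <- numeric(5000)
  none <- detect_tf_points(silent, sr)
  expect_equal(nrow(none), 0L)

  expect_error(detect_tf_points(rnorm(1000), 250000,
                                extraction_params(max_freq = 130)),
               "Nyquist")
})

test_that("the F-test false-positive rate on white noise is near its level", {
  set.seed(9)
  sr <- 250000
  noise <- rnorm(0.1 * sr, 0, 0.1)
  params <- extraction_params(overlap_fraction = 0)   # independent windows
  L <- round(params$window_length * sr)
  nfrm <- floor(length(noise) / L)
  tap <- dpss_tapers(L, params$time_bandwidth, params$n_tapers)
  U0 <- colSums(tap); sumU2 <- sum(U0^2)
  nfft <- 2^ceiling(log2(4 * L))
  freqs <- (0:(nfft %/% 2)) * sr / nfft / 1000
  band <- freqs >= params$min_freq & freqs <= params$max_freq
  n_bins <- nfrm * sum(band)
  pts <- detect_tf_points(noise, sr, params)
  frac <- nrow(pts) / n_bins
  expect_gt(frac, 0.002)
  expect_lt(frac, 0.03)
})

test_that("tracing splits on gaps and drops short syllables", {
  sr <- 250000
  burst <- function(f0, n = 31) frequency_contour(rep(f0, n), hop = 0.001, "b")
  w1 <- synthesize_audio(burst(60), sr, pad = 0)
  w2 <- synthesize_audio(burst(90), sr, pad = 0)
  gap <- numeric(round(0.05 * sr))                     # 50 ms silence
  wav <- c(numeric(2500), w1, gap, w2, numeric(2500))
  params <- extraction_params(max_gap = 0.02)
  coll <- trace_contours(detect_tf_points(wav, sr, params), params)
  expect_equal(length(coll), 2L)
  med <- sort(vapply(coll$contours, function(cc) median(cc$freq), 1))
  expect_equal(med, c(60, 90), tolerance = 1)

  # a burst shorter than min_duration disappears
  tiny <- synthesize_audio(burst(70, 3), sr, pad = 0)  # 2 ms
  wav2 <- c(numeric(2500), tiny, numeric(2500))
  coll2 <- trace_contours(detect_tf_points(wav2, sr, params), params)
  expect_equal(length(coll2), 0L)

  empty <- trace_contours(
    data.frame(time = numeric(), freq_khz = numeric(), F = numeric(),
               p = numeric()), params)
  expect_equal(length(empty), 0L)
})

test_that("clipping is flagged at and above the threshold only", {
  expect_false(flag_clipping(0.5 * sin(1:100), 0.99))
  expect_true(flag_clipping(c(numeric(50), 1, numeric(50)), 0.99))
  expect_false(flag_clipping(c(0.999, -0.999), 1.0))
  expect_true(flag_clipping(c(0.999, -1), 1.0))

  # extraction carries the flag onto the affected syllable
  sr <- 250000
  cc <- frequency_contour(rep(70, 41), hop = 0.001, "c")
  wav <- synthesize_audio(cc, sr, amplitude = 0.5)
  coll_ok <- extract_contours(wav, sr)
  expect_false(any(clipped_flags(coll_ok)))
  wav_clip <- pmax(pmin(wav * 3, 1), -1)
  coll_clip <- extract_contours(wav_clip, sr)
  expect_true(all(clipped_flags(coll_clip)))
})

test_that("synthesize -> extract recovers contours and step status", {
  sr <- 250000
  cfg <- repertoire_config(n_individuals = c(WT = 1, HT = 1),
                           n_calls = c(WT = 6, HT = 6),
                           step_probability = c(WT = 0.5, HT = 0.5),
                           seed = 17)
  coll <- generate_repertoire(cfg)
  params <- extraction_params()
  for (cc in coll$contours) {
    wav <- synthesize_audio(cc, sr)
    ex <- extract_contours(wav, sr, params)
    expect_equal(length(ex), 1L)
    e <- ex$contours[[1]]
    rc <- resample_contour(e, cc$hop)
    n <- min(length(rc$freq), length(cc$freq))
    expect_lt(median(abs(rc$freq[1:n] - cc$freq[1:n])), 2)
    # duration recovered within two analysis windows
    expect_lt(abs(contour_duration(e) - contour_duration(cc)),
              2 * params$window_length + 1e-9)
  }
})
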
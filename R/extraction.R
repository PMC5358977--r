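#' Parameters for the audio extraction front-end
#'
#' Controls the simplified multitaper detection and contour tracing: short
#' overlapped segments are Fourier transformed under discrete prolate
#' spheroidal sequence (DPSS) windows, the Thomson harmonic F-test flags
#' time-frequency bins whose tonal power is significantly above the local
#' noise, and per time step the dominant significant bin is traced into a
#' frequency contour.
#'
#' Defaults target 250 kHz recordings: a 0.5 ms window with 50% overlap,
#' time-bandwidth NW = 3 with 5 tapers, analysis band 35-115 kHz, per-bin
#' significance level 0.01 (no multiplicity correction across bins).
#'
#' @param window_length analysis window, seconds.
#' @param overlap_fraction fractional overlap of consecutive windows, `[0, 1)`.
#' @param time_bandwidth DPSS time-bandwidth product NW (unitless).
#' @param n_tapers number of tapers; must satisfy `n_tapers <= 2 NW - 1`.
#' @param f_test_p per-bin significance level of the harmonic F-test.
#' @param min_freq,max_freq analysis band, kHz.
#' @param n_fft FFT length, samples; windows are zero-padded to this length
#'   so the F-test is evaluated on a frequency grid fine enough that tones
#'   falling between the natural bins are not missed. Default: the next
#'   power of two at least 4 times the window length.
#' @param max_gap silent gap (seconds) above which detections split into
#'   separate syllables.
#' @param min_duration syllables shorter than this (seconds) are dropped.
#' @param clip_threshold fraction of full scale at or above which a sample
#'   counts as clipped.
#' @return an object of class `extraction_params`.
#' @export
extraction_params <- function(window_length = 0.0005,
                              overlap_fraction = 0.5,
                              time_bandwidth = 3,
                              n_tapers = 5L,
                              f_test_p = 0.01,
                              n_fft = NULL,
                              min_freq = 35, max_freq = 115,
                              max_gap = 0.01,
                              min_duration = 0.005,
                              clip_threshold = 0.999) {
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("'overlap_fraction' must be in [0, 1)")
  if (n_tapers > 2 * time_bandwidth - 1)
    stop("'n_tapers' must be <= 2 * time_bandwidth - 1")
  if (f_test_p <= 0 || f_test_p >= 1) stop("'f_test_p' must be in (0, 1)")
  if (min_freq >= max_freq) stop("need min_freq < max_freq")
  structure(list(window_length = window_length,
                 overlap_fraction = overlap_fraction,
                 time_bandwidth = time_bandwidth,
                 n_tapers = as.integer(n_tapers), f_test_p = f_test_p,
                 n_fft = n_fft,
                 min_freq = min_freq, max_freq = max_freq,
                 max_gap = max_gap, min_duration = min_duration,
                 clip_threshold = clip_threshold),
            class = "extraction_params")
}

#' Discrete prolate spheroidal sequences
#'
#' Computes the first `k` DPSS (Slepian) tapers of length `n` with
#' time-bandwidth product `nw`, via the eigenvectors of the classic
#' symmetric tridiagonal matrix; tapers are unit-energy and ordered by
#' decreasing in-band energy concentration.
#'
#' @param n taper length, samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (`<= 2 nw - 1`).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 3, k = 5L) {
  if (k > 2 * nw - 1) stop("'k' must be <= 2 * nw - 1")
  w <- nw / n
  t <- seq_len(n) - 1L
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * w)
  off <- t[-1] * (n - t[-1]) / 2
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    s <- sum(tap[, j])
    if (abs(s) > 1e-8 && s < 0) tap[, j] <- -tap[, j]
  }
  tap
}

#' Multitaper harmonic F-test detection of tonal time-frequency points
#'
#' Slides DPSS-tapered windows over the waveform; at every window and
#' frequency bin within the analysis band, the Thomson harmonic F-statistic
#' (df 2, 2K-2) tests whether a sinusoidal line component stands above the
#' locally estimated background. Bins with `p < f_test_p` are returned.
#' All-zero windows yield no points (the F-statistic is undefined there).
#'
#' @param wav numeric waveform (full scale `[-1, 1]`).
#' @param sample_rate Hz; defaults to the waveform's attribute.
#' @param params an [extraction_params()].
#' @return data.frame with columns `time` (window center, s), `freq_khz`,
#'   `F`, `p`.
#' @export
detect_tf_points <- function(wav, sample_rate = attr(wav, "sample_rate"),
                             params = extraction_params()) {
  if (!length(wav)) stop("empty waveform")
  if (is.null(sample_rate)) stop("sample_rate required")
  if (params$max_freq * 1000 > sample_rate / 2)
    stop("analysis band exceeds the Nyquist frequency")
  L <- max(8L, round(params$window_length * sample_rate))
  hop <- max(1L, round(L * (1 - params$overlap_fraction)))
  K <- params$n_tapers
  tap <- dpss_tapers(L, params$time_bandwidth, K)
  U0 <- colSums(tap)
  sumU2 <- sum(U0^2)
  nfft <- if (!is.null(params$n_fft)) as.integer(params$n_fft) else
    2^ceiling(log2(4 * L))
  if (nfft < L) stop("'n_fft' must be at least the window length")

  nfrm <- (length(wav) - L) %/% hop + 1L
  if (nfrm < 1L)
    return(data.frame(time = numeric(), freq_khz = numeric(),
                      F = numeric(), p = numeric()))
  starts <- (seq_len(nfrm) - 1L) * hop + 1L
  freqs <- (0:(nfft %/% 2)) * sample_rate / nfft / 1000   # kHz
  band <- which(freqs >= params$min_freq & freqs <= params$max_freq)
  nb <- length(band)

  frames <- matrix(wav[outer(0:(L - 1L), starts, "+")], L, nfrm)
  active <- colSums(frames^2) > 0
  out_t <- vector("list", nfrm)
  Fcrit_df2 <- 2 * (K - 1)
  padded <- matrix(0, nfft, K)
  for (fi in which(active)) {
    seg <- frames[, fi]
    padded[seq_len(L), ] <- tap * seg
    Y <- mvfft(padded)[band, , drop = FALSE]      # nb x K eigencoefficients
    mu <- (Y %*% U0) / sumU2
    resid <- Y - mu %*% t(U0)
    denom <- rowSums(Mod(resid)^2)
    Fstat <- (K - 1) * Mod(mu[, 1])^2 * sumU2 / pmax(denom, 1e-300)
    p <- pf(Fstat, 2, Fcrit_df2, lower.tail = FALSE)
    keep <- which(p < params$f_test_p)
    if (length(keep))
      out_t[[fi]] <- data.frame(
        time = (starts[fi] - 1L + (L - 1) / 2) / sample_rate,
        freq_khz = freqs[band[keep]], F = Fstat[keep], p = p[keep])
  }
  res <- do.call(rbind, out_t)
  if (is.null(res))
    res <- data.frame(time = numeric(), freq_khz = numeric(),
                      F = numeric(), p = numeric())
  res
}

#' Trace frequency contours from detected time-frequency points
#'
#' Per time step, the frequency of the maximal-F significant point is
#' taken; consecutive detections separated by gaps larger than `max_gap`
#' become separate syllables, and syllables shorter than `min_duration` are
#' dropped. Missing frames inside a syllable are filled by linear
#' interpolation so contours are uniformly sampled at the window hop.
#'
#' @param points data.frame from [detect_tf_points()] (time-sorted).
#' @param params an [extraction_params()].
#' @param hop contour hop in seconds (the window hop of the detection run);
#'   inferred from the point times when omitted.
#' @param individual_id,group metadata stamped on the extracted contours.
#' @return a `usv_collection` (possibly empty).
#' @export
trace_contours <- function(points, params = extraction_params(), hop = NULL,
                           individual_id = "unknown", group = "unknown") {
  if (!nrow(points))
    return(contour_collection(list()))
  points <- points[order(points$time, -points$F), , drop = FALSE]
  best <- points[!duplicated(points$time), , drop = FALSE]
  if (is.null(hop)) {
    dt <- diff(sort(unique(best$time)))
    hop <- if (length(dt)) min(dt) else
      params$window_length * (1 - params$overlap_fraction)
  }
  gaps <- c(0, diff(best$time))
  syll <- cumsum(gaps > params$max_gap + 1e-12)
  contours <- list()
  for (s in unique(syll)) {
    b <- best[syll == s, , drop = FALSE]
    dur <- max(b$time) - min(b$time)
    if (dur < params$min_duration) next
    n <- round(dur / hop) + 1L
    if (n < 2L) next
    tt <- min(b$time) + (seq_len(n) - 1L) * hop
    ff <- approx(b$time, b$freq_khz, xout = pmin(tt, max(b$time)))$y
    contours[[length(contours) + 1L]] <- frequency_contour(
      ff, hop = hop,
      syllable_id = sprintf("%s_s%03d", individual_id, length(contours) + 1L),
      individual_id = individual_id, group = group,
      start_time = min(b$time), clipped = FALSE)
  }
  contour_collection(contours)
}

#' Clipping flag for a waveform
#'
#' `TRUE` iff any sample magnitude is at or above `clip_threshold` times
#' full scale (full scale = 1).
#'
#' @param wav numeric waveform.
#' @param clip_threshold fraction of full scale.
#' @return logical.
#' @export
flag_clipping <- function(wav, clip_threshold = 0.999) {
  any(abs(wav) >= clip_threshold)
}

#' Extract a contour collection from a waveform
#'
#' Runs [detect_tf_points()] and [trace_contours()], then marks each
#' extracted syllable clipped iff the waveform clips anywhere within its
#' time span (plus one window on each side).
#'
#' @inheritParams detect_tf_points
#' @inheritParams trace_contours
#' @return a `usv_collection`.
#' @export
extract_contours <- function(wav, sample_rate = attr(wav, "sample_rate"),
                             params = extraction_params(),
                             individual_id = "unknown", group = "unknown") {
  pts <- detect_tf_points(wav, sample_rate, params)
  coll <- trace_contours(pts, params, hop = NULL,
                         individual_id = individual_id, group = group)
  if (!length(coll)) return(coll)
  pad <- params$window_length
  coll$contours <- lapply(coll$contours, function(cc) {
    i0 <- max(1L, floor((cc$start_time - pad) * sample_rate))
    i1 <- min(length(wav),
              ceiling((cc$start_time + contour_duration(cc) + pad) * sample_rate))
    cc$clipped <- flag_clipping(wav[i0:i1], params$clip_threshold)
    cc
  })
  coll
}
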
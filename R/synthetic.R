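#' Configuration for the synthetic repertoire generator
#'
#' Describes a two-group (or k-group) study design for synthetic mouse-pup
#' isolation-call repertoires: how many individuals per group, how many calls
#' per group, the probability that a call is a step (jump) syllable, and the
#' magnitude of individual-level and sample-level frequency variation.
#'
#' Defaults mirror the study design the package targets: 5 wild-type and 6
#' heterozygous pups, 4718 and 4295 calls, and step probabilities 0.69 and
#' 0.48. Tests and examples pass smaller `n_calls` explicitly.
#'
#' @param groups character vector of group labels.
#' @param n_individuals named integer vector, individuals per group.
#' @param n_calls named integer vector, total calls per group (split as
#'   evenly as possible across that group's individuals).
#' @param step_probability named numeric vector in `[0, 1]`, probability that
#'   a generated call belongs to the step family.
#' @param individual_effect_sd SD (kHz) of the per-individual random shift of
#'   base frequency.
#' @param freq_jitter_sd SD (kHz) of per-sample frequency noise (truncated at
#'   4 SD so non-step contours never cross the step-detection threshold).
#' @param hop contour sampling interval, seconds.
#' @param band numeric length-2, admissible frequency band in kHz; generated
#'   contours stay inside it.
#' @param duration_range numeric length-2, syllable duration range in seconds.
#' @param step_jump_range numeric length-2 (kHz), range of the frequency
#'   discontinuity of step syllables; the lower end must exceed the intended
#'   detection threshold.
#' @param seed integer; one global seed drives a per-individual seed sequence
#'   so adding individuals does not perturb existing ones.
#'
#' @return an object of class `repertoire_config`.
#' @export
repertoire_config <- function(groups = c("WT", "HT"),
                              n_individuals = c(WT = 5L, HT = 6L),
                              n_calls = c(WT = 4718L, HT = 4295L),
                              step_probability = c(WT = 0.69, HT = 0.48),
                              individual_effect_sd = 3,
                              freq_jitter_sd = 0.5,
                              hop = 0.001,
                              band = c(35, 115),
                              duration_range = c(0.015, 0.13),
                              step_jump_range = c(12, 40),
                              seed = 1L) {
  groups <- as.character(groups)
  pick <- function(v, what) {
    if (is.null(names(v))) v <- setNames(rep_len(v, length(groups)), groups)
    if (!all(groups %in% names(v)))
      stop("'", what, "' must be named for every group")
    v[groups]
  }
  n_individuals <- pick(n_individuals, "n_individuals")
  n_calls <- pick(n_calls, "n_calls")
  step_probability <- pick(step_probability, "step_probability")
  if (any(n_individuals < 1L)) stop("each group needs at least 1 individual")
  if (any(n_calls < 1L)) stop("each group needs at least 1 call")
  if (any(step_probability < 0 | step_probability > 1))
    stop("step probabilities must lie in [0, 1]")
  if (individual_effect_sd < 0 || freq_jitter_sd < 0)
    stop("standard deviations must be >= 0")
  if (hop <= 0) stop("'hop' must be > 0")
  if (band[1] <= 0 || band[2] <= band[1]) stop("invalid frequency band")
  structure(list(groups = groups, n_individuals = n_individuals,
                 n_calls = n_calls, step_probability = step_probability,
                 individual_effect_sd = individual_effect_sd,
                 freq_jitter_sd = freq_jitter_sd, hop = hop, band = band,
                 duration_range = duration_range,
                 step_jump_range = step_jump_range,
                 seed = as.integer(seed)),
            class = "repertoire_config")
}

# Non-step template families. Each returns the noiseless trajectory (kHz)
# for n samples. Chevrons are parabolic arcs; sweeps are linear.
.usv_templates <- list(
  flat     = function(n, base, extent) rep(base, n),
  upsweep  = function(n, base, extent) base + extent * seq(0, 1, length.out = n),
  downsweep = function(n, base, extent) base + extent * seq(1, 0, length.out = n),
  chevron  = function(n, base, extent) {
    u <- seq(-1, 1, length.out = n)
    base + extent * (1 - u^2)
  }
)

# One individual's calls, drawn from that individual's own RNG stream.
.generate_individual <- function(ind_id, group, n_calls, p_step, cfg, seed_i) {
  set.seed(seed_i)
  # truncate the individual effect at 3 SD so base frequencies keep a safe
  # margin to the band edges
  ind_shift <- max(-3, min(3, rnorm(1))) * cfg$individual_effect_sd
  lo <- cfg$band[1]; hi <- cfg$band[2]
  jmax <- 4 * cfg$freq_jitter_sd  # jitter is truncated at 4 SD
  families <- names(.usv_templates)
  out <- vector("list", n_calls)
  trunc_jitter <- function(n) {
    if (cfg$freq_jitter_sd == 0) return(numeric(n))
    pmin(pmax(rnorm(n, 0, cfg$freq_jitter_sd), -jmax), jmax)
  }
  for (k in seq_len(n_calls)) {
    dur <- runif(1, cfg$duration_range[1], cfg$duration_range[2])
    n <- max(2L, round(dur / cfg$hop) + 1L)
    base <- runif(1, 55, 90) + ind_shift
    is_step <- runif(1) < p_step
    if (is_step) {
      # the drawn jump is truncated to what fits in the band from this base
      # frequency (with a jitter safety margin), so contours never leave it
      margin <- 3 * jmax + 0.5
      up_room <- hi - margin - base
      dn_room <- base - (lo + margin)
      feas <- max(up_room, dn_room)
      j_hi <- max(cfg$step_jump_range[1], min(cfg$step_jump_range[2], feas))
      jump <- runif(1, cfg$step_jump_range[1], j_hi)
      up_ok <- up_room >= jump
      dn_ok <- dn_room >= jump
      sgn <- if (up_ok && dn_ok) sample(c(-1, 1), 1) else if (up_ok) 1 else -1
      split <- max(1L, min(n - 1L, round(n * runif(1, 0.3, 0.7))))
      f <- c(rep(base, split), rep(base + sgn * jump, n - split)) +
        trunc_jitter(n)
      # re-impose the drawn discontinuity exactly so the step-family
      # invariant (exactly one adjacent jump >= step_jump) survives jitter
      f[(split + 1L):n] <- f[(split + 1L):n] - (f[split + 1L] - f[split]) +
        sgn * jump
    } else {
      fam <- sample(families, 1)
      extent <- switch(fam, flat = 0,
                       chevron = runif(1, 8, 18) * sample(c(-1, 1), 1),
                       runif(1, 8, 22) * sample(c(-1, 1), 1))
      # cap the per-sample slope so that slope + worst-case jitter (2 x the
      # 4 SD truncation) stays strictly below the 10 kHz step threshold;
      # chevrons are steepest at their ends (|df| ~ 4 extent / (n - 1))
      max_ext <- if (fam == "chevron") 1.25 * (n - 1) else 5 * (n - 1)
      extent <- sign(extent) * min(abs(extent), max_ext)
      f <- .usv_templates[[fam]](n, base, extent) + trunc_jitter(n)
      # clamping to the band only flattens extremes; it cannot create an
      # adjacent-sample jump
      f <- pmin(pmax(f, lo + 0.1), hi - 0.1)
    }
    out[[k]] <- frequency_contour(
      f, hop = cfg$hop, syllable_id = sprintf("%s_c%04d", ind_id, k),
      individual_id = ind_id, group = group, start_time = 0, clipped = FALSE)
    attr(out[[k]], "family") <- if (is_step) "step" else fam
  }
  out
}

#' Generate a synthetic USV repertoire
#'
#' Draws a contour collection from the design in `cfg`: per individual, calls
#' are step syllables with the group's step probability, otherwise one of
#' four non-step template families (flat, up/down linear sweeps, parabolic
#' chevrons); base frequencies carry a per-individual random shift, and each
#' sample carries truncated Gaussian jitter. Step syllables contain exactly
#' one adjacent-sample discontinuity drawn from `step_jump_range`; non-step
#' syllables never exceed the detection threshold between adjacent samples.
#'
#' Each generated contour carries a `"family"` attribute recording its
#' template family (ground truth for tests).
#'
#' @param cfg a [repertoire_config()].
#' @return a `usv_collection`; deterministic given `cfg$seed`.
#' @export
generate_repertoire <- function(cfg) {
  stopifnot(inherits(cfg, "repertoire_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  contours <- list()
  for (g in cfg$groups) {
    n_ind <- cfg$n_individuals[[g]]
    total <- cfg$n_calls[[g]]
    per <- rep(total %/% n_ind, n_ind)
    if (total %% n_ind) per[seq_len(total %% n_ind)] <- per[seq_len(total %% n_ind)] + 1L
    for (j in seq_len(n_ind)) {
      ind_id <- sprintf("%s_p%02d", g, j)
      # the individual stream is seeded from its id, not its position, so
      # growing the design never perturbs existing individuals
      h <- 0
      for (ch in utf8ToInt(ind_id)) h <- (h * 31 + ch) %% 2147483647
      seed_i <- (cfg$seed * 10007 + h) %% 2147483647
      contours <- c(contours,
                    .generate_individual(ind_id, g, per[j],
                                         cfg$step_probability[[g]], cfg, seed_i))
    }
  }
  contour_collection(contours)
}

#' Template family ground truth of a generated collection
#'
#' @param x a `usv_collection` produced by [generate_repertoire()].
#' @return character vector of family labels (`NA` for contours that were not
#'   generated by this package).
#' @export
contour_families <- function(x) {
  vapply(x$contours, function(cc) {
    f <- attr(cc, "family"); if (is.null(f)) NA_character_ else f
  }, character(1))
}

#' Synthesize an FM tone from a contour
#'
#' Produces a frequency-modulated sinusoid whose instantaneous frequency
#' follows the contour (linear interpolation between contour samples), padded
#' with silence on both sides. This is an analytic fixture for the audio
#' front-end, not a model of the mouse vocal tract.
#'
#' @param c a `usv_contour`.
#' @param sample_rate audio sampling rate in Hz; must satisfy Nyquist
#'   (`>= 2 * max frequency`).
#' @param amplitude peak amplitude on a full scale of 1.
#' @param pad silence padding on each side, seconds.
#' @return numeric waveform vector in `[-1, 1]`, with attributes
#'   `sample_rate` and `onset` (seconds of leading silence).
#' @export
synthesize_audio <- function(c, sample_rate = 250000, amplitude = 0.8,
                             pad = 0.01) {
  f_max_hz <- max(c$freq) * 1000
  if (sample_rate < 2 * f_max_hz)
    stop("sample_rate violates Nyquist for a ", max(c$freq), " kHz contour")
  dur <- contour_duration(c)
  n <- floor(dur * sample_rate) + 1L
  t <- (seq_len(n) - 1L) / sample_rate
  t_c <- (seq_along(c$freq) - 1L) * c$hop
  # zero-order hold: each contour sample sets the instantaneous frequency
  # for one hop, so frequency discontinuities in the contour stay abrupt
  # in the signal instead of being smeared into ramps
  f_inst <- approx(t_c, c$freq * 1000, xout = pmin(t, max(t_c)),
                   method = "constant", rule = 2)$y
  phase <- 2 * pi * cumsum(f_inst) / sample_rate
  sig <- amplitude * sin(phase)
  npad <- round(pad * sample_rate)
  wav <- c(numeric(npad), sig, numeric(npad))
  attr(wav, "sample_rate") <- sample_rate
  attr(wav, "onset") <- npad / sample_rate
  wav
}
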
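test_that("generation is deterministic given the seed", {
  cfg <- repertoire_config(n_individuals = c(WT = 2, HT = 2),
                           n_calls = c(WT = 30, HT = 30), seed = 7)
  a <- generate_repertoire(cfg)
  b <- generate_repertoire(cfg)
  expect_identical(lapply(a$contours, `[[`, "freq"),
                   lapply(b$contours, `[[`, "freq"))
  cfg2 <- repertoire_config(n_individuals = c(WT = 2, HT = 2),
                            n_calls = c(WT = 30, HT = 30), seed = 8)
  c2 <- generate_repertoire(cfg2)
  expect_false(identical(lapply(a$contours, `[[`, "freq"),
                         lapply(c2$contours, `[[`, "freq")))
})

test_that("adding individuals does not perturb existing ones", {
  small <- repertoire_config(n_individuals = c(WT = 2, HT = 2),
                             n_calls = c(WT = 20, HT = 20), seed = 3)
  big <- repertoire_config(n_individuals = c(WT = 3, HT = 2),
                           n_calls = c(WT = 30, HT = 20), seed = 3)
  a <- generate_repertoire(small)
  b <- generate_repertoire(big)
  fa <- lapply(a$contours, `[[`, "freq")
  fb <- lapply(b$contours, `[[`, "freq")
  ia <- individuals(a); ib <- individuals(b)
  for (ind in c("WT_p01", "WT_p02", "HT_p01", "HT_p02"))
    expect_identical(fa[ia == ind], fb[ib == ind], label = ind)
})

test_that("step prevalence follows the configured probabilities", {
  # zero step probability: no contour contains a jump at threshold
  cfg0 <- repertoire_config(groups = c("A", "B"),
                            n_individuals = c(A = 2, B = 2),
                            n_calls = c(A = 60, B = 60),
                            step_probability = c(A = 0, B = 0), seed = 5)
  coll0 <- generate_repertoire(cfg0)
  expect_false(any(vapply(coll0$contours, detect_step, logical(1))))

  # study defaults at 1000 calls/group: realized fractions within 3
  # binomial SDs of the target probabilities
  cfg <- repertoire_config(n_individuals = c(WT = 5, HT = 6),
                           n_calls = c(WT = 1000, HT = 1000),
                           step_probability = c(WT = 0.69, HT = 0.48),
                           seed = 11)
  coll <- generate_repertoire(cfg)
  fam <- contour_families(coll)
  grp <- groups(coll)
  for (g in c("WT", "HT")) {
    p <- cfg$step_probability[[g]]
    realized <- mean(fam[grp == g] == "step")
    expect_lt(abs(realized - p), 3 * sqrt(p * (1 - p) / 1000), label = g)
    # detect_step agrees with the generating family exactly
    det <- vapply(coll$contours[grp == g], detect_step, logical(1))
    expect_equal(det, fam[grp == g] == "step")
  }
})

test_that("generated contours respect the frequency band and jump rules", {
  cfg <- repertoire_config(n_individuals = c(WT = 3, HT = 3),
                           n_calls = c(WT = 150, HT = 150),
                           step_probability = c(WT = 0.6, HT = 0.6),
                           seed = 21)
  coll <- generate_repertoire(cfg)
  fam <- contour_families(coll)
  for (i in seq_along(coll$contours)) {
    f <- coll$contours[[i]]$freq
    expect_true(all(f >= 35 & f <= 115))
    jumps <- sum(abs(diff(f)) >= cfg$step_jump_range[1])
    if (fam[i] == "step") expect_equal(jumps, 1L)
    else expect_lt(max(abs(diff(f))), 10)
  }
  dur <- vapply(coll$contours, contour_duration, numeric(1))
  expect_true(all(dur >= 0.005 & dur <= 0.15))
})

test_that("larger step-probability differences give larger step chi-squared", {
  mean_chi2 <- function(p_ht) {
    vals <- vapply(1:3, function(s) {
      cfg <- repertoire_config(n_individuals = c(WT = 2, HT = 2),
                               n_calls = c(WT = 250, HT = 250),
                               step_probability = c(WT = 0.7, HT = p_ht),
                               seed = 500 + s)
      coll <- generate_repertoire(cfg)
      det <- vapply(coll$contours, detect_step, logical(1))
      tab <- table(groups(coll), factor(det, levels = c(TRUE, FALSE)))
      chi_square_2x2(matrix(as.integer(tab), 2), FALSE)$statistic
    }, numeric(1))
    mean(vals)
  }
  chis <- c(mean_chi2(0.7), mean_chi2(0.5), mean_chi2(0.3))
  expect_true(all(diff(chis) > 0))
})

test_that("audio synthesis produces the requested FM tone", {
  const <- frequency_contour(rep(70, 41), hop = 0.001, "tone")
  wav <- synthesize_audio(const, 250000)
  expect_equal(attr(wav, "sample_rate"), 250000)
  # spectral peak of the central segment at 70 kHz
  seg <- wav[round(length(wav) / 2) + 0:4095]
  spec <- Mod(fft(seg * (0.5 - 0.5 * cos(2 * pi * (0:4095) / 4095))))
  fpk <- (which.max(spec[1:2048]) - 1) * 250000 / 4096 / 1000
  expect_lt(abs(fpk - 70), 0.5)

  silent <- synthesize_audio(const, 250000, amplitude = 0)
  expect_true(all(silent == 0))

  expect_error(synthesize_audio(const, 120000), "Nyquist")
})
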
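fake_map <- function(coords) {
  structure(list(coordinates = as.matrix(coords),
                 syllable_order = as.character(seq_len(nrow(coords))),
                 params = list()), class = "usv_map")
}

test_that("a single point gives a normalized Gaussian bump at its cell", {
  map <- fake_map(cbind(1.3, -2.1))
  grid <- grid_spec(map, 50, 50, margin = 10)
  dens <- density_map(map, grid = grid, sigma = 2)
  expect_equal(sum(dens$rho) * grid$cell_area, 1, tolerance = 1e-6)
  peak <- which(dens$rho == max(dens$rho), arr.ind = TRUE)
  expect_equal(grid$xc[peak[1]], 1.3, tolerance = grid$xc[2] - grid$xc[1])
  expect_equal(grid$yc[peak[2]], -2.1, tolerance = grid$yc[2] - grid$yc[1])
  # profile proportional to the 2-D Gaussian kernel
  ref <- outer(dnorm(grid$xc, 1.3, 2), dnorm(grid$yc, -2.1, 2))
  expect_equal(dens$rho / max(dens$rho), ref / max(ref), tolerance = 1e-6)
})

test_that("two distant equal-weight points give two equal maxima", {
  map <- fake_map(rbind(c(-12, 0), c(12, 0)))
  grid <- grid_spec(map, 61, 41, margin = 9)
  dens <- density_map(map, grid = grid, sigma = 2)
  # closed-form two-Gaussian sum as oracle
  ref <- (outer(dnorm(grid$xc, -12, 2), dnorm(grid$yc, 0, 2)) +
          outer(dnorm(grid$xc, 12, 2), dnorm(grid$yc, 0, 2))) / 2
  expect_equal(dens$rho, ref / (sum(ref) * grid$cell_area), tolerance = 1e-9)
  v_left <- max(dens$rho[grid$xc < 0, ])
  v_right <- max(dens$rho[grid$xc > 0, ])
  expect_equal(v_left, v_right, tolerance = 1e-9)
})

test_that("normalization holds for arbitrary subsets", {
  set.seed(3)
  map <- fake_map(matrix(rnorm(60, sd = 8), 30, 2))
  grid <- grid_spec(map, 40, 40, margin = 12)
  for (k in c(1, 7, 30)) {
    dens <- density_map(map, subset = seq_len(k), grid = grid, sigma = 4)
    expect_equal(sum(dens$rho) * grid$cell_area, 1, tolerance = 1e-6)
  }
  expect_error(density_map(map, subset = integer(0), grid = grid), "empty")
})

test_that("embedding entropy matches closed forms", {
  map <- fake_map(cbind(0, 0))
  grid <- grid_spec(map, 10, 10, margin = 5)
  base <- density_map(map, grid = grid, sigma = 2)

  uniform <- base
  uniform$rho <- matrix(1 / (100 * grid$cell_area), 10, 10)
  expect_equal(embedding_entropy(uniform), log2(100))

  point <- base
  point$rho <- matrix(0, 10, 10); point$rho[4, 7] <- 1 / grid$cell_area
  expect_equal(embedding_entropy(point), 0)

  half <- base
  half$rho <- matrix(0, 10, 10)
  half$rho[c(2, 9), 5] <- 0.5 / grid$cell_area
  expect_equal(embedding_entropy(half), 1)

  bad <- base; bad$rho <- bad$rho * 2
  expect_error(embedding_entropy(bad), "not normalized")
})

test_that("Sidak threshold follows its closed form", {
  expect_equal(sidak_threshold(0.05, 0), 0.05)
  expect_equal(sidak_threshold(0.05, log2(20)), 1 - 0.95^(1 / 20))
  expect_equal(sidak_threshold(1e-9, 3), -expm1(log1p(-1e-9) / 8))
  expect_lt(sidak_threshold(1e-12, 5), 1e-12)   # alpha -> 0 limit
  expect_error(sidak_threshold(0, 2), "alpha")
  expect_error(sidak_threshold(0.05, -1), "H")
})

test_that("bootstrap cell distributions are seeded and degenerate-safe", {
  map <- fake_map(matrix(2.5, 10, 2))      # all points identical
  grid <- grid_spec(map, 20, 20, margin = 8)
  qb <- bootstrap_cell_distributions(map, grid = grid, sigma = 2,
                                     n_boot = 20, seed = 1)
  # every replicate resamples the same point: all cells are point masses
  expect_true(all(qb$fit$sd == 0))
  expect_true(all(qb$fit$k == 1L))

  set.seed(11)
  map2 <- fake_map(matrix(rnorm(40, sd = 6), 20, 2))
  grid2 <- grid_spec(map2, 25, 25, margin = 9)
  q1 <- bootstrap_cell_distributions(map2, grid = grid2, sigma = 3,
                                     n_boot = 50, seed = 7)
  q2 <- bootstrap_cell_distributions(map2, grid = grid2, sigma = 3,
                                     n_boot = 50, seed = 7)
  expect_identical(q1$fit, q2$fit)
  q3 <- bootstrap_cell_distributions(map2, grid = grid2, sigma = 3,
                                     n_boot = 50, seed = 8)
  expect_false(identical(q1$fit, q3$fit))
})

test_that("bootstrap means are consistent with the point-estimate density", {
  set.seed(21)
  map <- fake_map(matrix(rnorm(300, sd = 10), 150, 2))
  grid <- grid_spec(map, 50, 50, margin = 12)
  dens <- density_map(map, grid = grid, sigma = 4)
  qb <- bootstrap_cell_distributions(map, grid = grid, sigma = 4,
                                     n_boot = 1000, seed = 3)
  hi <- which(dens$rho >= quantile(dens$rho, 0.95))
  rel <- abs(qb$boot_mean[hi] - dens$rho[hi]) / dens$rho[hi]
  expect_lt(max(rel), 0.05)
})

test_that("per-cell mixture fits agree with an independent GMM fitter", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(5)
  x <- c(rnorm(250, 0, 1), rnorm(250, 6, 1))
  fit <- usvmap:::gmm_fit_cells_cpp(matrix(x, ncol = 1))
  mc <- mclust::Mclust(x, G = fit$k[1], modelNames = "V", verbose = FALSE)
  expect_gte(fit$k[1], 2L)
  ours <- sort(fit$mu[seq_len(fit$k[1]), 1])
  theirs <- sort(as.numeric(mc$parameters$mean))
  # the two dominant component means agree
  expect_equal(ours[c(1, fit$k[1])], theirs[c(1, fit$k[1])], tolerance = 0.3)
})

test_that("P(HT > WT) behaves correctly for analytic cell models", {
  # identical continuous models at every cell -> 0.5
  n <- 5L
  fit_a <- make_cell_fit(rep(1L, n), matrix(c(1, 0, 0), 3, n),
                         matrix(c(2, 0, 0), 3, n), matrix(c(0.5, 0, 0), 3, n))
  sig <- significance_map(fit_to_boot(fit_a), fit_to_boot(fit_a),
                          alpha = 0.05, H = 2)
  expect_equal(as.numeric(sig$p_ht), rep(0.5, n), tolerance = 1e-3)
  expect_equal(sig$alpha_corrected, sidak_threshold(0.05, 2))
  expect_false(any(sig$mask_ht_greater) || any(sig$mask_wt_greater))

  # point mass strictly above the other model's support -> 1
  fit_pm <- make_cell_fit(rep(1L, n), matrix(c(1, 0, 0), 3, n),
                          matrix(c(50, 0, 0), 3, n), matrix(0, 3, n))
  sig2 <- significance_map(fit_to_boot(fit_a), fit_to_boot(fit_pm),
                           alpha = 0.05, H = 0)
  expect_equal(as.numeric(sig2$p_ht), rep(1, n))
  expect_true(all(sig2$mask_ht_greater))

  # unit-variance Gaussians separated by delta -> Phi(delta / sqrt(2))
  deltas <- c(-2, -0.5, 0, 0.7, 1.5, 3)
  fit_wt <- make_cell_fit(rep(1L, 6), matrix(c(1, 0, 0), 3, 6),
                          matrix(c(0, 0, 0), 3, 6), matrix(c(1, 0, 0), 3, 6))
  fit_ht <- make_cell_fit(rep(1L, 6), matrix(c(1, 0, 0), 3, 6),
                          rbind(deltas, 0, 0), matrix(c(1, 0, 0), 3, 6))
  sig3 <- significance_map(fit_to_boot(fit_wt), fit_to_boot(fit_ht),
                           alpha = 0.05, H = 0)
  expect_equal(as.numeric(sig3$p_ht), pnorm(deltas / sqrt(2)),
               tolerance = 1e-4)
})
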
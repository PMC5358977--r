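#' Grid specification over a repertoire map
#'
#' A regular `n_x` by `n_y` grid of cell centers covering the embedded
#' points with a margin (default 3 kernel widths, so Gaussian mass is not
#' truncated at the edges).
#'
#' @param map a `usv_map` (or n x 2 coordinate matrix).
#' @param n_x,n_y cell counts (>= 2).
#' @param margin margin added on every side, map units.
#' @return an object of class `usv_grid`: `x_range`, `y_range`, `n_x`,
#'   `n_y`, cell-center vectors `xc`, `yc`, and `cell_area`.
#' @export
grid_spec <- function(map, n_x = 100L, n_y = 100L, margin = 12) {
  coords <- if (inherits(map, "usv_map")) map$coordinates else as.matrix(map)
  if (n_x < 2L || n_y < 2L) stop("grid needs n_x, n_y >= 2")
  x_range <- range(coords[, 1]) + c(-margin, margin)
  y_range <- range(coords[, 2]) + c(-margin, margin)
  xc <- seq(x_range[1], x_range[2], length.out = n_x)
  yc <- seq(y_range[1], y_range[2], length.out = n_y)
  dx <- xc[2] - xc[1]; dy <- yc[2] - yc[1]
  structure(list(x_range = x_range, y_range = y_range,
                 n_x = as.integer(n_x), n_y = as.integer(n_y),
                 xc = xc, yc = yc, cell_area = dx * dy),
            class = "usv_grid")
}

# Gaussian kernel evaluation matrices for a point set on a grid: the
# kernel is separable, so the density is Gx %*% t(Gy) up to weights.
.kernel_mats <- function(grid, px, py, sigma) {
  list(Gx = outer(grid$xc, px, function(a, b) dnorm(a - b, sd = sigma)),
       Gy = outer(grid$yc, py, function(a, b) dnorm(a - b, sd = sigma)))
}

.normalize_rho <- function(rho_raw, cell_area) {
  tot <- sum(rho_raw) * cell_area
  if (tot <= 0) stop("density normalization failed (no mass on grid)")
  rho_raw / tot
}

#' Gridded Gaussian kernel density of map points
#'
#' Sum of isotropic Gaussian kernels (standard deviation `sigma`, map
#' units) over a subset of embedded points, evaluated at the grid cell
#' centers and renormalized so that `sum(rho) * cell_area == 1`.
#'
#' @param map a `usv_map`.
#' @param subset integer (or logical) index of points to include; default
#'   all points.
#' @param grid a `usv_grid`; default [grid_spec()] of the map.
#' @param sigma kernel width (standard deviation) in map units; the
#'   pipeline default is 4.
#' @param group label stored with the result (e.g. `"WT"`, `"pooled"`).
#' @return an object of class `usv_density`: `grid`, `rho` (n_x x n_y),
#'   `sigma`, `group`, `n_points`.
#' @export
density_map <- function(map, subset = NULL, grid = NULL, sigma = 4,
                        group = "pooled") {
  coords <- map$coordinates
  if (is.null(subset)) subset <- seq_len(nrow(coords))
  if (is.logical(subset)) subset <- which(subset)
  if (!length(subset)) stop("empty subset")
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (is.null(grid)) grid <- grid_spec(map, margin = 3 * sigma)
  km <- .kernel_mats(grid, coords[subset, 1], coords[subset, 2], sigma)
  rho <- .normalize_rho(km$Gx %*% t(km$Gy), grid$cell_area)
  structure(list(grid = grid, rho = rho, sigma = sigma, group = group,
                 n_points = length(subset)), class = "usv_density")
}

#' @export
print.usv_density <- function(x, ...) {
  cat(sprintf("<usv_density> %s: %d points on %d x %d grid (sigma %.3g)\n",
              x$group, x$n_points, x$grid$n_x, x$grid$n_y, x$sigma))
  invisible(x)
}

#' Entropy of a map density, in bits
#'
#' Discrete cell-probability entropy of the gridded density:
#' `H = -sum(p_i log2 p_i)` with `p_i = rho_i * cell_area`. This is the
#' grid quadrature of the differential entropy integral up to an additive
#' `log2(cell_area)` constant; the grid resolution is therefore part of the
#' convention and is recorded with every density.
#'
#' @param rho a `usv_density` (normalized).
#' @return entropy in bits.
#' @export
embedding_entropy <- function(rho) {
  p <- rho$rho * rho$grid$cell_area
  if (abs(sum(p) - 1) > 1e-6) stop("density is not normalized")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Sidak-corrected per-cell significance level
#'
#' Familywise correction for `m = 2^H` effective comparisons, with `H` the
#' entropy (bits) of the pooled map density; `m` is used as a real number,
#' without rounding. Returns `1 - (1 - alpha)^(1/m)`.
#'
#' @param alpha nominal familywise level in (0, 1).
#' @param H entropy in bits (>= 0).
#' @return per-cell level.
#' @export
sidak_threshold <- function(alpha, H) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (H < 0) stop("'H' must be >= 0")
  -expm1(log1p(-alpha) / 2^H)
}

#' Bootstrap distributions of the density value at every grid cell
#'
#' Resamples the subset of embedded points with replacement `n_boot` times;
#' each replicate's normalized Gaussian density is evaluated on the grid.
#' At every cell, univariate Gaussian mixtures with 1-3 components are
#' fitted to the `n_boot` density values and the component count is chosen
#' by AIC. Cells whose bootstrap values are constant (e.g. far from all
#' points) are represented as point masses.
#'
#' @inheritParams density_map
#' @param n_boot number of bootstrap replicates (>= 2). The study-scale
#'   value is 10,000; desk-scale analyses use fewer.
#' @param seed integer seed for the resampling.
#' @param kmax maximum mixture components (default 3).
#' @return an object of class `usv_cellboot`: `grid`, `fit` (per-cell
#'   mixture parameters), `sigma`, `n_boot`, `group`, and `boot_mean`
#'   (per-cell mean of bootstrap densities, for diagnostics).
#' @export
bootstrap_cell_distributions <- function(map, subset = NULL, grid = NULL,
                                         sigma = 4, n_boot = 1000L,
                                         seed = 0L, group = "group",
                                         kmax = 3L) {
  coords <- map$coordinates
  if (is.null(subset)) subset <- seq_len(nrow(coords))
  if (is.logical(subset)) subset <- which(subset)
  n <- length(subset)
  if (n < 2L) stop("subset must contain at least 2 points")
  if (n_boot < 2L) stop("'n_boot' must be >= 2")
  if (is.null(grid)) grid <- grid_spec(map, margin = 3 * sigma)

  km <- .kernel_mats(grid, coords[subset, 1], coords[subset, 2], sigma)
  ncell <- grid$n_x * grid$n_y

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  boot <- matrix(0, n_boot, ncell)
  tGy <- t(km$Gy)
  for (b in seq_len(n_boot)) {
    w <- tabulate(sample.int(n, n, replace = TRUE), nbins = n)
    rho <- .normalize_rho((km$Gx * rep(w, each = grid$n_x)) %*% tGy,
                          grid$cell_area)
    boot[b, ] <- rho
  }
  # cells whose bootstrap densities never rise above a numerical support
  # floor (1e-9 of the group's peak) are represented as point masses at
  # their mean rather than mixture-fitted; the flag lets the comparison
  # stage treat "below floor in both groups" as carrying no evidence
  cmax <- apply(boot, 2, max)
  tiny <- cmax < 1e-9 * max(cmax)
  fit_sub <- gmm_fit_cells_cpp(boot[, !tiny, drop = FALSE], kmax = kmax)
  fit <- list(k = integer(ncell), w = matrix(0, kmax, ncell),
              mu = matrix(0, kmax, ncell), sd = matrix(0, kmax, ncell),
              tiny = tiny)
  fit$k[!tiny] <- fit_sub$k
  fit$w[, !tiny] <- fit_sub$w
  fit$mu[, !tiny] <- fit_sub$mu
  fit$sd[, !tiny] <- fit_sub$sd
  if (any(tiny)) {
    fit$k[tiny] <- 1L
    fit$w[1, tiny] <- 1
    fit$mu[1, tiny] <- colMeans(boot[, tiny, drop = FALSE])
  }
  structure(list(grid = grid, fit = fit, sigma = sigma, n_boot = n_boot,
                 group = group, boot_mean = colMeans(boot)),
            class = "usv_cellboot")
}

#' Significance map of per-cell density differences
#'
#' At every grid cell, computes `P_HT = Prob(rho_HT > rho_WT)` under
#' independence of the two bootstrap-estimated density distributions, by
#' numerical integration of the fitted per-cell mixtures. Cells with
#' `P_HT > 1 - alpha'` are flagged as HT-enriched and cells with
#' `P_HT < alpha'` as WT-enriched, where `alpha'` is the Sidak-corrected
#' per-cell level for `m = 2^H` comparisons.
#'
#' @param q_wt,q_ht `usv_cellboot` objects for the two groups, on the same
#'   grid (`q_wt` is the reference group; `P` is the probability that
#'   `q_ht`'s density exceeds it).
#' @param alpha nominal familywise level (default 0.05).
#' @param H embedding entropy in bits (from [embedding_entropy()] of the
#'   pooled density).
#' @return an object of class `usv_signif`: `grid`, `p_ht` (n_x x n_y),
#'   `alpha`, `H`, `m`, `alpha_corrected`, `mask_ht_greater`,
#'   `mask_wt_greater`.
#' @export
significance_map <- function(q_wt, q_ht, alpha = 0.05, H) {
  g <- q_wt$grid
  if (!identical(unclass(g)[c("n_x", "n_y")], unclass(q_ht$grid)[c("n_x", "n_y")]) ||
      max(abs(g$xc - q_ht$grid$xc), abs(g$yc - q_ht$grid$yc)) > 1e-9)
    stop("cell-model grids do not match")
  p <- pht_cells_cpp(q_wt$fit, q_ht$fit)
  p_ht <- matrix(p, g$n_x, g$n_y)
  ac <- sidak_threshold(alpha, H)
  structure(list(grid = g, p_ht = p_ht, alpha = alpha, H = H, m = 2^H,
                 alpha_corrected = ac,
                 mask_ht_greater = p_ht > 1 - ac,
                 mask_wt_greater = p_ht < ac),
            class = "usv_signif")
}

#' @export
print.usv_signif <- function(x, ...) {
  cat(sprintf(paste0("<usv_signif> %d x %d cells; H = %.2f bits, m = %.1f, ",
                     "alpha' = %.3g; %d cells HT>WT, %d cells WT>HT\n"),
              x$grid$n_x, x$grid$n_y, x$H, x$m, x$alpha_corrected,
              sum(x$mask_ht_greater), sum(x$mask_wt_greater)))
  invisible(x)
}

#' Group density maps and bootstrap significance, end to end
#'
#' Convenience wrapper running the full density-comparison stage for a
#' two-group collection: per-group densities, the pooled density
#' `rho = (rho_A + rho_B) / 2`, its entropy, per-group bootstrap cell
#' distributions, and the significance map of `Prob(rho_B > rho_A)` (the
#' second group plays the HT role).
#'
#' @param map a `usv_map`.
#' @param group_labels character vector of group labels, one per map point.
#' @param groups length-2 character: reference group and comparison group;
#'   default the sorted unique labels.
#' @param grid optional `usv_grid`.
#' @param sigma kernel width, map units.
#' @param n_boot bootstrap replicates per group.
#' @param alpha nominal familywise level.
#' @param seed integer seed.
#' @return list with `density` (named list of `usv_density`, including
#'   `"pooled"`), `H`, `boot` (named list of `usv_cellboot`), and
#'   `signif` (`usv_signif`).
#' @export
density_significance <- function(map, group_labels, groups = NULL,
                                 grid = NULL, sigma = 4, n_boot = 1000L,
                                 alpha = 0.05, seed = 0L) {
  stopifnot(length(group_labels) == nrow(map$coordinates))
  if (is.null(groups)) groups <- sort(unique(group_labels))
  if (length(groups) != 2L) stop("need exactly two groups")
  if (is.null(grid)) grid <- grid_spec(map, margin = 3 * sigma)
  dens <- lapply(groups, function(g)
    density_map(map, subset = group_labels == g, grid = grid, sigma = sigma,
                group = g))
  names(dens) <- groups
  pooled <- dens[[1]]
  pooled$rho <- (dens[[1]]$rho + dens[[2]]$rho) / 2
  pooled$group <- "pooled"
  pooled$n_points <- length(group_labels)
  dens$pooled <- pooled
  H <- embedding_entropy(pooled)
  boot <- lapply(seq_along(groups), function(i)
    bootstrap_cell_distributions(map, subset = group_labels == groups[i],
                                 grid = grid, sigma = sigma, n_boot = n_boot,
                                 seed = seed + i, group = groups[i]))
  names(boot) <- groups
  sig <- significance_map(boot[[1]], boot[[2]], alpha = alpha, H = H)
  list(density = dens, H = H, boot = boot, signif = sig)
}
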
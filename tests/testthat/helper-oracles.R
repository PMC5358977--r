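# Brute-force DTW oracle: enumerates every monotone boundary-to-boundary
# warping path and returns the minimum of (path cost sum) / (path length).
# Exponential in the contour lengths; usable for lengths <= ~7.
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  rec <- function(i, j, acc, len) {
    acc <- acc + (a[i] - b[j])^2
    len <- len + 1L
    if (i == n && j == m) {
      r <- acc / len
      if (r < best) best <<- r
      return(invisible(NULL))
    }
    if (i < n && j < m) rec(i + 1L, j + 1L, acc, len)
    if (i < n) rec(i + 1L, j, acc, len)
    if (j < m) rec(i, j + 1L, acc, len)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# Closed-form uncorrected Pearson chi-squared for a 2x2 table
chi2_2x2_closed_form <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# k-nearest-neighbour class purity of a 2-D embedding
knn_purity <- function(coords, classes, k = 5L) {
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  diag(D) <- Inf
  hits <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mean(classes[nb] == classes[i])
  }, numeric(1))
  mean(hits)
}

# small two-individual collection with hand-set contours
toy_collection <- function() {
  contour_collection(list(
    frequency_contour(c(70, 70, 70), hop = 0.001, "s1", "p1", "WT"),
    frequency_contour(c(40, 60, 80), hop = 0.001, "s2", "p1", "WT"),
    frequency_contour(c(80, 60, 40, 50), hop = 0.001, "s3", "p2", "HT"),
    frequency_contour(c(55, 65), hop = 0.001, "s4", "p2", "HT",
                      clipped = TRUE)
  ))
}

# fabricate a per-cell mixture-fit list (the structure produced by
# gmm_fit_cells_cpp) from per-cell component tables
make_cell_fit <- function(k, w, mu, sd) {
  list(k = as.integer(k), w = as.matrix(w), mu = as.matrix(mu),
       sd = as.matrix(sd))
}

# wrap a fabricated fit in a minimal usv_cellboot on an ncell x 1 grid so
# it can be fed to significance_map()
fit_to_boot <- function(fit) {
  ncell <- length(fit$k)
  g <- structure(list(x_range = c(0, 1), y_range = c(0, 1),
                      n_x = as.integer(ncell), n_y = 1L,
                      xc = as.numeric(seq_len(ncell)), yc = 0,
                      cell_area = 1), class = "usv_grid")
  structure(list(grid = g, fit = fit, sigma = 1, n_boot = 2L, group = "x",
                 boot_mean = NULL), class = "usv_cellboot")
}
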
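#' Two-dimensional t-SNE repertoire map from a distance matrix
#'
#' Embeds the all-to-all DTW dissimilarity matrix into two dimensions with
#' t-distributed stochastic neighbor embedding, run directly on the
#' precomputed dissimilarities. Per-point Gaussian kernel bandwidths are
#' tuned by binary search so that each point's transition distribution has
#' the target Shannon entropy in bits (equivalently, perplexity
#' `2^transition_entropy`; the default 5 bits is perplexity 32). Gradient
#' descent stops when the relative change of the KL cost drops below
#' `convergence_tol`.
#'
#' Initialization is deterministic: classical multidimensional scaling of
#' the dissimilarities (scaled to small norm, the usual PCA-style start),
#' falling back to seeded Gaussian noise if the MDS solution is degenerate.
#' The embedding axes are arbitrary; every downstream statistic is invariant
#' to rigid rotation/reflection of the map.
#'
#' @param d a `usv_distmat` (or square symmetric matrix of dissimilarities).
#' @param transition_entropy target transition entropy in bits (> 0).
#' @param convergence_tol relative KL-cost change at which to stop.
#' @param seed integer seed (used for the random fallback and recorded for
#'   provenance; the run is deterministic given it).
#' @param max_iter maximum gradient-descent iterations.
#' @param eta learning rate; default scales with n.
#' @return an object of class `usv_map`: list with `coordinates` (n x 2),
#'   `syllable_order`, and `params` (entropy, tol, seed, cost, iterations).
#' @export
embed_repertoire <- function(d, transition_entropy = 5,
                             convergence_tol = 1e-4, seed = 0L,
                             max_iter = 1000L, eta = NULL) {
  if (inherits(d, "usv_distmat")) {
    D <- d$values; ids <- d$syllable_order
  } else {
    D <- as.matrix(d); ids <- rownames(D)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(D)))
  }
  n <- nrow(D)
  if (n < 4L) stop("need at least 4 points to embed")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) || any(!is.finite(D)))
    stop("distance matrix must be finite and symmetric")
  if (transition_entropy <= 0) stop("'transition_entropy' must be > 0")

  P <- .tsne_affinities(D, transition_entropy)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Y0 <- tryCatch({
    init <- suppressWarnings(cmdscale(sqrt(pmax(D, 0)), k = 2))
    if (ncol(init) < 2 || any(!is.finite(init)) || sd(init[, 1]) == 0)
      stop("degenerate")
    # small-norm start, as with PCA initialization
    init / sd(init[, 1]) * 1e-4
  }, error = function(e) matrix(rnorm(n * 2, sd = 1e-4), n, 2))

  if (is.null(eta)) eta <- max(200, n / 12)
  exag_end <- min(250L, max_iter %/% 4L)
  res <- tsne_cpp(P, Y0, max_iter = max_iter, tol = convergence_tol,
                  eta = eta, exaggeration = 12, exag_end = exag_end,
                  momentum_init = 0.5, momentum_final = 0.8,
                  mom_switch = exag_end, check_every = 10L)
  coords <- res$Y
  dimnames(coords) <- list(ids, c("x", "y"))
  structure(list(coordinates = coords, syllable_order = ids,
                 params = list(transition_entropy = transition_entropy,
                               convergence_tol = convergence_tol,
                               seed = seed, eta = eta,
                               exaggeration = 12, exag_end = exag_end,
                               kl_cost = res$cost, iterations = res$iter)),
            class = "usv_map")
}

# Symmetrized joint affinities from a dissimilarity matrix. The
# dissimilarities (already squared-error-like, kHz^2) enter the Gaussian
# kernel linearly: p_{j|i} ~ exp(-beta_i d_ij), with beta_i tuned per point
# so the transition entropy (bits) matches the target.
.tsne_affinities <- function(D, entropy_bits) {
  n <- nrow(D)
  target <- entropy_bits * log(2)          # nats
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta_lo <- 0; beta_hi <- Inf; beta <- 1 / (mean(di) + 1e-12)
    for (it in 1:64) {
      w <- exp(-beta * (di - min(di)))
      sw <- sum(w)
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))  # nats
      if (abs(H - target) < 1e-7) break
      if (H > target) {                    # too diffuse -> narrow kernel
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta_lo + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- (beta_lo + beta_hi) / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' @export
print.usv_map <- function(x, ...) {
  if (length(x$params))
    cat(sprintf("<usv_map> %d points; entropy %.2f bits; KL %.4f after %d iterations\n",
                nrow(x$coordinates), x$params$transition_entropy,
                x$params$kl_cost, x$params$iterations))
  else
    cat(sprintf("<usv_map> %d points\n", nrow(x$coordinates)))
  invisible(x)
}

#' Write / read a repertoire map as CSV
#'
#' Columns `syllable_id, x, y`.
#' @param map a `usv_map`.
#' @param path CSV path.
#' @export
write_map <- function(map, path) {
  df <- data.frame(syllable_id = map$syllable_order,
                   x = map$coordinates[, 1], y = map$coordinates[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  coords <- as.matrix(df[, c("x", "y")])
  rownames(coords) <- df$syllable_id
  structure(list(coordinates = coords, syllable_order = df$syllable_id,
                 params = list()), class = "usv_map")
}
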
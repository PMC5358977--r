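#' Mean-frequency subtraction
#'
#' Subtracts a contour's mean frequency from every sample, so pairwise
#' comparisons measure frequency-modulation shape, not register. Idempotent;
#' output samples sum to zero.
#'
#' @param c a `usv_contour`.
#' @return a list with the same structure as a contour but whose `freq` is
#'   centred (centred traces are not positive, so the object is returned
#'   unclassed with a `mean_subtracted` flag).
#' @export
mean_subtract <- function(c) {
  out <- unclass(c)
  out$freq <- c$freq - mean(c$freq)
  out$mean_subtracted <- TRUE
  out
}

#' DTW mean-squared-error dissimilarity between two contours
#'
#' Classic dynamic-time-warping dynamic program with local cost
#' `(f_a[i] - f_b[j])^2` and the symmetric unit step pattern (match, insert,
#' delete), boundary to boundary, no window constraint. The returned value
#' is the accumulated squared error divided by the warping-path length —
#' the minimum mean squared error over all monotone alignments (units kHz^2).
#' Symmetric, zero iff one contour is a warping-equivalent of the other.
#'
#' Both contours should be mean-subtracted and on a common hop; the
#' convenience wrapper [all_pairs()] takes care of both.
#'
#' @param a,b mean-subtracted contours (objects with a `$freq` vector) or
#'   plain numeric vectors of length >= 2.
#' @return nonnegative dissimilarity in kHz^2.
#' @export
dtw_mse <- function(a, b) {
  fa <- if (is.list(a)) a$freq else as.numeric(a)
  fb <- if (is.list(b)) b$freq else as.numeric(b)
  dtw_mse_cpp(fa, fb)
}

#' All-to-all DTW distance matrix of a collection
#'
#' Mean-subtracts every non-clipped contour and evaluates [dtw_mse()] on all
#' `n (n - 1) / 2` pairs. Clipped contours are excluded first; the matrix
#' row/column order is the collection order of the remaining contours.
#'
#' @param x a `usv_collection` with at least 2 non-clipped contours.
#' @return an object of class `usv_distmat`: list with `n`, `values`
#'   (symmetric n x n matrix, zero diagonal), and `syllable_order`.
#' @export
all_pairs <- function(x) {
  x <- drop_clipped(x)
  n <- length(x)
  if (n < 2L) stop("need at least 2 non-clipped contours")
  centred <- lapply(x$contours, function(cc) cc$freq - mean(cc$freq))
  D <- dtw_all_pairs_cpp(centred)
  ids <- syllable_ids(x)
  dimnames(D) <- list(ids, ids)
  structure(list(n = n, values = D, syllable_order = ids),
            class = "usv_distmat")
}

#' @export
print.usv_distmat <- function(x, ...) {
  cat(sprintf("<usv_distmat> %d x %d (%s pairwise comparisons)\n",
              x$n, x$n, format(x$n * (x$n - 1) / 2, big.mark = ",")))
  invisible(x)
}

#' Size of the all-pairs comparison task
#'
#' Reports, without computing any distance, the matrix dimension and
#' comparison counts the all-pairs stage would entail for a collection:
#' `n_pairs = n (n - 1) / 2` distinct evaluations, and `basis = n^2 / 2`,
#' the half-matrix comparison basis conventionally quoted for all-to-all
#' matrices.
#'
#' @param x a `usv_collection`.
#' @return list with `n`, `n_pairs`, `basis`.
#' @export
comparison_count <- function(x) {
  n <- length(drop_clipped(x))
  list(n = n, n_pairs = n * (n - 1) / 2, basis = n^2 / 2)
}

#' Persist / load a distance matrix
#'
#' The dense condensed upper triangle is written as a little-endian binary
#' array of doubles, with a JSON sidecar (`<path>.json`) recording `n` and
#' the syllable order, so the matrix can be reconstructed unambiguously.
#'
#' @param d a `usv_distmat`.
#' @param path output path for the binary array.
#' @export
write_distances <- function(d, path) {
  ut <- d$values[upper.tri(d$values)]
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.numeric(ut), con, size = 8, endian = "little")
  jsonlite::write_json(list(n = d$n, syllable_order = d$syllable_order,
                            storage = "upper-triangle, column-major, float64"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  n <- meta$n
  con <- file(path, "rb"); on.exit(close(con))
  ut <- readBin(con, "numeric", n * (n - 1) / 2, size = 8, endian = "little")
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- ut
  D <- D + t(D)
  dimnames(D) <- list(meta$syllable_order, meta$syllable_order)
  structure(list(n = n, values = D, syllable_order = meta$syllable_order),
            class = "usv_distmat")
}
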
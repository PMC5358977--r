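#' Per-syllable acoustic measures
#'
#' Computes the three simple measures used throughout: duration
#' (`(n - 1) * hop`, seconds), bandwidth (max minus min contour frequency,
#' kHz), and mean frequency (unweighted arithmetic mean of the contour
#' samples, kHz), plus the step flag at the given jump threshold.
#'
#' Bandwidth is defined on the extracted contour, not as a spectral
#' bandwidth; contours carry no amplitude, so the mean is unweighted.
#'
#' @param c a `usv_contour`.
#' @param jump_threshold step-detection threshold in kHz (see
#'   [detect_step()]).
#' @return a one-row data.frame with columns `syllable_id, individual_id,
#'   group, duration, bandwidth, mean_frequency, has_step, clipped`.
#' @export
measure_contour <- function(c, jump_threshold = 10) {
  data.frame(syllable_id = c$syllable_id, individual_id = c$individual_id,
             group = c$group,
             duration = contour_duration(c),
             bandwidth = max(c$freq) - min(c$freq),
             mean_frequency = mean(c$freq),
             has_step = detect_step(c, jump_threshold),
             clipped = c$clipped)
}

#' @rdname measure_contour
#' @param x a `usv_collection`.
#' @return `measure_collection()`: one row per contour (clipped included,
#'   flagged).
#' @export
measure_collection <- function(x, jump_threshold = 10) {
  do.call(rbind, lapply(x$contours, measure_contour,
                        jump_threshold = jump_threshold))
}

#' Detect a frequency step in a contour
#'
#' A step (jump) syllable contains an abrupt, discontinuous change in
#' frequency between adjacent contour samples. The detector flags a contour
#' iff any adjacent-sample `|delta f| >= jump_threshold` (the boundary case
#' counts as a step).
#'
#' The default threshold of 10 kHz between adjacent samples cleanly
#' separates continuous sweeps (around 1 kHz per 1-ms hop) from jump
#' discontinuities, and is configurable.
#'
#' @param c a `usv_contour`.
#' @param jump_threshold kHz, must be > 0.
#' @return logical.
#' @export
detect_step <- function(c, jump_threshold = 10) {
  if (jump_threshold <= 0) stop("'jump_threshold' must be > 0")
  any(abs(diff(c$freq)) >= jump_threshold)
}

#' Per-individual means of an acoustic measure
#'
#' The unit of analysis for group comparisons is the individual: for each
#' individual, the arithmetic mean of the per-syllable measure over its
#' non-clipped contours.
#'
#' @param x a `usv_collection`.
#' @param measure_name one of `"duration"`, `"bandwidth"`,
#'   `"mean_frequency"`.
#' @param jump_threshold passed to [measure_collection()].
#' @return a data.frame with columns `individual_id, group, mean_value, n`.
#' @export
individual_means <- function(x, measure_name = c("duration", "bandwidth",
                                                 "mean_frequency"),
                             jump_threshold = 10) {
  measure_name <- match.arg(measure_name)
  m <- measure_collection(x, jump_threshold)
  all_ind <- unique(m$individual_id)
  m <- m[!m$clipped, , drop = FALSE]
  gone <- setdiff(all_ind, unique(m$individual_id))
  if (length(gone))
    stop("individual(s) with zero non-clipped contours: ",
         paste(gone, collapse = ", "))
  agg <- aggregate(m[[measure_name]],
                   by = list(individual_id = m$individual_id, group = m$group),
                   FUN = mean)
  names(agg)[3] <- "mean_value"
  cnt <- aggregate(m[[measure_name]],
                   by = list(individual_id = m$individual_id), FUN = length)
  agg$n <- cnt$x[match(agg$individual_id, cnt$individual_id)]
  agg[order(agg$group, agg$individual_id), , drop = FALSE]
}

#' One-way ANOVA on per-individual means
#'
#' Standard single-factor ANOVA comparing groups on the individual means of
#' one acoustic measure; with `k` groups and `N` individuals in total the
#' test has `df = (k - 1, N - k)`.
#'
#' @param values_by_group named list, one numeric vector of per-individual
#'   means per group (each of length >= 2).
#' @return list with elements `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(values_by_group) {
  if (length(values_by_group) < 2L) stop("need at least 2 groups")
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L))
    stop("each group needs at least 2 individuals; offending group(s): ",
         paste(names(values_by_group)[sizes < 2L], collapse = ", "))
  v <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), sizes))
  tab <- anova(lm(v ~ g))
  list(F = tab$`F value`[1], df1 = tab$Df[1], df2 = tab$Df[2],
       p = tab$`Pr(>F)`[1])
}

#' @rdname anova_oneway
#' @param x a `usv_collection`.
#' @param measure_name measure to test (see [individual_means()]).
#' @return `anova_by_measure()`: the same list, computed from the
#'   collection's per-individual means.
#' @export
anova_by_measure <- function(x, measure_name) {
  im <- individual_means(x, measure_name)
  anova_oneway(split(im$mean_value, im$group))
}
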
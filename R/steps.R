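#' Watershed segmentation of the pooled density map
#'
#' Splits the map into catchment regions around the local maxima of the
#' pooled density (watershed of the negated density). Cells jointly holding
#' the lowest `background_mass` fraction of total probability mass are
#' treated as background (region 0).
#'
#' @param pooled a normalized `usv_density` (typically the pooled map).
#' @param background_mass fraction of total mass assigned to background
#'   (default 0.01; 0 assigns every cell to a region).
#' @param tolerance watershed merge tolerance as a fraction of the peak
#'   density; peaks shallower than this relative height are merged into
#'   their neighbor.
#' @return integer `n_x` x `n_y` matrix of region ids (0 = background).
#' @export
segment_regions <- function(pooled, background_mass = 0.01,
                            tolerance = 0.05) {
  rho <- pooled$rho
  mass <- rho * pooled$grid$cell_area
  if (abs(sum(mass) - 1) > 1e-6) stop("density is not normalized")
  work <- rho
  if (background_mass > 0) {
    o <- order(mass)
    cum <- cumsum(mass[o])
    bg <- o[cum <= background_mass]
    work[bg] <- 0
  }
  labels <- EBImage::watershed(work / max(work), tolerance = tolerance)
  regions <- matrix(as.integer(labels), nrow(rho), ncol(rho))
  regions[work == 0] <- 0L
  regions
}

#' Map points to grid cells
#'
#' @param map a `usv_map`.
#' @param grid a `usv_grid`.
#' @return integer matrix with columns `ix`, `iy` (1-based cell indices of
#'   the nearest cell center).
#' @export
map_to_cells <- function(map, grid) {
  nearest <- function(v, centers) {
    i <- findInterval(v, centers + c(diff(centers) / 2, Inf)) + 1L
    pmin(pmax(i, 1L), length(centers))
  }
  cbind(ix = nearest(map$coordinates[, 1], grid$xc),
        iy = nearest(map$coordinates[, 2], grid$yc))
}

#' Genotype-blind step/non-step labeling of map regions
#'
#' Each watershed region is classified as step territory iff the majority
#' (> 0.5) of its member contours contain a frequency step by
#' [detect_step()]; every vocalization then inherits its region's class.
#' The classification uses only map position and contour shape — group
#' identity never enters, so the labeling is blind to genotype.
#' Vocalizations falling on background cells are assigned to the nearest
#' non-background region by cell-center distance.
#'
#' @param regions region-id matrix from [segment_regions()].
#' @param map a `usv_map` of the same collection.
#' @param x the `usv_collection` (non-clipped contours in map order).
#' @param grid the `usv_grid` the regions were computed on.
#' @param jump_threshold step-detection threshold, kHz.
#' @return list with `region_of_vocal` (integer), `region_class` (named
#'   character, `"step"`/`"non_step"`), and `vocal_labels` (character
#'   vector aligned with the map points).
#' @export
classify_regions <- function(regions, map, x, grid, jump_threshold = 10) {
  x <- drop_clipped(x)
  n <- nrow(map$coordinates)
  if (length(x) != n)
    stop("collection and map sizes differ (clipped contours excluded?)")
  cells <- map_to_cells(map, grid)
  reg <- regions[cbind(cells[, "ix"], cells[, "iy"])]

  if (any(reg == 0L)) {
    fg <- which(regions != 0L, arr.ind = TRUE)
    if (!nrow(fg)) stop("no non-background regions")
    fgx <- grid$xc[fg[, 1]]; fgy <- grid$yc[fg[, 2]]
    fgr <- regions[fg]
    for (i in which(reg == 0L)) {
      d2 <- (fgx - map$coordinates[i, 1])^2 + (fgy - map$coordinates[i, 2])^2
      reg[i] <- fgr[which.min(d2)]
    }
  }

  has_step <- vapply(x$contours, detect_step, logical(1),
                     jump_threshold = jump_threshold)
  frac <- tapply(has_step, reg, mean)
  region_class <- ifelse(frac > 0.5, "step", "non_step")
  names(region_class) <- names(frac)
  vocal_labels <- unname(region_class[as.character(reg)])
  list(region_of_vocal = reg, region_class = region_class,
       vocal_labels = vocal_labels)
}

#' Group-by-label contingency table of step vocalizations
#'
#' @param labels result of [classify_regions()] (or a character vector of
#'   `"step"`/`"non_step"` labels aligned with the collection).
#' @param x the `usv_collection` the labels refer to.
#' @return a 2-column integer matrix, rows = groups, columns
#'   `c("step", "non_step")`.
#' @export
step_table <- function(labels, x) {
  lab <- if (is.list(labels)) labels$vocal_labels else labels
  x <- drop_clipped(x)
  if (length(lab) != length(x) || any(is.na(lab)))
    stop("every non-clipped vocalization must carry a label")
  grp <- groups(x)
  if (any(table(grp) == 0)) stop("empty group")
  tab <- table(group = grp, label = factor(lab, levels = c("step", "non_step")))
  out <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), colnames(tab)))
  out
}

#' Pearson chi-squared test on a 2x2 step table
#'
#' With `continuity_correction = TRUE` (the default) the Yates-corrected
#' statistic is returned; the uncorrected Pearson statistic
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` is available by flag.
#'
#' @param table 2x2 integer matrix (rows groups, columns step/non-step).
#' @param continuity_correction logical.
#' @return list with `statistic`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(table, continuity_correction = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ht <- suppressWarnings(
    chisq.test(table, correct = continuity_correction))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Map-based step analysis, end to end
#'
#' Runs the full genotype-blind step pipeline on an embedded collection:
#' pooled density, watershed regions, majority-vote region classes, the
#' group-by-label table, per-group step proportions, and the
#' continuity-corrected chi-squared test.
#'
#' @param map a `usv_map`.
#' @param x the matching `usv_collection`.
#' @param grid optional `usv_grid`.
#' @param sigma density kernel width, map units.
#' @param jump_threshold step threshold, kHz.
#' @param continuity_correction passed to [chi_square_2x2()].
#' @return list with `regions`, `labels`, `table`, `proportions`,
#'   `chi_square`.
#' @export
step_analysis <- function(map, x, grid = NULL, sigma = 4,
                          jump_threshold = 10,
                          continuity_correction = TRUE) {
  if (is.null(grid)) grid <- grid_spec(map, margin = 3 * sigma)
  pooled <- density_map(map, grid = grid, sigma = sigma, group = "pooled")
  regions <- segment_regions(pooled)
  labels <- classify_regions(regions, map, x, grid,
                             jump_threshold = jump_threshold)
  tab <- step_table(labels, x)
  prop <- tab[, "step"] / rowSums(tab)
  list(regions = regions, labels = labels, table = tab, proportions = prop,
       chi_square = chi_square_2x2(tab, continuity_correction))
}
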
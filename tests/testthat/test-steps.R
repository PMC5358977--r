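two_blob_density <- function(sep = 24, n = 60, sigma = 3) {
  map <- structure(list(coordinates = rbind(c(-sep / 2, 0), c(sep / 2, 0)),
                        syllable_order = c("a", "b"), params = list()),
                   class = "usv_map")
  grid <- grid_spec(map, n, n, margin = 3 * sigma)
  list(dens = density_map(map, grid = grid, sigma = sigma), grid = grid)
}

test_that("watershed segmentation finds the density modes", {
  # unimodal density -> one region
  map1 <- structure(list(coordinates = matrix(c(0, 0), 1), params = list()),
                    class = "usv_map")
  g1 <- grid_spec(map1, 40, 40, margin = 9)
  r1 <- segment_regions(density_map(map1, grid = g1, sigma = 3))
  expect_equal(max(r1), 1L)

  # two well-separated blobs -> two regions split near the midline
  tb <- two_blob_density()
  r2 <- segment_regions(tb$dens)
  expect_equal(max(r2), 2L)
  left <- r2[tb$grid$xc < -2, ]
  right <- r2[tb$grid$xc > 2, ]
  expect_equal(unique(left[left > 0]), r2[5, 30])
  expect_true(all(setdiff(unique(right[right > 0]), 0) !=
                  unique(left[left > 0])))

  # background floor 0 assigns every cell
  r3 <- segment_regions(tb$dens, background_mass = 0)
  expect_true(all(r3 > 0))
  expect_gt(sum(r2 == 0), 0)
})

test_that("region classification is a genotype-blind majority vote", {
  # two map clusters; left cluster holds step contours, right flat ones
  set.seed(6)
  n_per <- 20
  coords <- rbind(cbind(rnorm(n_per, -12, 1.5), rnorm(n_per, 0, 1.5)),
                  cbind(rnorm(n_per, 12, 1.5), rnorm(n_per, 0, 1.5)))
  contours <- c(
    lapply(seq_len(n_per), function(i) frequency_contour(
      c(rep(60, 5), rep(80, 5)), hop = 0.001, sprintf("st%02d", i),
      sprintf("p%d", i %% 2 + 1), c("WT", "HT")[i %% 2 + 1])),
    lapply(seq_len(n_per), function(i) frequency_contour(
      rep(70, 10), hop = 0.001, sprintf("fl%02d", i),
      sprintf("p%d", i %% 2 + 1), c("WT", "HT")[i %% 2 + 1]))
  )
  coll <- contour_collection(contours)
  map <- structure(list(coordinates = coords,
                        syllable_order = syllable_ids(coll),
                        params = list()), class = "usv_map")
  grid <- grid_spec(map, 60, 60, margin = 9)
  pooled <- density_map(map, grid = grid, sigma = 3)
  regions <- segment_regions(pooled)
  labels <- classify_regions(regions, map, coll, grid)
  expect_setequal(unique(labels$vocal_labels[1:n_per]), "step")
  expect_setequal(unique(labels$vocal_labels[n_per + 1:n_per]), "non_step")

  # permuting group labels changes nothing in the vocal labels
  coll_perm <- coll
  set.seed(7)
  perm_grp <- sample(groups(coll))
  for (i in seq_along(coll_perm$contours)) {
    coll_perm$contours[[i]]$group <- perm_grp[i]
    coll_perm$contours[[i]]$individual_id <- paste0("q", i)
  }
  labels_perm <- classify_regions(regions, map, coll_perm, grid)
  expect_identical(labels_perm$vocal_labels, labels$vocal_labels)
  # while the contingency table margins do change
  t1 <- step_table(labels, coll)
  t2 <- step_table(labels_perm, coll_perm)
  expect_equal(sum(t1), sum(t2))

  st <- step_table(labels, coll)
  expect_equal(rownames(st), c("HT", "WT"))
  expect_equal(rowSums(st), c(HT = 20, WT = 20))
})

test_that("chi-squared matches its closed form and symmetry", {
  tab <- matrix(c(120, 80, 70, 130), 2, byrow = TRUE)
  res <- chi_square_2x2(tab, continuity_correction = FALSE)
  expect_equal(res$statistic, chi2_2x2_closed_form(tab), tolerance = 1e-12)
  expect_equal(res$df, 1L)

  # Yates correction shrinks the statistic
  res_c <- chi_square_2x2(tab, continuity_correction = TRUE)
  expect_lt(res_c$statistic, res$statistic)

  # swapping rows together with columns leaves the statistic unchanged
  swapped <- tab[2:1, 2:1]
  expect_equal(chi_square_2x2(swapped, FALSE)$statistic, res$statistic)

  flat <- matrix(c(50, 50, 50, 50), 2)
  expect_equal(chi_square_2x2(flat, FALSE)$statistic, 0)

  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "marginal")
  expect_error(chi_square_2x2(matrix(1:6, 2)), "2x2")
})

test_that("map-based step proportions track direct step detection", {
  cfg <- repertoire_config(n_individuals = c(WT = 2, HT = 2),
                           n_calls = c(WT = 150, HT = 150),
                           step_probability = c(WT = 0.75, HT = 0.35),
                           hop = 0.003, seed = 31)
  coll <- generate_repertoire(cfg)
  map <- embed_repertoire(all_pairs(coll), seed = 1)
  # desk-scale map: the density kernel is kept narrow relative to the
  # (small) map extent so watershed regions resolve the template families
  st <- step_analysis(map, coll, sigma = 2)
  m <- measure_collection(coll)
  direct <- tapply(m$has_step, m$group, mean)
  # per-syllable agreement between the map-derived label and the direct
  # detector, and close group proportions (desk-scale collection, so the
  # majority votes carry a little sampling noise)
  agree <- mean((st$labels$vocal_labels == "step") == m$has_step)
  expect_gt(agree, 0.9)
  expect_lt(max(abs(st$proportions[names(direct)] - direct)), 0.07)
  expect_equal(sum(st$table), 300)
})
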
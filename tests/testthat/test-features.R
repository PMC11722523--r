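test_that("overlap metrics match exhaustive intersection counts", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(mito_ld_overlap(a, b)$overlap_px, 0)
  expect_equal(mito_ld_overlap(a, b)$overlap_pct, 0)
  # containment: M superset of L with |L| = 50
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  l <- matrix(FALSE, 20, 20); l[1:5, 1:10] <- TRUE
  ov <- mito_ld_overlap(m, l)
  expect_equal(ov$overlap_px, 50)
  expect_equal(ov$overlap_pct, 100)
  # random masks: brute-force AND count, and symmetry of overlap_px
  for (s in 1:10) {
    set.seed(s)
    x <- matrix(runif(64 * 64) < 0.2, 64, 64)
    y <- matrix(runif(64 * 64) < 0.2, 64, 64)
    expect_equal(mito_ld_overlap(x, y)$overlap_px, sum(x & y))
    expect_equal(mito_ld_overlap(x, y)$overlap_px,
                 mito_ld_overlap(y, x)$overlap_px)
  }
})

test_that("minimum distances match the all-pairs oracle and the overlap rule", {
  # overlapping pair -> 0
  m <- matrix(FALSE, 10, 10); m[3:6, 3:6] <- TRUE
  l <- matrix(0L, 10, 10); l[5:8, 5:8] <- 1L
  d <- mito_ld_min_distance(m, l, 1)
  expect_equal(d$min_dist_um, 0)
  # Pythagorean singletons
  m2 <- matrix(FALSE, 10, 10); m2[1, 1] <- TRUE
  l2 <- matrix(0L, 10, 10); l2[4, 5] <- 1L
  expect_equal(mito_ld_min_distance(m2, l2, 1)$min_dist_um, 5)
  expect_equal(mito_ld_min_distance(m2, l2, 0.4)$min_dist_um, 2)
  # random small masks vs brute-force min over all pixel pairs, and the
  # equivalence min_dist == 0 <=> overlap > 0
  for (s in 1:10) {
    set.seed(s)
    mm <- matrix(runif(48 * 48) < 0.05, 48, 48)
    if (!any(mm)) mm[10, 10] <- TRUE
    lm <- matrix(0L, 48, 48)
    lm[disk_mask(48, 48, sample(5:43, 1), sample(5:43, 1), 3)] <- 1L
    got <- mito_ld_min_distance(mm, lm, 1)$min_dist_um
    expect_equal(got, brute_min_dist(mm, lm), tolerance = 1e-12)
    ov <- mito_ld_overlap(mm, lm > 0)$overlap_px
    expect_identical(got == 0, ov > 0)
  }
  # empty mitochondria mask -> missing distances
  d_na <- mito_ld_min_distance(matrix(FALSE, 10, 10), l, 1)
  expect_true(is.na(d_na$min_dist_um))
})

test_that("per-cell aggregates distinguish zero counts from missing means", {
  empty <- organelle_table(matrix(0L, 5, 5), 1)
  s <- per_cell_stats(100, empty, prefix = "ld")
  expect_equal(s$ld_count, 0)
  expect_equal(s$ld_density, 0)
  expect_true(is.na(s$ld_mean_area_um2))
  # 3 LDs of areas 2, 4, 6 um^2 in a 100 um^2 cell
  orgs <- tibble::tibble(area_um2 = c(2, 4, 6), circularity = c(1, 1, 1),
                         eccentricity = c(0, 0, 0), perimeter_um = c(5, 7, 9),
                         mean_intensity = c(0.5, 0.6, 0.7))
  s2 <- per_cell_stats(100, orgs, prefix = "ld")
  expect_equal(s2$ld_total_area_um2, 12)
  expect_equal(s2$ld_mean_area_um2, 4)
  expect_equal(s2$ld_density, 0.12)
  expect_equal(s2$ld_count_density, 3)
  expect_error(per_cell_stats(0, orgs), class = "lobulemap_data_error")
})

test_that("feature table is empty-but-complete on a blank image", {
  tbl <- build_feature_table(matrix(0L, 10, 10), matrix(0L, 10, 10),
                             matrix(0L, 10, 10))
  expect_equal(nrow(tbl), 0)
  expect_identical(names(tbl), feature_dictionary()$column)
})

test_that("feature table recovers generator counts exactly on truth masks", {
  sim <- cached_sim("control", 1)
  tbl <- cached_features("control", 1)
  expect_equal(nrow(tbl), length(unique(sim$truth$cell_mask[sim$truth$cell_mask > 0])))
  org <- sim$truth$organelles
  truth_ld <- table(factor(org$cell[org$kind == "ld"], levels = tbl$cell))
  truth_mito <- table(factor(org$cell[org$kind == "mito"], levels = tbl$cell))
  expect_equal(tbl$ld_count, as.vector(truth_ld))
  expect_equal(tbl$mito_count, as.vector(truth_mito))
  # densities are proper fractions; overlap bounded by the smaller mask
  expect_true(all(tbl$mito_density >= 0 & tbl$mito_density <= 1))
  expect_true(all(tbl$ld_density >= 0 & tbl$ld_density <= 1))
  expect_true(all(tbl$overlap_pct >= 0 & tbl$overlap_pct <= 100))
})

test_that("fasted lobules show more mitochondria-LD overlap than control", {
  wins <- vapply(1:5, function(s) {
    mean(cached_features("fasted", s)$overlap_px) >
      mean(cached_features("control", s)$overlap_px)
  }, logical(1))
  expect_true(all(wins))
})
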
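toy_veins <- function(h = 40, w = 40) {
  cv <- matrix(FALSE, h, w); cv[18:22, 2:4] <- TRUE
  pv <- matrix(FALSE, h, w); pv[18:22, 37:39] <- TRUE
  vein_annotation(cv, pv)
}

test_that("distance maps are zero on veins and exactly Euclidean", {
  veins <- toy_veins()
  maps <- distance_maps(veins, pixel_size_um = 1)
  expect_true(all(maps$cv[veins$cv] == 0))
  # single-pixel vein: Pythagorean distance
  cv1 <- matrix(FALSE, 10, 10); cv1[1, 1] <- TRUE
  pv1 <- matrix(FALSE, 10, 10); pv1[10, 10] <- TRUE
  m <- distance_maps(vein_annotation(cv1, pv1), 1)
  expect_equal(m$cv[4, 5], 5)  # (3, 4) offset from (0, 0)
  # random masks against the exhaustive min-over-vein-pixels oracle
  for (s in 1:3) {
    set.seed(s)
    vm <- matrix(runif(32 * 32) < 0.04, 32, 32)
    if (!any(vm)) vm[5, 5] <- TRUE
    got <- distance_maps(vein_annotation(vm, vm), 1)$cv
    expect_equal(got, brute_distance_map(vm), tolerance = 1e-12)
  }
  expect_error(vein_annotation(matrix(FALSE, 5, 5), matrix(TRUE, 5, 5)),
               class = "lobulemap_data_error")
})

test_that("normalized CV distance has the right endpoints and symmetry", {
  veins <- toy_veins()
  # centroid on the CV boundary
  on_cv <- normalized_cv_distance(c(3, 20), veins)
  expect_equal(on_cv$r, 0)
  # equidistant from both veins
  mid <- normalized_cv_distance(c(20.5, 20), veins)
  expect_equal(mid$r, 0.5)
  # on both masks simultaneously is a geometry error
  cv <- matrix(FALSE, 10, 10); cv[5, 5] <- TRUE
  expect_error(normalized_cv_distance(c(5, 5), vein_annotation(cv, cv)),
               class = "lobulemap_data_error")
  expect_error(normalized_cv_distance(c(99, 99), veins),
               class = "lobulemap_data_error")
})

test_that("recovered r tracks the generator's true r within 0.05", {
  for (s in 1:5) {
    sim <- cached_sim("control", s)
    tbl <- cached_features("control", s)
    j <- merge(tbl, sim$truth$cells, by = "cell")
    expect_lte(max(abs(j$r - j$r_true)), 0.05)
  }
})

test_that("bin assignment follows the 12-bin periportal-to-pericentral rule", {
  expect_equal(assign_bin(0, 12), 12L)   # pericentral, closest to the CV
  expect_equal(assign_bin(1, 12), 1L)    # periportal
  expect_equal(assign_bin(0.49, 12), 7L)
  # monotone non-increasing in r
  r <- sort(runif(200))
  b <- assign_bin(r, 12)
  expect_true(all(diff(b) <= 0))
  # uniform r covers every bin
  expect_setequal(assign_bin(seq(0, 1, length.out = 500), 12), 1:12)
  expect_error(assign_bin(1.2, 12), class = "lobulemap_data_error")
  expect_error(assign_bin(0.5, 0), class = "lobulemap_config_error")
})

test_that("axis summary recovers the generator's spacing and cell count", {
  for (s in 1:5) {
    sim <- cached_sim("control", s)
    spec <- sim$truth$spec
    a <- axis_summary(sim$truth$cells, sim$truth$veins, spec$pixel_size_um)
    expect_lt(abs(a$axis_length_um - 250) / 250, 0.10)
    expect_equal(a$n_cells, spec$n_cells_per_axis)
  }
  # single cell in an explicit ROI
  veins <- toy_veins()
  veins$roi <- c(1, 1, 40, 40)
  a1 <- axis_summary(tibble::tibble(x = 20, y = 20), veins, 1)
  expect_equal(a1$n_cells, 1L)
  expect_error(axis_summary(tibble::tibble(x = numeric(), y = numeric()),
                            veins, 1),
               class = "lobulemap_data_error")
})
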
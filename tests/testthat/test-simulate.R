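# the generator is first-class code: determinism, ground-truth consistency
# and gradient fidelity are all asserted against the rendered masks

small_spec <- function(overrides = list()) {
  lobule_spec(modifyList(list(axis_length_um = 120, n_cells_per_axis = 7,
                              n_cell_rows = 2, cell_radius_um = 6), overrides))
}

test_that("identical spec and seed give bit-identical output", {
  a <- simulate_lobule(small_spec(), seed = 7)
  b <- simulate_lobule(small_spec(), seed = 7)
  expect_identical(a$channels$channels, b$channels$channels)
  expect_identical(a$truth$cell_mask, b$truth$cell_mask)
  expect_identical(a$truth$organelles, b$truth$organelles)
})

test_that("zero LD gradient yields an empty LD mask and a flat LD channel", {
  spec <- small_spec(list(gradients = list(ld_count = c(pc = 0, pp = 0)),
                          noise = list(sigma = 0, background = 0.03,
                                       poisson = FALSE)))
  sim <- simulate_lobule(spec, seed = 3)
  expect_equal(sum(sim$truth$ld_mask), 0)
  expect_equal(unique(as.vector(sim$channels$channels$ld)),
               round(0.03 * 65535) / 65535)
})

test_that("contact_fraction = 1 makes every LD share a pixel with a mitochondrion", {
  spec <- small_spec(list(gradients = list(contact_fraction = c(pc = 1, pp = 1))))
  sim <- simulate_lobule(spec, seed = 11)
  ld_px <- split(which(sim$truth$ld_mask > 0),
                 sim$truth$ld_mask[sim$truth$ld_mask > 0])
  expect_gt(length(ld_px), 0)
  # brute-force mask intersection per droplet
  touches <- vapply(ld_px, function(idx) any(sim$truth$mito_mask[idx] > 0),
                    logical(1))
  expect_true(all(touches))
  expect_true(all(sim$truth$organelles$contact_realized[
    sim$truth$organelles$kind == "ld"]))
})

test_that("noise-free channels re-threshold to the exact ground-truth pixel sets", {
  spec <- small_spec(list(noise = list(sigma = 0, background = 0.03,
                                       poisson = FALSE)))
  sim <- simulate_lobule(spec, seed = 5)
  bg <- round(0.03 * 65535) / 65535
  expect_identical(sim$channels$channels$mito > bg, sim$truth$mito_mask > 0)
  expect_identical(sim$channels$channels$ld > bg, sim$truth$ld_mask > 0)
})

test_that("every organelle lies inside exactly one cell and flags match overlap", {
  sim <- cached_sim("control", 1)
  for (mask in list(sim$truth$mito_mask, sim$truth$ld_mask)) {
    px <- split(which(mask > 0), mask[which(mask > 0)])
    owners <- vapply(px, function(idx) {
      u <- unique(sim$truth$cell_mask[idx])
      length(u) == 1L && all(u > 0L)
    }, logical(1))
    expect_true(all(owners))
  }
  org <- sim$truth$organelles
  lds <- org[org$kind == "ld", ]
  ld_px <- split(which(sim$truth$ld_mask > 0),
                 sim$truth$ld_mask[sim$truth$ld_mask > 0])
  realized <- vapply(as.character(lds$label),
                     function(l) any(sim$truth$mito_mask[ld_px[[l]]] > 0),
                     logical(1))
  expect_equal(unname(realized), lds$contact_realized)
})

test_that("cell bins cover the axis and match the bin rule applied to true r", {
  sim <- cached_sim("control", 1)
  cells <- sim$truth$cells
  expect_equal(cells$bin, assign_bin(cells$r_true, 12))
  expect_true(all(1:12 %in% cells$bin))
})

test_that("realized LD counts follow the planted gradient slope across seeds", {
  slopes <- vapply(1:5, function(s) {
    sim <- cached_sim("control", s)
    org <- sim$truth$organelles
    counts <- table(factor(org$cell[org$kind == "ld"],
                           levels = sim$truth$cells$cell))
    stats::coef(stats::lm(as.numeric(counts) ~ sim$truth$cells$r_true))[2]
  }, numeric(1))
  # control ld_count decreases with r, so all slopes must be negative
  expect_true(all(slopes < 0))
})

test_that("overcrowded specs fail with a placement error naming the constraint", {
  expect_error(
    simulate_lobule(lobule_spec(list(axis_length_um = 60, n_cells_per_axis = 14)),
                    seed = 1),
    regexp = "packed", class = "lobulemap_placement_error"
  )
})
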
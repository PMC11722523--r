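test_that("combination channel handles degenerate inputs", {
  z <- matrix(0, 20, 20)
  expect_equal(make_combination_channel(z, z, 2), z)
  # sigma 0: no blur, output is the rescaled sum
  a <- matrix(runif(400), 20, 20)
  m <- matrix(runif(400), 20, 20)
  comb <- make_combination_channel(a, m, 0)
  direct <- rescale01(rescale01(a, 0.01, 0.99) + rescale01(m, 0.01, 0.99))
  expect_equal(comb, direct, tolerance = 1e-12)
  expect_error(make_combination_channel(a, matrix(0, 5, 5)),
               class = "lobulemap_data_error")
})

test_that("blurred impulse matches a direct convolution oracle", {
  mito <- matrix(0, 31, 31); mito[16, 16] <- 1
  actin <- matrix(0, 31, 31)
  comb <- make_combination_channel(actin, mito, sigma_px = 3)
  # oracle: direct O(n^2 k^2) convolution with the same normalized kernel
  r <- ceiling(3 * 3)
  k <- outer(dnorm(-r:r, sd = 3), dnorm(-r:r, sd = 3)); k <- k / sum(k)
  direct <- matrix(0, 31, 31)
  for (i in 1:31) for (j in 1:31) {
    di <- 16 - i; dj <- 16 - j
    if (abs(di) <= r && abs(dj) <= r) direct[i, j] <- k[di + r + 1, dj + r + 1]
  }
  direct <- direct / max(direct)   # combination output is rescaled to [0, 1]
  expect_equal(comb, direct, tolerance = 1e-9)
  expect_equal(which.max(comb), which.max(direct))
})

test_that("watershed baseline recovers disjoint bright objects and splits bridges", {
  expect_equal(max(segment_instances(matrix(0.5, 30, 30), backend_watershed())), 0)

  img <- matrix(0.05, 80, 200)
  truth <- matrix(0L, 80, 200)
  ctrs <- cbind(x = c(25, 65, 105, 145, 185), y = c(40, 25, 55, 40, 30))
  for (i in 1:5) {
    m <- disk_mask(80, 200, ctrs[i, 1], ctrs[i, 2], 12)
    img[m] <- 0.9; truth[m] <- i
  }
  seg <- segment_instances(img, backend_watershed(), min_area_px = 5)
  expect_equal(max(seg), 5)
  for (i in 1:5) {
    t <- truth == i
    lab <- as.integer(names(which.max(table(seg[t & seg > 0]))))
    s <- seg == lab
    expect_gte(sum(s & t) / sum(s | t), 0.9)
  }

  # two disks joined by a 1-px bridge split along the distance transform
  img2 <- matrix(0, 60, 100)
  img2[disk_mask(60, 100, 30, 30, 15)] <- 1
  img2[disk_mask(60, 100, 70, 30, 15)] <- 1
  img2[30, 44:56] <- 1
  seg2 <- segment_instances(img2, backend_watershed(sigma_px = 0, threshold = 0.5), 5)
  expect_equal(max(seg2), 2)
})

test_that("min_area_px filtering relabels survivors consecutively", {
  img <- matrix(0, 40, 40)
  img[disk_mask(40, 40, 10, 10, 6)] <- 1
  img[20, 30] <- 1   # single speckle
  seg <- segment_instances(img, backend_watershed(sigma_px = 0, threshold = 0.5),
                           min_area_px = 5)
  expect_equal(sort(unique(as.vector(seg))), c(0L, 1L))
})

test_that("backend failures carry the backend name", {
  bad <- segmenter_backend(function(img, params) stop("boom"), name = "flaky")
  expect_error(segment_instances(matrix(0, 5, 5), bad), regexp = "flaky")
})

test_that("LD intensity filter removes dim objects and is idempotent", {
  mask <- matrix(0L, 20, 40)
  mask[5:8, 5:8] <- 1L
  mask[5:8, 25:28] <- 2L
  ch <- matrix(0, 20, 40)
  ch[mask == 1L] <- 10; ch[mask == 2L] <- 100
  res <- filter_ld_segments(mask, ch, threshold = 50)
  expect_equal(sort(unique(as.vector(res$mask))), c(0L, 1L))
  expect_equal(res$removed$label, 1L)
  expect_true(all(ch[res$mask == 1L] == 100))

  # threshold 0 leaves the mask unchanged
  res0 <- filter_ld_segments(mask, ch, threshold = 0)
  expect_identical(res0$mask, mask)
  # idempotence at a fixed threshold
  res2 <- filter_ld_segments(res$mask, ch, threshold = 50)
  expect_identical(res2$mask, res$mask)
  expect_equal(nrow(res2$removed), 0)
})

test_that("otsu on per-object means removes exactly the dim synthetic droplets", {
  set.seed(42)
  h <- 60; w <- 220
  mask <- matrix(0L, h, w)
  centers <- expand.grid(y = c(15, 45), x = seq(12, 205, by = 21))[1:20, ]
  for (i in 1:20) mask[disk_mask(h, w, centers$x[i], centers$y[i], 4)] <- i
  ch <- matrix(0.03, h, w)
  dim_ids <- c(3, 7, 11, 16, 20)
  for (i in 1:20) {
    ch[mask == i] <- if (i %in% dim_ids) 0.03 + rnorm(sum(mask == i), 0, 0.005)
      else 0.8 + rnorm(sum(mask == i), 0, 0.02)
  }
  res <- filter_ld_segments(mask, ch, threshold = "otsu")
  expect_setequal(res$removed$label, dim_ids)
  expect_equal(max(res$mask), 15)
  # oracle: exhaustive per-object means split at the applied threshold
  means <- vapply(1:20, function(i) mean(ch[mask == i]), numeric(1))
  expect_setequal(which(means < res$threshold), dim_ids)
})

test_that("organelle assignment follows the plurality rule with brute-force parity", {
  cells <- matrix(0L, 30, 30)
  cells[1:30, 1:15] <- 1L; cells[1:30, 16:30] <- 2L
  org <- matrix(0L, 30, 30)
  org[5:8, 5:8] <- 1L                 # wholly inside cell 1
  org[10:14, 13:17] <- 2L             # 60/40 split across the border
  a <- assign_organelles_to_cells(org, cells, min_fraction = 0.5)
  expect_equal(a$map$cell[a$map$organelle == 1], 1L)
  expect_equal(a$map$cell[a$map$organelle == 2], 1L)

  # orphaned when mostly outside any cell
  cells2 <- matrix(0L, 30, 30); cells2[1:30, 1:5] <- 1L
  a2 <- assign_organelles_to_cells(org, cells2, min_fraction = 0.5)
  expect_setequal(a2$orphans, c(1L, 2L))

  # random masks: parity with a brute-force pixel tally, and conservation
  for (s in 1:5) {
    set.seed(s)
    cm <- matrix(sample(0:4, 64 * 64, replace = TRUE), 64, 64)
    om <- random_blob_mask(64, 64, 6, seed = 100 + s)
    a3 <- assign_organelles_to_cells(om, cm, min_fraction = 0)
    labs <- sort(unique(om[om > 0]))
    expect_equal(nrow(a3$map) + length(a3$orphans), length(labs))
    for (l in labs) {
      owners <- cm[om == l]; owners <- owners[owners > 0]
      if (length(owners) == 0) {
        expect_true(l %in% a3$orphans)
      } else {
        tab <- table(owners)
        winners <- as.integer(names(tab)[tab == max(tab)])
        expect_equal(a3$map$cell[a3$map$organelle == l], min(winners))
      }
    }
  }
})
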
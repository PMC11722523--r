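test_that("bin aggregation computes mean, n-1 SD and flags missing bins", {
  tbl <- tibble::tibble(bin = c(1, 1, 2), f = c(2, 4, 7))
  prof <- aggregate_by_bin(tbl, "f", n_bins = 3)
  df <- tidy(prof)
  expect_equal(df$mean[df$bin == 1], 3)
  expect_equal(df$sd[df$bin == 1], sqrt(2))
  # single observation: mean is the value, SD missing
  expect_equal(df$mean[df$bin == 2], 7)
  expect_true(is.na(df$sd[df$bin == 2]))
  # empty bin retained with n = 0 and missing mean
  expect_equal(df$n[df$bin == 3], 0)
  expect_true(is.na(df$mean[df$bin == 3]))
  expect_error(aggregate_by_bin(tbl, "nope"), class = "lobulemap_key_error")
})

test_that("standardization z-scores features, drops constants and round-trips", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  rownames(m) <- paste0("R", 1:3)
  expect_warning(zs <- standardize_profile(m), regexp = "constant")
  expect_false("b" %in% colnames(zs$z))
  expect_equal(unname(zs$z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(zs$z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(zs$z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unstandardize(zs), m[, c("a", "c")], tolerance = 1e-9)
})

test_that("PCA embedding matches an eigendecomposition oracle up to sign", {
  set.seed(7)
  m <- matrix(rnorm(12 * 8), 12, 8)
  p <- pca_embed(m, 3)
  cm <- sweep(m, 2, colMeans(m))
  ev <- eigen(cov(cm), symmetric = TRUE)
  sc <- cm %*% ev$vectors[, 1:3]
  for (j in 1:3) {  # apply the same sign convention to the oracle
    i <- which.max(abs(ev$vectors[, j]))
    if (ev$vectors[i, j] < 0) sc[, j] <- -sc[, j]
  }
  expect_equal(unname(p$scores), unname(sc), tolerance = 1e-8)
  expect_true(all(diff(p$var_explained) <= 1e-12))
  expect_lte(sum(p$var_explained), 1 + 1e-12)
})

test_that("PCA degenerate geometries behave analytically", {
  # identical rows: all scores at the origin
  m <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4)
  expect_warning(p <- pca_embed(m, 2), regexp = "rank")
  expect_equal(max(abs(p$scores)), 0, tolerance = 1e-12)
  # collinear 2-D points: PC1 explains ~100%
  t <- seq(0, 1, length.out = 10)
  line <- cbind(2 * t, -t + 0.5)
  expect_warning(p2 <- pca_embed(line, 2), regexp = "rank")
  expect_equal(p2$var_explained[1], 1, tolerance = 1e-9)
  # scores invariant to feature ordering
  set.seed(1)
  m3 <- matrix(rnorm(60), 10, 6); colnames(m3) <- letters[1:6]
  expect_equal(pca_embed(m3, 2)$scores,
               pca_embed(m3[, sample(6)], 2)$scores, tolerance = 1e-9)
})

test_that("hierarchical clustering merges duplicates at zero and splits outliers", {
  m <- rbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  cm <- hierarchical_clustermap(m, k = 2)
  expect_equal(min(cm$row_hclust$height), 0)
  expect_equal(unname(cm$clusters["a"]), unname(cm$clusters["b"]))
  # forced 1-D geometry {0, 0.1, 10} at k = 2
  m2 <- matrix(c(0, 0.1, 10), 3, 1)
  cl <- hierarchical_clustermap(m2, k = 2)$clusters
  expect_equal(unname(cl), c(1L, 1L, 2L))
  expect_error(hierarchical_clustermap(m2[1, , drop = FALSE]),
               class = "lobulemap_data_error")
})

test_that("planted three-zone structure is recovered by clustering and PCA", {
  skip_if_not_installed("mclust")
  aris <- ok_pca <- logical(5)
  for (s in 1:5) {
    tbl <- cached_features("zones", 100 + s)
    zs <- standardize_profile(aggregate_by_bin(tbl))
    cl <- hierarchical_clustermap(zs, k = 3)
    aris[s] <- mclust::adjustedRandIndex(unname(cl$clusters),
                                         planted_zone_labels) >= 0.8
    p <- pca_embed(zs, 2)
    d <- as.matrix(dist(p$scores))
    same <- outer(planted_zone_labels, planted_zone_labels, "==") & upper.tri(d)
    diff <- outer(planted_zone_labels, planted_zone_labels, "!=") & upper.tri(d)
    ok_pca[s] <- mean(d[same]) < mean(d[diff])
  }
  expect_true(all(aris))
  expect_true(all(ok_pca))
})

test_that("condition correlation matches the direct covariance formula", {
  mk_prof <- function(seed, cond) {
    set.seed(seed)
    tbl <- tibble::tibble(bin = rep(1:6, each = 4),
                          f1 = rnorm(24), f2 = rnorm(24), f3 = rnorm(24),
                          f4 = rnorm(24))
    aggregate_by_bin(tbl, paste0("f", 1:4), n_bins = 6, condition = cond)
  }
  pa <- mk_prof(1, "a"); pb <- mk_prof(2, "b")
  cc <- condition_correlation(pa, pb)
  # oracle: direct covariance-formula Pearson on the same pooled z-scores
  ma <- profile_matrix(pa); mb <- profile_matrix(pb)
  pooled <- rbind(ma, mb)
  z <- sweep(sweep(pooled, 2, colMeans(pooled)), 2, apply(pooled, 2, sd), "/")
  za <- z[1:6, ]; zb <- z[7:12, ]
  direct <- function(u, v) {
    du <- u - mean(u); dv <- v - mean(v)
    sum(du * dv) / sqrt(sum(du^2) * sum(dv^2))
  }
  for (i in c(1, 3, 6)) for (j in c(2, 5)) {
    expect_equal(cc[i, j], direct(za[i, ], zb[j, ]), tolerance = 1e-10)
  }
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
  # a profile against itself: symmetric with unit diagonal
  self <- condition_correlation(pa, pa)
  expect_equal(unname(diag(self)), rep(1, 6), tolerance = 1e-12)
  expect_equal(unclass(self), t(unclass(self)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # perfectly anti-correlated bins
  m_anti <- rbind(R1 = c(1, 2, 3, 4), R2 = -c(1, 2, 3, 4))
  r <- cor(m_anti[1, ], m_anti[2, ])
  expect_equal(r, -1)
  expect_error(condition_correlation(
    aggregate_by_bin(tibble::tibble(bin = 1:2, f1 = 1:2, f2 = 2:1), n_bins = 2),
    aggregate_by_bin(tibble::tibble(bin = 1:2, f1 = 1:2, f2 = 2:1), n_bins = 2)
  ), class = "lobulemap_stats_error")
})

test_that("overlap heatmap extracts per-bin means consistently per condition", {
  tbl0 <- tibble::tibble(bin = rep(1:4, 3), overlap_px = 0)
  p0 <- aggregate_by_bin(tbl0, "overlap_px", n_bins = 4, condition = "quiet")
  oh0 <- overlap_heatmap(list(p0))
  expect_equal(oh0$quiet, rep(0, 4))
  set.seed(3)
  tbl1 <- tibble::tibble(bin = rep(1:4, 5), overlap_px = rpois(20, 30))
  p1 <- aggregate_by_bin(tbl1, "overlap_px", n_bins = 4, condition = "busy")
  oh <- overlap_heatmap(list(p0, p1))
  expect_equal(oh$busy, unname(profile_matrix(p1)[, "overlap_px"]))
  expect_error(overlap_heatmap(list(p1), feature = "not_there"),
               class = "lobulemap_key_error")
})

test_that("tidiers and autoplots return the documented shapes", {
  tbl <- cached_features("control", 1)
  prof <- aggregate_by_bin(tbl, condition = "control")
  expect_s3_class(autoplot(prof, features = c("ld_count", "mito_count")), "ggplot")
  zs <- standardize_profile(prof)
  p <- pca_embed(zs, 2)
  expect_s3_class(autoplot(p), "ggplot")
  expect_named(glance(p), c("n_components", "total_var_explained"))
  cm <- hierarchical_clustermap(zs, k = 3)
  expect_s3_class(autoplot(cm), "ggplot")
  expect_equal(nrow(tidy(cm)), 12)
  cc <- condition_correlation(prof, prof)
  expect_s3_class(autoplot(cc), "ggplot")
  expect_equal(nrow(tidy(cc)), 144)
  oh <- overlap_heatmap(list(control = prof))
  expect_s3_class(autoplot(oh), "ggplot")
})
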
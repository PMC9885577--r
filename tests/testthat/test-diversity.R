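test_that("alpha diversity matches closed forms", {
  u <- matrix(rep(10, 10), nrow = 1)
  expect_equal(alpha_diversity(u, "shannon")[[1]], log(10), tolerance = 1e-12)
  expect_equal(alpha_diversity(u, "simpson")[[1]], 0.9, tolerance = 1e-12)
  expect_equal(alpha_diversity(u, "invsimpson")[[1]], 10, tolerance = 1e-12)
  expect_equal(alpha_diversity(u, "observed")[[1]], 10)
  single <- matrix(c(42, 0, 0), nrow = 1)
  expect_equal(alpha_diversity(single, "shannon")[[1]], 0, tolerance = 1e-12)
  expect_equal(alpha_diversity(single, "simpson")[[1]], 0, tolerance = 1e-12)
  expect_equal(alpha_diversity(single, "invsimpson")[[1]], 1, tolerance = 1e-12)
  ## bias-corrected richness: S=4, F1=2, F2=1 -> 4 + 2*1/(2*2)
  expect_equal(alpha_diversity(matrix(c(5, 1, 1, 2), nrow = 1), "chao1")[[1]],
               4.5, tolerance = 1e-12)
  expect_error(alpha_diversity(rbind(c(1, 1), c(0, 0)), "shannon"), "empty")
})

test_that("Bray-Curtis matches hand computation and its bounds", {
  expect_equal(bray_curtis(rbind(c(1, 2, 3), c(2, 2, 0)))[1, 2], 0.4,
               tolerance = 1e-12)
  expect_equal(bray_curtis(rbind(c(3, 1), c(3, 1)))[1, 2], 0)
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 5)))[1, 2], 1)
  set.seed(1)
  m <- matrix(rpois(60, 4), nrow = 6)
  d <- bray_curtis(m)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0), c(1, 2))), "all-zero")
})

test_that("PCoA reproduces planar configurations and triangle eigenvalues", {
  tri <- as.matrix(dist(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))))
  out <- pcoa(tri, 2)
  expect_equal(out$eigenvalues, c(0.5, 0.5, 0), tolerance = 1e-9)
  ## planar point set: later eigenvalues vanish and distances are reproduced
  set.seed(3)
  pts <- cbind(rnorm(8), rnorm(8))
  d <- as.matrix(dist(pts))
  o <- pcoa(d, 2)
  expect_true(all(abs(o$eigenvalues[-(1:2)]) < 1e-9))
  expect_equal(as.matrix(dist(o$coordinates)), d,
               tolerance = 1e-9, ignore_attr = TRUE)
  ## duplicated sample lands on coincident coordinates
  d2 <- as.matrix(dist(rbind(pts, pts[1, ])))
  o2 <- pcoa(d2, 2)
  expect_equal(o2$coordinates[1, ], o2$coordinates[9, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_warning(pcoa(tri, 3), "axes")
})

test_that("PERMANOVA agrees with the exhaustive enumeration oracle at n = 6", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(6, 0), ncol = 2), matrix(rnorm(6, 1.2), ncol = 2))
  dm <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 3)
  p_exact <- oracle_exact_permanova_p(dm, g)
  res <- permanova(dm, g, n_perm = 10000, seed = 1)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(res$p_value - p_exact), 2 * se + 1e-4)
})

test_that("PERMANOVA handles degenerate and extreme configurations", {
  dm <- matrix(0, 8, 8)
  res <- permanova(dm, rep(c("a", "b"), 4), n_perm = 99, seed = 1)
  expect_equal(res$p_value, 1)
  ## two perfectly separated clusters reach the permutation floor
  pts <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
               matrix(rnorm(20, 50, 0.01), ncol = 2))
  g <- rep(c("a", "b"), each = 10)
  res2 <- permanova(as.matrix(dist(pts)), g, n_perm = 199, seed = 2)
  expect_equal(res2$p_value, 1 / 200, tolerance = 1e-12)
  expect_warning(
    permanova(as.matrix(dist(pts)), g,
              strata = c("x", rep(c("u", "v"), length.out = 19)),
              n_perm = 99, seed = 1),
    "strata")
})

test_that("PERMDISP flags unequal dispersions and rejects a single group", {
  set.seed(5)
  tight <- matrix(rnorm(30, sd = 0.05), ncol = 2)
  wide <- matrix(rnorm(30, sd = 5), ncol = 2)
  d <- as.matrix(dist(rbind(tight, wide)))
  g <- rep(c("t", "w"), each = 15)
  res <- permdisp(d, g, n_perm = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200, tolerance = 5e-2)
  expect_error(permdisp(d, rep("t", 30)), "2 groups")
})

test_that("group comparisons control type-I error and detect shifts", {
  set.seed(8)
  ## null: permuted labels, BH discoveries stay rare
  any_disc <- replicate(200, {
    x <- matrix(rnorm(30 * 20), nrow = 30)
    g <- sample(rep(c("a", "b"), 15))
    res <- group_compare(x, g, test = "wilcoxon", correction = "bh")
    sum(res$q < 0.05)
  })
  expect_lte(mean(any_disc > 0), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
  ## power: a 2-SD location shift at n = 20/20 is nearly always caught
  hits <- replicate(100, {
    v <- c(rnorm(20), rnorm(20, 2))
    res <- group_compare(v, rep(c("a", "b"), each = 20), test = "wilcoxon")
    res$p < 0.01
  })
  expect_gte(mean(hits), 0.95)
  ## single feature: BH leaves the p-value untouched
  v <- c(rnorm(10), rnorm(10, 1))
  res <- group_compare(v, rep(c("a", "b"), each = 10), test = "ttest")
  expect_equal(res$q, res$p)
  ## constants are flagged with p = 1
  resc <- group_compare(rep(1, 20), rep(c("a", "b"), each = 10), test = "ttest")
  expect_true(resc$constant)
  expect_equal(resc$p, 1)
})
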
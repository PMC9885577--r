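test_that("components equal or orthogonal to the cohort indicator are handled", {
  set.seed(1)
  n <- 60
  cohort <- rep(c("big", "big", "small"), length.out = n)
  ind <- as.numeric(cohort == "big")
  ## feature 1 is the (scaled) indicator: its principal component stands out
  ## of the noise floor, sits below the variance cap, and must be removed
  ## with |r| ~ 1
  X <- cbind(ind * 3.5, matrix(rnorm(n * 20), nrow = n))
  fair <- fair_component_filter(X, cohort)
  r_removed <- abs(fair$r[fair$removed])
  expect_true(any(r_removed > 0.9))
  ## cohort-orthogonal data: nothing exceeds the threshold
  X0 <- matrix(rnorm(n * 6), nrow = n)
  fair0 <- fair_component_filter(X0, cohort, r_threshold = 0.45)
  expect_length(fair0$removed, 0)
  expect_equal(fair0$retained_variance, 1)
  expect_error(fair_component_filter(X, rep("one", n)), "2 cohorts")
})

test_that("component selection finds a planted fibrosis component", {
  set.seed(2)
  n <- 60
  cohort <- rep(c("a", "b"), each = 30)
  y <- factor(rep(c("F0", "F12"), length.out = n))
  X <- matrix(rnorm(n * 30), nrow = n)
  X[, 3] <- X[, 3] + 3 * (as.numeric(y) - 1.5)   # one informative direction
  fair <- fair_component_filter(X, cohort, r_threshold = 0.45)
  sel <- select_fair_components(fair, y, n_top = 5, seed = 1)
  expect_equal(nrow(sel), 5)
  top_comp <- sel$component[1]
  expect_lt(sel$q[1], 0.05)
  ## identity selection when n_top covers everything
  sel_all <- select_fair_components(fair, y, n_top = 1000, seed = 1)
  expect_equal(nrow(sel_all), ncol(fair$coordinates))
})

test_that("association graphs reflect duplicate, null and block structure", {
  set.seed(3)
  n <- 200
  base <- rnorm(n)
  X <- cbind(a = base, b = base, matrix(rnorm(n * 10), nrow = n,
                                        dimnames = list(NULL, paste0("n", 1:10))))
  A <- build_association_graph(X, threshold = 0.5)
  expect_equal(A["a", "b"], 1, tolerance = 1e-12)
  offdiag <- A[upper.tri(A)]
  expect_lt(mean(offdiag > 0), 0.02)          # null edges essentially absent
  expect_equal(unname(diag(A)), rep(0, ncol(X)))
  ## block covariance: denser within than between blocks
  blk <- rep(1:3, each = 10)
  Z <- sapply(1:30, function(j) rnorm(100))
  common <- sapply(1:3, function(b) rnorm(100))
  Z <- Z * 0.6 + common[, blk] * 0.8
  B <- build_association_graph(Z, threshold = 0.3)
  within <- mean(B[outer(blk, blk, "==") & upper.tri(B)] > 0)
  between <- mean(B[outer(blk, blk, "!=") & upper.tri(B)] > 0)
  expect_gt(within, between)
  expect_warning(build_association_graph(cbind(X, const = 1)), "constant")
})

test_that("l1-spectral clustering recovers disconnected cliques exactly", {
  blocks <- c(4, 5, 6)
  n <- sum(blocks)
  lab_true <- rep(seq_along(blocks), blocks)
  A <- outer(lab_true, lab_true, "==") * 1
  diag(A) <- 0
  for (s in 1:3) {
    cl <- l1_spectral_cluster(A, k = 3, seed = s)
    expect_equal(oracle_ari(cl$labels, lab_true), 1)
  }
  ## automatic k lands on the number of components
  cl_auto <- l1_spectral_cluster(A, k = "auto", seed = 1)
  expect_equal(cl_auto$k, 3)
  expect_error(l1_spectral_cluster(matrix(0, 4, 4)), "empty")
  expect_error(l1_spectral_cluster(A, k = 99), "number of nodes")
})

test_that("l1-spectral clustering solves stochastic block models", {
  aris <- vapply(1:10, function(s) {
    set.seed(100 + s)
    lab_true <- rep(1:3, each = 10)
    P <- ifelse(outer(lab_true, lab_true, "=="), 0.9, 0.05)
    A <- matrix(rbinom(900, 1, P), 30, 30)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    cl <- l1_spectral_cluster(A, k = 3, seed = s)
    oracle_ari(cl$labels, lab_true)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("l1-spectral partitions are near the brute-force normalized-cut optimum", {
  bank <- six_node_graph_bank()
  for (nm in names(bank)) {
    A <- bank[[nm]]
    cl <- l1_spectral_cluster(A, k = 2, seed = 1)
    got <- fairbiome:::normalized_cut(A, cl$labels)
    best <- oracle_min_ncut(A, 2)
    expect_lte(got, best * 1.1 + 1e-9)
  }
})

test_that("fairlet decomposition respects balance and feasibility", {
  set.seed(4)
  pts <- matrix(rnorm(24), ncol = 2)
  ## equal colors, balance 1:1 -> perfect color-paired couples
  colors <- rep(c("x", "y"), 6)
  fl <- fairlet_decompose(pts, colors, balance = c(1, 1))
  expect_true(all(lengths(fl$members) == 2))
  for (m in fl$members) expect_setequal(as.character(colors[m]), c("x", "y"))
  ## colors 2:1 with balance 1:2 -> triples with one minority point each
  colors2 <- rep(c("maj", "maj", "min"), 4)
  fl2 <- fairlet_decompose(pts, colors2, balance = c(1, 2))
  expect_true(all(lengths(fl2$members) == 3))
  for (m in fl2$members) expect_equal(sum(colors2[m] == "min"), 1)
  expect_error(fairlet_decompose(pts, rep("x", 12)), "single color")
  expect_error(fairlet_decompose(pts, colors2, balance = c(1, 1)), "achievable")
})

test_that("fair k-median respects balance and the exhaustive oracle ordering", {
  set.seed(5)
  pts <- matrix(rnorm(16), ncol = 2)
  colors <- rep(c("r", "b"), 4)
  D <- as.matrix(dist(pts))
  km <- fair_kmedian(pts, colors, k = 2, balance = c(1, 1), seed = 1)
  expect_gte(km$objective, oracle_kmedian_optimum(D, 2) - 1e-9)
  expect_true(all(apply(km$composition, 1, function(r) min(r) / max(r)) >= 1 - 1e-9))
  ## k = 1: single balanced cluster, objective = distances to the 1-median
  km1 <- fair_kmedian(pts, colors, k = 1, balance = c(1, 1), seed = 1)
  expect_equal(km1$objective, oracle_kmedian_optimum(D, 1), tolerance = 1e-9)
  ## well-separated balanced blobs are recovered exactly
  blob <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
                matrix(rnorm(20, 10, 0.1), ncol = 2))
  bcol <- rep(c("r", "b"), 10)
  kmb <- fair_kmedian(blob, bcol, k = 2, balance = c(1, 1), seed = 1)
  expect_equal(oracle_ari(kmb$labels, rep(1:2, each = 10)), 1)
  expect_error(fair_kmedian(pts, colors, k = 20), "exceeds")
})

test_that("cluster-fibrosis association detects planted clusters and keeps size", {
  set.seed(6)
  n <- 60; p <- 30
  y <- factor(rep(c("F0", "F12"), each = 30))
  X <- matrix(rnorm(n * p), nrow = n, dimnames = list(NULL, paste0("o", 1:p)))
  X[, 1:5] <- X[, 1:5] + 2 * (as.numeric(y) - 1.5)
  labels <- stats::setNames(rep(c(1, 2, 3), each = 10), colnames(X))
  res <- cluster_group_association(labels, X, y)
  expect_lt(res$q[res$cluster == 1], 0.05)
  expect_gt(min(res$q[res$cluster != 1]), 0.05)
  ## single cluster: q equals p
  one <- cluster_group_association(stats::setNames(rep(1, p), colnames(X)), X, y)
  expect_equal(one$q, one$p)
  ## null clusters stay quiet across repeated simulations
  sig <- replicate(100, {
    Z <- matrix(rnorm(40 * 20), nrow = 40, dimnames = list(NULL, paste0("z", 1:20)))
    lb <- stats::setNames(rep(1:2, each = 10), colnames(Z))
    r <- cluster_group_association(lb, Z, factor(rep(c("a", "b"), 20)))
    any(r$q < 0.05)
  })
  expect_lte(mean(sig), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})
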
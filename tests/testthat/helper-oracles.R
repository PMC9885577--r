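## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths.

## CSS scaling factor, re-derived from first principles: sort the non-zero
## counts, take the inclusive empirical quantile by linear interpolation
## (h = (n-1)p + 1), and sum every count not exceeding it.
oracle_css_factor <- function(x, p) {
  nz <- sort(x[x > 0])
  n <- length(nz)
  if (n == 0) return(NA_real_)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  q <- nz[lo] + (h - lo) * (nz[min(lo + 1, n)] - nz[lo])
  s <- 0
  for (v in x) if (v <= q) s <- s + v
  s
}

## one-way PERMANOVA pseudo-F from a distance matrix, written directly from
## the sums-of-squares partition
oracle_pseudo_f <- function(dm, groups) {
  n <- nrow(dm)
  groups <- as.factor(groups)
  sst <- sum(dm[upper.tri(dm)]^2) / n
  ssw <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- dm[idx, idx]
      ssw <- ssw + sum(sub[upper.tri(sub)]^2) / length(idx)
    }
  }
  ssb <- sst - ssw
  k <- nlevels(groups)
  (ssb / (k - 1)) / (ssw / (n - k))
}

## exact permutation p-value by full enumeration of distinct labellings
oracle_exact_permanova_p <- function(dm, groups) {
  n <- nrow(dm)
  f_obs <- oracle_pseudo_f(dm, groups)
  perms <- combn(n, sum(groups == unique(groups)[1]))
  fs <- apply(perms, 2, function(idx) {
    g <- rep("b", n); g[idx] <- "a"
    oracle_pseudo_f(dm, g)
  })
  mean(fs >= f_obs - 1e-12)
}

## exhaustive unconstrained k-median (medoid) optimum on small point sets
oracle_kmedian_optimum <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  meds <- combn(n, k)
  for (j in seq_len(ncol(meds))) {
    m <- meds[, j]
    best <- min(best, sum(apply(D[, m, drop = FALSE], 1, min)))
  }
  best
}

## exhaustive minimum normalized cut over all k-partitions of a small graph
oracle_min_ncut <- function(A, k) {
  n <- nrow(A)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    lab <- as.integer(grid[i, ])
    if (length(unique(lab)) != k) next
    best <- min(best, fairbiome:::normalized_cut(A, lab))
  }
  best
}

## adjusted Rand index between two partitions
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  maxi <- (si + sj) / 2
  if (abs(maxi - expected) < 1e-12) return(1)
  (sij - expected) / (maxi - expected)
}

## small fixed bank of 6-node test graphs for spectral-clustering checks
six_node_graph_bank <- function() {
  g <- list()
  ## two triangles joined by one bridge edge
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- 1
  a[4, 5] <- a[5, 6] <- a[4, 6] <- 1
  a[3, 4] <- 0.25
  g$bridged_triangles <- a + t(a)
  ## two disconnected triangles
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- 1
  a[4, 5] <- a[5, 6] <- a[4, 6] <- 1
  g$disconnected_triangles <- a + t(a)
  ## six-cycle
  a <- matrix(0, 6, 6)
  for (i in 1:5) a[i, i + 1] <- 1
  a[6, 1] <- 1
  g$cycle <- a + t(a)
  ## path
  a <- matrix(0, 6, 6)
  for (i in 1:5) a[i, i + 1] <- 1
  g$path <- a + t(a)
  ## unbalanced: K4 plus a pendant pair
  a <- matrix(0, 6, 6)
  for (i in 1:3) for (j in (i + 1):4) a[i, j] <- 1
  a[4, 5] <- 0.2; a[5, 6] <- 1
  g$clique_plus_pair <- a + t(a)
  ## weighted two-community graph
  a <- matrix(0, 6, 6)
  a[1, 2] <- a[1, 3] <- a[2, 3] <- 0.9
  a[4, 5] <- a[4, 6] <- a[5, 6] <- 0.7
  a[2, 5] <- 0.15; a[3, 4] <- 0.1
  g$weighted_communities <- a + t(a)
  g
}

## small simulated study shared across tests (cheap: cached per session)
small_sim <- local({
  cache <- NULL
  function(seed = 1, ...) {
    key <- paste(seed, ...)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$sim)
    sim <- simulate_cohort_study(generator_config(seed = seed, ...))
    cache <<- list(key = key, sim = sim)
    sim
  }
})
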
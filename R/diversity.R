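#' Per-sample alpha diversity
#'
#' Standard definitions: `observed` = number of non-zero OTUs; `chao1` =
#' bias-corrected estimator `S + F1(F1-1)/(2(F2+1))` with `F1`/`F2` the
#' singleton/doubleton counts (defined even when no doubletons exist);
#' `shannon` = `-sum p log p` (natural log); `simpson` = `1 - sum p^2`;
#' `invsimpson` = `1 / sum p^2`. Shannon/Simpson variants are delegated to
#' \pkg{vegan}.
#'
#' @param counts Samples x OTUs count matrix; every sample must have > 0 reads.
#' @param index One of `"observed"`, `"chao1"`, `"shannon"`, `"simpson"`,
#'   `"invsimpson"`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(counts,
                            index = c("observed", "chao1", "shannon",
                                      "simpson", "invsimpson")) {
  index <- match.arg(index)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  empty <- rowSums(counts) == 0
  if (any(empty))
    stop("alpha_diversity: empty sample(s): ",
         paste(which(empty), collapse = ", "))
  out <- switch(index,
    observed = rowSums(counts > 0),
    chao1 = apply(counts, 1, function(x) {
      s <- sum(x > 0); f1 <- sum(x == 1); f2 <- sum(x == 2)
      s + f1 * (f1 - 1) / (2 * (f2 + 1))
    }),
    shannon = vegan::diversity(counts, index = "shannon"),
    simpson = vegan::diversity(counts, index = "simpson"),
    invsimpson = vegan::diversity(counts, index = "invsimpson"))
  stats::setNames(as.numeric(out), rownames(counts))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = 1 - 2 sum(min(x_i, x_j)) / (sum x_i + sum x_j)`, bounded in
#' `[0, 1]`; computed with \pkg{vegan}.
#'
#' @param x Samples x features matrix of non-negative values (counts or
#'   normalized abundances).
#' @return Symmetric distance matrix with zero diagonal and sample ids.
#' @export
bray_curtis <- function(x) {
  if (any(x < 0)) stop("bray_curtis: negative values")
  zero <- rowSums(x) == 0
  if (sum(zero) >= 2)
    stop("bray_curtis: distance undefined between all-zero samples: ",
         paste(rownames(x)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Eigendecomposition of the double-centered `-D^2/2` matrix; coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues are reported, not dropped.
#'
#' @param dist Distance matrix (square matrix or `dist`).
#' @param n_axes Number of axes requested.
#' @return List with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing), `proportion` (variance fraction of each positive axis).
#' @export
pcoa <- function(dist, n_axes = 2) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  res <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sort(res$eig, decreasing = TRUE)
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (n_axes > pos) {
    warning("pcoa: only ", pos, " axes with positive eigenvalues available")
    n_axes <- max(pos, 1)
  }
  coords <- res$points[, seq_len(min(n_axes, ncol(res$points))), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  prop <- pmax(eig, 0) / sum(pmax(eig, 0))
  list(coordinates = coords, eigenvalues = eig, proportion = prop)
}

#' PERMANOVA on a distance matrix, optionally stratified by a covariate
#'
#' Pseudo-F from the partition of squared distances by group
#' (\pkg{vegan}'s `adonis2`). When `strata` is supplied (e.g. the cohort),
#' permutations are restricted to within-stratum shuffles, conditioning the
#' test on the blocking factor. The permutation p-value uses the
#' `(hits + 1) / (n_perm + 1)` convention.
#'
#' @param dist Distance matrix.
#' @param groups Group labels, one per sample.
#' @param strata Optional blocking factor for restricted permutations.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return List with `statistic` (pseudo-F), `p_value`, `n_permutations`,
#'   `method`, `groups`.
#' @export
permanova <- function(dist, groups, strata = NULL, n_perm = 999, seed = 1) {
  dm <- as.matrix(dist)
  if (n_perm < 99) stop("permanova: n_perm must be >= 99")
  groups <- as.factor(groups)
  keep <- rep(TRUE, nrow(dm))
  if (!is.null(strata)) {
    strata <- as.factor(strata)
    small <- names(table(strata))[table(strata) < 2]
    if (length(small) > 0) {
      warning("permanova: dropping strata with < 2 samples: ",
              paste(small, collapse = ", "))
      keep <- !strata %in% small
      strata <- droplevels(strata[keep])
    }
  }
  dm <- dm[keep, keep, drop = FALSE]
  groups <- droplevels(groups[keep])
  if (max(dm) < 1e-12)
    return(list(statistic = NA_real_, p_value = 1, n_permutations = n_perm,
                method = "permanova", groups = levels(groups)))
  ctrl <- if (is.null(strata)) permute::how(nperm = n_perm)
          else permute::how(nperm = n_perm, blocks = strata)
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(dm) ~ g,
                        data = data.frame(g = groups),
                        permutations = ctrl)
  list(statistic = fit$F[1], p_value = fit$`Pr(>F)`[1],
       n_permutations = n_perm, method = "permanova",
       groups = levels(groups))
}

#' Multivariate dispersion homogeneity test (PERMDISP)
#'
#' Distances of samples to their group spatial median in principal-coordinate
#' space, followed by a permutation F-test (\pkg{vegan}'s
#' `betadisper`/`permutest`).
#'
#' @inheritParams permanova
#' @return List with `statistic`, `p_value`, `n_permutations`, `method`,
#'   `groups`.
#' @export
permdisp <- function(dist, groups, n_perm = 999, seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("permdisp: need at least 2 groups")
  bd <- vegan::betadisper(stats::as.dist(as.matrix(dist)), groups,
                          type = "median")
  set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(statistic = pt$tab$F[1], p_value = pt$tab$`Pr(>F)`[1],
       n_permutations = n_perm, method = "permdisp", groups = levels(groups))
}

#' Per-feature two-or-more-group comparisons with BH correction
#'
#' Applies a Wilcoxon rank-sum, Kruskal-Wallis, or Welch t-test to each
#' feature (column) and adjusts p-values by Benjamini-Hochberg. Features that
#' are constant across all samples get `p = 1` and a flag.
#'
#' @param values Numeric vector (one feature) or samples x features matrix.
#' @param groups Group labels per sample.
#' @param test `"wilcoxon"`, `"kruskal"`, or `"ttest"`.
#' @param correction `"bh"` or `"none"`.
#' @return data.frame with `feature`, `statistic`, `p`, `q`, `constant`.
#' @export
group_compare <- function(values, groups,
                          test = c("wilcoxon", "kruskal", "ttest"),
                          correction = c("bh", "none")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(NULL, "feature"))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feature", seq_len(ncol(values)))
  groups <- as.factor(groups)
  if (test %in% c("wilcoxon", "ttest") && nlevels(groups) != 2)
    stop("group_compare: ", test, " requires exactly 2 groups")
  res <- apply(values, 2, function(v) {
    if (stats::var(v) < .Machine$double.eps)
      return(c(stat = NA_real_, p = 1, const = 1))
    out <- switch(test,
      wilcoxon = { w <- stats::wilcox.test(v ~ groups, exact = FALSE)
                   c(w$statistic, w$p.value) },
      kruskal = { k <- stats::kruskal.test(v, groups)
                  c(k$statistic, k$p.value) },
      ttest = { t_ <- stats::t.test(v ~ groups)
                c(t_$statistic, t_$p.value) })
    c(stat = unname(out[1]), p = unname(out[2]), const = 0)
  })
  q <- if (correction == "bh") stats::p.adjust(res["p", ], method = "BH")
       else res["p", ]
  data.frame(feature = colnames(values), statistic = res["stat", ],
             p = res["p", ], q = q, constant = res["const", ] == 1,
             row.names = NULL)
}
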
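## binary cohort indicator: largest cohort vs all others
cohort_indicator <- function(cohort) {
  cohort <- as.factor(cohort)
  largest <- names(which.max(table(cohort)))
  as.numeric(cohort == largest)
}

#' Remove cohort-correlated principal components
#'
#' PCA of the normalized table; each component's Pearson correlation with the
#' binary cohort indicator (largest cohort vs the rest) is computed.
#' Under the default `"per_component"` rule, every component with
#' `|r| > r_threshold` whose individual variance fraction is below
#' `max_removed_info` is removed (a dominant component is never discarded
#' outright). Under `"cumulative"`, exceeders are removed in decreasing `|r|`
#' order until removing the next would push the total removed variance above
#' `max_removed_info`; a warning then lists the still-correlated components.
#'
#' @param X Samples x features normalized matrix (centered internally).
#' @param cohort Cohort labels (>= 2 cohorts).
#' @param r_threshold Absolute correlation above which a component counts as
#'   cohort-correlated (default 0.1).
#' @param max_removed_info Variance-fraction cap (default 0.20); see above
#'   for its role under each rule.
#' @param removal_mode `"per_component"` or `"cumulative"`.
#' @return Object of class `fair_components`: `retained`, `removed`
#'   (component indices), `r` (per-component correlation), `variance_fraction`,
#'   `retained_variance`, `coordinates` (samples x retained components),
#'   `rotation` (features x components), `indicator`.
#' @export
fair_component_filter <- function(X, cohort, r_threshold = 0.1,
                                  max_removed_info = 0.20,
                                  removal_mode = c("per_component", "cumulative")) {
  removal_mode <- match.arg(removal_mode)
  if (length(unique(cohort)) < 2)
    stop("fair_component_filter: need at least 2 cohorts")
  if (max_removed_info <= 0 || max_removed_info >= 1)
    stop("fair_component_filter: max_removed_info must lie in (0, 1)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nz <- pc$sdev > .Machine$double.eps
  scores <- pc$x[, nz, drop = FALSE]
  varfrac <- pc$sdev[nz]^2 / sum(pc$sdev[nz]^2)
  ind <- cohort_indicator(cohort)
  r <- apply(scores, 2, function(s) suppressWarnings(stats::cor(s, ind)))
  r[is.na(r)] <- 0

  exceed <- which(abs(r) > r_threshold)
  exceed <- exceed[order(abs(r)[exceed], decreasing = TRUE)]
  removed <- integer(0)
  cum <- 0
  if (removal_mode == "per_component") {
    removed <- exceed[varfrac[exceed] < max_removed_info]
    cum <- sum(varfrac[removed])
    leftover <- setdiff(exceed, removed)
  } else {
    leftover <- integer(0)
    for (j in exceed) {
      if (cum + varfrac[j] <= max_removed_info) {
        removed <- c(removed, j)
        cum <- cum + varfrac[j]
      } else {
        leftover <- exceed[!exceed %in% removed]
        break
      }
    }
  }
  if (length(leftover) > 0)
    warning("fair_component_filter: variance cap leaves components ",
            paste(leftover, collapse = ", "), " cohort-correlated")
  retained <- setdiff(seq_len(ncol(scores)), removed)
  structure(list(retained = retained, removed = sort(removed), r = r,
                 variance_fraction = varfrac,
                 retained_variance = 1 - cum,
                 coordinates = scores[, retained, drop = FALSE],
                 rotation = pc$rotation[, nz, drop = FALSE],
                 indicator = ind),
            class = "fair_components")
}

#' Rank fair components by predictiveness and test fibrosis association
#'
#' Random-forest importance ranking of the retained components against the
#' fibrosis labels; the top `n_top` are kept and each is tested between
#' groups (Wilcoxon for 2 groups, Kruskal-Wallis otherwise) with BH
#' correction across the selected components.
#'
#' @param fair A [fair_component_filter()] result.
#' @param y Fibrosis labels.
#' @param n_top Number of components to keep (clamped to the retained count).
#' @param seed Integer seed for the forest.
#' @return data.frame `component` (index into the retained set ordering of
#'   `fair$coordinates`), `importance`, `rank`, `p`, `q`, `selected`.
#' @export
select_fair_components <- function(fair, y, n_top = 10, seed = 1) {
  stopifnot(inherits(fair, "fair_components"))
  coords <- fair$coordinates
  n_top <- min(n_top, ncol(coords))
  imp <- rf_importance(coords, y, seed = seed)
  sel <- imp$feature[seq_len(n_top)]
  y <- as.factor(y)
  test <- if (nlevels(y) == 2) "wilcoxon" else "kruskal"
  gc_ <- group_compare(coords[, sel, drop = FALSE], y, test = test,
                       correction = "bh")
  data.frame(component = sel, importance = imp$importance[seq_len(n_top)],
             rank = seq_len(n_top), p = gc_$p, q = gc_$q,
             selected = TRUE, row.names = NULL)
}

#' Build an OTU association graph from a normalized table
#'
#' Edge weight is the absolute (partial) correlation when it reaches
#' `threshold`, else 0; the diagonal is zero. Partial correlations are
#' computed from a ridge-regularized inverse of the correlation matrix.
#'
#' @param X Samples x OTUs normalized matrix (>= 3 samples).
#' @param method `"correlation"` or `"partial_correlation"`.
#' @param threshold Minimum absolute association retained as an edge.
#' @param ridge Regularization added to the correlation matrix diagonal
#'   before inversion (partial correlations only).
#' @return Symmetric non-negative adjacency matrix with zero diagonal and
#'   attributes `method` and `threshold`.
#' @export
build_association_graph <- function(X, method = c("correlation", "partial_correlation"),
                                    threshold = 0.3, ridge = 0.1) {
  method <- match.arg(method)
  if (nrow(X) < 3) stop("build_association_graph: need at least 3 samples")
  sds <- apply(X, 2, stats::sd)
  if (any(sds < .Machine$double.eps))
    warning("build_association_graph: constant OTU column(s) get zero rows: ",
            paste(colnames(X)[sds < .Machine$double.eps], collapse = ", "))
  R <- suppressWarnings(stats::cor(X))
  R[is.na(R)] <- 0
  if (method == "partial_correlation") {
    Om <- solve(R + diag(ridge, ncol(R)))
    d <- sqrt(diag(Om))
    R <- -Om / tcrossprod(d)
  }
  A <- abs(R)
  A[A < threshold] <- 0
  diag(A) <- 0
  A <- (A + t(A)) / 2
  structure(A, method = method, threshold = threshold)
}

## normalized cut of a labelled partition: sum over clusters of
## cut(C, complement) / vol(C); empty or zero-volume clusters count 0
normalized_cut <- function(A, labels) {
  labels <- as.integer(factor(labels))
  total <- 0
  for (c_ in unique(labels)) {
    inC <- labels == c_
    vol <- sum(A[inC, , drop = FALSE])
    if (vol > 0)
      total <- total + sum(A[inC, !inC, drop = FALSE]) / vol
  }
  total
}

## leading sparse non-negative community indicator of a (sub)graph via
## soft-thresholded power iteration on the (unnormalized) adjacency, whose
## leading eigenvector localizes on the densest community
sparse_indicator <- function(A, thresh_frac = 0.15, max_iter = 200, seed = 1) {
  n <- nrow(A)
  M <- A
  set.seed(seed)
  x <- abs(stats::rnorm(n)) + 0.1
  x <- x / sqrt(sum(x^2))
  for (it in seq_len(max_iter)) {
    y <- as.numeric(M %*% x)
    y <- pmax(y, 0)
    lam <- thresh_frac * max(y)
    y <- pmax(y - lam, 0)
    ny <- sqrt(sum(y^2))
    if (ny < 1e-12) break
    y <- y / ny
    if (sqrt(sum((y - x)^2)) < 1e-10) { x <- y; break }
    x <- y
  }
  x
}

#' l1-penalized spectral clustering of an association graph
#'
#' Community-indicator vectors are estimated one at a time: a
#' soft-thresholded power iteration on the normalized adjacency of the
#' still-unassigned subgraph yields a sparse non-negative indicator whose
#' support becomes the next cluster and is removed before continuing
#' (deflation). The support boundary is placed at the largest gap of the
#' sorted indicator when soft-thresholding leaves it dense. Remaining nodes
#' form the last cluster; isolated leftovers are attached to the nearest
#' cluster in the spectral embedding. A final local-move sweep reduces the
#' normalized cut.
#'
#' @param A Symmetric non-negative adjacency matrix with zero diagonal.
#' @param k Number of clusters, or `"auto"` for eigengap selection on the
#'   normalized Laplacian (2..`k_max`).
#' @param seed Integer seed (power-iteration initialization).
#' @param k_max Upper bound for automatic k selection.
#' @param refine Run the local-move normalized-cut refinement (default TRUE).
#' @return Object of class `cluster_assignment`: `labels` (named, 1..k),
#'   `k`, `method = "l1spectral"`.
#' @export
l1_spectral_cluster <- function(A, k = "auto", seed = 1, k_max = 8,
                                refine = TRUE) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (n == 0 || sum(A) == 0) stop("l1_spectral_cluster: empty graph")
  if (!identical(k, "auto") && k > n) stop("l1_spectral_cluster: k > number of nodes")
  deg <- rowSums(A)
  dsi <- 1 / sqrt(pmax(deg, .Machine$double.eps))
  M <- A * tcrossprod(dsi)
  eg <- eigen(M, symmetric = TRUE)
  lap_ev <- sort(1 - eg$values)          # normalized Laplacian spectrum, ascending
  if (identical(k, "auto")) {
    kmax <- min(k_max, n - 1)
    gaps <- diff(lap_ev)[seq_len(kmax)]
    k <- which.max(gaps)
    k <- max(k, 2)
  }
  k <- as.integer(k)
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  U <- U / pmax(rn, .Machine$double.eps)

  labels <- rep(NA_integer_, n)
  avail <- seq_len(n)
  for (j in seq_len(k - 1)) {
    if (length(avail) <= k - j) break
    As <- A[avail, avail, drop = FALSE]
    if (sum(As) == 0) break
    x <- sparse_indicator(As, seed = seed + j)
    if (max(x) <= 0) break
    ## place the support boundary at the largest gap of the sorted indicator,
    ## leaving room for the remaining clusters
    ord <- order(x, decreasing = TRUE)
    hi <- length(avail) - (k - j)
    xs <- x[ord]
    gaps <- xs[seq_len(hi)] - xs[seq_len(hi) + 1]
    cut_at <- which.max(gaps)
    supp <- ord[seq_len(cut_at)]
    supp <- supp[x[supp] > 0]
    if (length(supp) == 0) break
    labels[avail[supp]] <- j
    avail <- avail[-supp]
  }
  labels[avail] <- k
  ## attach any unassigned node to the nearest cluster centroid in embedding
  if (anyNA(labels)) {
    cent <- do.call(rbind, lapply(seq_len(k), function(c_) {
      idx <- which(labels == c_)
      if (length(idx) == 0) rep(Inf, ncol(U)) else colMeans(U[idx, , drop = FALSE])
    }))
    for (i in which(is.na(labels)))
      labels[i] <- which.min(rowSums(sweep(cent, 2, U[i, ])^2))
  }
  ## ensure every label 1..k is used
  labels <- as.integer(factor(labels))
  k_eff <- max(labels)

  ## local-move refinement is quadratic per sweep; applied on small graphs
  ## where it can polish the cut toward the combinatorial optimum
  if (refine && k_eff > 1 && n <= 60) {
    for (pass in seq_len(10)) {
      moved <- FALSE
      for (i in seq_len(n)) {
        best <- labels[i]; best_cut <- normalized_cut(A, labels)
        sizes <- table(labels)
        if (sizes[as.character(labels[i])] == 1) next
        for (c_ in setdiff(seq_len(k_eff), labels[i])) {
          trial <- labels; trial[i] <- c_
          nc <- normalized_cut(A, trial)
          if (nc < best_cut - 1e-12) { best <- c_; best_cut <- nc }
        }
        if (best != labels[i]) { labels[i] <- best; moved <- TRUE }
      }
      if (!moved) break
    }
  }
  nm <- rownames(A)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  structure(list(labels = stats::setNames(labels, nm), k = k_eff,
                 method = "l1spectral"),
            class = "cluster_assignment")
}

#' Decompose colored points into balance-respecting fairlets
#'
#' Two-color fairlet decomposition for a `1:q` balance: every fairlet holds
#' one minority-color point and between 1 and `q` majority-color points, so
#' any union of fairlets has a color ratio within `[1:q, 1:1]`. Majority
#' points are attached to minority seeds greedily by distance (a matching
#' when the colors are balanced 1:1), approximately minimizing within-fairlet
#' cost.
#'
#' @param points Samples x dims coordinate matrix, or a symmetric distance
#'   matrix with `is_dist = TRUE`.
#' @param colors Two-level color labels (e.g. largest cohort vs rest).
#' @param balance Integer pair `c(p, q)`, `p <= q`; reduced by their gcd,
#'   after which `p` must equal 1.
#' @param is_dist Treat `points` as a distance matrix.
#' @return List of class `fairlets`: `members` (list of index vectors),
#'   `centers` (medoid index per fairlet), `colors`, `balance`.
#' @export
fairlet_decompose <- function(points, colors, balance = c(1, 1), is_dist = FALSE) {
  colors <- as.factor(colors)
  if (nlevels(colors) < 2) stop("fairlet_decompose: single color")
  if (nlevels(colors) > 2) stop("fairlet_decompose: only two colors supported")
  g <- function(a, b) ifelse(b == 0, a, Recall(b, a %% b))
  d_ <- g(balance[1], balance[2])
  p_ <- balance[1] / d_; q_ <- balance[2] / d_
  if (p_ != 1) stop("fairlet_decompose: balance must reduce to 1:q")
  tab <- table(colors)
  minority <- names(tab)[which.min(tab)]
  m <- min(tab); M <- max(tab)
  if (M > q_ * m) {
    g2 <- g(m, M)
    stop("fairlet_decompose: balance 1:", q_, " infeasible for color counts ",
         m, ":", M, "; achievable balance is ", m / g2, ":", M / g2)
  }
  D <- if (is_dist) as.matrix(points) else as.matrix(stats::dist(points))
  seeds <- which(colors == minority)
  maj <- which(colors != minority)
  cap <- rep(q_, length(seeds))
  assigned <- rep(NA_integer_, length(maj))

  ## round 1: each seed takes its nearest free majority point (greedy matching)
  pairs <- expand.grid(s = seq_along(seeds), j = seq_along(maj))
  pairs$d <- D[cbind(seeds[pairs$s], maj[pairs$j])]
  pairs <- pairs[order(pairs$d), ]
  seed_has <- rep(FALSE, length(seeds))
  for (r in seq_len(nrow(pairs))) {
    s <- pairs$s[r]; j <- pairs$j[r]
    if (!seed_has[s] && is.na(assigned[j])) {
      assigned[j] <- s; seed_has[s] <- TRUE; cap[s] <- cap[s] - 1
    }
    if (all(seed_has)) break
  }
  ## round 2: remaining majority points go to the nearest seed with capacity
  for (j in which(is.na(assigned))) {
    open <- which(cap > 0)
    s <- open[which.min(D[seeds[open], maj[j]])]
    assigned[j] <- s; cap[s] <- cap[s] - 1
  }
  members <- lapply(seq_along(seeds), function(s) c(seeds[s], maj[assigned == s]))
  centers <- vapply(members, function(idx) {
    if (length(idx) == 1) return(idx)
    idx[which.min(rowSums(D[idx, idx, drop = FALSE]))]
  }, integer(1))
  structure(list(members = members, centers = centers, colors = colors,
                 balance = c(1, q_), distances = D),
            class = "fairlets")
}

#' Cohort-balanced (fair) k-median clustering
#'
#' Points are first decomposed into balance-respecting fairlets; the k-median
#' objective is then solved over the fairlet centers (PAM medoids on the
#' center distance matrix) and every fairlet member inherits its center's
#' cluster, which guarantees each final cluster's color ratio lies within the
#' fairlet balance. The reported objective is the sum of distances of all
#' points to their cluster medoid (recomputed over members).
#'
#' @inheritParams fairlet_decompose
#' @param k Number of clusters (<= number of fairlets).
#' @param seed Integer seed (kept for interface symmetry; PAM is
#'   deterministic).
#' @return Object of class `cluster_assignment`: `labels`, `k`,
#'   `method = "fair_kmedian"`, `objective`, `composition` (color counts per
#'   cluster), `medoids`.
#' @export
fair_kmedian <- function(points, colors, k = 3, balance = c(1, 1), seed = 1,
                         is_dist = FALSE) {
  fl <- fairlet_decompose(points, colors, balance = balance, is_dist = is_dist)
  if (k > length(fl$centers))
    stop("fair_kmedian: k exceeds the number of fairlets (", length(fl$centers), ")")
  D <- fl$distances
  Dc <- D[fl$centers, fl$centers, drop = FALSE]
  set.seed(seed)
  pm <- cluster::pam(stats::as.dist(Dc), k = k, diss = TRUE)
  n <- nrow(D)
  labels <- integer(n)
  for (f in seq_along(fl$members)) labels[fl$members[[f]]] <- pm$clustering[f]
  ## recompute cluster medoids over the full membership and the objective
  medoids <- integer(k)
  objective <- 0
  for (c_ in seq_len(k)) {
    idx <- which(labels == c_)
    med <- idx[which.min(rowSums(D[idx, idx, drop = FALSE]))]
    medoids[c_] <- med
    objective <- objective + sum(D[idx, med])
  }
  comp <- table(cluster = labels, color = fl$colors)
  ## balance invariant: every cluster's minority:majority ratio >= 1:q
  q_ <- fl$balance[2]
  ratios <- apply(comp, 1, function(r) min(r) / max(r))
  stopifnot(all(ratios >= 1 / q_ - 1e-9))
  nm <- rownames(D)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  structure(list(labels = stats::setNames(labels, nm), k = k,
                 method = "fair_kmedian", objective = objective,
                 composition = comp, medoids = medoids),
            class = "cluster_assignment")
}

#' Test OTU clusters for association with fibrosis groups
#'
#' For each cluster, the mean normalized abundance of its member OTUs is
#' computed per sample and compared between fibrosis groups (Welch t-test for
#' 2 groups, Kruskal-Wallis otherwise), with BH correction across clusters.
#' Singleton clusters are tested but flagged.
#'
#' @param clusters A `cluster_assignment` over the OTUs of `X` (or a named
#'   label vector).
#' @param X Samples x OTUs normalized matrix.
#' @param y Fibrosis labels per sample.
#' @return data.frame `cluster`, `n_otus`, `statistic`, `p`, `q`, `singleton`.
#' @export
cluster_group_association <- function(clusters, X, y) {
  labels <- if (inherits(clusters, "cluster_assignment")) clusters$labels else clusters
  stopifnot(!is.null(names(labels)), all(names(labels) %in% colnames(X)))
  y <- as.factor(y)
  ks <- sort(unique(labels))
  means <- vapply(ks, function(c_) {
    ids <- names(labels)[labels == c_]
    rowMeans(X[, ids, drop = FALSE])
  }, numeric(nrow(X)))
  colnames(means) <- paste0("cluster", ks)
  test <- if (nlevels(y) == 2) "ttest" else "kruskal"
  gc_ <- group_compare(means, y, test = test, correction = "bh")
  data.frame(cluster = ks,
             n_otus = as.integer(table(labels)[as.character(ks)]),
             statistic = gc_$statistic, p = gc_$p, q = gc_$q,
             singleton = as.integer(table(labels)[as.character(ks)]) == 1,
             row.names = NULL)
}
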
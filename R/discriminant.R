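## soft-threshold a weight vector so that exactly keepx entries survive,
## then renormalize; ties broken by first occurrence
soft_threshold_keepx <- function(w, keepx) {
  p <- length(w)
  if (keepx >= p) return(w / sqrt(sum(w^2)))
  ord <- order(abs(w), decreasing = TRUE)
  lambda <- abs(w)[ord[keepx + 1]]
  ws <- sign(w) * pmax(abs(w) - lambda, 0)
  ws[-ord[seq_len(keepx)]] <- 0
  nrm <- sqrt(sum(ws^2))
  if (nrm < .Machine$double.eps) {  # all surviving weights tied with lambda
    ws[ord[seq_len(keepx)]] <- sign(w[ord[seq_len(keepx)]])
    nrm <- sqrt(sum(ws^2))
  }
  ws / nrm
}

#' Fit a (sparse) PLS discriminant analysis model
#'
#' PLS2 on the one-hot encoded class membership via iterative NIPALS
#' deflation. With `keepX` supplied, each component's X-weight vector is
#' soft-thresholded so exactly `keepX[h]` features carry non-zero loadings
#' (lasso-style selection, parameterized by count as in the mixOmics
#' convention), then renormalized before deflation.
#'
#' @param X Samples x features matrix (normalized abundances).
#' @param y Class labels (2 or more classes).
#' @param n_comp Number of latent components.
#' @param keepX Optional integer vector (recycled to `n_comp`) of features to
#'   keep per component; `NULL` fits the dense PLS-DA.
#' @param scale Unit-variance scale features (default `TRUE`).
#' @return Object of class `plsda`: loadings (features x components, zeros
#'   for dropped constant features), scores, `keepX`, class centroids in
#'   score space, centering/scaling vectors.
#' @export
plsda_fit <- function(X, y, n_comp = 2, keepX = NULL, scale = TRUE) {
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("plsda_fit: need at least 2 classes")
  X <- as.matrix(X)
  p_all <- ncol(X)
  feat_names <- colnames(X)
  if (is.null(feat_names)) feat_names <- paste0("V", seq_len(p_all))

  sds <- apply(X, 2, stats::sd)
  keep_cols <- sds > .Machine$double.eps
  if (!all(keep_cols))
    warning("plsda_fit: dropping ", sum(!keep_cols), " constant feature(s)")
  Xw <- X[, keep_cols, drop = FALSE]
  mu <- colMeans(Xw)
  sc <- if (scale) sds[keep_cols] else rep(1, ncol(Xw))
  Xc <- sweep(sweep(Xw, 2, mu), 2, sc, "/")

  Y <- stats::model.matrix(~ y - 1)
  Y <- sweep(Y, 2, colMeans(Y))
  n <- nrow(Xc); p <- ncol(Xc)
  n_comp <- min(n_comp, p, n - 1)
  if (!is.null(keepX)) keepX <- pmin(rep_len(as.integer(keepX), n_comp), p)

  W <- matrix(0, p, n_comp); P <- matrix(0, p, n_comp)
  Tm <- matrix(0, n, n_comp); Q <- matrix(0, ncol(Y), n_comp)
  Xd <- Xc; Yd <- Y
  for (h in seq_len(n_comp)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    w <- rep(0, p)
    for (it in seq_len(500)) {
      w_new <- crossprod(Xd, u)[, 1]
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-14) { w_new <- w; break }
      w_new <- w_new / nw
      if (!is.null(keepX)) w_new <- soft_threshold_keepx(w_new, keepX[h])
      tt <- Xd %*% w_new
      q <- crossprod(Yd, tt)[, 1] / sum(tt^2)
      u_new <- Yd %*% q / sum(q^2)
      if (sqrt(sum((w_new - w)^2)) < 1e-10) { w <- w_new; u <- u_new[, 1]; break }
      w <- w_new; u <- u_new[, 1]
    }
    tt <- Xd %*% w
    denom <- sum(tt^2)
    if (denom < 1e-14) { n_comp <- h - 1; break }
    pvec <- crossprod(Xd, tt)[, 1] / denom
    q <- crossprod(Yd, tt)[, 1] / denom
    W[, h] <- w; P[, h] <- pvec; Tm[, h] <- tt; Q[, h] <- q
    Xd <- Xd - tcrossprod(tt, pvec)
    Yd <- Yd - tcrossprod(tt, q)
  }
  W <- W[, seq_len(n_comp), drop = FALSE]; P <- P[, seq_len(n_comp), drop = FALSE]
  Tm <- Tm[, seq_len(n_comp), drop = FALSE]; Q <- Q[, seq_len(n_comp), drop = FALSE]

  ## map loadings back onto the full feature set (zeros for dropped columns)
  W_full <- matrix(0, p_all, n_comp,
                   dimnames = list(feat_names, paste0("comp", seq_len(n_comp))))
  W_full[keep_cols, ] <- W
  centroids <- apply(Tm, 2, function(s) tapply(s, y, mean))

  structure(list(loadings = W_full, scores = Tm, x_loadings = P, y_loadings = Q,
                 keepX = keepX, classes = levels(y), y = y,
                 centroids = centroids, center = mu, scale_ = sc,
                 keep_cols = keep_cols, n_comp = n_comp),
            class = "plsda")
}

#' @rdname plsda_fit
#' @export
splsda_fit <- function(X, y, n_comp = 2, keepX = rep(10, n_comp), scale = TRUE) {
  if (any(keepX < 1)) stop("splsda_fit: keepX must be >= 1")
  if (any(keepX > ncol(X))) {
    warning("splsda_fit: keepX clamped to the number of features")
    keepX <- pmin(keepX, ncol(X))
  }
  plsda_fit(X, y, n_comp = n_comp, keepX = keepX, scale = scale)
}

#' Project new samples and predict classes from a fitted PLS-DA model
#'
#' Scores are computed with the rotation `W (P'W)^{-1}`; classes are assigned
#' by the nearest training-class centroid in score space.
#'
#' @param object A `plsda` fit.
#' @param newdata Samples x features matrix (same features as training).
#' @param ... Unused.
#' @return List with `scores` and `class`.
#' @export
predict.plsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xn <- newdata[, object$keep_cols, drop = FALSE]
  Xn <- sweep(sweep(Xn, 2, object$center), 2, object$scale_, "/")
  W <- object$loadings[object$keep_cols, , drop = FALSE]
  R <- W %*% solve(crossprod(object$x_loadings, W))
  scores <- Xn %*% R
  d2 <- sapply(seq_along(object$classes), function(ci)
    rowSums(sweep(scores, 2, object$centroids[ci, ])^2))
  d2 <- matrix(d2, nrow = nrow(scores))
  cls <- object$classes[apply(d2, 1, which.min)]
  list(scores = scores, class = factor(cls, levels = object$classes))
}

## mean per-class error rate (1 - balanced accuracy)
balanced_error <- function(truth, pred) {
  truth <- as.factor(truth)
  mean(vapply(levels(truth), function(l)
    mean(pred[truth == l] != l), numeric(1)))
}

#' Tune the sPLS-DA sparsity by leave-one-out cross-validation
#'
#' For each candidate `keepX` (used on every component) the model is refit
#' leaving each sample out in turn; the value minimizing the LOO balanced
#' error rate is chosen, ties broken toward the smaller (sparser) value.
#'
#' @param X,y,n_comp As in [plsda_fit()].
#' @param grid Candidate keepX values.
#' @return List with `keepX` (chosen), `errors` (per grid value), `grid`.
#' @export
splsda_tune <- function(X, y, grid = c(5, 10, 20, 50), n_comp = 2) {
  if (length(grid) == 0) stop("splsda_tune: empty grid")
  y <- as.factor(y)
  if (any(table(y) < 2)) stop("splsda_tune: a class has fewer than 2 samples")
  grid <- sort(unique(pmin(grid, ncol(X))))
  if (length(grid) == 1)
    return(list(keepX = grid, errors = stats::setNames(NA_real_, grid), grid = grid))
  n <- nrow(X)
  errs <- vapply(grid, function(kx) {
    preds <- character(n)
    for (i in seq_len(n)) {
      fit <- splsda_fit(X[-i, , drop = FALSE], y[-i], n_comp = n_comp,
                        keepX = rep(kx, n_comp))
      preds[i] <- as.character(predict(fit, X[i, , drop = FALSE])$class)
    }
    balanced_error(y, preds)
  }, numeric(1))
  list(keepX = grid[which.min(errs)], errors = stats::setNames(errs, grid),
       grid = grid)
}

#' Leave-one-out cross-validated first-component scores
#'
#' Each sample's score is projected from a model fitted without it, giving
#' honest discriminant scores for ROC evaluation.
#'
#' @inheritParams plsda_fit
#' @return Numeric vector of held-out first-component scores.
#' @export
loo_scores <- function(X, y, n_comp = 1, keepX = NULL) {
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    fit <- plsda_fit(X[-i, , drop = FALSE], y[-i], n_comp = n_comp, keepX = keepX)
    pr <- predict(fit, X[i, , drop = FALSE])
    ## orient the component so higher scores point to the second class
    orient <- sign(fit$centroids[2, 1] - fit$centroids[1, 1])
    s[i] <- pr$scores[1, 1] * orient
  }
  s
}

#' Empirical ROC curve and trapezoid AUC
#'
#' @param scores Per-sample real-valued discriminant scores.
#' @param labels Binary labels; the second factor level is the positive class.
#' @return List of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `baseline` (0.5).
#' @export
roc_evaluate <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("roc_evaluate: need exactly 2 classes")
  pos <- labels == levels(labels)[2]
  if (!any(pos) || all(pos)) stop("roc_evaluate: one class only")
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, baseline = 0.5), class = "roc_result")
}

#' Random-forest permutation-importance ranking
#'
#' Seeded wrapper around \pkg{randomForest} returning the full feature
#' ranking by mean decrease in accuracy.
#'
#' @param X Samples x features matrix.
#' @param y Class labels.
#' @param n_trees Number of trees (>= 100).
#' @param seed Integer seed.
#' @return data.frame `feature`, `importance`, `rank` (1 = most important).
#' @export
rf_importance <- function(X, y, n_trees = 500, seed = 1) {
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("rf_importance: need at least 2 classes")
  if (n_trees < 100) stop("rf_importance: n_trees must be >= 100")
  set.seed(seed)
  fit <- randomForest::randomForest(x = as.data.frame(X), y = y,
                                    ntree = n_trees, importance = TRUE)
  imp <- randomForest::importance(fit, type = 1)[, 1]
  ord <- order(imp, decreasing = TRUE)
  data.frame(feature = names(imp)[ord], importance = imp[ord],
             rank = seq_along(imp), row.names = NULL)
}
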
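make_signal_data <- function(n = 60, p = 50, n_signal = 1, delta = 3, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("A", "B"), length.out = n))
  X <- matrix(rnorm(n * p), nrow = n,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X[, seq_len(n_signal)] <- X[, seq_len(n_signal), drop = FALSE] +
    delta * (as.numeric(y) - 1.5)
  list(X = X, y = y)
}

test_that("a leaked label feature dominates the first component", {
  d <- make_signal_data(n_signal = 1, delta = 20, seed = 2)
  fit <- plsda_fit(d$X, d$y, n_comp = 2)
  expect_equal(which.max(abs(fit$loadings[, 1])), c(f1 = 1L))
  ## scores on component 1 separate the classes perfectly
  s <- fit$scores[, 1]
  expect_true(max(s[d$y == "A"]) < min(s[d$y == "B"]) ||
                min(s[d$y == "A"]) > max(s[d$y == "B"]))
})

test_that("sPLS-DA with keepX = all features equals the dense PLS-DA", {
  d <- make_signal_data(n = 40, p = 20, seed = 3)
  dense <- plsda_fit(d$X, d$y, n_comp = 2)
  sparse <- splsda_fit(d$X, d$y, n_comp = 2, keepX = c(20, 20))
  expect_equal(dense$loadings, sparse$loadings, tolerance = 1e-10)
  expect_equal(dense$scores, sparse$scores, tolerance = 1e-10)
})

test_that("the sparsity contract holds for every keepX", {
  d <- make_signal_data(n = 40, p = 30, n_signal = 3, seed = 4)
  for (kx in c(1, 5, 12)) {
    fit <- splsda_fit(d$X, d$y, n_comp = 2, keepX = c(kx, kx))
    nz <- colSums(fit$loadings != 0)
    expect_true(all(nz <= kx))
    expect_equal(unname(nz[1]), kx)   # generically exact
    ## loadings are unit-norm per component
    expect_equal(unname(sqrt(colSums(fit$loadings^2))), rep(1, 2),
                 tolerance = 1e-8)
  }
  expect_warning(splsda_fit(d$X, d$y, keepX = c(400, 400)), "clamped")
})

test_that("planted differential features are recovered by sparse selection", {
  hits <- vapply(1:5, function(s) {
    d <- make_signal_data(n = 60, p = 200, n_signal = 10, delta = 1.5, seed = s)
    fit <- splsda_fit(d$X, d$y, n_comp = 1, keepX = 10)
    sel <- rownames(fit$loadings)[fit$loadings[, 1] != 0]
    sum(sel %in% paste0("f", 1:10))
  }, numeric(1))
  expect_gte(mean(hits), 8)
})

test_that("LOO tuning prefers the planted support size and handles edge cases", {
  d <- make_signal_data(n = 40, p = 100, n_signal = 5, delta = 2.5, seed = 6)
  tuned <- splsda_tune(d$X, d$y, grid = c(5, 50, 100), n_comp = 1)
  expect_equal(tuned$keepX, 5)
  single <- splsda_tune(d$X, d$y, grid = 7, n_comp = 1)
  expect_equal(single$keepX, 7)
  expect_error(splsda_tune(d$X, factor(c("A", rep("B", 39))), grid = c(2, 5)),
               "fewer than 2")
})

test_that("pure-noise sPLS-DA stays at chance in leave-one-out", {
  set.seed(7)
  X <- matrix(rnorm(40 * 80), nrow = 40)
  colnames(X) <- paste0("f", 1:80)
  y <- factor(rep(c("A", "B"), each = 20))
  err <- numeric(40)
  preds <- character(40)
  for (i in 1:40) {
    fit <- splsda_fit(X[-i, ], y[-i], n_comp = 1, keepX = 10)
    preds[i] <- as.character(predict(fit, X[i, , drop = FALSE])$class)
  }
  acc <- mean(preds == as.character(y))
  ## leave-one-out on pure noise is chance-or-below (the held-out sample's
  ## class is depleted in training, the usual LOO pessimism); the claim that
  ## matters is the absence of optimistic bias
  expect_lt(acc, 0.5 + 2 * sqrt(0.25 / 40))
})

test_that("dense loadings agree with the mixOmics reference up to sign", {
  d <- make_signal_data(n = 30, p = 15, n_signal = 2, delta = 2, seed = 8)
  ours <- plsda_fit(d$X, d$y, n_comp = 1)
  ref <- mixOmics::plsda(d$X, d$y, ncomp = 1, scale = TRUE)
  r <- cor(ours$loadings[, 1], ref$loadings$X[, 1])
  expect_gt(abs(r), 0.99)
})

test_that("ROC evaluation matches closed cases and is monotone-invariant", {
  sc <- c(0.1, 0.4, 0.35, 0.8)
  lab <- factor(c("neg", "neg", "pos", "pos"), levels = c("neg", "pos"))
  expect_equal(roc_evaluate(c(1, 2, 3, 4), lab)$auc, 1)
  r <- roc_evaluate(sc, lab)
  expect_equal(roc_evaluate(-sc, lab)$auc, 1 - r$auc, tolerance = 1e-12)
  expect_equal(roc_evaluate(exp(3 * sc), lab)$auc, r$auc, tolerance = 1e-12)
  ref <- suppressMessages(pROC::auc(pROC::roc(lab, sc, quiet = TRUE)))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  set.seed(9)
  null_auc <- roc_evaluate(rnorm(100), factor(rep(c("a", "b"), 50)))$auc
  expect_true(abs(null_auc - 0.5) < 0.1)
  expect_error(roc_evaluate(1:4, factor(rep("a", 4))), "2 classes")
})

test_that("random-forest importance ranks planted and duplicated features sensibly", {
  d <- make_signal_data(n = 60, p = 30, n_signal = 1, delta = 4, seed = 10)
  firsts <- vapply(1:5, function(s)
    rf_importance(d$X, d$y, n_trees = 300, seed = s)$feature[1], character(1))
  expect_true(all(firsts == "f1"))
  ## duplicated informative feature: both copies in the top ranks
  X2 <- cbind(d$X, f1copy = d$X[, 1])
  imp <- rf_importance(X2, d$y, n_trees = 500, seed = 1)
  expect_true(all(c("f1", "f1copy") %in% imp$feature[1:4]))
  expect_error(rf_importance(d$X, rep("A", 60)), "2 classes")
  expect_error(rf_importance(d$X, d$y, n_trees = 10), "100")
})
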
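toy_counts <- function() {
  m <- rbind(c(10, 4, 0, 1),
             c(3, 0, 2, 8))
  dimnames(m) <- list(c("s1", "s2"), c("o1", "o2", "o3", "o4"))
  m
}

test_that("abundance filter removes exactly the OTUs below the overall threshold", {
  ## overall relative abundances 0.5, 2e-4, 5e-5 with threshold 1e-4
  tot <- 1e5
  m <- rbind(c(0.5, 2e-4, 5e-5) * tot / 2,
             c(0.5, 2e-4, 5e-5) * tot / 2)
  m <- cbind(m, tot / 2 - rowSums(m))  # filler OTU to fix the grand total
  colnames(m) <- c("a", "b", "c", "fill")
  out <- filter_low_abundance(m, 1e-4)
  expect_setequal(colnames(out), c("a", "b", "fill"))

  z <- cbind(toy_counts(), o5 = c(0, 0))
  expect_false("o5" %in% colnames(filter_low_abundance(z, 1e-6)))
  expect_identical(filter_low_abundance(toy_counts(), 0), toy_counts())
  expect_error(filter_low_abundance(toy_counts(), 1), "all")
})

test_that("raising the filter threshold never enlarges the retained set", {
  set.seed(1)
  m <- matrix(rpois(200, 3), nrow = 10,
              dimnames = list(NULL, paste0("o", 1:20)))
  kept_prev <- colnames(m)
  for (thr in c(0, 1e-3, 5e-3, 2e-2, 5e-2)) {
    kept <- colnames(filter_low_abundance(m, thr))
    expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("signature prefilter applies prevalence and group-mean rules", {
  n <- 30
  md <- data.frame(sample_id = paste0("s", 1:n),
                   fibrosis = rep(c("F0", "F1", "F2"), each = 10))
  ## group means (140, 160, 20): only the F1 mean clears 150, prevalence 30/30
  keepme <- rep(c(140, 160, 20), each = 10)
  ## sparse OTU: present in 30% of samples but group means (140, 160, 20)
  ## evaluated on all samples of the group still pass via F1
  sparse_pass <- c(rep(0, 7), 700, 700, 0,     # F0 mean 140
                   rep(0, 7), 800, 800, 0,     # F1 mean 160
                   rep(0, 8), 100, 100)        # F2 mean 20
  m <- cbind(keepme = keepme, sparse_pass = sparse_pass,
             allzero = 0, low_everywhere = 100)
  rownames(m) <- md$sample_id
  out <- signature_prefilter(m, md, prevalence = 0.25, mean_count = 150)
  expect_true("keepme" %in% colnames(out$counts))
  expect_false("sparse_pass" %in% colnames(out$counts))   # prevalence 0.2 <= 0.25
  expect_false("allzero" %in% colnames(out$counts))
  expect_false("low_everywhere" %in% colnames(out$counts))  # no group mean > 150
  ## with the all-groups rule even keepme fails (F0 and F2 below 150)
  strict <- signature_prefilter(m, md, group_rule = "all")
  expect_false("keepme" %in% colnames(strict$counts))
  expect_error(signature_prefilter(m, transform(md, fibrosis = "F9")), "unknown")
})

test_that("CSS scaling factors match the brute-force oracle exactly", {
  set.seed(42)
  for (trial in 1:100) {
    n <- sample(2:10, 1); p <- sample(2:10, 1)
    m <- matrix(rpois(n * p, sample(1:20, 1)), nrow = n)
    m[sample(length(m), length(m) %/% 3)] <- 0
    m[rowSums(m) == 0, 1] <- 1
    pct <- sample(c(0.25, 0.5, 0.75), 1)
    got <- attr(css_normalize(m, percentile = pct), "parameters")$scaling_factors
    want <- apply(m, 1, oracle_css_factor, p = pct)
    expect_equal(unname(got), unname(want))
  }
})

test_that("CSS normalization is symmetric and maps zeros to zero", {
  m <- rbind(a = c(4, 0, 7, 1), b = c(4, 0, 7, 1), c = c(9, 2, 0, 5))
  v <- css_normalize(m)
  expect_equal(v[1, ], v[2, ])
  expect_equal(unname(v[m == 0]), rep(0, sum(m == 0)))
  expect_error(css_normalize(rbind(z = c(0, 0, 0))), "all-zero")
})

test_that("TF-IDF matches hand computation and annihilates ubiquitous OTUs", {
  m <- rbind(s1 = c(2, 1, 0),
             s2 = c(1, 0, 1),
             s3 = c(1, 1, 1))
  colnames(m) <- c("u", "v", "w")
  got <- tfidf_normalize(m)
  tf <- m / rowSums(m)
  idf <- c(u = log(3 / 3), v = log(3 / 2), w = log(3 / 2))
  expect_equal(unname(got), unname(sweep(tf, 2, idf, "*")), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(got[, "u"]), c(0, 0, 0))       # present everywhere
  single <- cbind(m, rare = c(5, 0, 0))
  expect_equal(attr(tfidf_normalize(single), "parameters")$idf[["rare"]], log(3))
})

test_that("taxonomic aggregation conserves totals and merges correctly", {
  m <- toy_counts()
  tax <- data.frame(otu_id = colnames(m),
                    phylum = c("P1", "P1", "P2", "P2"),
                    family = paste0("F", 1:4), genus = paste0("G", 1:4))
  agg <- aggregate_taxa(m, tax, "phylum")
  expect_equal(rowSums(agg), rowSums(m))
  expect_equal(unname(agg[, "P1"]), unname(m[, "o1"] + m[, "o2"]))
  one <- aggregate_taxa(m, transform(tax, phylum = "P1"), "phylum")
  expect_equal(unname(one[, 1]), unname(rowSums(m)))
  expect_error(aggregate_taxa(m, tax[-1, ], "phylum"), "without taxonomy")
})
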
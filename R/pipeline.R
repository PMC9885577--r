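#' Pipeline configuration
#'
#' Houses every threshold of the analysis chain: the overall relative
#' abundance filter (0.01 percent), the prevalence/mean-count signature
#' prefilter (25 percent, 150 counts), CSS parameters, the fair-component
#' rules (|r| > 0.1, at most 20 percent of variance removed), the number of
#' predictive components kept (10), the fair k-median k (3), permutation and
#' FDR settings, and the sPLS-DA tuning grid.
#'
#' @param abundance_filter_threshold Overall relative-abundance cutoff.
#' @param signature_prevalence,signature_mean_count Prefilter thresholds.
#' @param css_percentile,log_base CSS parameters.
#' @param fair_r_threshold,fair_max_removed_info Fair component-filter rules.
#' @param rf_top_components Predictive components kept in the fair RF arm.
#' @param fair_rf_otus_per_component Top-loading OTUs taken per significant
#'   fair component.
#' @param fair_otu_r_threshold Cohort-correlation cutoff above which an OTU
#'   is dropped before graph construction in the l1-spectral arm.
#' @param graph_threshold Association-graph edge threshold.
#' @param l1spec_k Cluster count for the l1-spectral arm, or `"auto"`.
#' @param kmedian_k Cluster count for the fair k-median arm.
#' @param splsda_grid,splsda_ncomp sPLS-DA tuning grid and component count.
#' @param n_permutations Permutations for PERMANOVA/PERMDISP.
#' @param fdr_alpha BH significance level.
#' @param consensus_rule `"intersection"` or `"majority"`.
#' @param seed Integer seed governing every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance_filter_threshold = 1e-4,
                            signature_prevalence = 0.25,
                            signature_mean_count = 150,
                            css_percentile = 0.5,
                            log_base = 2,
                            fair_r_threshold = 0.1,
                            fair_max_removed_info = 0.20,
                            rf_top_components = 10,
                            fair_rf_otus_per_component = 10,
                            fair_otu_r_threshold = 0.5,
                            graph_threshold = 0.3,
                            l1spec_k = "auto",
                            kmedian_k = 3,
                            splsda_grid = c(5, 10, 20, 50),
                            splsda_ncomp = 2,
                            n_permutations = 999,
                            fdr_alpha = 0.05,
                            consensus_rule = c("majority", "intersection"),
                            seed = 1L) {
  consensus_rule <- match.arg(consensus_rule)
  stopifnot(abundance_filter_threshold >= 0,
            signature_prevalence >= 0, signature_prevalence <= 1,
            fair_max_removed_info > 0, fair_max_removed_info < 1,
            fdr_alpha > 0, fdr_alpha < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

## F0 vs merged F1/2 contrast used throughout the discriminant stages
merge_f12 <- function(fibrosis) {
  factor(ifelse(fibrosis == "F0", "F0", "F12"), levels = c("F0", "F12"))
}

## Jaccard similarity of two sets
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

## OTU coloring for the fair k-median arm: the cohort in which an OTU has its
## highest mean relative abundance, binarized as largest cohort vs rest
otu_cohort_colors <- function(counts, metadata) {
  rel <- relative_abundance(counts)
  cohorts <- unique(metadata$cohort)
  mm <- vapply(cohorts, function(co)
    colMeans(rel[metadata$cohort == co, , drop = FALSE]), numeric(ncol(counts)))
  top <- cohorts[apply(mm, 1, which.max)]
  largest <- names(which.max(table(metadata$cohort)))
  factor(ifelse(top == largest, "largest", "rest"), levels = c("largest", "rest"))
}

#' Run the full signature-discovery pipeline
#'
#' Executes the analysis chain on a simulated or supplied study: abundance
#' filter, CSS and TF-IDF normalization, diversity testing (Bray-Curtis,
#' PCoA, cohort-stratified PERMANOVA, PERMDISP), per-OTU BH-corrected tests
#' on the F0 vs merged F1/2 contrast, the standard sPLS-DA arm (LOO-tuned
#' keepX, LOO ROC), and the three fairness arms (cohort-decorrelated
#' principal components + random forest, l1-spectral clustering of the
#' cohort-adjusted OTU association graph, fairlet-based cohort-balanced
#' k-median), each arm pruned to individually significant OTUs, finishing in
#' a consensus signature with taxonomy annotation and, for simulated data, an
#' evaluation against the planted truth.
#'
#' @param config A [pipeline_config()].
#' @param data Optional list with `counts`, `metadata`, `taxonomy` (and
#'   optionally `truth`); when `NULL`, a study is simulated.
#' @param generator A [generator_config()] used in simulate mode; its seed is
#'   overridden by `config$seed`.
#' @param outdir Optional directory: when given, tables, the report and a
#'   manifest are written as TSV/JSON.
#' @return List of class `signature_report`; see Details in the vignette.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         generator = generator_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))

  if (is.null(data)) {
    generator$seed <- config$seed
    data <- simulate_cohort_study(generator)
    say("simulated study: ", nrow(data$counts), " samples x ",
        ncol(data$counts), " OTUs")
  }
  counts <- data$counts; metadata <- data$metadata; taxonomy <- data$taxonomy
  fib <- metadata$fibrosis[match(rownames(counts), metadata$sample_id)]
  cohort <- metadata$cohort[match(rownames(counts), metadata$sample_id)]
  y2 <- merge_f12(fib)

  ## --- filtering and normalization -------------------------------------
  filtered <- filter_low_abundance(counts, config$abundance_filter_threshold)
  say("abundance filter: ", ncol(counts), " -> ", ncol(filtered), " OTUs")
  prefilter <- signature_prefilter(filtered, metadata,
                                   prevalence = config$signature_prevalence,
                                   mean_count = config$signature_mean_count)
  css <- css_normalize(filtered, percentile = config$css_percentile,
                       log_base = config$log_base)
  tfidf <- tfidf_normalize(filtered)

  ## --- diversity --------------------------------------------------------
  alpha <- sapply(c("observed", "chao1", "shannon", "simpson", "invsimpson"),
                  function(ix) alpha_diversity(filtered, ix))
  bc <- bray_curtis(relative_abundance(filtered))
  ord <- pcoa(bc, n_axes = 2)
  perma <- permanova(bc, y2, strata = cohort, n_perm = config$n_permutations,
                     seed = config$seed)
  disp <- permdisp(bc, y2, n_perm = config$n_permutations, seed = config$seed)
  alpha_tests <- group_compare(alpha, fib, test = "kruskal")

  ## --- per-OTU significance (shared prune across arms) ------------------
  otu_tests <- group_compare(css, y2, test = "ttest", correction = "bh")
  sig_otus <- otu_tests$feature[otu_tests$q < config$fdr_alpha & !otu_tests$constant]
  say("per-OTU BH t-tests: ", length(sig_otus), " significant of ", ncol(css))

  ## --- standard arm: sPLS-DA --------------------------------------------
  tune <- splsda_tune(css, y2, grid = config$splsda_grid,
                      n_comp = config$splsda_ncomp)
  spls <- splsda_fit(css, y2, n_comp = config$splsda_ncomp,
                     keepX = rep(tune$keepX, config$splsda_ncomp))
  cand_splsda <- rownames(spls$loadings)[rowSums(abs(spls$loadings)) > 0]
  roc <- roc_evaluate(loo_scores(css, y2, n_comp = 1,
                                 keepX = rep(tune$keepX, 1)), y2)
  say("sPLS-DA: keepX = ", tune$keepX, ", LOO AUC = ", round(roc$auc, 3))

  ## --- fair arm 1: cohort-decorrelated components + random forest -------
  fair <- fair_component_filter(css, cohort,
                                r_threshold = config$fair_r_threshold,
                                max_removed_info = config$fair_max_removed_info)
  sel <- select_fair_components(fair, y2, n_top = config$rf_top_components,
                                seed = config$seed)
  sig_comp <- sel$component[sel$q < config$fdr_alpha]
  cand_rf <- unique(unlist(lapply(sig_comp, function(cn) {
    load <- sort(abs(fair$rotation[, cn]), decreasing = TRUE)
    names(load)[seq_len(min(config$fair_rf_otus_per_component, length(load)))]
  })))
  if (is.null(cand_rf)) cand_rf <- character(0)
  say("fair components: removed ", length(fair$removed), ", retained variance ",
      round(100 * fair$retained_variance, 1), "%; ", length(sig_comp),
      " of top ", config$rf_top_components, " components fibrosis-associated")

  ## --- fair arm 2: l1-spectral clustering of the association graph ------
  r_cohort <- apply(css, 2, function(v)
    suppressWarnings(stats::cor(v, fair$indicator)))
  r_cohort[is.na(r_cohort)] <- 0
  keep_l1 <- abs(r_cohort) <= config$fair_otu_r_threshold
  Xl <- css[, keep_l1, drop = FALSE]
  ## within-cohort centering so residual cohort fingerprints do not shape edges
  for (co in unique(cohort)) {
    idx <- cohort == co
    Xl[idx, ] <- sweep(Xl[idx, , drop = FALSE], 2,
                       colMeans(Xl[idx, , drop = FALSE]))
  }
  graph <- build_association_graph(Xl, method = "correlation",
                                   threshold = config$graph_threshold)
  l1 <- l1_spectral_cluster(graph, k = config$l1spec_k, seed = config$seed,
                            refine = FALSE)
  l1_assoc <- cluster_group_association(l1, css[, keep_l1, drop = FALSE], y2)
  l1_sig <- l1_assoc$cluster[l1_assoc$q < config$fdr_alpha]
  cand_l1 <- names(l1$labels)[l1$labels %in% l1_sig]
  say("l1-spectral: ", sum(!keep_l1), " cohort-correlated OTUs removed, k = ",
      l1$k, ", ", length(l1_sig), " cluster(s) fibrosis-associated")
  if (length(cand_l1) == 0) cand_l1 <- character(0)

  ## --- fair arm 3: fairlet k-median -------------------------------------
  colors <- otu_cohort_colors(filtered, metadata)
  ## embed OTUs from the cohort-adjusted table so the fair clusters reflect
  ## abundance structure, not cohort fingerprints
  pc_otu <- stats::prcomp(t(Xl_full <- {
    tmp <- css
    for (co in unique(cohort)) {
      idx <- cohort == co
      tmp[idx, ] <- sweep(tmp[idx, , drop = FALSE], 2,
                          colMeans(tmp[idx, , drop = FALSE]))
    }
    tmp
  }), center = TRUE, scale. = FALSE)
  ## two leading structural axes: with k = 3 the medoids can only track the
  ## dominant geometry, and further axes add distance noise that blurs the
  ## co-abundant groups
  n_emb <- min(2, ncol(pc_otu$x))
  pts <- pc_otu$x[, seq_len(n_emb), drop = FALSE]
  tabc <- table(colors)
  bal_q <- max(1, ceiling(max(tabc) / min(tabc)))
  km <- fair_kmedian(pts, colors, k = config$kmedian_k,
                     balance = c(1, bal_q), seed = config$seed)
  km_assoc <- cluster_group_association(km, css, y2)
  km_sig <- km_assoc$cluster[km_assoc$q < config$fdr_alpha]
  cand_km <- names(km$labels)[km$labels %in% km_sig]
  say("fair k-median: balance 1:", bal_q, ", ", length(km_sig),
      " cluster(s) fibrosis-associated")

  ## --- consensus ---------------------------------------------------------
  method_sets <- list(splsda = intersect(cand_splsda, sig_otus),
                      fair_rf = intersect(cand_rf, sig_otus),
                      l1spectral = intersect(cand_l1, sig_otus),
                      fair_kmedian = intersect(cand_km, sig_otus))
  consensus <- consensus_signature(method_sets, rule = config$consensus_rule)
  say("consensus (", config$consensus_rule, "): ",
      length(consensus$consensus), " OTUs")

  gm <- vapply(levels(y2), function(l)
    colMeans(css[y2 == l, , drop = FALSE]), numeric(ncol(css)))
  otu_stats <- data.frame(otu_id = otu_tests$feature,
                          css_mean_F0 = gm[, "F0"], css_mean_F12 = gm[, "F12"],
                          p = otu_tests$p, q = otu_tests$q, row.names = NULL)
  annot <- taxonomy[match(consensus$consensus, taxonomy$otu_id),
                    c("otu_id", "phylum", "family", "genus")]
  annot <- merge(annot, otu_stats, by = "otu_id", sort = FALSE)

  evaluation <- NULL
  if (!is.null(data$truth)) {
    planted <- data$truth$differential_otu_ids
    found <- consensus$consensus
    evaluation <- list(planted = planted,
                       recovered = intersect(found, planted),
                       n_recovered = length(intersect(found, planted)),
                       false_positives = setdiff(found, planted),
                       n_false_positives = length(setdiff(found, planted)))
    say("truth: recovered ", evaluation$n_recovered, "/", length(planted),
        " planted OTUs, ", evaluation$n_false_positives, " false positives")
  }

  wc <- wordcloud_ranking(css, tfidf, taxonomy, rank = "family")
  manifest <- list(package_version = as.character(utils::packageVersion("fairbiome")),
                   seed = config$seed, config = unclass(config),
                   n_samples = nrow(counts), n_otus_input = ncol(counts),
                   n_otus_filtered = ncol(filtered))

  report <- structure(list(
    method_sets = method_sets, consensus = consensus, annotation = annot,
    otu_stats = otu_stats, evaluation = evaluation,
    diversity = list(alpha = alpha, alpha_tests = alpha_tests,
                     permanova = perma, permdisp = disp, pcoa = ord),
    splsda = list(keepX = tune$keepX, roc_auc = roc$auc, model = spls),
    fair_components = fair, fair_component_selection = sel,
    l1spectral = list(assignment = l1, association = l1_assoc),
    fair_kmedian = list(assignment = km, association = km_assoc),
    venn = set_specific_otus(filtered, fib),
    venn_prefiltered = set_specific_otus(prefilter$counts, fib),
    wordcloud = wc, manifest = manifest, log = log_lines),
    class = "signature_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' Write the pipeline report artifacts to disk
#'
#' @param report A `signature_report`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, `outdir`.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$annotation, file.path(outdir, "consensus_signature.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$otu_stats, file.path(outdir, "otu_statistics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$wordcloud, file.path(outdir, "wordcloud_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- report$method_sets
  sets_df <- data.frame(method = rep(names(sets), lengths(sets)),
                        otu_id = unlist(sets), row.names = NULL)
  utils::write.table(sets_df, file.path(outdir, "method_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report$log, file.path(outdir, "pipeline.log"))
  invisible(outdir)
}

## cross-validated balanced accuracy of the full fair pipeline for one
## target label: inside every training fold the component filter is refit
## (so held-out samples never inform the decorrelation), the q components
## most correlated with the target on the training fold are selected from
## the leading `pool` retained axes, and an LDA predicts the held-out fold
cv_fair_balanced_accuracy <- function(css, cohort, target, seed = 1, q = 10,
                                      n_folds = 10, filter = TRUE, pool = 30,
                                      r_threshold = 0.1, max_removed_info = 0.2) {
  y <- droplevels(as.factor(target))
  set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = nrow(css)))
  pred <- factor(rep(NA, nrow(css)), levels = levels(y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    ctr <- colMeans(css[tr, , drop = FALSE])
    Xtr <- sweep(css[tr, , drop = FALSE], 2, ctr)
    Xte <- sweep(css[!tr, , drop = FALSE], 2, ctr)
    if (filter) {
      fair <- suppressWarnings(fair_component_filter(Xtr, cohort[tr],
                                                     r_threshold = r_threshold,
                                                     max_removed_info = max_removed_info))
      rot <- fair$rotation[, fair$retained, drop = FALSE]
    } else {
      pc <- stats::prcomp(Xtr, center = FALSE)
      rot <- pc$rotation[, pc$sdev > 1e-12, drop = FALSE]
    }
    rot <- rot[, seq_len(min(pool, ncol(rot))), drop = FALSE]
    Str <- Xtr %*% rot
    Ste <- Xte %*% rot
    ok <- apply(Str, 2, stats::sd) > 1e-8
    Str <- Str[, ok, drop = FALSE]; Ste <- Ste[, ok, drop = FALSE]
    r <- apply(Str, 2, function(v)
      abs(stats::cor(v, as.numeric(y[tr] == levels(y)[2]))))
    sel <- order(r, decreasing = TRUE)[seq_len(min(q, ncol(Str)))]
    fit <- MASS::lda(Str[, sel, drop = FALSE], grouping = y[tr])
    pred[folds == f] <- stats::predict(fit, Ste[, sel, drop = FALSE])$class
  }
  mean(vapply(levels(y), function(l) mean(pred[y == l] == l), numeric(1)))
}

#' Quantify the cohort-fairness of the component filter
#'
#' Measures, on one simulated (or supplied) study, how predictable the
#' cohort (largest vs rest) and the fibrosis contrast (F0 vs F1/2) are from
#' the fair-filtered principal-component coordinates. The whole procedure is
#' cross-validated: the component filter is refit inside every training fold
#' and held-out samples are projected onto that fold's retained components,
#' so the reported balanced accuracies are free of decorrelation leakage.
#' The classifier mirrors the analysis chain: the `rf_top_components` most
#' target-associated retained components (training fold only) feed an LDA.
#' A successful filter drives the cohort accuracy to chance while fibrosis
#' accuracy survives.
#'
#' @param data List with `counts` and `metadata` (e.g. from
#'   [simulate_cohort_study()]).
#' @param config A [pipeline_config()]; `rf_top_components` sets how many
#'   selected components feed the classifier.
#' @return List with `ba_cohort_before`, `ba_cohort_after`,
#'   `ba_fibrosis_after`, `retained_variance`, `n_removed`.
#' @export
fairness_evaluation <- function(data, config = pipeline_config()) {
  counts <- data$counts; metadata <- data$metadata
  cohort <- metadata$cohort[match(rownames(counts), metadata$sample_id)]
  fib <- metadata$fibrosis[match(rownames(counts), metadata$sample_id)]
  y2 <- merge_f12(fib)
  filtered <- filter_low_abundance(counts, config$abundance_filter_threshold)
  css <- css_normalize(filtered, percentile = config$css_percentile,
                       log_base = config$log_base)
  fair <- fair_component_filter(css, cohort,
                                r_threshold = config$fair_r_threshold,
                                max_removed_info = config$fair_max_removed_info)
  ind <- factor(ifelse(fair$indicator == 1, "largest", "rest"))
  q <- config$rf_top_components
  list(ba_cohort_before = cv_fair_balanced_accuracy(css, cohort, ind,
         seed = config$seed, q = q, filter = FALSE),
       ba_cohort_after = cv_fair_balanced_accuracy(css, cohort, ind,
         seed = config$seed, q = q, filter = TRUE,
         r_threshold = config$fair_r_threshold,
         max_removed_info = config$fair_max_removed_info),
       ba_fibrosis_after = cv_fair_balanced_accuracy(css, cohort, y2,
         seed = config$seed, q = q, filter = TRUE,
         r_threshold = config$fair_r_threshold,
         max_removed_info = config$fair_max_removed_info),
       retained_variance = fair$retained_variance,
       n_removed = length(fair$removed))
}
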
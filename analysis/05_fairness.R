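#!/usr/bin/env Rscript
## Step 5 -- the three cohort-fairness strategies.
##
## (1) removes cohort-correlated principal components and checks that the
## cohort is no longer predictable while the fibrosis contrast is, (2) runs
## the l1-penalized spectral clustering of the cohort-adjusted OTU
## association graph, (3) runs the fairlet-based cohort-balanced k-median;
## writes cluster assignments and the fairness report under results/fairness/.

library(fairbiome)

sim <- simulate_cohort_study(generator_config(seed = 1))
cfg <- pipeline_config(seed = 1)
filtered <- filter_low_abundance(sim$counts, cfg$abundance_filter_threshold)
css <- css_normalize(filtered)
cohort <- sim$metadata$cohort
y2 <- factor(ifelse(sim$metadata$fibrosis == "F0", "F0", "F12"))

fair <- fair_component_filter(css, cohort)
cat("removed ", length(fair$removed), " cohort-correlated components; ",
    round(100 * fair$retained_variance, 1), "% of variance retained\n", sep = "")

fe <- fairness_evaluation(sim, cfg)
cat("cohort balanced accuracy: ", round(fe$ba_cohort_before, 2), " -> ",
    round(fe$ba_cohort_after, 2), " after filtering\n", sep = "")
cat("fibrosis balanced accuracy from fair components: ",
    round(fe$ba_fibrosis_after, 2), "\n", sep = "")

sel <- select_fair_components(fair, y2, n_top = cfg$rf_top_components, seed = 1)
cat("fibrosis-associated fair components (BH q < 0.05): ",
    sum(sel$q < 0.05), " of top ", nrow(sel), "\n", sep = "")

## l1-spectral clustering on the cohort-adjusted association graph
Xl <- css
for (co in unique(cohort)) {
  idx <- cohort == co
  Xl[idx, ] <- sweep(Xl[idx, , drop = FALSE], 2, colMeans(Xl[idx, , drop = FALSE]))
}
A <- build_association_graph(Xl, threshold = cfg$graph_threshold)
cl <- l1_spectral_cluster(A, k = "auto", seed = 1, refine = FALSE)
assoc <- cluster_group_association(cl, css, y2)
cat("l1-spectral: k = ", cl$k, ", cluster sizes ",
    paste(table(cl$labels), collapse = "/"), "\n", sep = "")
print(assoc)

## fairlet k-median over OTUs colored by their dominant cohort
pc <- prcomp(t(Xl), center = TRUE)
colors <- fairbiome:::otu_cohort_colors(filtered, sim$metadata)
tabc <- table(colors)
km <- fair_kmedian(pc$x[, 1:2], colors, k = cfg$kmedian_k,
                   balance = c(1, max(1, ceiling(max(tabc) / min(tabc)))), seed = 1)
cat("fair k-median cluster composition (rows = clusters):\n")
print(km$composition)
print(cluster_group_association(km, css, y2))

dir.create("results/fairness", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(otu_id = names(cl$labels), l1spectral = cl$labels,
                       fair_kmedian = km$labels[names(cl$labels)]),
            "results/fairness/otu_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(fairness = fe, removed_components = fair$removed,
                          retained_variance = fair$retained_variance),
                     "results/fairness/fair_components.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/fairness/\n")
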
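#!/usr/bin/env Rscript
## Step 3 -- alpha and beta diversity.
##
## Computes the standard alpha indices per sample, Bray-Curtis distances,
## a PCoA, a cohort-stratified PERMANOVA of the F0 vs F1/2 contrast and the
## PERMDISP dispersion test; writes results under results/diversity/.

library(fairbiome)

sim <- simulate_cohort_study(generator_config(seed = 1))
filtered <- filter_low_abundance(sim$counts, 1e-4)
fib <- sim$metadata$fibrosis
y2 <- factor(ifelse(fib == "F0", "F0", "F12"))

alpha <- sapply(c("observed", "chao1", "shannon", "simpson", "invsimpson"),
                function(ix) alpha_diversity(filtered, ix))
cat("alpha diversity (mean per fibrosis group):\n")
print(round(apply(alpha, 2, function(v) tapply(v, fib, mean)), 2))

kw <- group_compare(alpha, fib, test = "kruskal")
cat("Kruskal-Wallis across F0/F1/F2 (BH-adjusted):\n")
print(kw[, c("feature", "statistic", "p", "q")])

bc <- bray_curtis(relative_abundance(filtered))
ord <- pcoa(bc, n_axes = 2)
cat("PCoA: first two axes explain ",
    round(100 * sum(ord$proportion[1:2]), 1), "% of the variation\n", sep = "")

pm <- permanova(bc, y2, strata = sim$metadata$cohort, n_perm = 999, seed = 1)
cat("PERMANOVA (cohort-stratified) F = ", round(pm$statistic, 2),
    ", p = ", pm$p_value, "\n", sep = "")
pd <- permdisp(bc, y2, n_perm = 999, seed = 1)
cat("PERMDISP F = ", round(pd$statistic, 2), ", p = ", pd$p_value, "\n", sep = "")

dir.create("results/diversity", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(sample_id = rownames(alpha), alpha),
            "results/diversity/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
            "results/diversity/pcoa_coordinates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(permanova = pm, permdisp = pd),
                     "results/diversity/tests.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/diversity/\n")
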
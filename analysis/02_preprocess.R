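#!/usr/bin/env Rscript
## Step 2 -- filtering and normalization.
##
## Applies the 0.01% overall-abundance filter, the 25%-prevalence /
## 150-mean-count signature prefilter, and the CSS-log and TF-IDF
## normalizations; writes the normalized tables under results/preprocess/.

library(fairbiome)

sim <- simulate_cohort_study(generator_config(seed = 1))
filtered <- filter_low_abundance(sim$counts, 1e-4)
cat("abundance filter: ", ncol(sim$counts), " -> ", ncol(filtered), " OTUs\n", sep = "")

pf <- signature_prefilter(filtered, sim$metadata)
cat("signature prefilter keeps ", ncol(pf$counts), " OTUs\n", sep = "")

css <- css_normalize(filtered)
tfidf <- tfidf_normalize(filtered)

phy <- aggregate_taxa(filtered, sim$taxonomy, "phylum")
comp <- sort(colMeans(phy / rowSums(phy)), decreasing = TRUE)
cat("mean phylum composition:\n")
print(round(comp, 3))

dir.create("results/preprocess", recursive = TRUE, showWarnings = FALSE)
write.table(data.frame(otu_id = colnames(css), t(css), check.names = FALSE),
            "results/preprocess/css_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(otu_id = colnames(tfidf), t(tfidf), check.names = FALSE),
            "results/preprocess/tfidf_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(pf$audit, "results/preprocess/prefilter_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/preprocess/\n")
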
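---
title: "Fairness-aware discovery of liver-microbiota fibrosis signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fairness-aware discovery of liver-microbiota fibrosis signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairbiome)
```

## The problem

Liver biopsies carry a low-biomass tissue microbiota whose 16S rRNA profile
may mark the earliest stages of fibrosis (histological scores F0, F1, F2).
Detecting such a signature in a multi-centre study is confounded by the
cohort of origin: patients recruited in different countries differ in
sequencing batch, environment and group size, and the largest cohort can
dominate any naive classifier. `fairbiome` implements an analysis chain for
this setting: OTU filtering and normalization, diversity testing, sparse
supervised classification, and three *cohort-fairness* strategies whose
goal is to select fibrosis-associated OTUs that are not artifacts of the
cohort structure. Because real multi-centre sequencing data cannot ship
with a package, a synthetic-data generator with known ground truth stands
in for the study and makes every stage verifiable.

The clinical contrast throughout is F0 versus the merged F1/2 group: early
fibrosis stages are hard to tell apart and merging them balances the group
sizes, so the two-class contrast is the default and the three-stage
labels remain available for the diversity tests.

## The synthetic study

`generator_config()` fixes the study conditions: 82 patients in four
cohorts of 36/10/19/17, fibrosis groups of 34/37/11, 450 OTUs of which
about 290--320 survive the abundance filter, a dominant Proteobacteria-like
block of 20 OTUs carrying 75% of the expected reads, a mean library of
30,300 classified reads, and an overall zero-cell fraction of 0.7.
Cohort and fibrosis labels are assigned from an iterative-proportional-fit
contingency table, with the largest cohort's odds of F1/F2 membership
multiplied by `confounding_odds` (default 2, a mild confounding of the
kind that makes fairness necessary).

Counts follow a zero-inflated log-normal--Poisson scheme:

* per-OTU baseline relative abundances are log-normal (sdlog 1) with the
  dominant block rescaled to carry exactly `dominance_fraction` of the
  expected mass;
* ten planted differential OTUs, drawn from the upper-abundance
  non-dominant tier (matching the moderately abundant taxa that microbiome
  studies actually report as signatures), are multiplied by
  `2^differential_log2fc` (default 4x) in F1/F2 samples;
* every (cohort, OTU) pair receives a multiplicative batch fingerprint,
  log2-uniform in `[-batch_log2fc, batch_log2fc]`. A per-sample scalar
  would vanish under any compositional normalization, so batch effects are
  modelled per OTU, which is what makes cohort-correlated principal
  components appear in the normalized table;
* the planted OTUs share half of their log-noise variance through a
  per-sample host factor (`guild_correlation = 0.5`). Differential taxa in
  real data respond to a common host state and therefore co-vary; this
  module structure is precisely what association-graph clustering is
  designed to detect, and with independent noise no clustering method
  could (or should) group the planted set;
* structural zeros are abundance-dependent: the dropout probability is
  logistic in `log1p(rate)` with slope 2, and its intercept is calibrated
  by root-finding so the expected overall zero fraction hits
  `sparsity_target`. Uniform dropout is unrealistic (abundant taxa do not
  vanish at random) and would destroy both the filter calibration and the
  planted effects;
* a noise-free mode returns expected counts for exact oracle tests.

What the generator does *not* emulate: phylogenetic correlation between
OTUs, read-level errors and chimeras, clinical covariates beyond the
cohort and stage labels, and overdispersion structure specific to
particular sequencing platforms. Passing tests therefore demonstrate that
the chain recovers planted multiplicative effects under realistic sparsity
and confounding -- not that it would behave identically on any real
dataset.

## Normalization

`css_normalize()` implements cumulative sum scaling: each sample's scaling
factor is the sum of its counts up to the chosen quantile (default the
median) of its non-zero counts, and values are `log2(count / factor *
1000 + 1)`, so zeros map to zero. The quantile is the inclusive empirical
quantile; the scaling factors are recorded in the result so any table can
be audited, and the test suite checks them against an independently coded
brute-force oracle on random matrices.

`tfidf_normalize()` re-purposes text-mining term weighting: term frequency
(count over sample total) times the natural-log inverse document
frequency `log(N / n_o)`. An OTU present in every sample gets weight
exactly zero -- the point of the transform is to silence the ubiquitous
dominant block and expose rare, concentrated OTUs. The word-cloud tables
(`wordcloud_ranking()`) report taxa ranked under both CSS and TF-IDF
weighting with the rank shift per taxon.

The abundance filter reads its threshold as a fraction of overall relative
abundance (default `1e-4`, i.e. 0.01%); the signature prefilter keeps OTUs
that are non-zero in more than 25% of samples *and* exceed a mean of 150
counts in at least one fibrosis group ("any group" semantics; an
"all groups" flag exists because the quantifier is genuinely ambiguous in
the field's usage).

## Diversity

Alpha indices use the standard closed forms (Chao1 in the bias-corrected
form `S + F1(F1-1)/(2(F2+1))`, defined even without doubletons), Shannon,
Simpson and inverse Simpson via vegan. Beta diversity is Bray-Curtis;
ordination is classical PCoA with negative eigenvalues reported rather
than dropped. PERMANOVA conditions on the cohort by restricting
permutations to within-cohort shuffles (the standard way to block on a
covariate); PERMDISP tests dispersion homogeneity around group spatial
medians. All permutation p-values use the `(hits + 1) / (n_perm + 1)`
convention with explicit seeds.

## Sparse discriminant analysis

`plsda_fit()` is PLS2 on the one-hot class matrix via NIPALS deflation.
The sparse variant soft-thresholds each component's X-weight vector so
exactly `keepX` features survive, then renormalizes -- sparsity is
parameterized by a count (the mixOmics convention) rather than a penalty
value, and `keepX` equal to the feature count reproduces the dense fit to
numerical precision (a tested invariant). `splsda_tune()` selects `keepX`
by leave-one-out balanced error with ties broken toward the sparser model.
ROC curves are computed from leave-one-out projected first-component
scores, so the reported AUC is honest; a resubstitution mode is not
offered. Note that leave-one-out estimates on pure noise fall slightly
*below* chance (each held-out sample's class is depleted in its training
set); the calibration tests therefore check the one-sided property that no
optimistic bias exists.

## The three fairness strategies

**Component filtering.** `fair_component_filter()` computes a PCA of the
normalized table and the Pearson correlation of every component with the
binary cohort indicator (largest cohort versus the rest, the contrast that
dominates the data). Components with `|r| > 0.1` are removed provided each
one's variance fraction is below 0.2 -- a dominant component is never
silently discarded, and a cumulative-cap variant is available
(`removal_mode = "cumulative"`). On simulated data the filter removes the
batch components (around 15--20% of the variance, leaving roughly 80%
retained) and cohort predictability collapses.

Measuring that collapse fairly required care, and two artifacts are worth
recording. First, a nonlinear classifier (random forest) can still detect
the cohort from zero-pattern and variance signatures that no
linear-correlation filter addresses; the filter's guarantee is linear
decorrelation, so the evaluation classifier is linear (LDA on selected
components). Second, if the filter is fit on all samples and the
classifier is then cross-validated inside the filtered data, test-fold
correlations are *negatively* biased (the truncation saw the test data)
and balanced accuracy lands well below 0.5. `fairness_evaluation()`
therefore nests the entire filter inside every training fold and projects
held-out samples onto that fold's retained components: cohort balanced
accuracy then sits at chance while the fibrosis contrast remains
classifiable from the same coordinates.

**l1-penalized spectral clustering.** The OTU association graph uses
thresholded absolute correlation (default 0.3) on within-cohort-centered
CSS values; centering removes the cohort fingerprints that would otherwise
dominate every edge, and OTUs strongly correlated with the cohort
indicator are dropped beforehand. A ridge-regularized partial-correlation
builder is available; the graph estimator is deliberately pluggable and a
Poisson log-normal graphical model is out of scope. Cluster indicators are
then recovered one at a time by soft-thresholded power iteration on the
adjacency matrix, the support boundary placed at the largest gap of the
sorted indicator, each support removed before the next (deflation), and
leftovers attached by spectral-embedding distance. The power iteration
runs on the *unnormalized* adjacency: under degree normalization every
connected pair has leading eigenvalue 1 and the iteration localizes on
near-duplicate pairs instead of the densest community. The number of
clusters defaults to the eigengap of the normalized Laplacian; on small
graphs a local-move sweep polishes the normalized cut, which the tests
hold within 10% of the exhaustive optimum on a fixed six-node graph bank.

**Fairlet k-median.** OTUs are colored by the cohort in which they are
most abundant (binarized largest-versus-rest), decomposed into fairlets --
micro-groups of one minority-color point and between one and q
majority-color points, built by greedy distance matching -- and the
k-median objective (k = 3) is solved over fairlet centers with PAM. Every
cluster inherits the fairlet balance, which is asserted on every run. The
OTU embedding uses the two leading principal axes of the cohort-centered
table: with three medoids only the dominant geometry can be tracked, and
additional axes were found to blur the co-abundant groups (a
correlation-distance embedding was tried and was less stable).

## The consensus signature

Each arm yields a candidate OTU set: the union of sPLS-DA selections
across components; the top-loading OTUs (ten per component) of
fair components that are predictive under random-forest ranking and
associated with fibrosis; and the members of l1-spectral and fair-k-median
clusters whose mean abundance differs between F0 and F1/2. Every candidate
set is then pruned to the OTUs individually significant in a BH-corrected
Welch test on the CSS scale, which is what controls false positives. The
per-component candidate width defaults to ten OTUs — wide enough that a
signal concentrated in one or two components keeps its recall, while the
significance prune keeps precision.

The consensus combines the four arms by the *majority* rule (an OTU must
be selected by more than half of the arms). A strict intersection is
available and is the more literal reading of a
"common to all strategies" table, but it proved brittle in simulation:
whenever a single arm fails completely -- the fibrosis-aligned component
being removed by the fairness filter under confounding, or no cluster
reaching significance at k = 3 -- the intersection empties even though the
other three arms each recover 8--10 of the 10 planted OTUs. The majority
rule preserves the multi-strategy character (no single method can push an
OTU through) while tolerating one failed arm; with the default
configuration it recovers 9/10 planted OTUs on average with about 0.1
false positives per run.

## Numerical choices and degenerate inputs

Permutation tests use explicit seeds and the +1 convention; strata with
fewer than two samples are dropped with a warning. A PERMANOVA on an
all-zero distance matrix returns p = 1 by convention. CSS refuses all-zero
samples by name; Bray-Curtis refuses pairs of all-zero samples. Constant
features are dropped from PLS fits with a warning and reported with zero
loadings; constant features in group tests return p = 1 with a flag.
Soft-threshold ties are broken by first occurrence; if every surviving
weight ties with the threshold the survivors are kept at equal magnitude.
Any all-zero OTU column in the generator receives one pseudo-read at its
highest-rate sample so marginals stay positive.

## Problem sizes

The packaged analyses and tests run the full 82 x 450 study: a complete
pipeline takes a few seconds, and the replicated end-to-end checks use ten
generator seeds. The statistical-calibration tests use 200 null
simulations at 24 samples x 15--20 features, and the brute-force oracles
run at the sizes where exhaustive enumeration is exact (n = 6 label
permutations, 8-point k-median, 6-node graphs). These sizes were chosen so
that every claim is backed by either an exact oracle or a replicated
simulation.

## Known limitations

The fairness guarantee is linear: cohort signatures carried by zero
patterns or variance differences survive the component filter (and are
visible to a random forest). Under cohort-fibrosis confounding the filter
can legitimately remove part of the fibrosis signal -- fairness and
sensitivity genuinely trade off, and the majority consensus is what keeps
the pipeline robust to that loss. The fair k-median at k = 3 tests
cluster-mean contrasts, which dilute a ten-OTU guild inside large
clusters; it is the weakest arm on sparse planted signals. TF-IDF weights
depend on presence calls and are therefore sensitive to the zero-inflation
model. Finally, compositional closure means that planting an increase in
ten OTUs induces a small spurious decrease everywhere else; cluster-level
tests can pick this counter-shift up as significance in "null" clusters,
another reason the per-OTU significance prune backs every arm.
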
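#' Venn partition of OTUs by group-wise presence
#'
#' An OTU belongs to a group's presence set when it has a non-zero count in
#' at least `min_samples` samples of that group; the Venn regions are all
#' set-algebra combinations of the group presence sets (7 regions for 3
#' groups, 3 for 2). OTUs absent everywhere form an `"none"` region so the
#' regions always partition the input OTU set.
#'
#' @param counts Samples x OTUs count matrix.
#' @param groups Group labels per sample (e.g. fibrosis scores).
#' @param min_samples Minimum number of non-zero samples for presence
#'   (default 1).
#' @return Object of class `venn_partition`: `regions` (named list of OTU id
#'   vectors, names like `"F0"`, `"F0+F1"`), `counts` (per-region sizes),
#'   `presence` (groups x OTUs logical matrix).
#' @export
set_specific_otus <- function(counts, groups, min_samples = 1) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("set_specific_otus: empty group")
  gl <- levels(groups)
  presence <- vapply(gl, function(g)
    colSums(counts[groups == g, , drop = FALSE] > 0) >= min_samples,
    logical(ncol(counts)))
  presence <- t(presence)  # groups x OTUs
  code <- apply(presence, 2, function(z)
    if (!any(z)) "none" else paste(gl[z], collapse = "+"))
  regions <- split(colnames(counts), code)
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 presence = presence),
            class = "venn_partition")
}

#' Consensus of per-method discriminant OTU sets
#'
#' @param method_sets Named list (>= 2) of OTU id vectors, one per method.
#' @param rule `"intersection"` (OTUs in every set; the default, matching a
#'   signatures-common-to-all-strategies report) or `"majority"` (OTUs in
#'   more than half of the sets).
#' @return List of class `consensus`: `consensus` (OTU ids), `rule`,
#'   `method_sets`, `support` (per-OTU number of supporting methods).
#' @export
consensus_signature <- function(method_sets, rule = c("intersection", "majority")) {
  rule <- match.arg(rule)
  if (length(method_sets) < 2)
    stop("consensus_signature: need at least 2 method sets")
  all_otus <- unique(unlist(method_sets))
  support <- vapply(all_otus, function(o)
    sum(vapply(method_sets, function(s) o %in% s, logical(1))), integer(1))
  names(support) <- all_otus
  consensus <- switch(rule,
    intersection = all_otus[support == length(method_sets)],
    majority = all_otus[support > length(method_sets) / 2])
  if (length(consensus) == 0)
    message("consensus_signature: empty consensus under rule '", rule, "'")
  structure(list(consensus = consensus, rule = rule,
                 method_sets = method_sets, support = support),
            class = "consensus")
}

#' Taxa rankings under CSS vs TF-IDF weighting (word-cloud tables)
#'
#' Taxa at the chosen rank are ranked by the mean CSS-normalized weight of
#' their member OTUs and, separately, by the mean TF-IDF weight; the rank
#' shift per taxon shows which low-frequency taxa the TF-IDF view exposes.
#' Ubiquitous OTUs carry weight exactly 0 under TF-IDF.
#'
#' @param css CSS-normalized matrix (samples x OTUs).
#' @param tfidf TF-IDF matrix over the same OTUs.
#' @param taxonomy Taxonomy table covering all OTUs.
#' @param rank Taxonomic rank for aggregation.
#' @return data.frame `taxon`, `css_weight`, `tfidf_weight`, `css_rank`,
#'   `tfidf_rank`, `rank_shift` (positive = promoted by TF-IDF).
#' @export
wordcloud_ranking <- function(css, tfidf, taxonomy,
                              rank = c("genus", "family", "phylum")) {
  rank <- match.arg(rank)
  if (!identical(colnames(css), colnames(tfidf)))
    stop("wordcloud_ranking: CSS and TF-IDF tables must share the same OTUs")
  missing <- setdiff(colnames(css), taxonomy$otu_id)
  if (length(missing) > 0)
    stop("wordcloud_ranking: OTUs without taxonomy: ",
         paste(missing, collapse = ", "))
  tax <- taxonomy[[rank]][match(colnames(css), taxonomy$otu_id)]
  w_css <- tapply(colMeans(css), tax, mean)
  w_tfidf <- tapply(colMeans(tfidf), tax, mean)
  r_css <- rank(-w_css, ties.method = "average")
  r_tfidf <- rank(-w_tfidf, ties.method = "average")
  out <- data.frame(taxon = names(w_css), css_weight = as.numeric(w_css),
                    tfidf_weight = as.numeric(w_tfidf),
                    css_rank = as.numeric(r_css),
                    tfidf_rank = as.numeric(r_tfidf),
                    rank_shift = as.numeric(r_css - r_tfidf),
                    row.names = NULL)
  out[order(out$tfidf_rank), ]
}
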
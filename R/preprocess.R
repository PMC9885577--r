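#' Remove OTUs of low overall relative abundance
#'
#' Drops every OTU whose overall relative abundance (OTU total divided by the
#' grand total) is strictly below `threshold`. The default pipeline threshold
#' is 1e-4, i.e. 0.01 percent of all reads.
#'
#' @param counts Samples x OTUs count matrix.
#' @param threshold Minimum overall relative abundance to retain an OTU.
#' @return The filtered count matrix (same samples).
#' @export
filter_low_abundance <- function(counts, threshold) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0)
    stop("filter_low_abundance: empty table")
  if (threshold < 0) stop("filter_low_abundance: threshold must be >= 0")
  rel <- colSums(counts) / sum(counts)
  keep <- rel >= threshold
  if (threshold == 0) keep <- rep(TRUE, ncol(counts))
  if (!any(keep))
    stop("filter_low_abundance: all ", ncol(counts),
         " OTUs fall below threshold ", threshold)
  counts[, keep, drop = FALSE]
}

#' Prevalence / mean-count prefilter for signature analyses
#'
#' Keeps OTUs that are non-zero in more than `prevalence` of all samples AND
#' have a mean raw count above `mean_count` in at least one fibrosis group
#' (`group_rule = "any"`, the default) or in every group (`"all"`).
#'
#' @param counts Samples x OTUs count matrix.
#' @param metadata data.frame with `sample_id` and `fibrosis` covering all rows.
#' @param prevalence Fraction of non-zero samples required (exclusive).
#' @param mean_count Group-mean count threshold (exclusive).
#' @param group_rule `"any"` or `"all"` group semantics for the mean rule.
#' @return List with `counts` (kept table) and `audit` (per-OTU data.frame of
#'   which rule passed).
#' @export
signature_prefilter <- function(counts, metadata, prevalence = 0.25,
                                mean_count = 150, group_rule = c("any", "all")) {
  group_rule <- match.arg(group_rule)
  if (!all(rownames(counts) %in% metadata$sample_id))
    stop("signature_prefilter: metadata does not cover all samples")
  fib <- metadata$fibrosis[match(rownames(counts), metadata$sample_id)]
  if (any(!fib %in% c("F0", "F1", "F2")))
    stop("signature_prefilter: unknown fibrosis labels: ",
         paste(unique(setdiff(fib, c("F0", "F1", "F2"))), collapse = ", "))
  prev <- colMeans(counts > 0)
  gm <- vapply(unique(fib), function(g) colMeans(counts[fib == g, , drop = FALSE]),
               numeric(ncol(counts)))
  mean_ok <- if (group_rule == "any") apply(gm > mean_count, 1, any)
             else apply(gm > mean_count, 1, all)
  keep <- prev > prevalence & mean_ok
  audit <- data.frame(otu_id = colnames(counts), prevalence = prev,
                      prevalence_pass = prev > prevalence,
                      mean_count_pass = mean_ok, kept = keep,
                      row.names = NULL)
  list(counts = counts[, keep, drop = FALSE], audit = audit)
}

## brute-force-checkable CSS scaling factor of one sample: the sum of counts
## no greater than the chosen quantile of the sample's non-zero counts
css_scaling_factor <- function(x, percentile) {
  nz <- x[x > 0]
  if (length(nz) == 0) return(NA_real_)
  q <- stats::quantile(nz, probs = percentile, names = FALSE, type = 7)
  sum(x[x <= q])
}

#' Cumulative sum scaling (CSS) normalization with log transform
#'
#' Per sample, the scaling factor is the sum of counts less than or equal to
#' the `percentile` quantile (inclusive empirical quantile) of that sample's
#' non-zero counts. Values are `log_base`-logarithms of
#' `count / factor * 1000 + 1`, so zero counts map to exactly 0.
#'
#' @param counts Samples x OTUs count matrix; every sample must have > 0 reads.
#' @param percentile Quantile of the non-zero count distribution (default 0.5).
#' @param log_base Logarithm base (default 2).
#' @return Numeric matrix with attributes `normalization = "css_log"` and
#'   `parameters` (percentile, log base, per-sample scaling factors).
#' @export
css_normalize <- function(counts, percentile = 0.5, log_base = 2) {
  empty <- rowSums(counts) == 0
  if (any(empty))
    stop("css_normalize: sample(s) with all-zero counts: ",
         paste(rownames(counts)[empty], collapse = ", "))
  sf <- apply(counts, 1, css_scaling_factor, percentile = percentile)
  vals <- log(sweep(counts, 1, sf, "/") * 1000 + 1, base = log_base)
  structure(vals, normalization = "css_log",
            parameters = list(percentile = percentile, log_base = log_base,
                              scaling_factors = sf))
}

#' TF-IDF weighting of an OTU count table
#'
#' `value(s, o) = tf(s, o) * idf(o)` with term frequency `count / sample
#' total` and inverse document frequency `log(N / n_o)` (natural log), where
#' `n_o` is the number of samples in which OTU `o` is non-zero. OTUs present
#' in every sample get weight exactly 0; OTUs present nowhere get idf 0 by
#' convention. With `smooth = TRUE`, `idf = log((N + 1) / (n_o + 1))`.
#'
#' @param counts Samples x OTUs count matrix.
#' @param smooth Apply +1 smoothing to the idf (default `FALSE`).
#' @return Numeric matrix with attribute `normalization = "tfidf"`.
#' @export
tfidf_normalize <- function(counts, smooth = FALSE) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0)
    stop("tfidf_normalize: empty table")
  n <- nrow(counts)
  tf <- counts / pmax(rowSums(counts), 1)
  df_ <- colSums(counts > 0)
  idf <- if (smooth) log((n + 1) / (df_ + 1)) else ifelse(df_ == 0, 0, log(n / df_))
  structure(sweep(tf, 2, idf, "*"), normalization = "tfidf",
            parameters = list(smooth = smooth, idf = idf))
}

#' Relative-abundance (total sum scaling) view of a count table
#'
#' @param counts Samples x OTUs count matrix.
#' @return Row-normalized matrix; all-zero samples stay zero.
#' @export
relative_abundance <- function(counts) {
  structure(counts / pmax(rowSums(counts), .Machine$double.eps),
            normalization = "relative", parameters = list())
}

#' Aggregate OTU counts at a taxonomic rank
#'
#' Counts are summed within each taxon of the chosen rank; total counts are
#' conserved exactly.
#'
#' @param counts Samples x OTUs count matrix.
#' @param taxonomy data.frame with `otu_id` and the rank columns.
#' @param rank One of `"phylum"`, `"family"`, `"genus"`.
#' @return Samples x taxa matrix of summed counts.
#' @export
aggregate_taxa <- function(counts, taxonomy, rank = c("phylum", "family", "genus")) {
  rank <- match.arg(rank)
  missing <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(missing) > 0)
    stop("aggregate_taxa: OTUs without taxonomy: ", paste(missing, collapse = ", "))
  tax <- taxonomy[[rank]][match(colnames(counts), taxonomy$otu_id)]
  t(rowsum(t(counts), group = tax))
}
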
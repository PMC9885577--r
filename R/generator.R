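#' Configuration for the synthetic multi-cohort liver-microbiota generator
#'
#' Defines the study conditions emulated by [simulate_cohort_study()]: four
#' unbalanced European cohorts (82 patients), three early fibrosis stages
#' (F0/F1/F2), a sparse OTU count table dominated by a Proteobacteria-like
#' block of taxa, per-cohort multiplicative batch effects, and a planted set
#' of fibrosis-differential OTUs whose identity is recorded as ground truth.
#'
#' @param n_samples_per_cohort Named integer vector of cohort sizes. The
#'   default reproduces the study layout: Romania 36, Austria 10, Italy 19,
#'   Spain 17.
#' @param group_sizes Named integer vector of fibrosis-group sizes
#'   (F0/F1/F2); must sum to `sum(n_samples_per_cohort)`.
#' @param n_otus Number of OTUs generated before any filtering.
#' @param n_differential Number of planted fibrosis-differential OTUs.
#' @param differential_log2fc log2 fold change applied to planted OTUs in
#'   F1/F2 samples relative to F0.
#' @param batch_log2fc Half-width of the per-(cohort, OTU) uniform log2
#'   batch-multiplier distribution; cohort fingerprints are drawn in
#'   `[-batch_log2fc, batch_log2fc]`. Set 0 for no batch effect.
#' @param dominance_fraction Fraction of total expected abundance carried by
#'   the dominant (Proteobacteria-like) OTU block.
#' @param n_dominant Number of OTUs in the dominant block.
#' @param sparsity_target Desired overall fraction of zero cells; structural
#'   zero-inflation is calibrated on top of sampling zeros to reach it.
#' @param library_size_mean Mean per-sample read count classified in OTUs.
#' @param library_size_dispersion Log-normal sdlog of library sizes.
#' @param biological_sd sdlog of the per-cell log-normal abundance noise.
#' @param guild_correlation Fraction of the differential OTUs' log-noise
#'   variance carried by a shared per-sample host factor, making the planted
#'   set a co-abundant guild (the module structure that association-graph
#'   clustering targets). 0 gives independent noise.
#' @param confounding_odds Odds multiplier tilting F1/F2 membership toward
#'   the largest cohort (1 = cohort and fibrosis independent).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_samples_per_cohort = c(Romania = 36L, Austria = 10L,
                                                      Italy = 19L, Spain = 17L),
                             group_sizes = c(F0 = 34L, F1 = 37L, F2 = 11L),
                             n_otus = 450L,
                             n_differential = 10L,
                             differential_log2fc = 2,
                             batch_log2fc = 1.5,
                             dominance_fraction = 0.75,
                             n_dominant = 20L,
                             sparsity_target = 0.7,
                             library_size_mean = 30300,
                             library_size_dispersion = 0.3,
                             biological_sd = 0.8,
                             guild_correlation = 0.5,
                             confounding_odds = 2,
                             seed = 1L) {
  cfg <- list(n_samples_per_cohort = n_samples_per_cohort,
              group_sizes = group_sizes,
              n_otus = as.integer(n_otus),
              n_differential = as.integer(n_differential),
              differential_log2fc = differential_log2fc,
              batch_log2fc = batch_log2fc,
              dominance_fraction = dominance_fraction,
              n_dominant = as.integer(n_dominant),
              sparsity_target = sparsity_target,
              library_size_mean = library_size_mean,
              library_size_dispersion = library_size_dispersion,
              biological_sd = biological_sd,
              guild_correlation = guild_correlation,
              confounding_odds = confounding_odds,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  if (sum(cfg$group_sizes) != sum(cfg$n_samples_per_cohort))
    stop("generator_config: group_sizes must sum to the total number of samples (",
         sum(cfg$n_samples_per_cohort), "), got ", sum(cfg$group_sizes))
  if (cfg$n_differential > cfg$n_otus)
    stop("generator_config: n_differential exceeds n_otus")
  if (cfg$dominance_fraction < 0 || cfg$dominance_fraction > 1)
    stop("generator_config: dominance_fraction must lie in [0, 1]")
  if (cfg$sparsity_target < 0 || cfg$sparsity_target > 1)
    stop("generator_config: sparsity_target must lie in [0, 1]")
  if (cfg$n_dominant >= cfg$n_otus)
    stop("generator_config: n_dominant must be smaller than n_otus")
  if (is.null(names(cfg$n_samples_per_cohort)))
    stop("generator_config: n_samples_per_cohort must be named by cohort")
  invisible(cfg)
}

## Round a real-valued contingency table to integers while preserving both
## margins exactly (floor + greedy largest-remainder repair).
round_preserving_margins <- function(target, row_totals, col_totals) {
  fl <- floor(target)
  row_def <- row_totals - rowSums(fl)
  col_def <- col_totals - colSums(fl)
  frac <- target - fl
  while (sum(row_def) > 0) {
    elig <- outer(row_def > 0, col_def > 0, "&")
    if (!any(elig)) stop("margin rounding failed")  # cannot happen: deficits balance
    cand <- which(elig & frac == max(frac[elig]), arr.ind = TRUE)[1, , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    fl[i, j] <- fl[i, j] + 1
    frac[i, j] <- -1
    row_def[i] <- row_def[i] - 1
    col_def[j] <- col_def[j] - 1
  }
  fl
}

## Iterative proportional fitting of a seed table to integer-valued margins.
ipf_table <- function(seed_tab, row_totals, col_totals, max_iter = 200, tol = 1e-10) {
  tab <- seed_tab
  for (it in seq_len(max_iter)) {
    tab <- tab * (row_totals / pmax(rowSums(tab), .Machine$double.eps))
    tab <- sweep(tab, 2, col_totals / pmax(colSums(tab), .Machine$double.eps), "*")
    if (max(abs(rowSums(tab) - row_totals)) < tol) break
  }
  tab
}

#' Generate per-sample metadata (cohort and fibrosis stage)
#'
#' Cohort and fibrosis labels are jointly assigned from an iterative
#' proportional fit of a tilted contingency table, so that both margins are
#' met exactly while the largest cohort is enriched for F1/F2 by a factor of
#' `confounding_odds` (odds scale). With `confounding_odds = 1` the realized
#' table equals the independence expectation up to integer rounding.
#'
#' @param config A [generator_config()].
#' @return A data.frame with columns `sample_id`, `cohort`, `fibrosis`.
#' @export
generate_metadata <- function(config) {
  validate_generator_config(config)
  cohorts <- names(config$n_samples_per_cohort)
  groups <- names(config$group_sizes)
  nc <- config$n_samples_per_cohort
  ng <- config$group_sizes
  n <- sum(nc)

  ## tilt: largest cohort has elevated odds of the non-reference (F1/F2) stages
  tilt <- matrix(1, nrow = length(cohorts), ncol = length(groups),
                 dimnames = list(cohorts, groups))
  largest <- cohorts[which.max(nc)]
  tilt[largest, setdiff(groups, groups[1])] <- config$confounding_odds
  seed_tab <- outer(nc / n, ng / n) * n * tilt
  tab <- ipf_table(seed_tab, as.numeric(nc), as.numeric(ng))
  tab <- round_preserving_margins(tab, as.numeric(nc), as.numeric(ng))

  set.seed(config$seed)
  cohort <- rep(cohorts, times = nc)
  fibrosis <- character(n)
  for (ci in seq_along(cohorts)) {
    lab <- rep(groups, times = tab[ci, ])
    fibrosis[cohort == cohorts[ci]] <- sample(lab)
  }
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             cohort = cohort,
             fibrosis = fibrosis,
             stringsAsFactors = FALSE)
}

#' Generate OTU counts with planted effects, plus the ground-truth record
#'
#' Counts follow a zero-inflated log-normal--Poisson scheme: heavy-tailed
#' per-OTU baseline relative abundances (a dominant block carrying
#' `dominance_fraction` of the expected mass), planted differential OTUs
#' multiplied by `2^differential_log2fc` in F1/F2 samples, per-(cohort, OTU)
#' multiplicative batch fingerprints, log-normal biological noise, log-normal
#' library sizes and Poisson sampling. Structural zero-inflation is calibrated
#' against the expected sampling-zero fraction so the overall zero fraction
#' approaches `sparsity_target`.
#'
#' @param metadata Output of [generate_metadata()].
#' @param config The same [generator_config()].
#' @param noise_free If `TRUE`, return expected counts (no noise, no Poisson
#'   sampling, no zero-inflation) as a real-valued matrix, for exact oracle
#'   checks of the planted effects.
#' @return A list with `counts` (samples x OTUs matrix) and `truth`
#'   (differential OTU ids, effect sizes, batch multipliers, baselines).
#' @export
generate_counts <- function(metadata, config, noise_free = FALSE) {
  validate_generator_config(config)
  stopifnot(all(c("sample_id", "cohort", "fibrosis") %in% names(metadata)))
  n <- nrow(metadata)
  p <- config$n_otus
  otu_ids <- sprintf("OTU%04d", seq_len(p))
  cohorts <- names(config$n_samples_per_cohort)

  set.seed(config$seed + 1000L)
  ## heavy-tailed baselines; first n_dominant OTUs form the dominant block.
  ## sdlog 1 calibrates the non-dominant tail so that ~0.9 of OTUs clear the
  ## 0.01 percent overall-abundance filter downstream (~411 of 450)
  base <- stats::rlnorm(p, meanlog = 0, sdlog = 1.0)
  dom <- seq_len(config$n_dominant)
  df_ <- config$dominance_fraction
  base[dom] <- base[dom] * (df_ / (1 - df_)) * sum(base[-dom]) / sum(base[dom])
  base <- base / sum(base)

  ## planted differential OTUs: non-dominant but in the upper-abundance tier,
  ## matching the moderately abundant taxa reported as fibrosis signatures
  nondom <- setdiff(seq_len(p), dom)
  eligible <- nondom[rank(base[nondom]) > 2 * length(nondom) / 3]
  diff_idx <- sort(sample(eligible, config$n_differential))
  lfc <- rep(config$differential_log2fc, config$n_differential)

  ## per-cohort, per-OTU multiplicative batch fingerprints
  batch_log2 <- matrix(0, nrow = length(cohorts), ncol = p,
                       dimnames = list(cohorts, otu_ids))
  if (config$batch_log2fc > 0)
    batch_log2[] <- stats::runif(length(cohorts) * p,
                                 -config$batch_log2fc, config$batch_log2fc)

  is_f12 <- metadata$fibrosis %in% c("F1", "F2")
  mu <- matrix(rep(base, each = n), nrow = n)          # samples x OTUs
  mu[, diff_idx] <- sweep(mu[, diff_idx, drop = FALSE], 1,
                          ifelse(is_f12, 2^config$differential_log2fc, 1), "*")
  mu <- mu * 2^batch_log2[metadata$cohort, , drop = FALSE]
  if (!noise_free && config$biological_sd > 0) {
    ## planted OTUs share part of their log-noise through a per-sample host
    ## factor (co-abundant guild); all other noise is cell-independent
    z <- matrix(stats::rnorm(n * p), nrow = n)
    rho <- config$guild_correlation
    if (rho > 0 && length(diff_idx) > 0) {
      shared <- stats::rnorm(n)
      z[, diff_idx] <- sqrt(rho) * shared +
        sqrt(1 - rho) * z[, diff_idx, drop = FALSE]
    }
    mu <- mu * exp(config$biological_sd * z)
  }
  mu <- mu / rowSums(mu)                               # compositional closure

  if (noise_free) {
    lib <- rep(config$library_size_mean, n)
  } else {
    lib <- stats::rlnorm(n, meanlog = log(config$library_size_mean) -
                           config$library_size_dispersion^2 / 2,
                         sdlog = config$library_size_dispersion)
  }
  lambda <- mu * lib

  ## abundance-dependent structural dropout, logistic in log(1 + rate), with
  ## the intercept calibrated so expected overall zeros hit sparsity_target
  ## (dropout concentrates in low-abundance cells, as in real count tables)
  ## slope 2 keeps dropout essentially confined to low-rate cells, giving the
  ## quasi presence/absence pattern of real tables
  zero_frac <- function(a) mean(stats::plogis(a - 2 * log1p(lambda)) +
                                  (1 - stats::plogis(a - 2 * log1p(lambda))) *
                                  exp(-lambda))
  if (zero_frac(-30) >= config$sparsity_target) {
    dropout_a <- -Inf
  } else if (zero_frac(30) <= config$sparsity_target) {
    dropout_a <- Inf
  } else {
    dropout_a <- stats::uniroot(function(a) zero_frac(a) - config$sparsity_target,
                                c(-30, 30), tol = 1e-8)$root
  }
  pi_cell <- stats::plogis(dropout_a - 2 * log1p(lambda))

  if (noise_free) {
    counts <- lambda
  } else {
    keep <- matrix(stats::rbinom(n * p, 1, 1 - pi_cell), nrow = n)
    counts <- matrix(stats::rpois(n * p, lambda), nrow = n) * keep
    ## guarantee positive marginals: any all-zero OTU gets one pseudo-read at
    ## its highest-rate sample
    empty <- which(colSums(counts) == 0)
    for (j in empty) counts[which.max(lambda[, j]), j] <- 1
    storage.mode(counts) <- "integer"
  }
  dimnames(counts) <- list(metadata$sample_id, otu_ids)

  truth <- list(differential_otu_ids = otu_ids[diff_idx],
                direction = stats::setNames(rep(1, length(diff_idx)), otu_ids[diff_idx]),
                log2fc = stats::setNames(lfc, otu_ids[diff_idx]),
                batch_log2 = batch_log2,
                baseline = stats::setNames(base, otu_ids),
                dominant_otu_ids = otu_ids[dom],
                dropout_intercept = dropout_a)
  list(counts = counts, truth = truth)
}

## fixed taxonomy bank; the first phylum is the dominant one
.taxa_bank <- function() {
  list(
    Proteobacteria = list(
      Enterobacteriaceae = c("Escherichia-Shigella", "Kluyvera", "Morganella",
                             "Enterobacter", "Kosakonia", "Multi-affiliation"),
      Pseudomonadaceae = c("Pseudomonas"),
      Xanthobacteraceae = c("Bradyrhizobium"),
      Burkholderiaceae = c("Ralstonia", "Delftia", "Comamonas", "Janthinobacterium"),
      Xanthomonadaceae = c("Stenotrophomonas"),
      Moraxellaceae = c("Acinetobacter"),
      Caulobacteraceae = c("Caulobacter"),
      Sphingomonadaceae = c("Sphingomonas"),
      Rhodobacteraceae = c("Paracoccus")),
    Firmicutes = list(
      Streptococcaceae = c("Streptococcus"),
      Ruminococcaceae = c("Faecalibacterium"),
      Lachnospiraceae = c("Blautia", "Multi-affiliation"),
      Peptostreptococcaceae = c("Romboutsia")),
    Bacteroidetes = list(
      Flavobacteriaceae = c("Flavobacterium"),
      Weeksellaceae = c("Cloacibacterium"),
      Spirosomaceae = c("Pseudarcicella")),
    Actinobacteria = list(
      Microbacteriaceae = c("Rhodoluna", "Clavibacter"),
      Micrococcaceae = c("Kocuria"),
      Corynebacteriaceae = c("Corynebacterium"),
      Intrasporangiaceae = c("Multi-affiliation")))
}

#' Generate a taxonomy table for the synthetic OTUs
#'
#' OTUs are assigned (phylum, family, genus) from a small fixed bank. The
#' dominant-abundance block is always mapped to the Proteobacteria-like
#' phylum (mostly Enterobacteriaceae/Pseudomonadaceae), and a share of the
#' remaining OTUs as well, so phylum-level aggregation reproduces the
#' dominant-phylum structure of the emulated data.
#'
#' @param config A [generator_config()].
#' @return data.frame with columns `otu_id`, `phylum`, `family`, `genus`.
#' @export
generate_taxonomy <- function(config) {
  validate_generator_config(config)
  bank <- .taxa_bank()
  p <- config$n_otus
  otu_ids <- sprintf("OTU%04d", seq_len(p))
  set.seed(config$seed + 2000L)

  pick <- function(phylum) {
    fam <- sample(names(bank[[phylum]]), 1)
    genus <- sample(bank[[phylum]][[fam]], 1)
    c(phylum, fam, genus)
  }
  phyla <- names(bank)
  out <- matrix("", nrow = p, ncol = 3)
  dom <- seq_len(config$n_dominant)
  for (i in dom) out[i, ] <- pick(phyla[1])
  for (i in setdiff(seq_len(p), dom)) {
    ph <- sample(phyla, 1, prob = c(0.35, 0.25, 0.2, 0.2))
    out[i, ] <- pick(ph)
  }
  data.frame(otu_id = otu_ids, phylum = out[, 1], family = out[, 2],
             genus = out[, 3], stringsAsFactors = FALSE)
}

#' Simulate a complete multi-cohort study
#'
#' Convenience wrapper bundling [generate_metadata()], [generate_counts()]
#' and [generate_taxonomy()] under a single configuration and seed.
#'
#' @param config A [generator_config()].
#' @param noise_free Passed to [generate_counts()].
#' @return List with `metadata`, `counts`, `taxonomy`, `truth`, `config`.
#' @export
simulate_cohort_study <- function(config = generator_config(), noise_free = FALSE) {
  metadata <- generate_metadata(config)
  gc_ <- generate_counts(metadata, config, noise_free = noise_free)
  taxonomy <- generate_taxonomy(config)
  list(metadata = metadata, counts = gc_$counts, taxonomy = taxonomy,
       truth = gc_$truth, config = config)
}

#' Write a simulated study to disk as plain-text artifacts
#'
#' OTU table TSV (rows = OTUs, first column `otu_id`), metadata TSV,
#' taxonomy TSV and ground-truth JSON.
#'
#' @param sim Output of [simulate_cohort_study()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  otu_path <- file.path(outdir, "otu_table.tsv")
  otu_df <- data.frame(otu_id = colnames(sim$counts), t(sim$counts),
                       check.names = FALSE)
  utils::write.table(otu_df, otu_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- file.path(outdir, "metadata.tsv")
  utils::write.table(sim$metadata, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tax_path <- file.path(outdir, "taxonomy.tsv")
  utils::write.table(sim$taxonomy, tax_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(outdir, "truth.json")
  truth <- sim$truth
  truth$batch_log2 <- as.data.frame(truth$batch_log2)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(otu_path, meta_path, tax_path, truth_path))
}

#' Read an OTU table written by [write_simulation()]
#'
#' @param path TSV path, rows = OTUs, first column `otu_id`.
#' @return Integer matrix, samples x OTUs.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$otu_id
  storage.mode(m) <- "integer"
  m
}
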
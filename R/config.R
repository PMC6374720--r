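#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults reproduce the study conditions: genotypes are retained when the
#' supporting allele(s) carry at least 80% of reads with a minimum of five
#' unique reads; sites are kept at minor allele frequency >= 1%, call rate
#' >= 20%, and a heterozygosity rate bounded by twice the product of the two
#' most common allele frequencies; diagnostic panels demand a 100% call rate;
#' parsimony networks use a 95% connection probability; backcrosses are
#' called at a hybrid index of 0.75 and later-generation hybrids at a panel
#' heterozygosity of 0.25.
#'
#' @param allele_support_frac Minimum fraction of reads supporting the called
#'   allele(s) at a site (default 0.80).
#' @param min_unique_reads Minimum unique reads supporting the most common
#'   allele (default 5).
#' @param min_base_qual Minimum PHRED base quality assumed for the counts
#'   handed to the caller; recorded for provenance, quality filtering itself
#'   happens upstream of the count table (default 20).
#' @param min_maf Minimum minor allele frequency for site retention
#'   (default 0.01).
#' @param min_call_rate Minimum fraction of specimens with a called genotype
#'   at a retained site (default 0.20).
#' @param panel_call_rate Call-rate requirement for diagnostic-panel loci
#'   (default 1.00).
#' @param network_confidence Connection probability for statistical parsimony
#'   networks (default 0.95).
#' @param backcross_index Hybrid-index threshold for calling a first
#'   generation backcross (default 0.75).
#' @param latergen_het Panel heterozygosity at or below which an intermediate
#'   specimen is called a later-generation hybrid (default 0.25).
#' @param f1_het_min Minimum panel heterozygosity for an F1 call
#'   (default 0.95).
#' @param parental_index_min Minimum hybrid index (or 1 minus it) for a
#'   parental call (default 0.95).
#' @param het_z Number of binomial standard errors of slack allowed when
#'   testing the observed heterozygote fraction against the 2pq bound; 0
#'   applies the bound strictly (default 3).
#' @param het_support_each If TRUE, each of the two alleles of a heterozygote
#'   must individually reach \code{min_unique_reads}; if FALSE (default) only
#'   the most common allele must.
#' @param sexlink_max_mismatch Number of specimens allowed to deviate from
#'   the expected sex-linked pattern per locus (default 0).
#' @param collapse_match_ambiguous If TRUE, haplotype collapsing merges
#'   sequences identical over columns where both are unambiguous and
#'   ungapped; default FALSE (strict string identity).
#' @param diagnostic_lenient If TRUE, diagnostic character scanning resolves
#'   IUPAC ambiguity codes against their expansions; default FALSE (strict).
#' @param rng_seed Integer seed recorded in run manifests.
#'
#' @return An object of class \code{snowfly_config} (a validated list).
#' @export
#' @examples
#' cfg <- snowfly_config()
#' cfg$min_maf
snowfly_config <- function(allele_support_frac = 0.80,
                           min_unique_reads = 5L,
                           min_base_qual = 20L,
                           min_maf = 0.01,
                           min_call_rate = 0.20,
                           panel_call_rate = 1.00,
                           network_confidence = 0.95,
                           backcross_index = 0.75,
                           latergen_het = 0.25,
                           f1_het_min = 0.95,
                           parental_index_min = 0.95,
                           het_z = 3,
                           het_support_each = FALSE,
                           sexlink_max_mismatch = 0L,
                           collapse_match_ambiguous = FALSE,
                           diagnostic_lenient = FALSE,
                           rng_seed = 1L) {
  cfg <- list(
    allele_support_frac = allele_support_frac,
    min_unique_reads = as.integer(min_unique_reads),
    min_base_qual = as.integer(min_base_qual),
    min_maf = min_maf,
    min_call_rate = min_call_rate,
    panel_call_rate = panel_call_rate,
    network_confidence = network_confidence,
    backcross_index = backcross_index,
    latergen_het = latergen_het,
    f1_het_min = f1_het_min,
    parental_index_min = parental_index_min,
    het_z = het_z,
    het_support_each = isTRUE(het_support_each),
    sexlink_max_mismatch = as.integer(sexlink_max_mismatch),
    collapse_match_ambiguous = isTRUE(collapse_match_ambiguous),
    diagnostic_lenient = isTRUE(diagnostic_lenient),
    rng_seed = as.integer(rng_seed)
  )
  fracs <- c("allele_support_frac", "min_maf", "min_call_rate",
             "panel_call_rate", "network_confidence", "backcross_index",
             "latergen_het", "f1_het_min", "parental_index_min")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("config field '", f, "' must be a single fraction in [0, 1]")
  }
  if (cfg$min_unique_reads < 0L) stop("min_unique_reads must be >= 0")
  if (cfg$het_z < 0) stop("het_z must be >= 0")
  if (cfg$sexlink_max_mismatch < 0L) stop("sexlink_max_mismatch must be >= 0")
  structure(cfg, class = "snowfly_config")
}

#' @export
print.snowfly_config <- function(x, ...) {
  cat("snowfly analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_snowfly_config <- function(x) {
  if (inherits(x, "snowfly_config")) return(x)
  if (is.list(x)) return(do.call(snowfly_config, x))
  stop("cannot interpret object as a snowfly_config")
}
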
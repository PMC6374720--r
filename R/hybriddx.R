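#' Count SNPs shared between a focal taxon and comparison taxa
#'
#' A site is a SNP within a taxon when at least one called specimen of that
#' taxon carries a non-reference allele. The shared count for a comparison
#' taxon is the number of sites that are SNPs in both it and the focal
#' taxon. Potential parental taxa of a hybrid lineage are expected to share
#' the most SNPs with it.
#'
#' @param gm A \code{\link{genotype_matrix}} (already filtered to the
#'   desired call rate).
#' @param part A \code{\link{taxon_partition}}.
#' @param focal_taxon Taxon whose SNPs are the reference set.
#' @param other_taxa Character vector of comparison taxa.
#' @return Named integer vector of shared-SNP counts, one per comparison
#'   taxon, plus an attribute \code{n_focal_snps}.
#' @export
shared_snp_counts <- function(gm, part, focal_taxon, other_taxa) {
  stopifnot(inherits(gm, "genotype_matrix"))
  lookup <- partition_lookup(part)
  taxa <- unique(unname(lookup))
  unknown <- setdiff(c(focal_taxon, other_taxa), taxa)
  if (length(unknown) > 0L)
    stop("unknown taxon/taxa: ", paste(unknown, collapse = ", "))
  taxon_snp <- function(taxon) {
    sp <- intersect(names(lookup)[lookup == taxon], gm$specimens)
    if (length(sp) == 0L) stop("taxon has no genotyped specimens: ", taxon)
    colSums(gm$geno[sp, , drop = FALSE] >= 1L, na.rm = TRUE) > 0L
  }
  focal <- taxon_snp(focal_taxon)
  out <- vapply(other_taxa, function(tx) sum(focal & taxon_snp(tx)),
                integer(1L))
  attr(out, "n_focal_snps") <- sum(focal)
  out
}

#' Principal coordinate analysis of genotypes
#'
#' Classical PCoA of the pairwise genotypic distance between specimens:
#' squared distance = mean over co-called loci of the squared allele-count
#' difference, double-centred and eigendecomposed. Axes are ordered by
#' eigenvalue; each axis's sign is fixed by making its largest-magnitude
#' coordinate positive, so results are orientation-deterministic.
#'
#' @param gm A \code{\link{genotype_matrix}} (typically one SNP per locus
#'   at high call rate, selected upstream).
#' @param specimens Optional subset of specimens to ordinate.
#' @param k Number of axes to return (default 2).
#' @return A list: \code{coordinates} (specimens x k matrix),
#'   \code{eigenvalues} (all), \code{prop_explained}.
#' @export
pcoa_coordinates <- function(gm, specimens = NULL, k = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(specimens)) gm <- subset_gm(gm, specimens = specimens)
  n <- length(gm$specimens)
  if (n < 3L) stop("PCoA needs at least 3 specimens")
  g <- gm$geno
  D2 <- matrix(0, n, n, dimnames = list(gm$specimens, gm$specimens))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(both)) stop("specimens ", gm$specimens[i], " and ",
                           gm$specimens[j], " share no called loci")
      d2 <- mean((g[i, both] - g[j, both])^2)
      D2[i, j] <- D2[j, i] <- d2
    }
  }
  fit <- stats::cmdscale(sqrt(D2), k = min(k, n - 1L), eig = TRUE)
  coords <- fit$points
  for (ax in seq_len(ncol(coords))) {
    peak <- which.max(abs(coords[, ax]))
    if (coords[peak, ax] < 0) coords[, ax] <- -coords[, ax]
  }
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  eig <- fit$eig
  pos <- sum(eig[eig > 0])
  list(coordinates = coords, eigenvalues = eig,
       prop_explained = if (pos > 0) eig[seq_len(ncol(coords))] / pos else
         rep(NA_real_, ncol(coords)))
}

#' Build a fixed-difference diagnostic SNP panel
#'
#' Selects loci at which every called specimen of one parental taxon is
#' homozygous for one allele and every called specimen of the other
#' parental taxon is homozygous for the alternate allele, subject to the
#' panel call-rate requirement across all specimens
#' (\code{cfg$panel_call_rate}, default 100%). The orientation (which
#' allele belongs to parent A) is recorded per locus.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param part A \code{\link{taxon_partition}}.
#' @param parentA,parentB Parental taxon labels.
#' @param cfg A \code{\link{snowfly_config}}.
#' @return An object of class \code{diagnostic_panel}: list with
#'   \code{loci} (data frame: locus_id, allele_A is "ref" or "alt"),
#'   \code{parentA}, \code{parentB}, \code{call_rate_requirement}.
#' @export
build_fixed_panel <- function(gm, part, parentA, parentB,
                              cfg = snowfly_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cfg <- as_snowfly_config(cfg)
  lookup <- partition_lookup(part)
  spA <- intersect(names(lookup)[lookup == parentA], gm$specimens)
  spB <- intersect(names(lookup)[lookup == parentB], gm$specimens)
  if (length(spA) == 0L) stop("empty parental taxon: ", parentA)
  if (length(spB) == 0L) stop("empty parental taxon: ", parentB)
  if (length(spA) < 2L || length(spB) < 2L)
    warning("fewer than 2 specimens in a parental taxon; ",
            "fixation is weakly supported")
  cr <- call_rates(gm)
  gA <- gm$geno[spA, , drop = FALSE]
  gB <- gm$geno[spB, , drop = FALSE]
  fixedA0 <- colSums(gA != 0L, na.rm = TRUE) == 0L & colSums(!is.na(gA)) > 0L
  fixedA2 <- colSums(gA != 2L, na.rm = TRUE) == 0L & colSums(!is.na(gA)) > 0L
  fixedB0 <- colSums(gB != 0L, na.rm = TRUE) == 0L & colSums(!is.na(gB)) > 0L
  fixedB2 <- colSums(gB != 2L, na.rm = TRUE) == 0L & colSums(!is.na(gB)) > 0L
  keep <- cr >= cfg$panel_call_rate & ((fixedA0 & fixedB2) | (fixedA2 & fixedB0))
  loci <- gm$loci[keep]
  allele_A <- ifelse(fixedA2[keep], "alt", "ref")
  structure(list(loci = data.frame(locus_id = loci, allele_A = allele_A,
                                   stringsAsFactors = FALSE),
                 parentA = parentA, parentB = parentB,
                 call_rate_requirement = cfg$panel_call_rate),
            class = "diagnostic_panel")
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  cat("diagnostic_panel:", nrow(x$loci), "loci fixed for alternate alleles in",
      x$parentA, "vs", x$parentB, "\n")
  invisible(x)
}

#' Per-specimen hybrid index and heterozygosity at panel loci
#'
#' The hybrid index is the fraction of the specimen's alleles at called
#' panel loci that derive from parent A; the heterozygous fraction is the
#' proportion of called panel loci at which the specimen is heterozygous.
#' An F1 between the two parents shows index 0.5 and heterozygosity 1 at
#' every autosomal diagnostic locus.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param panel A \code{\link{build_fixed_panel}} result.
#' @param specimen Specimen id.
#' @return A list: \code{specimen_id}, \code{n_loci_called},
#'   \code{index_A}, \code{het_frac}, \code{class} (unset, NA).
#' @export
hybrid_metrics <- function(gm, panel, specimen) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(panel, "diagnostic_panel"))
  if (!specimen %in% gm$specimens) stop("unknown specimen: ", specimen)
  loci <- panel$loci$locus_id
  g <- gm$geno[specimen, loci]
  called <- !is.na(g)
  n <- sum(called)
  if (n == 0L) {
    warning("specimen ", specimen, " has no called panel loci")
    return(list(specimen_id = specimen, n_loci_called = 0L,
                index_A = NA_real_, het_frac = NA_real_,
                class = "unresolved"))
  }
  dosage_A <- ifelse(panel$loci$allele_A == "alt", g, 2L - g)
  index_A <- sum(dosage_A[called]) / (2 * n)
  het_frac <- sum(g[called] == 1L) / n
  list(specimen_id = specimen, n_loci_called = as.integer(n),
       index_A = index_A, het_frac = het_frac, class = NA_character_)
}

#' Classify a specimen from its hybrid metrics
#'
#' Ordered decision ladder: parental when the index is extreme and
#' heterozygosity near zero; F1 when heterozygosity is at least
#' \code{cfg$f1_het_min}; first-generation backcross when the index reaches
#' \code{cfg$backcross_index} toward either parent (the published >= 75%
#' rule); later-generation hybrid when heterozygosity is at most
#' \code{cfg$latergen_het} (the published <= 25% rule) at intermediate
#' index; otherwise unresolved. The ladder is total and ordered, so every
#' specimen receives exactly one class.
#'
#' @param m Metrics from \code{\link{hybrid_metrics}}.
#' @param cfg A \code{\link{snowfly_config}}.
#' @return One of "parental_A", "parental_B", "F1", "backcross_A",
#'   "backcross_B", "later_generation", "unresolved".
#' @export
classify_specimen <- function(m, cfg = snowfly_config()) {
  cfg <- as_snowfly_config(cfg)
  if (is.na(m$index_A) || is.na(m$het_frac) || m$n_loci_called == 0L)
    return("unresolved")
  hi <- m$index_A; het <- m$het_frac
  het_max_parental <- 1 - cfg$parental_index_min
  if (hi >= cfg$parental_index_min && het <= het_max_parental)
    return("parental_A")
  if (hi <= 1 - cfg$parental_index_min && het <= het_max_parental)
    return("parental_B")
  if (het >= cfg$f1_het_min) return("F1")
  if (hi >= cfg$backcross_index) return("backcross_A")
  if (hi <= 1 - cfg$backcross_index) return("backcross_B")
  if (het <= cfg$latergen_het) return("later_generation")
  "unresolved"
}

#' Hybrid metrics and classes for a set of specimens
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param panel A \code{\link{build_fixed_panel}} result.
#' @param specimens Specimen ids (default: all in \code{gm}).
#' @param cfg A \code{\link{snowfly_config}}.
#' @return Data frame: specimen_id, n_loci_called, index_A, het_frac, class.
#' @export
hybrid_report <- function(gm, panel, specimens = NULL,
                          cfg = snowfly_config()) {
  if (is.null(specimens)) specimens <- gm$specimens
  rows <- lapply(specimens, function(sp) {
    m <- suppressWarnings(hybrid_metrics(gm, panel, sp))
    m$class <- if (m$n_loci_called == 0L) "unresolved" else
      classify_specimen(m, cfg)
    as.data.frame(m, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
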
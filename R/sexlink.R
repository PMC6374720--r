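#' Classify panel-candidate loci as autosomal diagnostic, sex-linked or
#' nondiagnostic from hybrid genotypes
#'
#' For loci fixed for alternate alleles between the two parental taxa, the
#' genotypes of the hybrid cohort distinguish three patterns. Autosomal
#' diagnostic: every called hybrid is heterozygous (the F1 signature).
#' Sex-linked under X0 sex determination: every called hybrid male is
#' homozygous for the maternal parent's allele (males carry a single,
#' maternally inherited X, which short-read genotyping codes as homozygous)
#' while every called hybrid female is heterozygous. Anything else is
#' nondiagnostic. Up to \code{cfg$sexlink_max_mismatch} deviating specimens
#' are tolerated per locus (default 0).
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param panel A \code{\link{build_fixed_panel}} result covering the
#'   candidate loci.
#' @param records Metadata data frame (see \code{\link{read_metadata}})
#'   providing each specimen's sex.
#' @param hybrids Specimen ids of the hybrid cohort.
#' @param maternal_parent "A" or "B": which parental taxon is the mother.
#' @param cfg A \code{\link{snowfly_config}}.
#' @return An object of class \code{sex_linkage_report}: data frame with
#'   one row per candidate locus: locus_id, status, n_male_called,
#'   n_male_hom_maternal, n_female_called, n_female_het, n_het_total.
#' @export
detect_sex_linked_loci <- function(gm, panel, records, hybrids,
                                   maternal_parent = c("A", "B"),
                                   cfg = snowfly_config()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(panel, "diagnostic_panel"))
  maternal_parent <- match.arg(maternal_parent)
  cfg <- as_snowfly_config(cfg)
  sex <- stats::setNames(records$sex, records$specimen_id)
  hybrids <- intersect(hybrids, gm$specimens)
  males <- hybrids[!is.na(sex[hybrids]) & sex[hybrids] == "male"]
  females <- hybrids[!is.na(sex[hybrids]) & sex[hybrids] == "female"]
  if (length(males) + length(females) == 0L)
    stop("no sexed hybrid specimens")
  tol <- cfg$sexlink_max_mismatch
  rows <- lapply(seq_len(nrow(panel$loci)), function(i) {
    loc <- panel$loci$locus_id[i]
    # dosage of the maternal parent's allele
    gA <- gm$geno[hybrids, loc]
    dosA <- if (panel$loci$allele_A[i] == "alt") gA else 2L - gA
    dos_maternal <- if (maternal_parent == "A") dosA else 2L - dosA
    names(dos_maternal) <- hybrids
    gm_m <- dos_maternal[males]; gm_f <- dos_maternal[females]
    het_all <- gm$geno[hybrids, loc] == 1L
    n_called <- sum(!is.na(het_all))
    n_het <- sum(het_all, na.rm = TRUE)
    n_m_called <- sum(!is.na(gm_m)); n_f_called <- sum(!is.na(gm_f))
    n_m_hom_mat <- sum(gm_m == 2L, na.rm = TRUE)
    n_f_het <- sum(gm_f == 1L, na.rm = TRUE)
    status <- if (n_called > 0L && (n_called - n_het) <= tol) {
      "autosomal_diagnostic"
    } else if (n_m_called > 0L && n_f_called > 0L &&
               (n_m_called - n_m_hom_mat) <= tol &&
               (n_f_called - n_f_het) <= tol) {
      "sex_linked"
    } else {
      "nondiagnostic"
    }
    data.frame(locus_id = loc, status = status,
               n_male_called = n_m_called,
               n_male_hom_maternal = n_m_hom_mat,
               n_female_called = n_f_called, n_female_het = n_f_het,
               n_het_total = n_het, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("sex_linkage_report",
                                            "data.frame"))
}

#' Infer the maternal parent of a hybrid cohort from mitochondrial
#' haplotype assignments
#'
#' Mitochondria are maternally inherited, so the parental taxon whose
#' mitochondrial cluster contains the hybrids' haplotypes is the maternal
#' parent. Hybrids whose haplotypes split between both parental clusters
#' indicate bidirectional crossing.
#'
#' @param mito_assignments Named character vector: hybrid specimen_id ->
#'   parental taxon whose mitochondrial cluster holds its haplotype (from
#'   the haplotype/network stage). Hybrids with no assignment (NA) are
#'   excluded and reported.
#' @param hybrids Specimen ids of the hybrid cohort.
#' @param parentA,parentB Parental taxon labels.
#' @return A list: \code{maternal} (taxon label, or "bidirectional"),
#'   \code{direction} (human-readable statement), \code{counts} (named
#'   tally per parental taxon), \code{excluded} (hybrids lacking an
#'   assignment).
#' @export
infer_maternal_parent <- function(mito_assignments, hybrids,
                                  parentA, parentB) {
  assigned <- mito_assignments[intersect(hybrids, names(mito_assignments))]
  excluded <- setdiff(hybrids, names(assigned)[!is.na(assigned)])
  assigned <- assigned[!is.na(assigned)]
  if (length(excluded) > 0L)
    message("infer_maternal_parent: excluded ", length(excluded),
            " hybrid(s) with no mitochondrial assignment")
  if (length(assigned) == 0L)
    stop("no hybrid has a mitochondrial assignment")
  bad <- setdiff(unique(assigned), c(parentA, parentB))
  if (length(bad) > 0L)
    stop("mitochondrial assignment(s) outside the parental taxa: ",
         paste(bad, collapse = ", "))
  counts <- c(sum(assigned == parentA), sum(assigned == parentB))
  names(counts) <- c(parentA, parentB)
  if (all(counts > 0L)) {
    maternal <- "bidirectional"
    direction <- paste0("hybrid mitochondria split between ", parentA,
                        " (", counts[[1L]], ") and ", parentB, " (",
                        counts[[2L]], "): bidirectional crossing")
  } else {
    maternal <- names(counts)[counts > 0L]
    paternal <- setdiff(c(parentA, parentB), maternal)
    direction <- paste0("hybrids are progeny of female ", maternal,
                        " and male ", paternal)
  }
  list(maternal = maternal, direction = direction, counts = counts,
       excluded = excluded)
}
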
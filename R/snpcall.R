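#' Call a genotype from per-site allele read counts
#'
#' Implements the read-support retention rule: a homozygote is called when
#' the most common allele is supported by at least
#' \code{cfg$allele_support_frac} of the aligned reads and by at least
#' \code{cfg$min_unique_reads} reads; otherwise a heterozygote is called
#' when the two most common alleles jointly reach the support fraction and
#' the most common allele (each allele, if \code{cfg$het_support_each})
#' reaches the read minimum; otherwise the genotype is missing. Base
#' quality filtering is assumed to have happened upstream of the count
#' table.
#'
#' @param counts Named numeric vector of read counts over A, C, G, T
#'   (missing names count as zero).
#' @param cfg A \code{\link{snowfly_config}}.
#' @return A list: \code{call} ("hom", "het" or "missing") and
#'   \code{alleles} (the one or two supporting alleles, alphabetical for
#'   heterozygotes; NULL when missing).
#' @export
#' @examples
#' call_genotype_at_site(c(A = 10))          # hom A
#' call_genotype_at_site(c(A = 6, C = 5))    # het A/C
#' call_genotype_at_site(c(A = 4, C = 3, G = 3))  # missing
call_genotype_at_site <- function(counts, cfg = snowfly_config()) {
  cfg <- as_snowfly_config(cfg)
  full <- c(A = 0, C = 0, G = 0, T = 0)
  if (length(counts) > 0L) {
    if (is.null(names(counts)) || !all(names(counts) %in% names(full)))
      stop("counts must be named with bases A, C, G, T")
    if (any(counts < 0)) stop("negative read counts")
    full[names(counts)] <- counts
  }
  total <- sum(full)
  if (total == 0) return(list(call = "missing", alleles = NULL))
  ord <- order(-full, names(full))  # ties broken alphabetically
  a1 <- names(full)[ord[1L]]; n1 <- full[[ord[1L]]]
  a2 <- names(full)[ord[2L]]; n2 <- full[[ord[2L]]]
  if (n1 / total >= cfg$allele_support_frac && n1 >= cfg$min_unique_reads)
    return(list(call = "hom", alleles = a1))
  support_ok <- if (cfg$het_support_each)
    n1 >= cfg$min_unique_reads && n2 >= cfg$min_unique_reads
  else n1 >= cfg$min_unique_reads
  if (n2 > 0 && (n1 + n2) / total >= cfg$allele_support_frac && support_ok)
    return(list(call = "het", alleles = sort(c(a1, a2))))
  list(call = "missing", alleles = NULL)
}

#' Call genotypes for a whole site-count table
#'
#' Applies \code{\link{call_genotype_at_site}} to every specimen x site
#' cell and assembles a \code{\link{genotype_matrix}}. When \code{ref} and
#' \code{alt} are not supplied, the reference allele at each site is the
#' most common called allele (alphabetical tie-break) and the alternate is
#' the other observed allele; calls involving a third allele at a site are
#' set to missing.
#'
#' @param counts Data frame with columns \code{specimen_id},
#'   \code{locus_id}, \code{A}, \code{C}, \code{G}, \code{T}.
#' @param cfg A \code{\link{snowfly_config}}.
#' @param ref,alt Optional named character vectors (by locus) fixing the
#'   allele orientation.
#' @return A \code{\link{genotype_matrix}} of alternate-allele dosages.
#' @export
call_genotypes <- function(counts, cfg = snowfly_config(),
                           ref = NULL, alt = NULL) {
  cfg <- as_snowfly_config(cfg)
  needed <- c("specimen_id", "locus_id", "A", "C", "G", "T")
  if (!all(needed %in% names(counts)))
    stop("counts must have columns ", paste(needed, collapse = ", "))
  specimens <- unique(counts$specimen_id)
  loci <- unique(counts$locus_id)
  calls <- vector("list", nrow(counts))
  for (r in seq_len(nrow(counts))) {
    calls[[r]] <- call_genotype_at_site(
      c(A = counts$A[r], C = counts$C[r], G = counts$G[r], T = counts$T[r]),
      cfg)
  }
  geno <- matrix(NA_integer_, length(specimens), length(loci),
                 dimnames = list(specimens, loci))
  ref_out <- alt_out <- stats::setNames(rep(NA_character_, length(loci)), loci)
  for (loc in loci) {
    rows <- which(counts$locus_id == loc)
    loc_calls <- calls[rows]
    allele_counts <- table(unlist(lapply(loc_calls, function(cl) {
      if (cl$call == "hom") rep(cl$alleles, 2L)
      else if (cl$call == "het") cl$alleles
      else NULL
    })))
    if (length(allele_counts) == 0L) next
    ac <- as.integer(allele_counts)
    alleles <- names(allele_counts)[order(-ac, names(allele_counts))]
    if (!is.null(ref)) {
      rf <- unname(ref[loc]); al <- unname(alt[loc])
    } else {
      rf <- alleles[1L]
      al <- if (length(alleles) >= 2L) alleles[2L] else
        setdiff(c("A", "C", "G", "T"), rf)[1L]
    }
    ref_out[loc] <- rf; alt_out[loc] <- al
    for (k in seq_along(rows)) {
      cl <- loc_calls[[k]]
      sp <- counts$specimen_id[rows[k]]
      if (cl$call == "missing") next
      g <- if (cl$call == "hom") {
        if (cl$alleles == rf) 0L else if (cl$alleles == al) 2L else NA_integer_
      } else {
        if (setequal(cl$alleles, c(rf, al))) 1L else NA_integer_
      }
      geno[sp, loc] <- g
    }
  }
  genotype_matrix(geno, ref = ref_out, alt = alt_out)
}

#' Filter sites of a genotype matrix
#'
#' A site is retained when (in order of precedence of the failure codes)
#' its call rate is at least \code{cfg$min_call_rate}, it is polymorphic
#' among called genotypes, its minor allele frequency is at least
#' \code{cfg$min_maf}, and its observed heterozygote fraction does not
#' exceed twice the product of the two allele frequencies by more than
#' \code{cfg$het_z} binomial standard errors. The 2pq bound is a
#' population-level statement; the \code{het_z} slack (default 3 SE)
#' prevents ordinary Hardy-Weinberg sampling noise from triggering it while
#' still rejecting the all-heterozygote signature of collapsed paralogs.
#' Specimens with missing calls are excluded from both numerator and
#' denominator of every per-site statistic.
#'
#' @param gm A \code{\link{genotype_matrix}} (biallelic).
#' @param cfg A \code{\link{snowfly_config}}.
#' @return A list with \code{gm} (the filtered matrix), \code{report} (data
#'   frame: locus_id, call_rate, maf, het_obs, het_bound, status) and
#'   \code{summary} (named status counts). Status is one of retained,
#'   fail_call_rate, monomorphic, fail_maf, fail_het_constraint.
#' @export
filter_sites <- function(gm, cfg = snowfly_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cfg <- as_snowfly_config(cfg)
  g <- gm$geno
  n_called <- colSums(!is.na(g))
  call_rate <- n_called / nrow(g)
  alt_freq <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(alt_freq, 1 - alt_freq)
  het_obs <- colSums(g == 1L, na.rm = TRUE) / pmax(n_called, 1L)
  p <- pmax(alt_freq, 1 - alt_freq); q <- 1 - p
  het_exp <- 2 * p * q
  slack <- cfg$het_z * sqrt(pmax(het_exp * (1 - het_exp), 0) /
                              pmax(n_called, 1L))
  het_bound <- het_exp + slack
  status <- rep("retained", ncol(g))
  status[het_obs > het_bound] <- "fail_het_constraint"
  status[maf < cfg$min_maf] <- "fail_maf"
  status[maf == 0] <- "monomorphic"
  status[call_rate < cfg$min_call_rate] <- "fail_call_rate"
  report <- data.frame(locus_id = gm$loci,
                       call_rate = call_rate, maf = maf,
                       het_obs = het_obs, het_bound = het_bound,
                       status = status, stringsAsFactors = FALSE,
                       row.names = NULL)
  keep <- gm$loci[status == "retained"]
  out_gm <- subset_gm(gm, loci = keep)
  list(gm = out_gm, report = report,
       summary = table(factor(report$status,
                              levels = c("retained", "fail_maf",
                                         "fail_het_constraint",
                                         "fail_call_rate", "monomorphic"))))
}
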
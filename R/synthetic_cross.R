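#' Design of a synthetic interspecific cross
#'
#' Parameterizes the two-parental-taxon cross the simulator generates. The
#' defaults mirror the motivating study design: 36 and 20 parental
#' specimens, a 14-individual F1 cohort, 60 autosomal and 51 X-linked
#' diagnostic loci, 34 nondiagnostic loci, no genotyping error or
#' missingness, and the A taxon as the maternal parent. Nondiagnostic
#' allele frequencies are drawn independently per taxon from
#' Uniform(0.2, 0.8): moderate-frequency shared standing variation, so that
#' finite parental samples are vanishingly unlikely to be accidentally
#' fixed for opposite alleles.
#'
#' @param n_parentA,n_parentB,n_F1,n_BC1A,n_BC1B,n_F2 Cohort sizes (>= 0).
#' @param n_auto_diag,n_xlinked_diag,n_nondiag Locus counts by kind.
#' @param nondiag_freq_range Range from which per-taxon alternate-allele
#'   frequencies of nondiagnostic loci are drawn.
#' @param error_rate,missing_rate Post-hoc genotyping noise rates in
#'   [0, 0.5] (applied by \code{\link{add_genotyping_noise}}).
#' @param maternal_taxon "A" or "B": maternal parent of the F1s (and, via
#'   an F1 mother, of the backcross and F2 cohorts).
#' @param n_F1_female Number of F1 females (rest are male); default half,
#'   rounded down. Other cohorts alternate sexes 1:1.
#' @param taxonA,taxonB,hybrid_label Taxon labels used in the metadata.
#' @param seed Integer RNG seed.
#' @return An object of class \code{cross_design}.
#' @export
cross_design <- function(n_parentA = 36L, n_parentB = 20L, n_F1 = 14L,
                         n_BC1A = 0L, n_BC1B = 0L, n_F2 = 0L,
                         n_auto_diag = 60L, n_xlinked_diag = 51L,
                         n_nondiag = 34L,
                         nondiag_freq_range = c(0.2, 0.8),
                         error_rate = 0, missing_rate = 0,
                         maternal_taxon = c("A", "B"),
                         n_F1_female = NULL,
                         taxonA = "taxonA", taxonB = "taxonB",
                         hybrid_label = "hybrid",
                         seed = 1L) {
  maternal_taxon <- match.arg(maternal_taxon)
  counts <- c(n_parentA = n_parentA, n_parentB = n_parentB, n_F1 = n_F1,
              n_BC1A = n_BC1A, n_BC1B = n_BC1B, n_F2 = n_F2,
              n_auto_diag = n_auto_diag, n_xlinked_diag = n_xlinked_diag,
              n_nondiag = n_nondiag)
  if (any(counts < 0)) stop("all design counts must be >= 0")
  if (error_rate < 0 || error_rate > 0.5 || missing_rate < 0 ||
      missing_rate > 0.5)
    stop("error_rate and missing_rate must lie in [0, 0.5]")
  if (is.null(n_F1_female)) n_F1_female <- n_F1 %/% 2L
  if (n_F1_female > n_F1) stop("n_F1_female exceeds n_F1")
  structure(list(n_parentA = as.integer(n_parentA),
                 n_parentB = as.integer(n_parentB),
                 n_F1 = as.integer(n_F1), n_BC1A = as.integer(n_BC1A),
                 n_BC1B = as.integer(n_BC1B), n_F2 = as.integer(n_F2),
                 n_auto_diag = as.integer(n_auto_diag),
                 n_xlinked_diag = as.integer(n_xlinked_diag),
                 n_nondiag = as.integer(n_nondiag),
                 nondiag_freq_range = nondiag_freq_range,
                 error_rate = error_rate, missing_rate = missing_rate,
                 maternal_taxon = maternal_taxon,
                 n_F1_female = as.integer(n_F1_female),
                 taxonA = taxonA, taxonB = taxonB,
                 hybrid_label = hybrid_label,
                 seed = as.integer(seed)),
            class = "cross_design")
}

#' Simulate a genotype dataset from an interspecific cross
#'
#' Generates parental, F1, first-generation backcross (BC1) and F2 cohorts
#' under Mendelian inheritance with X0 sex chromosomes and maternally
#' inherited mitochondria. Diagnostic loci are fixed for alternate alleles
#' in the two parental taxa (allele orientation randomized and recorded);
#' nondiagnostic loci segregate at taxon-specific frequencies, with
#' offspring gametes drawn at population-level allele frequencies (loci are
#' independent; no linkage). X0 rules: females carry two X copies, one from
#' each parent; males carry a single, maternally inherited X that the
#' genotype matrix codes as homozygous. Backcross and F2 cohorts take
#' their mother from the F1 generation, so all hybrid-derived cohorts
#' carry the mitochondrial haplotype of the designated maternal taxon.
#'
#' @param design A \code{\link{cross_design}}.
#' @return A list: \code{gm} (\code{\link{genotype_matrix}}),
#'   \code{metadata} (specimen table with phenotypic labels: parentals get
#'   their taxon label, all hybrid cohorts the hybrid label),
#'   \code{mito} (named vector specimen_id -> taxon of its mitochondrial
#'   haplotype), \code{truth} (data frame: specimen_id, class, sex,
#'   maternal_lineage), \code{loci} (data frame: locus_id, kind, allele_A,
#'   pA_alt, pB_alt), \code{design}.
#' @export
simulate_cross_dataset <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  d <- design
  set.seed(d$seed)
  bases <- c("A", "C", "G", "T")
  loci <- c(if (d$n_auto_diag > 0L) paste0("AD", seq_len(d$n_auto_diag)),
            if (d$n_xlinked_diag > 0L) paste0("XD", seq_len(d$n_xlinked_diag)),
            if (d$n_nondiag > 0L) paste0("ND", seq_len(d$n_nondiag)))
  kind <- c(rep("auto_diag", d$n_auto_diag),
            rep("x_diag", d$n_xlinked_diag),
            rep("nondiag", d$n_nondiag))
  n_loci <- length(loci)
  if (n_loci == 0L) stop("design has no loci")
  ref <- character(n_loci); alt <- character(n_loci)
  for (i in seq_len(n_loci)) {
    ra <- sample(bases, 2L)
    ref[i] <- ra[1L]; alt[i] <- ra[2L]
  }
  # orientation: is the parent-A allele the alternate allele?
  A_is_alt <- sample(c(TRUE, FALSE), n_loci, replace = TRUE)
  lo <- d$nondiag_freq_range[1L]; hi <- d$nondiag_freq_range[2L]
  pA_alt <- ifelse(kind == "nondiag", stats::runif(n_loci, lo, hi),
                   ifelse(A_is_alt, 1, 0))
  pB_alt <- ifelse(kind == "nondiag", stats::runif(n_loci, lo, hi),
                   ifelse(A_is_alt, 0, 1))

  classes <- c(rep("parental_A", d$n_parentA),
               rep("parental_B", d$n_parentB),
               rep("F1", d$n_F1),
               rep("BC1A", d$n_BC1A), rep("BC1B", d$n_BC1B),
               rep("F2", d$n_F2))
  ids <- c(sprintf("A%03d", seq_len(d$n_parentA)),
           sprintf("B%03d", seq_len(d$n_parentB)),
           sprintf("F1_%03d", seq_len(d$n_F1)),
           sprintf("BC1A_%03d", seq_len(d$n_BC1A)),
           sprintf("BC1B_%03d", seq_len(d$n_BC1B)),
           sprintf("F2_%03d", seq_len(d$n_F2)))
  alternate <- function(n) rep_len(c("male", "female"), n)
  sex <- c(alternate(d$n_parentA), alternate(d$n_parentB),
           c(rep("male", d$n_F1 - d$n_F1_female),
             rep("female", d$n_F1_female)),
           alternate(d$n_BC1A), alternate(d$n_BC1B), alternate(d$n_F2))
  n_spec <- length(ids)
  if (n_spec == 0L) stop("design has no specimens")

  M_is_A <- d$maternal_taxon == "A"
  geno <- matrix(NA_integer_, n_spec, n_loci, dimnames = list(ids, loci))
  for (cl in unique(classes)) {
    rows <- which(classes == cl)
    n <- length(rows)
    male <- sex[rows] == "male"
    for (kd in unique(kind)) {
      cols <- which(kind == kd)
      k <- length(cols)
      dosA <- matrix(NA_real_, n, k)
      if (kd == "auto_diag") {
        dosA[] <- switch(cl,
          parental_A = 2,
          parental_B = 0,
          F1 = 1,
          BC1A = 1 + stats::rbinom(n * k, 1L, 0.5),
          BC1B = stats::rbinom(n * k, 1L, 0.5),
          F2 = stats::rbinom(n * k, 2L, 0.5))
      } else if (kd == "x_diag") {
        # single maternally inherited X in males, coded homozygous
        half <- function(nn) stats::rbinom(nn, 1L, 0.5)
        for (r in seq_len(n)) {
          if (cl == "parental_A") dosA[r, ] <- 2
          else if (cl == "parental_B") dosA[r, ] <- 0
          else if (cl == "F1")
            dosA[r, ] <- if (male[r]) (if (M_is_A) 2 else 0) else 1
          else if (cl == "BC1A")
            dosA[r, ] <- if (male[r]) 2 * half(k) else 1 + half(k)
          else if (cl == "BC1B")
            dosA[r, ] <- if (male[r]) 2 * half(k) else half(k)
          else if (cl == "F2")
            dosA[r, ] <- if (male[r]) 2 * half(k) else
              (if (M_is_A) 1 else 0) + half(k)
        }
      } else {  # nondiag: simulate alternate-allele dosage directly
        pA <- pA_alt[cols]; pB <- pB_alt[cols]
        pMix <- (pA + pB) / 2
        draw <- function(p) stats::rbinom(n * k, 1L, rep(p, each = n))
        alt_dos <- switch(cl,
          parental_A = draw(pA) + draw(pA),
          parental_B = draw(pB) + draw(pB),
          F1 = draw(pA) + draw(pB),
          BC1A = draw(pA) + draw(pMix),
          BC1B = draw(pB) + draw(pMix),
          F2 = draw(pMix) + draw(pMix))
        geno[rows, cols] <- as.integer(alt_dos)
        next
      }
      # convert parent-A allele dosage to alternate-allele dosage
      conv <- matrix(rep(A_is_alt[cols], each = n), n, k)
      geno[rows, cols] <- as.integer(ifelse(conv, dosA, 2 - dosA))
    }
  }

  gm <- genotype_matrix(geno, ref = ref, alt = alt)
  if (d$error_rate > 0 || d$missing_rate > 0)
    gm <- add_genotyping_noise(gm, d$error_rate, d$missing_rate,
                               seed = d$seed + 1L)

  taxon_label <- ifelse(classes == "parental_A", d$taxonA,
                        ifelse(classes == "parental_B", d$taxonB,
                               d$hybrid_label))
  metadata <- data.frame(specimen_id = ids, taxon_label = taxon_label,
                         sex = sex, locality = "syntopic_site",
                         notes = classes, stringsAsFactors = FALSE)
  maternal <- ifelse(classes == "parental_A", d$taxonA,
                     ifelse(classes == "parental_B", d$taxonB,
                            if (M_is_A) d$taxonA else d$taxonB))
  mito <- stats::setNames(maternal, ids)
  list(gm = gm, metadata = metadata, mito = mito,
       truth = data.frame(specimen_id = ids, class = classes, sex = sex,
                          maternal_lineage = maternal,
                          stringsAsFactors = FALSE),
       loci = data.frame(locus_id = loci, kind = kind,
                         allele_A = ifelse(A_is_alt, "alt", "ref"),
                         pA_alt = pA_alt, pB_alt = pB_alt,
                         stringsAsFactors = FALSE),
       design = d)
}

#' Add genotyping noise to a genotype matrix
#'
#' Each called genotype is independently perturbed to an adjacent dosage
#' (heterozygotes move to either homozygote with equal probability) with
#' probability \code{error_rate}, then set missing with probability
#' \code{missing_rate}. Seed-reproducible.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param error_rate,missing_rate Rates in [0, 1].
#' @param seed Integer RNG seed.
#' @return A perturbed \code{\link{genotype_matrix}}.
#' @export
add_genotyping_noise <- function(gm, error_rate, missing_rate, seed = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stopifnot(error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  g <- gm$geno
  called <- which(!is.na(g))
  if (error_rate > 0 && length(called) > 0L) {
    flip <- called[stats::runif(length(called)) < error_rate]
    for (i in flip) {
      g[i] <- switch(as.character(g[i]),
                     "0" = 1L, "2" = 1L,
                     "1" = sample(c(0L, 2L), 1L))
    }
  }
  if (missing_rate > 0 && length(called) > 0L) {
    drop <- called[stats::runif(length(called)) < missing_rate]
    g[drop] <- NA_integer_
  }
  genotype_matrix(g, ref = gm$ref, alt = gm$alt)
}

#' Simulate per-site read counts from true genotypes
#'
#' For each called specimen x locus cell, draws a Poisson read depth and
#' allocates reads to the genotype's alleles (an even split in expectation
#' for heterozygotes), then applies a per-read error to a uniformly chosen
#' other base. The result is the count-table contract consumed by
#' \code{\link{call_genotypes}}.
#'
#' @param gm_true A \code{\link{genotype_matrix}} of true genotypes.
#' @param depth_mean Mean sequencing depth (> 0).
#' @param error_rate Per-read error probability.
#' @param seed Integer RNG seed.
#' @return Data frame: specimen_id, locus_id, A, C, G, T.
#' @export
simulate_site_counts <- function(gm_true, depth_mean, error_rate = 0,
                                 seed = 1L) {
  stopifnot(inherits(gm_true, "genotype_matrix"), depth_mean > 0)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  g <- gm_true$geno
  cells <- which(!is.na(g), arr.ind = TRUE)
  n <- nrow(cells)
  counts <- matrix(0L, n, 4L, dimnames = list(NULL, bases))
  depth <- stats::rpois(n, depth_mean)
  for (r in seq_len(n)) {
    if (depth[r] == 0L) next
    loc <- colnames(g)[cells[r, 2L]]
    rf <- gm_true$ref[[loc]]; al <- gm_true$alt[[loc]]
    dose <- g[cells[r, 1L], cells[r, 2L]]
    n_alt <- if (dose == 0L) 0L else if (dose == 2L) depth[r] else
      stats::rbinom(1L, depth[r], 0.5)
    reads <- c(stats::setNames(depth[r] - n_alt, rf))
    reads[al] <- (if (al %in% names(reads)) reads[al] else 0L) + n_alt
    tally <- stats::setNames(rep(0L, 4L), bases)
    tally[names(reads)] <- reads
    if (error_rate > 0) {
      for (b in bases) {
        if (tally[b] == 0L) next
        n_err <- stats::rbinom(1L, tally[b], error_rate)
        if (n_err > 0L) {
          tally[b] <- tally[b] - n_err
          dest <- sample(setdiff(bases, b), n_err, replace = TRUE)
          for (dd in dest) tally[dd] <- tally[dd] + 1L
        }
      }
    }
    counts[r, ] <- tally[bases]
  }
  data.frame(specimen_id = rownames(g)[cells[, 1L]],
             locus_id = colnames(g)[cells[, 2L]],
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], stringsAsFactors = FALSE)
}
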
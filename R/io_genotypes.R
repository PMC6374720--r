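#' Construct a genotype matrix
#'
#' Genotypes are coded as alternate-allele dosage: 0, 1 or 2 copies of the
#' designated alternate allele, with NA for missing calls. Hemizygous
#' (single-X male) genotypes arrive coded as homozygous (0 or 2) because
#' short-read genotyping cannot distinguish hemizygosity from homozygosity.
#'
#' @param geno Integer matrix, specimens in rows, loci in columns, entries
#'   in \{0, 1, 2, NA\}. Row and column names are required.
#' @param ref,alt Character vectors of reference/alternate alleles, one per
#'   locus (defaults "A"/"T" placeholders when alleles are not tracked).
#' @return An object of class \code{genotype_matrix} with fields
#'   \code{geno}, \code{specimens}, \code{loci}, \code{ref}, \code{alt}.
#' @export
genotype_matrix <- function(geno, ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) ||
      (ncol(geno) > 0L && is.null(colnames(geno))))
    stop("geno must have specimen rownames and locus colnames")
  if (is.null(colnames(geno)))
    dimnames(geno) <- list(rownames(geno), character(0))
  storage.mode(geno) <- "integer"
  vals <- geno[!is.na(geno)]
  if (length(vals) > 0L && !all(vals %in% 0:2))
    stop("genotype entries must be 0, 1, 2 or NA")
  nl <- ncol(geno)
  if (is.null(ref)) ref <- rep("A", nl)
  if (is.null(alt)) alt <- rep("T", nl)
  if (length(ref) != nl || length(alt) != nl)
    stop("ref/alt must have one allele per locus")
  structure(list(geno = geno,
                 specimens = rownames(geno),
                 loci = colnames(geno),
                 ref = stats::setNames(as.character(ref), colnames(geno)),
                 alt = stats::setNames(as.character(alt), colnames(geno))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$specimens), "specimens x",
      length(x$loci), "loci;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Read a genotype matrix
#'
#' Two formats are supported. \code{"TSV"}: loci in rows with columns
#' \code{locus_id}, \code{ref}, \code{alt} followed by one column per
#' specimen holding 0/1/2/NA. \code{"VCF"}: a VCF v4.x file restricted to
#' biallelic SNP records; multiallelic records are skipped and their count
#' reported in the \code{skipped_multiallelic} attribute. Dosage equals the
#' number of non-reference alleles in the GT field; haploid GT values are
#' coded homozygous (0 or 2).
#'
#' @param path Path to the file.
#' @param format "TSV" or "VCF".
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("TSV", "VCF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "TSV") read_genotypes_tsv(path) else read_genotypes_vcf(path)
}

read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = NULL, check.names = FALSE)
  required <- c("locus_id", "ref", "alt")
  if (!all(required %in% names(df)))
    stop("genotype TSV must have columns locus_id, ref, alt, then specimens")
  spec_cols <- setdiff(names(df), required)
  if (length(spec_cols) == 0L) stop("genotype TSV has no specimen columns")
  g <- as.matrix(df[, spec_cols, drop = FALSE])
  bad <- which(!(g %in% c("0", "1", "2", "NA", "")))
  if (length(bad) > 0L) {
    idx <- arrayInd(bad[1L], dim(g))
    stop("malformed genotype value '", g[bad[1L]],
         "' at line ", idx[1L, 1L] + 1L, " of ", path)
  }
  g[g %in% c("NA", "")] <- NA
  storage.mode(g) <- "integer"
  geno <- t(g)
  colnames(geno) <- df$locus_id
  rownames(geno) <- spec_cols
  genotype_matrix(geno, ref = df$ref, alt = df$alt)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("VCF contains no variant records: ", path)
  bi <- vcfR::is.biallelic(vcf)
  snp <- nchar(vcf@fix[, "REF"]) == 1L &
    !grepl(",", vcf@fix[, "ALT"]) & nchar(vcf@fix[, "ALT"]) == 1L
  keep <- bi & snp
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("read_genotypes: skipped ", n_skipped,
            " multiallelic/non-SNP VCF record(s)")
  if (!any(keep)) stop("no biallelic SNP records in VCF: ", path)
  vcf <- vcf[keep, ]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  loci <- paste(vcf@fix[, "CHROM"], vcf@fix[, "POS"], sep = ":")
  ids <- unname(vcf@fix[, "ID"])
  loci <- unname(ifelse(is.na(ids) | ids == ".", loci, ids))
  rownames(gt) <- loci
  geno <- t(matrix(vapply(gt, gt_dosage, integer(1L)), nrow = nrow(gt),
                   dimnames = dimnames(gt)))
  gm <- genotype_matrix(geno, ref = vcf@fix[, "REF"], alt = vcf@fix[, "ALT"])
  attr(gm, "skipped_multiallelic") <- n_skipped
  gm
}

# Alternate-allele dosage from a GT string; handles phased/unphased diploid
# spellings and haploid calls (coded homozygous).
gt_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_integer_)
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (any(alleles == ".")) return(NA_integer_)
  if (!all(alleles %in% c("0", "1")))
    stop("unsupported GT allele in '", gt, "' (biallelic records only)")
  d <- sum(alleles == "1")
  if (length(alleles) == 1L) d <- 2L * d
  as.integer(d)
}

#' Write a genotype matrix to TSV
#'
#' Uses the loci-in-rows layout that \code{\link{read_genotypes}} reads.
#'
#' @param gm A \code{\link{genotype_matrix}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(locus_id = gm$loci, ref = unname(gm$ref),
                   alt = unname(gm$alt),
                   t(gm$geno), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-locus call rate (fraction of specimens with a non-missing genotype).
call_rates <- function(gm) colMeans(!is.na(gm$geno))

# Subset a genotype matrix by specimens and/or loci.
subset_gm <- function(gm, specimens = NULL, loci = NULL) {
  g <- gm$geno
  if (!is.null(specimens)) {
    missing <- setdiff(specimens, rownames(g))
    if (length(missing) > 0L)
      stop("unknown specimen(s): ", paste(missing, collapse = ", "))
    g <- g[specimens, , drop = FALSE]
  }
  if (!is.null(loci)) {
    missing <- setdiff(loci, colnames(g))
    if (length(missing) > 0L)
      stop("unknown locus/loci: ", paste(missing, collapse = ", "))
    g <- g[, loci, drop = FALSE]
  }
  genotype_matrix(g, ref = gm$ref[colnames(g)], alt = gm$alt[colnames(g)])
}
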
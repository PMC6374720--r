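#' Collapse aligned sequences into unique haplotypes
#'
#' Two specimens share a haplotype when their aligned sequences are
#' identical (the default, strict rule). With
#' \code{cfg$collapse_match_ambiguous = TRUE}, sequences are merged when they
#' agree at every column where both carry an unambiguous, ungapped base;
#' merging is greedy in first-occurrence order because compatibility under
#' ambiguity is not transitive. Haplotypes are numbered H1, H2, ... by first
#' occurrence, so the numbering is deterministic.
#'
#' @param aln An \code{\link{aligned_seq_set}}.
#' @param cfg A \code{\link{snowfly_config}}.
#' @return An object of class \code{haplotype_table}: list with
#'   \code{haplotypes} (data frame: haplotype_id, sequence, n_specimens),
#'   \code{membership} (named vector specimen_id -> haplotype_id),
#'   \code{gene} and \code{length}.
#' @export
collapse_haplotypes <- function(aln, cfg = snowfly_config()) {
  stopifnot(inherits(aln, "aligned_seq_set"))
  cfg <- as_snowfly_config(cfg)
  ids <- names(aln$sequences)
  seqs <- unname(aln$sequences)
  if (!cfg$collapse_match_ambiguous) {
    hap_seq <- unique(seqs)
    membership <- paste0("H", match(seqs, hap_seq))
  } else {
    hap_seq <- character()
    membership <- character(length(seqs))
    for (i in seq_along(seqs)) {
      hit <- NA_integer_
      for (j in seq_along(hap_seq)) {
        if (compatible_seqs(seqs[[i]], hap_seq[[j]])) { hit <- j; break }
      }
      if (is.na(hit)) {
        hap_seq <- c(hap_seq, seqs[[i]])
        hit <- length(hap_seq)
      }
      membership[i] <- paste0("H", hit)
    }
  }
  names(membership) <- ids
  tab <- table(factor(membership, levels = paste0("H", seq_along(hap_seq))))
  structure(list(
    haplotypes = data.frame(haplotype_id = paste0("H", seq_along(hap_seq)),
                            sequence = hap_seq,
                            n_specimens = as.integer(tab),
                            stringsAsFactors = FALSE),
    membership = membership,
    gene = aln$gene,
    length = aln$length), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$membership), "sequences collapsed to",
      nrow(x$haplotypes), "haplotypes (", x$gene, ")\n")
  invisible(x)
}

# TRUE when two equal-length sequences agree at every column where both are
# unambiguous bases.
compatible_seqs <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  both <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  all(ca[both] == cb[both])
}

#' Uncorrected p-distance between two aligned sequences
#'
#' The proportion of compared columns at which the sequences differ, with no
#' substitution-model correction. Columns with a gap or IUPAC ambiguity code
#' in either sequence are excluded (pairwise deletion). Returns NA when no
#' column is comparable.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @return A fraction in [0, 1], or NA.
#' @export
#' @examples
#' p_distance("AAAA", "AAAT")  # 0.25
#' p_distance("AA-A", "AATT")  # 1/3: the gapped column is excluded
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  ca <- strsplit(toupper(a), "")[[1L]]
  cb <- strsplit(toupper(b), "")[[1L]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  sum(ca[ok] != cb[ok]) / n
}

#' Within- and between-group mean p-distances among haplotypes
#'
#' Distances are computed among unique haplotypes, each haplotype counted
#' once per group regardless of how many specimens carry it. A haplotype
#' shared between two groups contributes a zero-distance cross-group pair.
#' The within-group entry is the mean over all unordered haplotype pairs in
#' the group and is NA for single-haplotype groups (report writers may print
#' such cells as 0.00).
#'
#' @param hap A \code{\link{haplotype_table}}.
#' @param part A \code{\link{taxon_partition}} covering the specimens in
#'   \code{hap} (specimens absent from the partition are ignored).
#' @param percent Report distances in percent (default TRUE).
#' @param digits Decimal places for rounding (half-even); default 2. Use
#'   NULL to skip rounding.
#' @return A symmetric matrix of mean pairwise distances with the
#'   within-group means on the diagonal, of class \code{distance_table}.
#' @export
group_distance_table <- function(hap, part, percent = TRUE, digits = 2) {
  stopifnot(inherits(hap, "haplotype_table"))
  lookup <- partition_lookup(part)
  specs <- intersect(names(hap$membership), names(lookup))
  if (length(specs) == 0L) stop("partition covers no specimen in the haplotype table")
  groups <- unique(unname(lookup[specs]))
  hap_sets <- lapply(groups, function(g) {
    unique(unname(hap$membership[specs[lookup[specs] == g]]))
  })
  names(hap_sets) <- groups
  empty <- groups[lengths(hap_sets) == 0L]
  if (length(empty) > 0L)
    stop("group(s) with zero haplotypes: ", paste(empty, collapse = ", "))
  seqs <- stats::setNames(hap$haplotypes$sequence, hap$haplotypes$haplotype_id)
  # pairwise distances among the haplotypes involved
  involved <- unique(unlist(hap_sets))
  D <- matrix(0, length(involved), length(involved),
              dimnames = list(involved, involved))
  if (length(involved) > 1L) {
    for (i in seq_len(length(involved) - 1L)) {
      for (j in seq(i + 1L, length(involved))) {
        d <- p_distance(seqs[[involved[i]]], seqs[[involved[j]]])
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  k <- length(groups)
  out <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) {
    hi <- hap_sets[[i]]
    if (length(hi) >= 2L) {
      sub <- D[hi, hi, drop = FALSE]
      out[i, i] <- mean(sub[upper.tri(sub)])
    }
    if (i < k) {
      for (j in seq(i + 1L, k)) {
        hj <- hap_sets[[j]]
        out[i, j] <- out[j, i] <- mean(D[hi, hj, drop = FALSE])
      }
    }
  }
  if (percent) out <- out * 100
  if (!is.null(digits)) out <- round(out, digits)
  structure(out, class = c("distance_table", class(out)),
            percent = percent, gene = hap$gene)
}

#' Write a distance table as TSV
#'
#' Mirrors the conventional barcoding layout: groups stacked, within-group
#' means on the diagonal. NA diagonal cells (single-haplotype groups) are
#' printed as 0.00 with an explanatory footnote.
#'
#' @param dt A \code{distance_table} (or a list of them, stacked with a gene
#'   column).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_table <- function(dt, path) {
  tables <- if (is.list(dt) && !inherits(dt, "distance_table")) dt else list(dt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", "group", colnames(tables[[1L]])), collapse = "\t"),
             con)
  for (tb in tables) {
    gene <- attr(tb, "gene")
    for (i in seq_len(nrow(tb))) {
      vals <- sprintf("%.2f", tb[i, ])
      vals[is.na(tb[i, ])] <- "0.00"
      vals[seq_len(ncol(tb)) > i] <- ""
      writeLines(paste(c(gene, rownames(tb)[i], vals), collapse = "\t"), con)
    }
  }
  writeLines("# single-haplotype groups have no within-group distance; printed as 0.00",
             con)
  invisible(path)
}

#' Find pure diagnostic nucleotide characters for a group
#'
#' Scans every alignment column for a nucleotide state carried by all
#' haplotypes of the focal group and by no haplotype outside it. With the
#' default strict rule, columns where any focal haplotype is gapped or
#' ambiguous are skipped and non-focal states are compared literally; with
#' \code{cfg$diagnostic_lenient = TRUE}, ambiguity codes are resolved
#' against their IUPAC expansions (the candidate state must be impossible
#' in every non-focal haplotype).
#'
#' @param aln An \code{\link{aligned_seq_set}}.
#' @param part A \code{\link{taxon_partition}}.
#' @param focal_group Taxon label whose diagnostic characters are sought.
#' @param cfg A \code{\link{snowfly_config}}.
#' @return Data frame with columns \code{position} (1-based alignment
#'   column), \code{state} and \code{focal_group}; zero rows when no
#'   diagnostic character exists.
#' @export
find_diagnostic_characters <- function(aln, part, focal_group,
                                       cfg = snowfly_config()) {
  stopifnot(inherits(aln, "aligned_seq_set"))
  cfg <- as_snowfly_config(cfg)
  hap <- collapse_haplotypes(aln, cfg)
  lookup <- partition_lookup(part)
  specs <- intersect(names(hap$membership), names(lookup))
  focal_specs <- specs[lookup[specs] == focal_group]
  if (length(focal_specs) == 0L) stop("focal group is empty: ", focal_group)
  focal_haps <- unique(unname(hap$membership[focal_specs]))
  # haplotypes shared between focal and non-focal specimens stay in the
  # comparison set: a state carried outside the focal group is never
  # diagnostic, even on a shared haplotype
  other_specs <- setdiff(specs, focal_specs)
  other_haps <- unique(unname(hap$membership[other_specs]))
  seqs <- stats::setNames(hap$haplotypes$sequence, hap$haplotypes$haplotype_id)
  fm <- do.call(rbind, strsplit(unname(seqs[focal_haps]), ""))
  om <- if (length(other_haps) > 0L)
    do.call(rbind, strsplit(unname(seqs[other_haps]), "")) else NULL
  hits <- list()
  for (col in seq_len(aln$length)) {
    f <- fm[, col]
    if (!cfg$diagnostic_lenient) {
      if (!all(f %in% c("A", "C", "G", "T"))) next
      if (length(unique(f)) != 1L) next
      s <- f[[1L]]
      if (!is.null(om) && any(om[, col] == s)) next
    } else {
      sets <- IUPAC_SETS[f]
      if (any(vapply(sets, is.null, logical(1L)))) next  # gapped focal
      shared <- Reduce(intersect, sets)
      if (length(shared) == 0L) next
      s <- NULL
      for (cand in shared) {
        o <- if (is.null(om)) character() else om[, col]
        possible <- vapply(o, function(ch) {
          st <- IUPAC_SETS[[ch]]
          !is.null(st) && cand %in% st
        }, logical(1L))
        if (!any(possible)) { s <- cand; break }
      }
      if (is.null(s)) next
      # lenient mode accepts a state only when it is fixed (not merely
      # compatible) in haplotypes with unambiguous bases
      unamb <- f %in% c("A", "C", "G", "T")
      if (any(unamb) && !all(f[unamb] == s)) next
    }
    hits[[length(hits) + 1L]] <- data.frame(position = col, state = s,
                                            focal_group = focal_group,
                                            stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(position = integer(), state = character(),
                      focal_group = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}
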
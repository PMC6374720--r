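#' @importFrom Biostrings readBStringSet
NULL

# Alphabet permitted in alignments: the four bases, IUPAC ambiguity codes,
# and the gap character.
ALN_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N", "-")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Construct an aligned sequence set
#'
#' @param sequences Named character vector of equal-length aligned sequences
#'   (names are specimen ids). Case-insensitive; U is mapped to T.
#' @param gene Gene label, one of "COI", "cytb", "ITS1", "other".
#' @return An object of class \code{aligned_seq_set} with fields
#'   \code{gene}, \code{sequences} and \code{length}.
#' @export
aligned_seq_set <- function(sequences, gene = c("other", "COI", "cytb", "ITS1")) {
  gene <- match.arg(gene)
  if (length(sequences) == 0L) stop("alignment is empty")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("every sequence must be named by its specimen_id")
  if (anyDuplicated(names(sequences)))
    stop("duplicate specimen_id in alignment: ",
         names(sequences)[anyDuplicated(names(sequences))])
  seqs <- chartr("u", "U", toupper(sequences))
  seqs <- chartr("U", "T", seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(seqs[bad]), " but '", names(seqs)[1L], "' has length ", lens[1L])
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  bad <- setdiff(chars, ALN_ALPHABET)
  if (length(bad) > 0L)
    stop("alignment contains characters outside the nucleotide/IUPAC/gap ",
         "alphabet: ", paste(bad, collapse = " "))
  structure(list(gene = gene, sequences = seqs, length = lens[[1L]]),
            class = "aligned_seq_set")
}

#' @export
print.aligned_seq_set <- function(x, ...) {
  cat("aligned_seq_set:", length(x$sequences), "sequences x", x$length,
      "columns (", x$gene, ")\n")
  invisible(x)
}

#' Read an aligned multi-FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the
#' specimen id. Sequences are upper-cased, U is mapped to T, and all
#' records must have equal length.
#'
#' @param path Path to a FASTA file.
#' @param gene Gene label for the alignment.
#' @return An \code{\link{aligned_seq_set}}.
#' @export
read_fasta <- function(path, gene = "other") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1L), 1L)
  aligned_seq_set(seqs, gene = gene)
}

#' Write an alignment to FASTA
#'
#' @param aln An \code{\link{aligned_seq_set}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "aligned_seq_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(aln$sequences))
    writeLines(c(paste0(">", id), aln$sequences[[id]]), con)
  invisible(path)
}

# Alignment as a character matrix (specimens x columns).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$sequences), ""))
  rownames(m) <- names(aln$sequences)
  m
}
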
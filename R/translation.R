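#' Translation sanity check for coding mitochondrial alignments
#'
#' Translates each sequence in the given reading frame and flags internal
#' stop codons and ambiguous amino acids (codons containing gaps, N, or
#' other ambiguity codes). A clean protein-coding mitochondrial alignment
#' should show neither; stop codons or heavy ambiguity suggest pseudogenes
#' (numts) or alignment problems.
#'
#' @param aln An \code{\link{aligned_seq_set}}.
#' @param genetic_code Genetic code identifier accepted by
#'   \code{Biostrings::getGeneticCode}; default "5", the invertebrate
#'   mitochondrial code.
#' @param frame Reading frame: 1, 2 or 3 (offset of the first codon).
#' @return Data frame with one row per sequence: \code{specimen_id},
#'   \code{n_codons}, \code{n_ambiguous}, \code{internal_stop},
#'   \code{stop_codon_positions} (comma-separated codon indices), and
#'   \code{ok} (no internal stop and no ambiguous amino acid).
#' @export
translation_check <- function(aln, genetic_code = "5", frame = 1) {
  stopifnot(inherits(aln, "aligned_seq_set"))
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3")
  code <- Biostrings::getGeneticCode(genetic_code)
  rows <- lapply(names(aln$sequences), function(id) {
    s <- substring(aln$sequences[[id]], frame)
    n_codons <- nchar(s) %/% 3L
    if (n_codons == 0L)
      return(data.frame(specimen_id = id, n_codons = 0L, n_ambiguous = 0L,
                        internal_stop = FALSE, stop_codon_positions = "",
                        ok = TRUE, stringsAsFactors = FALSE))
    starts <- seq(1L, by = 3L, length.out = n_codons)
    codons <- substring(s, starts, starts + 2L)
    aa <- ifelse(codons %in% names(code), unname(code[codons]), "X")
    stops <- which(aa == "*")
    internal <- stops[stops < n_codons]
    n_amb <- sum(aa == "X")
    data.frame(specimen_id = id, n_codons = n_codons, n_ambiguous = n_amb,
               internal_stop = length(internal) > 0L,
               stop_codon_positions = paste(internal, collapse = ","),
               ok = length(internal) == 0L && n_amb == 0L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
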
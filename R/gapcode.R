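#' Simple indel coding of alignment gaps
#'
#' Codes gaps as presence/absence characters by the simple indel coding
#' rule: every distinct maximal gap extent (identical start and end columns)
#' in the alignment becomes one binary character. A sequence is scored 1
#' (present) when it bears exactly that extent, NA (inapplicable) when one
#' of its gaps strictly contains the extent, and 0 otherwise. Characters are
#' ordered by (start, end).
#'
#' @param aln An \code{\link{aligned_seq_set}} that may contain "-".
#' @return An object of class \code{gap_character_block}: list with
#'   \code{characters} (data frame: start, end, both 1-based inclusive) and
#'   \code{scores} (sequences x characters matrix of 1/0/NA). Zero
#'   characters when the alignment has no gaps.
#' @export
#' @examples
#' aln <- aligned_seq_set(c(s1 = "A---A", s2 = "A--CA", s3 = "AAAAA"))
#' code_gaps(aln)$scores
code_gaps <- function(aln) {
  stopifnot(inherits(aln, "aligned_seq_set"))
  ids <- names(aln$sequences)
  runs <- lapply(aln$sequences, function(s) {
    m <- gregexpr("-+", s)[[1L]]
    if (m[1L] == -1L)
      return(data.frame(start = integer(), end = integer()))
    data.frame(start = as.integer(m),
               end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  extents <- unique(do.call(rbind, runs))
  if (nrow(extents) == 0L) {
    return(structure(list(characters = extents,
                          scores = matrix(integer(), nrow = length(ids),
                                          ncol = 0L,
                                          dimnames = list(ids, NULL))),
                     class = "gap_character_block"))
  }
  extents <- extents[order(extents$start, extents$end), , drop = FALSE]
  rownames(extents) <- NULL
  scores <- matrix(0L, nrow = length(ids), ncol = nrow(extents),
                   dimnames = list(ids, paste0("gap_", extents$start, "_",
                                               extents$end)))
  for (i in seq_along(ids)) {
    r <- runs[[i]]
    for (k in seq_len(nrow(extents))) {
      s <- extents$start[k]; e <- extents$end[k]
      if (any(r$start == s & r$end == e)) {
        scores[i, k] <- 1L
      } else if (any(r$start <= s & r$end >= e & (r$start < s | r$end > e))) {
        scores[i, k] <- NA_integer_
      }
    }
  }
  structure(list(characters = extents, scores = scores),
            class = "gap_character_block")
}

#' @export
print.gap_character_block <- function(x, ...) {
  cat("gap_character_block:", nrow(x$characters), "indel character(s) over",
      nrow(x$scores), "sequences\n")
  invisible(x)
}
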
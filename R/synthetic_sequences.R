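#' Simulate clustered haplotype alignments with planted structure
#'
#' Generates \code{n_groups} clusters of haplotypes. Group ancestors are
#' derived from a common random base sequence by mutating disjoint position
#' sets, so every pair of ancestors differs by at least \code{inter_steps}
#' (exactly \code{inter_steps} between the base group and each derived
#' group, 2 x \code{inter_steps} between derived groups). Within a group,
#' each additional haplotype carries 1..\code{intra_steps} private
#' substitutions at positions untouched by the ancestor-separating sets.
#' The planted truth (group membership and ancestor separations) is
#' returned alongside the alignment.
#'
#' @param n_haplotypes Haplotypes per group (>= 1).
#' @param length Alignment length in sites.
#' @param intra_steps Maximum substitutions separating a haplotype from its
#'   group ancestor.
#' @param inter_steps Substitutions separating each derived group ancestor
#'   from the base ancestor.
#' @param n_groups Number of groups (>= 1).
#' @param seed Integer RNG seed.
#' @return A list: \code{aln} (an \code{\link{aligned_seq_set}} with ids
#'   like "G1_H2"), \code{truth} (data frame: sequence_id, group),
#'   \code{ancestor_separation} = \code{inter_steps}.
#' @export
simulate_sequences <- function(n_haplotypes, length, intra_steps,
                               inter_steps, n_groups, seed = 1L) {
  stopifnot(n_haplotypes >= 1, n_groups >= 1, length > 0,
            intra_steps >= 0, inter_steps >= 0)
  if ((n_groups - 1L) * inter_steps + intra_steps > length)
    stop("length too short for the requested mutational steps")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  base_seq <- sample(bases, length, replace = TRUE)
  # disjoint separating sets for derived group ancestors
  sep_pool <- sample.int(length)
  ancestors <- list(base_seq)
  used <- integer()
  if (n_groups > 1L) {
    for (g in seq(2L, n_groups)) {
      pos <- sep_pool[seq((g - 2L) * inter_steps + 1L,
                          (g - 1L) * inter_steps)]
      anc <- base_seq
      for (p in pos) anc[p] <- sample(setdiff(bases, anc[p]), 1L)
      ancestors[[g]] <- anc
      used <- c(used, pos)
    }
  }
  free_pos <- setdiff(seq_len(length), used)
  seqs <- character(); ids <- character(); groups <- integer()
  for (g in seq_len(n_groups)) {
    seen <- character()
    for (h in seq_len(n_haplotypes)) {
      tries <- 0L
      repeat {
        s <- ancestors[[g]]
        if (h > 1L && intra_steps > 0L) {
          k <- sample.int(intra_steps, 1L)
          pos <- sample(free_pos, k)
          for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
        }
        sq <- paste(s, collapse = "")
        tries <- tries + 1L
        if (!(sq %in% seen) || tries > 100L) break
      }
      if (sq %in% seen)
        stop("could not generate distinct haplotypes; increase length or ",
             "intra_steps")
      seen <- c(seen, sq)
      seqs <- c(seqs, sq)
      ids <- c(ids, paste0("G", g, "_H", h))
      groups <- c(groups, g)
    }
  }
  names(seqs) <- ids
  list(aln = aligned_seq_set(seqs),
       truth = data.frame(sequence_id = ids, group = groups,
                          stringsAsFactors = FALSE),
       ancestor_separation = inter_steps)
}
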
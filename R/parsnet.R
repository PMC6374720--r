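#' Probability of parsimony for j differences over m sites
#'
#' The probability that two sequences of length \code{m} observed to differ
#' at \code{j} sites are separated by exactly \code{j} substitutions (no
#' superimposed, parallel or back substitutions). Computed under the
#' classic statistical-parsimony model for a sample of two: coalescent
#' (exponential) pairwise divergence time, per-site Poisson substitution,
#' and symmetric two-state change, which makes the per-site substitution
#' count geometric with rate parameter L/(1+L). The per-site divergence
#' parameter L is moment-matched to the observed difference fraction
#' (E[differ] = L/(1+2L) = j/m). Parsimony requires exactly one hit at each
#' differing site and none at each identical site, giving the closed form
#' \deqn{P_j = \left(\frac{1+2L}{(1+L)^2}\right)^m,\quad L = \frac{j}{m-2j}.}
#'
#' @param j Number of observed differences (mutational steps), >= 0.
#' @param m Sequence length (number of sites), > 0.
#' @return The probability of parsimony; 1 when j = 0, 0 when j >= m/2.
#' @export
parsimony_probability <- function(j, m) {
  stopifnot(length(j) == 1L, length(m) == 1L, m > 0, j >= 0)
  if (j == 0) return(1)
  if (2 * j >= m) return(0)
  L <- j / (m - 2 * j)
  ((1 + 2 * L) / (1 + L)^2)^m
}

#' Maximum mutational connection limit at a given confidence
#'
#' The largest number of steps \code{j} such that the probability of
#' parsimony \code{\link{parsimony_probability}(j, m)} is at least
#' \code{confidence}. Single-step connections are always allowed, so the
#' limit is at least 1. At 95% confidence this is the classic statistical
#' parsimony connection limit used to break haplotype networks into
#' independent subnetworks.
#'
#' @param seq_length Alignment length in sites (> 0).
#' @param confidence Connection probability in (0, 1); default 0.95.
#' @return Integer number of steps.
#' @export
#' @examples
#' connection_limit(563)  # the COI alignment length of the motivating study
connection_limit <- function(seq_length, confidence = 0.95) {
  stopifnot(seq_length > 0, confidence > 0, confidence < 1)
  j <- 1L
  while (2 * (j + 1L) < seq_length &&
         parsimony_probability(j + 1L, seq_length) >= confidence) {
    j <- j + 1L
  }
  j
}

#' Build statistical parsimony haplotype networks
#'
#' Haplotypes containing IUPAC ambiguity codes are excluded first (their
#' count is reported in the result). Alignment columns containing a gap in
#' any retained haplotype are excluded from the Hamming distance. Haplotype
#' pairs are then agglomerated in increasing distance order: at each
#' distance level d (up to the connection limit) an edge is added for every
#' pair at distance d whose endpoints were not already connected before
#' that level, so equally short alternative connections (loops) are
#' retained while longer redundant paths are not. Pairs at distance d > 1
#' are joined through d - 1 inferred, unobserved intermediate nodes so
#' every edge in the final graph represents a single mutation. The
#' resulting connected components are the independent networks.
#'
#' @param hap A \code{\link{haplotype_table}} (collapse before networking;
#'   identical haplotypes must not occur).
#' @param confidence Connection probability (default 0.95).
#' @param part Optional \code{\link{taxon_partition}} used to annotate each
#'   haplotype with its taxon composition.
#' @param limit Optional explicit step limit overriding the computed one.
#' @return An object of class \code{haplotype_network}: list with
#'   \code{nodes} (haplotype_id, observed, n_specimens, network, taxa),
#'   \code{edges} (from, to; every edge one mutational step),
#'   \code{limit}, \code{n_components}, \code{dropped_ambiguous},
#'   \code{used_columns}.
#' @export
build_networks <- function(hap, confidence = 0.95, part = NULL, limit = NULL) {
  stopifnot(inherits(hap, "haplotype_table"))
  seqs <- stats::setNames(hap$haplotypes$sequence, hap$haplotypes$haplotype_id)
  if (length(seqs) == 0L) stop("empty haplotype set")
  amb <- grepl("[^ACGT-]", seqs)
  dropped <- names(seqs)[amb]
  if (length(dropped) > 0L)
    message("build_networks: excluded ", length(dropped),
            " haplotype(s) with ambiguous nucleotides")
  seqs <- seqs[!amb]
  if (length(seqs) == 0L) stop("no haplotypes left after ambiguity exclusion")
  M <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(M) <- names(seqs)
  gapfree <- colSums(M == "-") == 0L
  M <- M[, gapfree, drop = FALSE]
  m <- ncol(M)
  if (m == 0L) stop("no gap-free columns available for Hamming distances")
  if (is.null(limit)) limit <- connection_limit(m, confidence)
  ids <- rownames(M)
  n <- length(ids)
  D <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        D[i, j] <- D[j, i] <- sum(M[i, ] != M[j, ])
      }
    }
  }
  # agglomerate by increasing distance; keep same-level alternative
  # connections (loops), skip pairs already connected before the level
  comp <- stats::setNames(seq_len(n), ids)  # union-find by relabel
  edges <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  n_inferred <- 0L
  if (n > 1L && limit >= 1L) {
    for (d in seq_len(limit)) {
      pairs <- which(upper.tri(D) & D == d, arr.ind = TRUE)
      if (nrow(pairs) == 0L) next
      ord <- order(ids[pairs[, 1L]], ids[pairs[, 2L]])
      pairs <- pairs[ord, , drop = FALSE]
      comp_at_level <- comp
      for (r in seq_len(nrow(pairs))) {
        a <- pairs[r, 1L]; b <- pairs[r, 2L]
        if (comp_at_level[a] == comp_at_level[b]) next
        if (d == 1L) {
          edges <- rbind(edges, data.frame(from = ids[a], to = ids[b],
                                           stringsAsFactors = FALSE))
        } else {
          inter <- paste0("I", n_inferred + seq_len(d - 1L))
          n_inferred <- n_inferred + d - 1L
          chain <- c(ids[a], inter, ids[b])
          edges <- rbind(edges,
                         data.frame(from = chain[-length(chain)],
                                    to = chain[-1L],
                                    stringsAsFactors = FALSE))
        }
        # merge components (visible from the next level on)
        old <- comp[b]; comp[comp == old] <- comp[a]
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(ids, if (n_inferred > 0L)
      paste0("I", seq_len(n_inferred)) else character())))
  memb <- igraph::components(g)$membership
  # renumber components deterministically by first haplotype occurrence
  first <- memb[ids]
  relabel <- stats::setNames(seq_along(unique(first)), unique(first))
  network_id <- unname(relabel[as.character(memb)])
  names(network_id) <- names(memb)
  counts <- stats::setNames(hap$haplotypes$n_specimens,
                            hap$haplotypes$haplotype_id)
  taxa <- rep("", length(names(memb)))
  if (!is.null(part)) {
    lookup <- partition_lookup(part)
    taxa <- vapply(names(memb), function(h) {
      if (!h %in% ids) return("")
      sp <- names(hap$membership)[hap$membership == h]
      sp <- intersect(sp, names(lookup))
      paste(sort(unique(unname(lookup[sp]))), collapse = ",")
    }, character(1L))
  }
  nodes <- data.frame(
    haplotype_id = names(memb),
    observed = names(memb) %in% ids,
    n_specimens = ifelse(names(memb) %in% ids,
                         as.integer(counts[names(memb)]), 0L),
    network = network_id,
    taxa = taxa,
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, limit = limit,
                 n_components = length(unique(network_id[nodes$observed])),
                 dropped_ambiguous = dropped, used_columns = m),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", sum(x$nodes$observed), "observed haplotypes in",
      x$n_components, "network(s); connection limit", x$limit, "steps over",
      x$used_columns, "columns\n")
  invisible(x)
}

#' Export a haplotype network as TSV edge list and node table
#'
#' @param net A \code{haplotype_network}.
#' @param edges_path,nodes_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_network <- function(net, edges_path, nodes_path) {
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edges_path, nodes_path))
}
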
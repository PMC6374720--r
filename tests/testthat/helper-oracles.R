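# Independent oracles, implemented deliberately differently from the
# package internals so they can cross-check them.

# p-distance by an explicit per-column loop using substr.
oracle_p_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ncmp <- 0L
  ndiff <- 0L
  for (i in seq_len(nchar(a))) {
    ca <- substr(a, i, i)
    cb <- substr(b, i, i)
    if (ca %in% c("A", "C", "G", "T") && cb %in% c("A", "C", "G", "T")) {
      ncmp <- ncmp + 1L
      if (ca != cb) ndiff <- ndiff + 1L
    }
  }
  if (ncmp == 0L) return(NA_real_)
  ndiff / ncmp
}

# Probability of parsimony by direct numerical evaluation of the per-site
# geometric substitution-count model: P(exactly one substitution at each
# differing site, zero at each identical site), with the per-site
# divergence parameter matched to the observed difference fraction. The
# odd/even-count conditioning probabilities are evaluated by truncated
# series summation instead of the closed form.
oracle_parsimony_probability <- function(j, m, kmax = 400L) {
  if (j == 0) return(1)
  if (2 * j >= m) return(0)
  L <- j / (m - 2 * j)
  r <- L / (1 + L)
  pk <- function(k) (1 / (1 + L)) * r^k       # geometric count pmf
  ks <- 0:kmax
  p_all <- pk(ks)
  p_differ <- sum(p_all[ks %% 2 == 1])        # odd counts flip the state
  p_same <- sum(p_all[ks %% 2 == 0])
  p1_given_differ <- pk(1) / p_differ
  p0_given_same <- pk(0) / p_same
  p1_given_differ^j * p0_given_same^(m - j)
}

oracle_connection_limit <- function(m, confidence = 0.95) {
  j <- 1L
  while (2 * (j + 1L) < m &&
         oracle_parsimony_probability(j + 1L, m) >= confidence) j <- j + 1L
  j
}

# Connected components of the thresholded Hamming graph by breadth-first
# search over an explicit adjacency matrix.
oracle_network_components <- function(seqs, limit) {
  n <- length(seqs)
  M <- do.call(rbind, strsplit(unname(seqs), ""))
  gapfree <- colSums(M == "-") == 0L
  M <- M[, gapfree, drop = FALSE]
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) adj[i, j] <- sum(M[i, ] != M[j, ]) <= limit
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  stats::setNames(comp, names(seqs))
}

# Random aligned sequences over ACGT with optional gaps/ambiguity.
random_seqs <- function(n, len, gap_frac = 0, amb_frac = 0) {
  pool <- c("A", "C", "G", "T")
  sapply(seq_len(n), function(i) {
    s <- sample(pool, len, replace = TRUE)
    k <- rbinom(1, len, gap_frac)
    if (k > 0) s[sample(len, k)] <- "-"
    k <- rbinom(1, len, amb_frac)
    if (k > 0) s[sample(len, k)] <- sample(c("N", "R", "Y"), k, replace = TRUE)
    paste(s, collapse = "")
  })
}

# A tiny hand-built genotype matrix helper.
make_gm <- function(geno, ref = NULL, alt = NULL) {
  genotype_matrix(geno, ref = ref, alt = alt)
}
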
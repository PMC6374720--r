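make_part <- function(ids, taxa) taxon_partition(ids, taxa)

test_that("shared SNP counts tally jointly polymorphic sites", {
  g <- rbind(f1 = c(1L, 0L, 2L, 0L),
             f2 = c(0L, 0L, 2L, 0L),
             o1 = c(1L, 0L, 0L, 0L),
             o2 = c(0L, 0L, 2L, 0L),
             p1 = c(0L, 1L, 0L, 0L))
  colnames(g) <- paste0("l", 1:4)
  gm <- genotype_matrix(g)
  part <- make_part(rownames(g), c("foc", "foc", "oth", "oth", "pp"))
  res <- shared_snp_counts(gm, part, "foc", c("oth", "pp"))
  # focal SNPs: l1, l3; oth SNPs: l1, l3; pp SNPs: l2
  expect_equal(unname(res["oth"]), 2L)
  expect_equal(unname(res["pp"]), 0L)
  expect_equal(attr(res, "n_focal_snps"), 2L)
  expect_error(shared_snp_counts(gm, part, "foc", "nope"), "unknown")
})

test_that("monomorphic-reference taxa share zero SNPs", {
  g <- matrix(0L, 4, 3, dimnames = list(paste0("s", 1:4), paste0("l", 1:3)))
  gm <- genotype_matrix(g)
  part <- make_part(rownames(g), c("a", "a", "b", "b"))
  res <- shared_snp_counts(gm, part, "a", "b")
  expect_equal(unname(res["b"]), 0L)
})

test_that("planted shared polymorphism is counted exactly", {
  set.seed(3)
  sim <- simulate_cross_dataset(cross_design(
    n_parentA = 15, n_parentB = 15, n_F1 = 0, n_auto_diag = 10,
    n_xlinked_diag = 0, n_nondiag = 40, seed = 31))
  part <- partition_from_metadata(sim$metadata)
  res <- shared_snp_counts(sim$gm, part, "taxonA", "taxonB")
  # oracle: direct column scan
  gA <- sim$gm$geno[sim$metadata$specimen_id[sim$metadata$taxon_label ==
                                               "taxonA"], ]
  gB <- sim$gm$geno[sim$metadata$specimen_id[sim$metadata$taxon_label ==
                                               "taxonB"], ]
  want <- sum(apply(gA, 2, function(x) any(x >= 1, na.rm = TRUE)) &
                apply(gB, 2, function(x) any(x >= 1, na.rm = TRUE)))
  expect_equal(unname(res["taxonB"]), want)
})

test_that("PCoA places identical specimens together and lines flat", {
  g <- rbind(s1 = c(0L, 0L, 2L, 1L), s2 = c(0L, 0L, 2L, 1L),
             s3 = c(2L, 2L, 0L, 1L))
  colnames(g) <- paste0("l", 1:4)
  pc <- pcoa_coordinates(genotype_matrix(g))
  expect_equal(pc$coordinates["s1", ], pc$coordinates["s2", ],
               tolerance = 1e-6)
  # three specimens on a genotypic line: second eigenvalue ~ 0
  g2 <- rbind(a = c(0L, 0L, 0L, 0L), b = c(1L, 1L, 1L, 1L),
              c = c(2L, 2L, 2L, 2L))
  colnames(g2) <- paste0("l", 1:4)
  pc2 <- pcoa_coordinates(genotype_matrix(g2))
  expect_lt(abs(pc2$eigenvalues[2]) / pc2$eigenvalues[1], 1e-8)
  expect_error(pcoa_coordinates(genotype_matrix(g2[1:2, ])), "3 specimens")
})

test_that("F1 centroid sits midway between parental centroids on axis 1", {
  sim <- simulate_cross_dataset(cross_design(
    n_parentA = 20, n_parentB = 20, n_F1 = 20, n_auto_diag = 40,
    n_xlinked_diag = 0, n_nondiag = 60, seed = 8))
  pc <- pcoa_coordinates(sim$gm)
  ax1 <- pc$coordinates[, 1]
  cen <- tapply(ax1, sim$truth$class, mean)
  mid <- (cen[["parental_A"]] + cen[["parental_B"]]) / 2
  spread <- abs(cen[["parental_A"]] - cen[["parental_B"]])
  expect_lt(abs(cen[["F1"]] - mid), 0.05 * spread)
})

test_that("fixed-difference panels require fixation in both parents", {
  g <- rbind(a1 = c(0L, 0L, 0L, NA), a2 = c(0L, 1L, 0L, 0L),
             b1 = c(2L, 2L, 2L, 2L), b2 = c(2L, 2L, 2L, 2L))
  colnames(g) <- paste0("l", 1:4)
  gm <- genotype_matrix(g)
  part <- make_part(rownames(g), c("pa", "pa", "pb", "pb"))
  panel <- build_fixed_panel(gm, part, "pa", "pb")
  # l2 has a het parent-A specimen; l4 misses the 100% call-rate bar
  expect_equal(panel$loci$locus_id, c("l1", "l3"))
  expect_equal(panel$loci$allele_A, c("ref", "ref"))
  # reversed orientation is recorded
  panel_rev <- build_fixed_panel(gm, part, "pb", "pa")
  expect_equal(panel_rev$loci$allele_A, c("alt", "alt"))
  expect_error(build_fixed_panel(gm, part, "nope", "pb"), "empty")
})

test_that("the simulator's planted fixed differences are recovered exactly", {
  for (seed in c(2, 12)) {
    sim <- simulate_cross_dataset(cross_design(
      n_parentA = 12, n_parentB = 12, n_F1 = 6, n_auto_diag = 25,
      n_xlinked_diag = 10, n_nondiag = 200, seed = seed))
    part <- partition_from_metadata(sim$metadata)
    panel <- build_fixed_panel(sim$gm, part, "taxonA", "taxonB")
    planted <- sim$loci$locus_id[sim$loci$kind %in% c("auto_diag", "x_diag")]
    expect_setequal(panel$loci$locus_id, planted)
    # orientation agrees with the planted allele assignment
    ori <- stats::setNames(sim$loci$allele_A, sim$loci$locus_id)
    expect_equal(panel$loci$allele_A,
                 unname(ori[panel$loci$locus_id]))
  }
})

test_that("hybrid metrics compute index and heterozygosity from dosages", {
  g <- rbind(h = c(1L, 1L, 1L, 1L), pa = c(2L, 2L, 2L, 2L),
             mix = c(2L, 1L, 1L, 0L))
  colnames(g) <- paste0("l", 1:4)
  gm <- genotype_matrix(g)
  panel <- structure(list(
    loci = data.frame(locus_id = colnames(g), allele_A = "alt",
                      stringsAsFactors = FALSE),
    parentA = "pa", parentB = "pb", call_rate_requirement = 1),
    class = "diagnostic_panel")
  m_h <- hybrid_metrics(gm, panel, "h")
  expect_equal(m_h$index_A, 0.5)
  expect_equal(m_h$het_frac, 1.0)
  m_pa <- hybrid_metrics(gm, panel, "pa")
  expect_equal(m_pa$index_A, 1.0)
  expect_equal(m_pa$het_frac, 0)
  m_mix <- hybrid_metrics(gm, panel, "mix")
  expect_equal(m_mix$index_A, 0.5)
  expect_equal(m_mix$het_frac, 0.5)
})

test_that("the classification ladder is total, ordered and matches the rules", {
  cls <- function(index, het)
    classify_specimen(list(index_A = index, het_frac = het,
                           n_loci_called = 20L))
  expect_equal(cls(0.5, 1.0), "F1")
  expect_equal(cls(1.0, 0.0), "parental_A")
  expect_equal(cls(0.0, 0.0), "parental_B")
  expect_equal(cls(0.75, 0.5), "backcross_A")
  expect_equal(cls(0.25, 0.5), "backcross_B")
  expect_equal(cls(0.5, 0.1), "later_generation")
  expect_equal(cls(0.6, 0.6), "unresolved")
  # every point of the metric space receives exactly one class
  for (index in seq(0, 1, by = 0.05)) {
    for (het in seq(0, 1, by = 0.05)) {
      out <- cls(index, het)
      expect_length(out, 1L)
      expect_true(out %in% c("parental_A", "parental_B", "F1", "backcross_A",
                             "backcross_B", "later_generation", "unresolved"))
    }
  }
  expect_equal(classify_specimen(list(index_A = NA_real_,
                                      het_frac = NA_real_,
                                      n_loci_called = 0L)), "unresolved")
})

test_that("sex-linked loci are flagged only for the X0 pattern", {
  # 13 hybrid males hom for the maternal (A) allele, 1 female heterozygous
  ids <- c(paste0("m", 1:13), "f1")
  g <- matrix(2L, length(ids), 3,
              dimnames = list(ids, c("x1", "x2", "auto")))
  g["f1", c("x1", "x2")] <- 1L
  g[, "auto"] <- 1L
  gm <- genotype_matrix(g)
  panel <- structure(list(
    loci = data.frame(locus_id = colnames(g), allele_A = "alt",
                      stringsAsFactors = FALSE),
    parentA = "pa", parentB = "pb", call_rate_requirement = 1),
    class = "diagnostic_panel")
  records <- data.frame(specimen_id = ids,
                        taxon_label = "hyb",
                        sex = c(rep("male", 13), "female"),
                        locality = "x", notes = "")
  rep <- detect_sex_linked_loci(gm, panel, records, ids, "A")
  st <- stats::setNames(rep$status, rep$locus_id)
  expect_equal(unname(st[c("x1", "x2")]), rep("sex_linked", 2))
  expect_equal(unname(st["auto"]), "autosomal_diagnostic")
  # one heterozygous male breaks the pattern at zero tolerance
  g2 <- g; g2["m1", "x1"] <- 1L
  rep2 <- detect_sex_linked_loci(genotype_matrix(g2), panel, records, ids, "A")
  expect_equal(rep2$status[rep2$locus_id == "x1"], "nondiagnostic")
  # wrong maternal side: males hom for the paternal allele is not X0
  rep3 <- detect_sex_linked_loci(gm, panel, records, ids, "B")
  expect_equal(rep3$status[rep3$locus_id == "x1"], "nondiagnostic")
  records_unsexed <- transform(records, sex = "unknown")
  expect_error(detect_sex_linked_loci(gm, panel, records_unsexed, ids, "A"),
               "no sexed hybrid")
})

test_that("maternal parent inference follows the mitochondrial clusters", {
  mito <- c(h1 = "pa", h2 = "pa", h3 = "pa")
  res <- infer_maternal_parent(mito, names(mito), "pa", "pb")
  expect_equal(res$maternal, "pa")
  expect_match(res$direction, "female pa and male pb")
  mito2 <- c(h1 = "pa", h2 = "pb")
  res2 <- infer_maternal_parent(mito2, names(mito2), "pa", "pb")
  expect_equal(res2$maternal, "bidirectional")
  mito3 <- c(h1 = "pa", h2 = NA)
  expect_message(res3 <- infer_maternal_parent(mito3, c("h1", "h2"),
                                               "pa", "pb"),
                 "excluded 1")
  expect_equal(res3$excluded, "h2")
  expect_error(suppressMessages(
    infer_maternal_parent(c(h1 = NA_character_), "h1", "pa", "pb")),
    "no hybrid")
})
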
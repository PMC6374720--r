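test_that("cross simulation is deterministic given the seed", {
  d <- cross_design(n_parentA = 8, n_parentB = 8, n_F1 = 8, n_BC1A = 8,
                    n_F2 = 8, n_auto_diag = 10, n_xlinked_diag = 5,
                    n_nondiag = 20, error_rate = 0.02, missing_rate = 0.05,
                    seed = 77)
  s1 <- simulate_cross_dataset(d)
  s2 <- simulate_cross_dataset(d)
  expect_identical(s1$gm$geno, s2$gm$geno)
  expect_identical(s1$loci, s2$loci)
  s3 <- simulate_cross_dataset(cross_design(
    n_parentA = 8, n_parentB = 8, n_F1 = 8, n_BC1A = 8, n_F2 = 8,
    n_auto_diag = 10, n_xlinked_diag = 5, n_nondiag = 20,
    error_rate = 0.02, missing_rate = 0.05, seed = 78))
  expect_false(identical(s1$gm$geno, s3$gm$geno))
})

test_that("diagnostic loci follow Mendelian and X0 inheritance exactly", {
  sim <- simulate_cross_dataset(cross_design(
    n_parentA = 6, n_parentB = 6, n_F1 = 10, n_F1_female = 3,
    n_BC1A = 10, n_auto_diag = 12, n_xlinked_diag = 8, n_nondiag = 0,
    maternal_taxon = "A", seed = 4))
  tr <- sim$truth
  loci <- sim$loci
  # work in parent-A allele dosage
  dosA <- sim$gm$geno
  flip <- loci$allele_A == "ref"
  dosA[, flip] <- 2L - dosA[, flip]
  auto <- loci$locus_id[loci$kind == "auto_diag"]
  xl <- loci$locus_id[loci$kind == "x_diag"]
  pa <- tr$specimen_id[tr$class == "parental_A"]
  pb <- tr$specimen_id[tr$class == "parental_B"]
  f1 <- tr$specimen_id[tr$class == "F1"]
  f1_m <- tr$specimen_id[tr$class == "F1" & tr$sex == "male"]
  f1_f <- tr$specimen_id[tr$class == "F1" & tr$sex == "female"]
  bc <- tr$specimen_id[tr$class == "BC1A"]
  expect_true(all(dosA[pa, ] == 2L))
  expect_true(all(dosA[pb, ] == 0L))
  expect_true(all(dosA[f1, auto] == 1L))
  # X0: F1 males carry only their mother's (taxon A) X, coded homozygous
  expect_true(all(dosA[f1_m, xl] == 2L))
  expect_true(all(dosA[f1_f, xl] == 1L))
  # BC1A autosomes: one guaranteed A allele plus a Mendelian draw
  expect_true(all(dosA[bc, auto] %in% c(1L, 2L)))
  # mitochondria follow the maternal line
  expect_true(all(sim$mito[c(f1, bc)] == "taxonA"))
  expect_true(all(sim$mito[pb] == "taxonB"))
})

test_that("maternal taxon B reverses the X0 and mitochondrial pattern", {
  sim <- simulate_cross_dataset(cross_design(
    n_parentA = 4, n_parentB = 4, n_F1 = 8, n_F1_female = 2,
    n_auto_diag = 5, n_xlinked_diag = 6, n_nondiag = 0,
    maternal_taxon = "B", seed = 9))
  tr <- sim$truth
  loci <- sim$loci
  dosA <- sim$gm$geno
  flip <- loci$allele_A == "ref"
  dosA[, flip] <- 2L - dosA[, flip]
  xl <- loci$locus_id[loci$kind == "x_diag"]
  f1_m <- tr$specimen_id[tr$class == "F1" & tr$sex == "male"]
  expect_true(all(dosA[f1_m, xl] == 0L))  # hom for the B (maternal) allele
  expect_true(all(sim$mito[tr$class == "F1"] == "taxonB"))
})

test_that("Mendelian marginals match expectation at scale", {
  # BC1 dosage is 1 or 2 with equal probability; F2 heterozygosity is 1/2.
  # chi-square goodness of fit per seed, family-wise alpha 0.01 over 10
  # seeds (per-test 0.001).
  for (seed in 1:10) {
    sim <- simulate_cross_dataset(cross_design(
      n_parentA = 0, n_parentB = 0, n_F1 = 0, n_BC1A = 0, n_F2 = 10000,
      n_auto_diag = 1, n_xlinked_diag = 0, n_nondiag = 0, seed = seed))
    het <- sum(sim$gm$geno == 1L)
    p <- stats::chisq.test(c(het, 10000 - het), p = c(0.5, 0.5))$p.value
    expect_gt(p, 0.001)
  }
  sim <- simulate_cross_dataset(cross_design(
    n_parentA = 0, n_parentB = 0, n_F1 = 0, n_BC1A = 10000,
    n_auto_diag = 1, n_xlinked_diag = 0, n_nondiag = 0, seed = 100))
  loci <- sim$loci
  dosA <- sim$gm$geno
  if (loci$allele_A == "ref") dosA <- 2L - dosA
  tab <- table(factor(dosA, levels = 0:2))
  expect_equal(unname(tab[["0"]]), 0L)
  p <- stats::chisq.test(c(tab[["1"]], tab[["2"]]), p = c(0.5, 0.5))$p.value
  expect_gt(p, 0.001)
})

test_that("genotyping noise perturbs only to adjacent dosages", {
  g <- matrix(rep(0:2, each = 400), 40, 30)
  dimnames(g) <- list(paste0("s", 1:40), paste0("l", 1:30))
  gm <- genotype_matrix(g)
  expect_identical(add_genotyping_noise(gm, 0, 0, seed = 1)$geno, gm$geno)
  allna <- add_genotyping_noise(gm, 0, 1, seed = 1)
  expect_true(all(is.na(allna$geno)))
  noisy <- add_genotyping_noise(gm, 0.3, 0, seed = 2)
  moved <- which(noisy$geno != gm$geno)
  expect_gt(length(moved), 0L)
  expect_true(all(abs(noisy$geno[moved] - gm$geno[moved]) == 1L))
  # error rate is approximately honoured
  expect_equal(mean(noisy$geno != gm$geno), 0.3, tolerance = 0.1)
})

test_that("sequence simulation plants the advertised structure", {
  sim <- simulate_sequences(n_haplotypes = 1, length = 50, intra_steps = 0,
                            inter_steps = 0, n_groups = 1, seed = 1)
  expect_length(sim$aln$sequences, 1L)
  sim2 <- simulate_sequences(n_haplotypes = 1, length = 100, intra_steps = 0,
                             inter_steps = 4, n_groups = 2, seed = 2)
  expect_equal(p_distance(sim2$aln$sequences[[1]],
                          sim2$aln$sequences[[2]]), 0.04)
  sim3 <- simulate_sequences(n_haplotypes = 5, length = 120, intra_steps = 3,
                             inter_steps = 10, n_groups = 3, seed = 3)
  expect_equal(anyDuplicated(sim3$aln$sequences), 0L)
  # within-group haplotypes stay within intra_steps of their ancestor
  anc <- sim3$aln$sequences[sim3$truth$sequence_id[c(1, 6, 11)]]
  for (g in 1:3) {
    members <- sim3$truth$sequence_id[sim3$truth$group == g]
    for (id in members) {
      d <- sum(strsplit(sim3$aln$sequences[[id]], "")[[1]] !=
                 strsplit(anc[[g]], "")[[1]])
      expect_lte(d, 3)
    }
  }
  expect_error(simulate_sequences(1, 10, 2, 10, 3, 1), "too short")
})

test_that("read-count simulation supports calling round trips", {
  g <- rbind(s1 = c(1L, 0L), s2 = c(2L, 1L))
  colnames(g) <- c("l1", "l2")
  gm <- genotype_matrix(g, ref = c("A", "C"), alt = c("G", "T"))
  counts <- simulate_site_counts(gm, depth_mean = 100, error_rate = 0,
                                 seed = 1)
  r1 <- counts[counts$specimen_id == "s1" & counts$locus_id == "l1", ]
  expect_equal(r1$A + r1$G, r1$A + r1$C + r1$G + r1$T)  # only ref/alt bases
  expect_gt(r1$A, 20)
  expect_gt(r1$G, 20)
  called <- call_genotypes(counts, ref = gm$ref, alt = gm$alt)
  expect_identical(called$geno[rownames(g), colnames(g)], g)
  # homozygote at depth ~3 fails the unique-read minimum
  counts_lo <- simulate_site_counts(gm, depth_mean = 3, error_rate = 0,
                                    seed = 2)
  cfg <- snowfly_config()
  shallow <- counts_lo[1, c("A", "C", "G", "T")]
  if (sum(shallow) < 5)
    expect_equal(call_genotype_at_site(unlist(shallow), cfg)$call, "missing")
})
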
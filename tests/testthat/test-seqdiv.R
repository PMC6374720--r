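test_that("haplotype collapsing groups identical sequences deterministically", {
  aln <- aligned_seq_set(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"))
  hap <- collapse_haplotypes(aln)
  expect_equal(nrow(hap$haplotypes), 2L)
  expect_equal(unname(hap$membership), c("H1", "H1", "H2"))
  expect_equal(hap$haplotypes$n_specimens, c(2L, 1L))

  aln2 <- aligned_seq_set(c(a = "AAAA", b = "AAAT", c = "AATT"))
  expect_equal(nrow(collapse_haplotypes(aln2)$haplotypes), 3L)
})

test_that("ambiguity-tolerant collapsing merges compatible sequences", {
  aln <- aligned_seq_set(c(s1 = "ACGT", s2 = "ACGN", s3 = "ACTA"))
  strict <- collapse_haplotypes(aln)
  expect_equal(nrow(strict$haplotypes), 3L)
  lenient <- collapse_haplotypes(
    aln, snowfly_config(collapse_match_ambiguous = TRUE))
  expect_equal(nrow(lenient$haplotypes), 2L)
  expect_equal(unname(lenient$membership[c("s1", "s2")]), c("H1", "H1"))
})

test_that("p-distance follows the pairwise-deletion definition", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("AA-A", "AATT"), 1 / 3)
  expect_true(is.na(p_distance("----", "AAAA")))
  expect_error(p_distance("AAA", "AAAA"), "length")
})

test_that("p-distance matches the per-column oracle on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_seqs(2, 40, gap_frac = 0.1, amb_frac = 0.05)
    d <- p_distance(s[1], s[2])
    expect_equal(d, oracle_p_distance(s[1], s[2]))
    expect_equal(d, p_distance(s[2], s[1]))  # symmetry
    if (!is.na(d)) expect_true(d >= 0 && d <= 1)
  }
})

test_that("group distance table reports within/between haplotype means", {
  # two groups, one haplotype each, 10% divergent
  aln <- aligned_seq_set(c(a1 = paste(rep("A", 10), collapse = ""),
                           b1 = paste(c("T", rep("A", 9)), collapse = "")))
  hap <- collapse_haplotypes(aln)
  part <- taxon_partition(c("a1", "b1"), c("gA", "gB"))
  dt <- group_distance_table(hap, part)
  expect_true(is.na(dt["gA", "gA"]))  # single-haplotype group
  expect_equal(dt["gA", "gB"], 10.00)
  expect_equal(dt["gB", "gA"], dt["gA", "gB"])

  # planted three-haplotype group: pairwise p = 0.4, 0.8, 0.4
  aln2 <- aligned_seq_set(c(x1 = "AAAAA", x2 = "TTAAA", x3 = "TTTTA",
                            y1 = "AAAAA"))
  part2 <- taxon_partition(c("x1", "x2", "x3", "y1"),
                           c("gX", "gX", "gX", "gY"))
  dt2 <- group_distance_table(collapse_haplotypes(aln2), part2)
  expect_equal(dt2["gX", "gX"], round(mean(c(0.4, 0.8, 0.4)) * 100, 2))
  # y1 shares haplotype H1 with x1: the cross pair (H1,H1) contributes 0
  expect_equal(dt2["gX", "gY"], round(mean(c(0, 0.4, 0.8)) * 100, 2))
})

test_that("a partition of identical sequences yields zeros and NAs", {
  aln <- aligned_seq_set(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"))
  part <- taxon_partition(letters[1:4], c("g1", "g1", "g2", "g2"))
  dt <- group_distance_table(collapse_haplotypes(aln), part)
  expect_true(is.na(dt["g1", "g1"]))  # one haplotype in the group
  expect_equal(dt["g1", "g2"], 0)
})

test_that("distance table writer renders NA diagonals as 0.00", {
  aln <- aligned_seq_set(c(a1 = "AAAA", b1 = "TAAA"))
  dt <- group_distance_table(collapse_haplotypes(aln),
                             taxon_partition(c("a1", "b1"), c("gA", "gB")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_table(dt, f)
  lines <- readLines(f)
  expect_match(lines[2], "^\\S*\tgA\t0\\.00")
  expect_match(lines[length(lines)], "^#")
})

test_that("diagnostic character scan finds fixed, exclusive states", {
  seqs <- c(f1 = "AAAAAACAAA", f2 = "AAAAAACAAA", f3 = "AATAAACAAA",
            o1 = "AAAAAAAAAA", o2 = "AATAAAAAAA")
  aln <- aligned_seq_set(seqs)
  part <- taxon_partition(names(seqs),
                          c("focal", "focal", "focal", "other", "other"))
  dc <- find_diagnostic_characters(aln, part, "focal")
  expect_equal(dc$position, 7L)
  expect_equal(dc$state, "C")
  # self-verifying postcondition: re-check fixity at the reported column
  for (r in seq_len(nrow(dc))) {
    col <- dc$position[r]
    focal_states <- substr(seqs[1:3], col, col)
    other_states <- substr(seqs[4:5], col, col)
    expect_true(all(focal_states == dc$state[r]))
    expect_false(any(other_states == dc$state[r]))
  }
  # no diagnostic character when every focal-fixed state also occurs
  # outside the focal group
  part_all <- taxon_partition(names(seqs), c("focal", "other", "other",
                                             "focal", "other"))
  expect_equal(nrow(find_diagnostic_characters(aln, part_all, "focal")), 0L)
})

test_that("strict scan skips focal-ambiguous columns; lenient resolves them", {
  seqs <- c(f1 = "CAAA", f2 = "YAAA", o1 = "AAAA")
  aln <- aligned_seq_set(seqs)
  part <- taxon_partition(names(seqs), c("focal", "focal", "other"))
  expect_equal(nrow(find_diagnostic_characters(aln, part, "focal")), 0L)
  dc <- find_diagnostic_characters(
    aln, part, "focal", snowfly_config(diagnostic_lenient = TRUE))
  expect_equal(dc$position, 1L)
  expect_equal(dc$state, "C")  # C fits both C and Y, impossible in other
})

test_that("simple indel coding scores extents, absences and inapplicables", {
  aln <- aligned_seq_set(c(s1 = "A--A", s2 = "A--A", s3 = "AAAA"))
  gc1 <- code_gaps(aln)
  expect_equal(nrow(gc1$characters), 1L)
  expect_equal(unname(gc1$scores[, 1]), c(1L, 1L, 0L))

  aln2 <- aligned_seq_set(c(s1 = "A---A", s2 = "A--CA"))
  gc2 <- code_gaps(aln2)
  expect_equal(nrow(gc2$characters), 2L)
  expect_equal(gc2$characters$start, c(2L, 2L))
  expect_equal(gc2$characters$end, c(3L, 4L))
  expect_true(is.na(gc2$scores["s1", "gap_2_3"]))  # strictly contained
  expect_equal(gc2$scores["s2", "gap_2_3"], 1L)
  expect_equal(gc2$scores["s1", "gap_2_4"], 1L)
  expect_equal(gc2$scores["s2", "gap_2_4"], 0L)

  expect_equal(nrow(code_gaps(aligned_seq_set(c(a = "ACGT")))$characters), 0L)
})

test_that("gap coding is invariant to sequence order", {
  seqs <- c(s1 = "A---A", s2 = "A--CA", s3 = "AAAAA", s4 = "-AAAA")
  g1 <- code_gaps(aligned_seq_set(seqs))
  g2 <- code_gaps(aligned_seq_set(rev(seqs)))
  expect_identical(g1$characters, g2$characters)
  expect_identical(g1$scores[names(seqs), ], g2$scores[names(seqs), ])
})

test_that("translation check flags internal stops and ambiguous residues", {
  aln <- aligned_seq_set(c(ok = "ATGAAA", stop = "ATGTAA",
                           amb = "ATGNNN"))
  # make them equal length by padding to 9
  aln <- aligned_seq_set(c(ok = "ATGAAAAAA", stop = "ATGTAAAAA",
                           amb = "ATGNNNAAA"))
  rep <- translation_check(aln, frame = 1)
  expect_true(rep$ok[rep$specimen_id == "ok"])
  expect_true(rep$internal_stop[rep$specimen_id == "stop"])
  expect_equal(rep$stop_codon_positions[rep$specimen_id == "stop"], "2")
  expect_equal(rep$n_ambiguous[rep$specimen_id == "amb"], 1L)
  expect_false(rep$ok[rep$specimen_id == "amb"])
  expect_error(translation_check(aln, frame = 4), "frame")
  # invertebrate mitochondrial code: AGA is serine, not a stop
  rep5 <- translation_check(aligned_seq_set(c(x = "ATGAGAAAA")), frame = 1)
  expect_true(rep5$ok)
  # frame shifts the codon grid
  rep_f2 <- translation_check(aligned_seq_set(c(x = "TTAAATTAA")), frame = 2)
  expect_true(rep_f2$internal_stop)  # TAA at codon 1 of 2
})
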
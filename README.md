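# snowfly

Sequence and SNP diagnostics for testing whether a putative species is of
hybrid origin.

Some "species" are not evolutionary lineages at all but standing cohorts of
first-generation hybrids between two other taxa: morphologically
distinctive (every individual is the same cross), yet showing mitochondrial
haplotypes shared with a sympatric congener, interspecific p-distances in
the ordinary within-species range, and no reciprocal monophyly. snowfly
implements the full diagnostic workflow for this situation, aimed at
taxonomists and conservation geneticists working with barcode sequences and
reduced-representation SNP data (e.g. genotyping by sequencing).

## What it computes

**Sequence side** — haplotype collapsing; uncorrected p-distances
(pairwise deletion) within and between taxa; pure diagnostic nucleotide
characters (a state fixed in all focal haplotypes and absent from all
others); simple indel coding of alignment gaps; translation checks under
the invertebrate mitochondrial code; statistical parsimony networks. The
95% connection limit is the largest step count *j* whose probability of
parsimony

P_j = ((1 + 2L̂) / (1 + L̂)²)^m,  L̂ = j / (m − 2j)

(sequence length *m*; per-site geometric substitution counts under
coalescent divergence, moment-matched to j/m) stays at or above the
confidence level. Haplotypes that cannot be connected within the limit
fall into separate networks — independent networks are conventionally read
as separate species.

**SNP side** — genotype calling from per-site read counts (80% allele
support, 5 unique reads); site filtering (MAF ≥ 1%, call rate ≥ 20%,
heterozygosity within the 2pq bound); shared-SNP counts between a focal
taxon and candidate parents; principal coordinate analysis of genotypic
distances; fixed-difference diagnostic panels (loci fixed for alternate
alleles in the two parental taxa at 100% call rate); per-specimen hybrid
index *h* (fraction of panel alleles from parent A) and interspecific
heterozygosity, with ladder classification — parental, F1 (het ≥ 0.95),
backcross (index ≥ 0.75 toward one parent), later-generation (het ≤ 0.25),
else unresolved; X0 sex-linked locus detection (all hybrid males homozygous
for the maternal allele, all females heterozygous); and maternal-parent
inference from mitochondrial haplotype clusters.

**Synthetic crosses** — a Mendelian simulator with X0 sex chromosomes,
maternally inherited mitochondria, fixed and frequency-divergent loci,
genotyping error/missingness, and a Poisson read-count generator, so every
stage can be validated against planted truth.

## Worked example

Simulate the motivating study design — two parental taxa, a hybrid cohort
of 13 males and one female, 60 autosomal and 51 X-linked fixed differences
— and run the diagnosis:

```r
library(snowfly)

sim <- simulate_cross_dataset(cross_design(
  n_parentA = 20, n_parentB = 20, n_F1 = 14, n_F1_female = 1,
  n_auto_diag = 60, n_xlinked_diag = 51, n_nondiag = 34, seed = 1))
part  <- partition_from_metadata(sim$metadata)
panel <- build_fixed_panel(sim$gm, part, "taxonA", "taxonB")
panel
#> diagnostic_panel: 111 loci fixed for alternate alleles in taxonA vs taxonB
```

All 111 planted fixed differences (60 autosomal + 51 X-linked) are
recovered. The hybrids' genotypes then split the panel:

```r
hybrids <- sim$truth$specimen_id[sim$truth$class == "F1"]
sexlink <- detect_sex_linked_loci(sim$gm, panel, sim$metadata, hybrids, "A")
table(sexlink$status)
#> autosomal_diagnostic           sex_linked
#>                   60                   51
```

Every autosomal diagnostic locus is heterozygous in every hybrid; at the
51 X-linked loci all 13 males are homozygous for the maternal allele while
the single female is heterozygous — the X0 signature. Restricting the
metrics to the autosomal subset:

```r
auto <- panel
auto$loci <- panel$loci[panel$loci$locus_id %in%
  sexlink$locus_id[sexlink$status == "autosomal_diagnostic"], ]
rep <- hybrid_report(sim$gm, auto, hybrids)
head(rep, 4)
#>   specimen_id n_loci_called index_A het_frac class
#> 1      F1_001            60     0.5        1    F1
#> 2      F1_002            60     0.5        1    F1
#> 3      F1_003            60     0.5        1    F1
#> 4      F1_004            60     0.5        1    F1
table(rep$class)
#> F1
#> 14
```

Each specimen draws exactly half its panel alleles from each parent and is
heterozygous at every locus: all 14 are F1s, with no backcross or
later-generation genotypes (nonintrogressive hybridization). The cross
direction comes from the mitochondria:

```r
infer_maternal_parent(sim$mito[hybrids], hybrids, "taxonA", "taxonB")$direction
#> "hybrids are progeny of female taxonA and male taxonB"
```

`run_full_analysis()` chains all stages (FASTA/VCF/TSV in, TSV/JSON out,
with a digest-bearing run manifest); `inst/scripts/snowfly-pipeline.R` is a
thin shell wrapper, and `scripts/table1_distances.R` recomputes per-gene
distance tables from user-downloaded alignments.

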
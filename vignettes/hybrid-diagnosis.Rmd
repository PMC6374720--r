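---
title: "Diagnosing hybrid-origin taxa with snowfly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing hybrid-origin taxa with snowfly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowfly)
```

## The problem

A putative species may in fact be a cohort of interspecific hybrids. The
classic warning signs are cytonuclear discord: mitochondrial haplotypes
shared with a sympatric congener, interspecific p-distances in the range of
ordinary within-species variation, no reciprocal monophyly — while the
morphology that motivated the species description stays perfectly
consistent, because every individual is the same kind of first-generation
(F1) cross. snowfly implements both halves of the diagnostic workflow:

1. **Sequence diagnostics** (mitochondrial barcodes, nuclear spacers):
   haplotype collapsing, uncorrected p-distances within and between taxa,
   pure diagnostic nucleotide characters, simple indel coding of gaps, and
   statistical parsimony networks with a 95% connection limit.
2. **Genome-wide SNP diagnostics** (e.g. genotyping-by-sequencing panels):
   genotype calling from read counts, site filtering, shared-SNP counts,
   principal coordinate analysis, fixed-difference diagnostic panels, a
   per-specimen hybrid index and interspecific heterozygosity with
   F1/backcross/later-generation classification, X0 sex-linked locus
   detection, and maternal-parent inference from mitochondrial clusters.

A Mendelian cross simulator with X0 sex chromosomes and maternally
inherited mitochondria generates fully truth-tagged data, so every stage is
testable end to end without external downloads.

## Sequence-level methods

**Haplotypes.** Specimens sharing an identical aligned sequence share a
haplotype (strict rule, the default). Because reference tools differ in how
they treat IUPAC ambiguity codes, an ambiguity-tolerant option merges
sequences that agree wherever both carry an unambiguous base; merging is
greedy in first-occurrence order since compatibility is not transitive.
Haplotype numbering follows first occurrence, making all downstream output
deterministic.

**p-distances.** `p_distance()` is the uncorrected proportion of differing
columns, with pairwise deletion: any column holding a gap or ambiguity code
in either sequence is excluded for that pair only. Pairwise (not complete)
deletion is the default behaviour of the distance tools most barcoding
studies rely on, and it preserves information in alignments where indels
are concentrated in a few sequences. Group distance tables average over
unique haplotypes — each haplotype counted once per group however many
specimens carry it — and a haplotype shared between two groups contributes
a zero-distance between-group pair, which is exactly the signal of
haplotype sharing. A single-haplotype group has no within-group mean; we
report NA and let the table writer print 0.00 (with a footnote) to match
the conventional published layout.

**Diagnostic characters.** A column state is diagnostic for a focal group
if every focal haplotype carries it and no haplotype carried by any
non-focal specimen does. Haplotypes shared across the group boundary sit in
the comparison set, so sharing suppresses diagnosis — as it should. Strict
mode (default) skips columns where a focal haplotype is gapped or
ambiguous; lenient mode resolves ambiguity codes against their IUPAC
expansions and accepts a state only if it is impossible in every non-focal
haplotype.

**Gap coding.** `code_gaps()` implements simple indel coding: each distinct
maximal gap extent is one presence/absence character; a sequence whose gap
strictly contains another extent is inapplicable (scored missing) for that
character. This lets indel variation in length-variable spacers contribute
characters without pretending gaps are a fifth base.

**Translation check.** Protein-coding mitochondrial alignments are
translated (invertebrate mitochondrial code by default) and screened for
internal stop codons and ambiguous residues, the standard guard against
numts and frame errors.

## Statistical parsimony networks

The network stage answers one question: which haplotypes can be connected
by mutational paths short enough that homoplasy is unlikely, at a stated
confidence? Haplotypes containing ambiguity codes are excluded first, and
alignment columns that are gapped in any retained haplotype are excluded
from the Hamming distance.

`parsimony_probability(j, m)` is the probability that two sequences of
length `m` observed to differ at `j` sites are separated by exactly `j`
substitutions. We model each site, for a sample of two, with an
exponential (coalescent) divergence time and Poisson substitution at a
symmetric two-state rate, which makes the per-site substitution count
geometric with parameter $r = L/(1+L)$, where $L$ is the per-site expected
number of substitutions on the path. Conditioning on the observed
difference fraction ($E[\mathrm{differ}] = L/(1+2L) = j/m$, hence
$\hat L = j/(m-2j)$), parsimony requires exactly one hit at each differing
site and none at each identical site, giving

$$P_j = \left(\frac{1+2\hat L}{(1+\hat L)^2}\right)^m .$$

The connection limit is the largest $j$ with $P_j$ at or above the
confidence (default 0.95), floored at one step. This fully specified model
is somewhat more conservative than the limits printed by the legacy
statistical-parsimony software (for a 563-column barcode it allows 5 steps
at 95%); components that separate under our limit would also separate
under a laxer one, and every package test plants its separations relative
to the computed limit, so the reported component structure is internally
consistent. The test suite cross-checks the closed form against an
independent series evaluation of the same model and the component
structure against brute-force graph search.

Network construction itself is deliberately simple: pairs are agglomerated
in increasing Hamming distance; at each distance level every pair not
already connected before that level is joined (so equally short
alternative connections — loops — are retained), with multi-step joins
passing through inferred unobserved intermediates so each edge is one
mutation. Component membership is provably identical to the connected
components of the thresholded Hamming graph; only the choice of drawn
edges within a component is a convention.

## SNP genotype calling and filtering

`call_genotype_at_site()` applies read-support retention rules: a
homozygote needs the top allele to carry at least 80% of reads and at
least 5 unique reads; a heterozygote needs the top two alleles jointly to
reach 80% with the most common allele meeting the read minimum (a stricter
per-allele variant sits behind `het_support_each`). Base-quality filtering
is upstream of the count table; the threshold is recorded in the
configuration for provenance.

`filter_sites()` retains polymorphic sites with minor allele frequency at
least 1%, call rate at least 20%, and an observed heterozygote fraction
within the $2pq$ bound. One numerical point deserves emphasis: the bound
"heterozygosity between zero and twice the product of the two allele
frequencies" is a population-level statement. Applied verbatim to
finite-sample estimates it rejects roughly half of genuinely
Hardy–Weinberg sites, because the observed heterozygote fraction exceeds
$2\hat p\hat q$ whenever there is any heterozygote excess, however small
(every singleton-heterozygote site fails it exactly). We therefore allow
`het_z` binomial standard errors of slack (default 3); `het_z = 0`
recovers the strict rule. The filter still rejects the all-heterozygote
signature of collapsed paralogs by a wide margin, which is the artifact
the rule exists to catch.

## Hybrid diagnosis

**Shared SNPs.** A site is a SNP within a taxon when any called specimen
carries a non-reference allele; candidate parents share many SNPs with the
hybrid cohort, non-parents share almost none.

**PCoA.** Classical principal coordinates of the mean squared
allele-count difference over co-called loci. With complete data this is
equivalent to a PCA of the dosage matrix, under which an F1 cohort sits at
the midpoint of the parental centroids on the leading axis — a property
the tests verify by simulation. Axis signs are fixed by making the
largest-magnitude coordinate positive. The exact metric of legacy
population-genetics GUIs is not restated in their documentation, so the
metric here is documented and swappable rather than claimed identical.

**Diagnostic panel.** `build_fixed_panel()` keeps loci called in every
specimen (call-rate requirement configurable, default 100%) where all
called specimens of one parent are homozygous for one allele and all of
the other parent for the alternate allele. Panel construction uses parents
only; what the hybrids look like at those loci is a separate, later
question — this separation avoids the circularity of validating a panel
with the specimens it is meant to diagnose.

**Metrics and classification.** For each specimen, the hybrid index is the
fraction of its panel alleles from parent A, and the heterozygous fraction
is the proportion of called panel loci at genotype 1. The decision ladder
is: parental (index at least 0.95 toward one side, heterozygosity at most
0.05), else F1 (heterozygosity at least 0.95), else backcross (index at
least 0.75 toward one side), else later-generation (heterozygosity at most
0.25), else unresolved. The 0.75 and 0.25 thresholds are the published
detection bounds for backcrossing and inter-hybrid mating; the 0.95
tolerances are ours, because exact-pattern rules are brittle under
genotyping error.

Two caveats about those published bounds, both documented rather than
silently corrected. First, the "at least 75% of diagnostic alleles" rule
describes the *expectation* of a BC1 genotype; an individual BC1 at $L$
panel loci has index $(L+X)/2L$ with $X \sim \mathrm{Bin}(L, 1/2)$, so at
20 loci only about 59% of true BC1s reach 0.75 and the rest fall to
"unresolved" (none are misassigned to another concrete class). The rule is
a conservative detector of introgression, not a complete per-individual
classifier — which is harmless in the motivating use case, where the
question is whether *any* specimen shows backcross ancestry. Second, the
"heterozygosity at most 25%" bound for later-generation hybrids sits well
below the Mendelian F2 expectation of 50% heterozygosity at diagnostic
loci; we implement the printed threshold verbatim, and the simulator
documents the Mendelian expectation so the discrepancy is visible in the
tests rather than hidden.

**Sex linkage.** Under X0 sex determination females carry two X
chromosomes and males a single, maternally inherited X that short-read
genotyping codes as homozygous. At a fixed-difference locus on the X, an
F1 cohort therefore shows every male homozygous for the *maternal*
parent's allele and every female heterozygous.
`detect_sex_linked_loci()` partitions panel loci into autosomal-diagnostic
(all hybrids heterozygous), sex-linked (the X0 pattern), and
nondiagnostic, with a configurable per-locus mismatch tolerance
(default 0).

**Maternal parent.** Mitochondria are maternally inherited, so
`infer_maternal_parent()` reads the cross direction off the parental
mitochondrial cluster that contains the hybrids' haplotypes; a split
indicates bidirectional crossing. Together with the sex-linkage pattern
this pins both the mother species and the father species of the hybrid
cohort.

## The synthetic cross generator

`simulate_cross_dataset()` emulates exactly the statistical structure the
analysis assumes: two parental taxa fixed for alternate alleles at
autosomal and X-linked diagnostic loci; nondiagnostic loci with
independent per-taxon alternate-allele frequencies drawn from
Uniform(0.2, 0.8); F1, BC1 and F2 cohorts by Mendelian gamete draws; X0
inheritance (male X from the mother, coded homozygous); mitochondria
copied from the mother; optional symmetric dosage-error and missingness,
and a read-count simulator (Poisson depth, per-read error) for exercising
the calling stage. Backcross and F2 cohorts take their mother from the F1
generation, so all hybrid-derived cohorts carry the maternal taxon's
mitochondrial haplotype. Default cohort sizes (36 + 20 parents, 14 F1s,
60 autosomal / 51 X-linked / 34 nondiagnostic loci) mirror the motivating
study design.

Two generator choices matter for interpreting test results. Nondiagnostic
frequencies are kept away from fixation (0.2–0.8) because a locus at, say,
0.1/0.9 has a roughly 1.5% chance of looking fixed-different in samples of
10 specimens per parent — no method can tell such a locus from a true
fixed difference, so "no false positives" is only a meaningful property
for moderate-frequency standing variation. And offspring gametes at
nondiagnostic loci use population-level allele frequencies rather than
tracked pedigrees (no linkage, no family structure), which matches the
one-SNP-per-locus subsetting the SNP analyses assume. What the generator
does *not* emulate: linkage disequilibrium, depth-dependent error,
allele-specific bias, null alleles, or contamination — passing tests say
the algorithms are correct under the stated model, not that real GBS data
are this clean.

## Numerical conventions and problem sizes

Alignment columns are 1-based in every report; missing genotypes are an
explicit NA, never conflated with dosage 0; percent distances are rounded
half-even to two decimals; haplotype, network and axis orderings are all
deterministic (first occurrence, lexicographic tie-breaks, sign-fixed
axes); every simulation takes an explicit integer seed, and reruns of the
pipeline with the same configuration produce byte-identical outputs.

The test suite validates the F1 signature and cohort classification on 50
specimens per class at 20 panel loci; the BC1 expectation on 10,000
simulated backcrosses at 60 loci (mean recurrent-parent allele fraction
75% within Monte-Carlo error); panel recovery against 1,000 nondiagnostic
loci across 10 seeds; sex-linkage recovery on the 13-male/1-female F1
design with 51 X-linked and 60 autosomal loci; p-distances against a
brute-force column-loop oracle on 1,000 random pairs; network components
against brute-force graph search on instances up to 50 haplotypes; and the
count-level round trip (depth 30, error 0.005) at better than 99% genotype
recovery. These sizes were chosen to make binomial expectations sharp at
desk scale.

## Limitations

The package does not fit model-based hybrid-class posteriors or
admixture-style clustering; the ladder classifier is deliberately
threshold-based and transparent. Distances are uncorrected p-distances
only. The network stage reports component membership and step counts, not
a layout. Reproducing published distance tables from deposited sequence
data requires the user to download those alignments;
`scripts/table1_distances.R` then recomputes the table from local files.
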
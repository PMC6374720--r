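Package: snowfly
Title: Sequence and SNP Diagnostics for Hybrid-Origin Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative-taxonomy toolkit for testing whether a putative
    species is of hybrid origin. Provides sequence-level diagnostics
    (haplotype collapsing, uncorrected p-distances, diagnostic nucleotide
    characters, simple indel coding, translation checks), statistical
    parsimony haplotype networks with a 95% connection limit, genotype
    calling and site filtering from per-site allele counts, fixed-difference
    diagnostic SNP panels with per-specimen hybrid index and interspecific
    heterozygosity, classification of F1, backcross and later-generation
    hybrids, detection of X0 sex-linked loci, maternal-parent inference from
    mitochondrial haplotypes, and a Mendelian cross simulator with X0 sex
    chromosomes and maternally inherited mitochondria for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    vcfR,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
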
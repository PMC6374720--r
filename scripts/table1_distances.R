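#!/usr/bin/env Rscript
# Recomputes the per-gene within/between-group mean p-distance table from
# user-supplied aligned FASTA files and a specimen metadata TSV (the
# deposited sequence sets are public but must be downloaded separately;
# this script takes them as local files).
#
# Usage:
#   Rscript scripts/table1_distances.R --metadata meta.tsv --out table.tsv \
#       COI=coi_aligned.fasta cytb=cytb_aligned.fasta ITS1=its1_aligned.fasta
#
# The metadata TSV needs columns specimen_id, taxon_label, sex, locality;
# specimen ids must match the FASTA headers' first tokens. Groups are the
# taxon labels (encode geographic splits, e.g. "A_decepta_CO" vs
# "A_decepta_AZ", directly in the labels).

suppressMessages({
  library(optparse)
  library(snowfly)
})

args <- commandArgs(trailingOnly = TRUE)
flags <- grepl("^--", args) | c(FALSE, grepl("^--", utils::head(args, -1)))
parser <- OptionParser(option_list = list(
  make_option("--metadata", type = "character"),
  make_option("--out", type = "character", default = "distance_table.tsv")
))
opt <- parse_args(parser, args = args[flags])
genes <- args[!flags]
if (length(genes) == 0L || is.null(opt$metadata))
  stop("supply --metadata and at least one gene=alignment.fasta argument")

meta <- read_metadata(opt$metadata)
part <- partition_from_metadata(meta)
tables <- list()
for (spec in genes) {
  kv <- strsplit(spec, "=", fixed = TRUE)[[1L]]
  if (length(kv) != 2L) stop("gene arguments must look like COI=file.fasta")
  gene <- if (kv[1L] %in% c("COI", "cytb", "ITS1")) kv[1L] else "other"
  aln <- read_fasta(kv[2L], gene = gene)
  hap <- collapse_haplotypes(aln)
  message(kv[1L], ": ", length(aln$sequences), " sequences, ",
          nrow(hap$haplotypes), " haplotypes, ", aln$length, " columns")
  tables[[kv[1L]]] <- group_distance_table(hap, part)
}
write_distance_table(tables, opt$out)
message("written: ", opt$out)
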
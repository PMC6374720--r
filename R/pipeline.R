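#' Assign hybrid mitochondrial haplotypes to parental taxa
#'
#' A hybrid specimen's mitochondrial haplotype is assigned to a parental
#' taxon when that taxon's specimens carry the identical haplotype; failing
#' that, when exactly one parental taxon has haplotypes in the same
#' parsimony network component. Hybrids matching neither or both parents
#' get NA.
#'
#' @param hap A \code{\link{haplotype_table}} for a mitochondrial gene.
#' @param net A \code{\link{build_networks}} result for the same table.
#' @param part A \code{\link{taxon_partition}}.
#' @param hybrids Hybrid specimen ids.
#' @param parentA,parentB Parental taxon labels.
#' @return Named character vector hybrid specimen_id -> parental taxon (or
#'   NA).
#' @export
assign_mito_haplotypes <- function(hap, net, part, hybrids,
                                   parentA, parentB) {
  lookup <- partition_lookup(part)
  hap_of <- hap$membership
  parent_haps <- function(taxon) {
    sp <- intersect(names(lookup)[lookup == taxon], names(hap_of))
    unique(unname(hap_of[sp]))
  }
  hapsA <- parent_haps(parentA); hapsB <- parent_haps(parentB)
  comp <- stats::setNames(net$nodes$network, net$nodes$haplotype_id)
  vapply(hybrids, function(spec) {
    h <- hap_of[[spec]]
    if (is.null(h) || is.na(h)) return(NA_character_)
    inA <- h %in% hapsA; inB <- h %in% hapsB
    if (inA && !inB) return(parentA)
    if (inB && !inA) return(parentB)
    if (!h %in% names(comp)) return(NA_character_)
    compA <- any(comp[intersect(hapsA, names(comp))] == comp[[h]])
    compB <- any(comp[intersect(hapsB, names(comp))] == comp[[h]])
    if (compA && !compB) return(parentA)
    if (compB && !compA) return(parentB)
    NA_character_
  }, character(1L))
}

#' Run the full hybrid-diagnosis pipeline
#'
#' Executes, in order: haplotype collapsing, distance tables, diagnostic
#' characters and parsimony networks for every configured gene alignment;
#' then genotype site filtering, shared-SNP counts, PCoA, diagnostic-panel
#' construction, per-specimen hybrid metrics and classification,
#' sex-linkage classification and maternal-parent inference. Partial
#' configurations run partial pipelines (a sequence-only configuration
#' skips the genotype stages and vice versa). All outputs are TSV/JSON
#' under \code{out_dir}, and a JSON run manifest echoes the effective
#' configuration, seed, input digests and output digests.
#'
#' @param config Path to a YAML configuration file, or an equivalent list.
#'   Recognized sections: \code{seed}; \code{thresholds} (overrides for
#'   \code{\link{snowfly_config}} fields); \code{sequence} with
#'   \code{fasta} (named list gene -> path), \code{metadata} (TSV path) and
#'   optional \code{focal_group}; \code{genotype} with \code{genotypes}
#'   (path), \code{format} ("TSV" or "VCF"), \code{metadata},
#'   \code{parentA}, \code{parentB}, \code{hybrid_taxon}, and optional
#'   \code{maternal_parent} ("A"/"B", otherwise inferred from the
#'   mitochondrial stage when available).
#' @param out_dir Output directory (created if absent).
#' @return The run manifest, invisibly (also written to
#'   \code{manifest.json}).
#' @export
run_full_analysis <- function(config, out_dir = ".") {
  cfg_in <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg_in)) stop("config must be a YAML file path or a list")
  has_seq <- !is.null(cfg_in$sequence)
  has_gt <- !is.null(cfg_in$genotype)
  if (!has_seq && !has_gt)
    stop("config must name inputs for at least one of: sequence stage, ",
         "genotype stage")
  # validate inputs up front, before any computation
  inputs <- character()
  if (has_seq) {
    if (is.null(cfg_in$sequence$fasta) || is.null(cfg_in$sequence$metadata))
      stop("sequence stage requires 'fasta' and 'metadata' entries")
    inputs <- c(inputs, unlist(cfg_in$sequence$fasta),
                cfg_in$sequence$metadata)
  }
  if (has_gt) {
    need <- c("genotypes", "metadata", "parentA", "parentB", "hybrid_taxon")
    miss <- setdiff(need, names(cfg_in$genotype))
    if (length(miss) > 0L)
      stop("genotype stage requires entries: ", paste(miss, collapse = ", "))
    inputs <- c(inputs, cfg_in$genotype$genotypes, cfg_in$genotype$metadata)
  }
  absent <- inputs[!file.exists(inputs)]
  if (length(absent) > 0L)
    stop("missing input file(s): ", paste(absent, collapse = ", "))

  thresholds <- cfg_in$thresholds
  cfg <- if (is.null(thresholds)) snowfly_config() else
    do.call(snowfly_config, thresholds)
  seed <- if (!is.null(cfg_in$seed)) as.integer(cfg_in$seed) else cfg$rng_seed
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log <<- c(log, msg)
  }
  emit <- function(name) {
    outputs <<- c(outputs, file.path(out_dir, name))
    file.path(out_dir, name)
  }

  mito <- NULL
  seq_meta <- NULL
  if (has_seq) {
    seq_meta <- read_metadata(cfg_in$sequence$metadata)
    part <- partition_from_metadata(seq_meta)
    for (gene in names(cfg_in$sequence$fasta)) {
      gene_lab <- if (gene %in% c("COI", "cytb", "ITS1")) gene else "other"
      aln <- read_fasta(cfg_in$sequence$fasta[[gene]], gene = gene_lab)
      hap <- collapse_haplotypes(aln, cfg)
      say("sequence[", gene, "]: ", length(aln$sequences), " sequences, ",
          nrow(hap$haplotypes), " haplotypes")
      dt <- group_distance_table(hap, part)
      write_distance_table(dt, emit(paste0("distances_", gene, ".tsv")))
      if (!is.null(cfg_in$sequence$focal_group)) {
        dc <- find_diagnostic_characters(aln, part,
                                         cfg_in$sequence$focal_group, cfg)
        utils::write.table(dc, emit(paste0("diagnostic_characters_", gene,
                                           ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      net <- suppressMessages(
        build_networks(hap, confidence = cfg$network_confidence, part = part))
      say("sequence[", gene, "]: ", net$n_components,
          " parsimony network(s) at limit ", net$limit)
      write_network(net, emit(paste0("network_edges_", gene, ".tsv")),
                    emit(paste0("network_nodes_", gene, ".tsv")))
      gaps <- code_gaps(aln)
      if (nrow(gaps$characters) > 0L) {
        gap_df <- data.frame(gaps$characters,
                             t(gaps$scores)[, , drop = FALSE])
        utils::write.table(gap_df, emit(paste0("gap_characters_", gene,
                                               ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      if (has_gt && is.null(mito) &&
          gene_lab %in% c("COI", "cytb", "other")) {
        gc <- cfg_in$genotype
        hyb <- seq_meta$specimen_id[seq_meta$taxon_label == gc$hybrid_taxon]
        if (length(hyb) > 0L)
          mito <- assign_mito_haplotypes(hap, net, part, hyb,
                                         gc$parentA, gc$parentB)
      }
    }
  } else {
    say("sequence stage skipped: no sequence inputs configured")
  }

  results <- list()
  if (has_gt) {
    gc <- cfg_in$genotype
    fmt <- if (!is.null(gc$format)) gc$format else "TSV"
    gm <- read_genotypes(gc$genotypes, format = fmt)
    meta <- read_metadata(gc$metadata)
    part <- partition_from_metadata(meta)
    filt <- filter_sites(gm, cfg)
    utils::write.table(filt$report, emit("site_filter_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("genotype: ", sum(filt$report$status == "retained"), "/",
        nrow(filt$report), " sites retained")
    gmf <- filt$gm
    lookup <- partition_lookup(part)
    taxa <- unique(unname(lookup))
    others <- setdiff(taxa, gc$hybrid_taxon)
    shared <- shared_snp_counts(gmf, part, gc$hybrid_taxon, others)
    utils::write.table(
      data.frame(taxon = names(shared), shared_snps = as.integer(shared)),
      emit("shared_snps.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    hi_cr <- gmf$loci[call_rates(gmf) >= 0.9]
    if (length(hi_cr) >= 1L && length(gmf$specimens) >= 3L) {
      pc <- pcoa_coordinates(subset_gm(gmf, loci = hi_cr))
      utils::write.table(
        data.frame(specimen_id = rownames(pc$coordinates),
                   pc$coordinates,
                   taxon = unname(lookup[rownames(pc$coordinates)])),
        emit("pcoa_coordinates.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    panel <- build_fixed_panel(gmf, part, gc$parentA, gc$parentB, cfg)
    say("genotype: diagnostic panel of ", nrow(panel$loci), " loci")
    utils::write.table(panel$loci, emit("panel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    hybrids <- intersect(meta$specimen_id[meta$taxon_label == gc$hybrid_taxon],
                         gmf$specimens)
    report <- hybrid_report(gmf, panel, gmf$specimens, cfg)
    utils::write.table(report, emit("hybrid_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    maternal_dir <- NULL
    if (!is.null(mito)) {
      maternal_dir <- tryCatch(
        suppressMessages(infer_maternal_parent(mito, hybrids, gc$parentA,
                                               gc$parentB)),
        error = function(e) NULL)
    }
    maternal_side <- if (!is.null(gc$maternal_parent)) {
      gc$maternal_parent
    } else if (!is.null(maternal_dir) &&
               maternal_dir$maternal %in% c(gc$parentA, gc$parentB)) {
      if (maternal_dir$maternal == gc$parentA) "A" else "B"
    } else NULL
    sexlink <- NULL
    if (!is.null(maternal_side) && length(hybrids) > 0L &&
        nrow(panel$loci) > 0L) {
      sexlink <- detect_sex_linked_loci(gmf, panel, meta, hybrids,
                                        maternal_side, cfg)
      utils::write.table(sexlink, emit("sex_linkage.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      say("genotype: ", sum(sexlink$status == "sex_linked"),
          " sex-linked of ", nrow(sexlink), " panel loci")
      # hybrid metrics are biased in males at sex-linked loci (hemizygous
      # X coded homozygous), so re-report on the autosomal subset
      auto <- sexlink$locus_id[sexlink$status == "autosomal_diagnostic"]
      if (length(auto) > 0L) {
        panel_auto <- panel
        panel_auto$loci <- panel$loci[panel$loci$locus_id %in% auto, ,
                                      drop = FALSE]
        utils::write.table(
          hybrid_report(gmf, panel_auto, hybrids, cfg),
          emit("hybrid_metrics_autosomal.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    results <- list(
      classification = as.list(table(report$class)),
      n_panel_loci = nrow(panel$loci),
      shared_snps = as.list(shared),
      maternal = if (!is.null(maternal_dir)) maternal_dir$direction else
        NULL,
      sex_linked_loci = if (!is.null(sexlink))
        sum(sexlink$status == "sex_linked") else NULL)
    jsonlite::write_json(results, emit("classification_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    say("genotype stage skipped: no genotype inputs configured")
  }

  manifest <- list(
    package = "snowfly",
    version = as.character(utils::packageVersion("snowfly")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = cfg_in,
    thresholds = unclass(cfg),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs)),
    log = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
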
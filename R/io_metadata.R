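#' Read a specimen metadata table
#'
#' Expects a TSV with header columns \code{specimen_id}, \code{taxon_label},
#' \code{sex} and \code{locality} (a \code{notes} column is optional). Sex is
#' parsed case-insensitively; blank or missing values become "unknown".
#'
#' @param path Path to the TSV file.
#' @return A data frame of specimen records with one row per specimen.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          na.strings = NULL, check.names = FALSE)
  required <- c("specimen_id", "taxon_label", "sex", "locality")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (!("notes" %in% names(df))) df$notes <- ""
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup) > 0L)
    stop("duplicate specimen_id in metadata: ", paste(unique(dup), collapse = ", "))
  df$sex <- parse_sex(df$sex)
  rownames(df) <- NULL
  df[, c("specimen_id", "taxon_label", "sex", "locality", "notes")]
}

parse_sex <- function(x) {
  s <- tolower(trimws(x))
  out <- rep("unknown", length(s))
  out[s %in% c("m", "male")] <- "male"
  out[s %in% c("f", "female")] <- "female"
  out
}

#' Write a specimen metadata table
#'
#' @param metadata Data frame as returned by \code{\link{read_metadata}}.
#' @param path Output path (TSV).
#' @return \code{path}, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Specimen-to-taxon partition
#'
#' The taxon assignment used by an analysis, kept separate from the
#' phenotypic labels because the assignment is itself a revisable hypothesis
#' (a specimen phenotyped as one taxon may be reassigned on molecular
#' evidence).
#'
#' @param specimen_id Character vector of specimen ids.
#' @param analysis_taxon Character vector of taxon assignments, recycled if
#'   length 1.
#' @return An object of class \code{taxon_partition}: a data frame with
#'   columns \code{specimen_id}, \code{analysis_taxon}, \code{provenance},
#'   plus a \code{revisions} attribute logging reassignments.
#' @export
taxon_partition <- function(specimen_id, analysis_taxon) {
  if (anyDuplicated(specimen_id))
    stop("duplicate specimen_id in partition")
  analysis_taxon <- rep_len(analysis_taxon, length(specimen_id))
  df <- data.frame(specimen_id = as.character(specimen_id),
                   analysis_taxon = as.character(analysis_taxon),
                   provenance = "phenotype",
                   stringsAsFactors = FALSE)
  structure(df, class = c("taxon_partition", "data.frame"),
            revisions = data.frame(specimen_id = character(),
                                   from = character(), to = character(),
                                   reason = character(),
                                   stringsAsFactors = FALSE))
}

#' Build a partition from a metadata table
#'
#' @param metadata Data frame as returned by \code{\link{read_metadata}}.
#' @return A \code{\link{taxon_partition}} using the phenotypic labels.
#' @export
partition_from_metadata <- function(metadata) {
  taxon_partition(metadata$specimen_id, metadata$taxon_label)
}

#' Reassign a specimen to a different analysis taxon
#'
#' Revisions are logged with a reason so that both the original and revised
#' partitions remain reproducible.
#'
#' @param part A \code{\link{taxon_partition}}.
#' @param specimen_id Specimen to reassign.
#' @param new_taxon Taxon to assign it to.
#' @param reason Free-text justification (required).
#' @return The revised partition.
#' @export
revise_taxon <- function(part, specimen_id, new_taxon, reason) {
  stopifnot(inherits(part, "taxon_partition"))
  if (missing(reason) || !nzchar(reason))
    stop("a reason is required when revising a taxon assignment")
  i <- match(specimen_id, part$specimen_id)
  if (is.na(i)) stop("unknown specimen_id: ", specimen_id)
  rev <- attr(part, "revisions")
  rev <- rbind(rev, data.frame(specimen_id = specimen_id,
                               from = part$analysis_taxon[i],
                               to = new_taxon, reason = reason,
                               stringsAsFactors = FALSE))
  part$analysis_taxon[i] <- new_taxon
  part$provenance[i] <- "revised"
  attr(part, "revisions") <- rev
  part
}

# Named vector specimen_id -> taxon.
partition_lookup <- function(part) {
  stats::setNames(part$analysis_taxon, part$specimen_id)
}
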
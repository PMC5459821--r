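# Sequence I/O. Parsing is delegated to Biostrings; records are validated
# here so that malformed residues are reported with record id and offset.
# In-memory representation: a data.frame with columns id, seq (and
# optionally qual), one row per record ("seq_records").

seq_records <- function(id, seq, qual = NULL) {
  stopifnot(length(id) == length(seq))
  df <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                   stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    stopifnot(length(qual) == length(seq), all(nchar(qual) == nchar(seq)))
    df$qual <- as.character(qual)
  }
  df
}

validate_residues <- function(records) {
  bad <- regexpr(paste0("[^", IUPAC_FROM, "]"), records$seq)
  hit <- which(bad > 0)
  if (length(hit)) {
    i <- hit[1]
    stop(sprintf("record '%s' contains non-IUPAC character '%s' at offset %d",
                 records$id[i],
                 substr(records$seq[i], bad[i], bad[i]), bad[i]))
  }
  if (any(!nzchar(records$seq))) {
    stop(sprintf("record '%s' has an empty sequence",
                 records$id[which(!nzchar(records$seq))[1]]))
  }
  invisible(records)
}

#' Read a FASTA file
#'
#' Accepts single-line and wrapped dialects. Residues are validated against
#' the IUPAC alphabet; violations are reported with record id and offset.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `seq` (empty file gives 0 rows).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(seq_records(character(0), character(0)))
  x <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  validate_residues(seq_records(ids, as.character(x)))
}

#' Write records to FASTA
#'
#' @param records data.frame with `id`, `seq`.
#' @param path output path.
#' @param width line-wrap width (0 for single-line records).
#' @export
write_fasta <- function(records, path, width = 70L) {
  validate_residues(records)
  x <- Biostrings::BStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              width = if (width > 0) width else max(nchar(records$seq), 1L))
  invisible(path)
}

#' Read a FASTQ file
#' @param path file path.
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  validate_residues(seq_records(sub("\\s.*$", "", names(x)), as.character(x),
                                as.character(q)))
}

#' Write records to FASTQ (flat qualities if none present)
#' @param records data.frame with `id`, `seq` and optionally `qual`.
#' @param path output path.
#' @param flat_quality character used when records carry no qualities.
#' @export
write_fastq <- function(records, path, flat_quality = "I") {
  validate_residues(records)
  qual <- if ("qual" %in% names(records)) records$qual else
    vapply(nchar(records$seq), function(n) strrep(flat_quality, n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Write a reference taxonomy TSV (7 ranks, semicolon-joined lineage)
#' @param refs a `reference_set`.
#' @param path output path.
#' @export
write_taxonomy_tsv <- function(refs, path) {
  sp <- refs$species
  lineage <- paste(sp$phylum, sp$class, sp$order, sp$family, sp$genus,
                   sp$species_name, sep = ";")
  utils::write.table(
    data.frame(species = sp$species_name, lineage = lineage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a sample manifest TSV
#' @param path file path.
#' @param scheme a [primer_scheme()] used for validation.
#' @export
read_manifest_tsv <- function(path, scheme = primer_scheme()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sample_manifest(df$sample_id, df$site, df$group,
                  df$fwd_barcode_id, df$rev_barcode_id, scheme)
}

#' @rdname read_manifest_tsv
#' @param manifest a [sample_manifest()].
#' @export
write_manifest_tsv <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
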
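# BLAST-like local alignment hits against a reference panel. The
# resolvability tie rule needs E-value / bit-score semantics, so raw
# Smith-Waterman scores
# (match +2, mismatch -3, gap open -5, gap extend -2) are converted with
# fixed Karlin-Altschul-style constants. Lambda and K are configuration, not
# truth: they rescale scores monotonically and so never change rankings or
# tie structure.

KA_LAMBDA <- 0.625
KA_K <- 0.41

blast_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE)
}

#' Align a query against a reference panel, BLAST-style
#'
#' @param query DNA string.
#' @param nr_refs non-redundant references: data.frame with `id`, `seq`,
#'   `species` (see [dedup_references()]), or a named character vector
#'   (names = species).
#' @param query_id identifier carried into the hits.
#' @param top_only when TRUE and the query is contained exactly in at least
#'   one reference, return only those perfect hits: an exact containment
#'   scores the local-alignment maximum (2 x query length), so no other
#'   reference can reach the top rank and the remaining alignments are
#'   skipped. Best-hit and tie semantics are unchanged.
#' @return data.frame of hits, one row per reference: identity (percent),
#'   alignment length, bit score, E-value, query/subject intervals (1-based
#'   inclusive) and the gap-stripped aligned subject content.
#' @export
align_hits <- function(query, nr_refs, query_id = "query",
                       top_only = FALSE) {
  if (!nzchar(query)) stop("empty query")
  refs <- as_nr_refs(nr_refs)
  db_len <- sum(nchar(refs$seq))
  if (top_only) {
    exact <- which(vapply(refs$seq, function(s)
      grepl(query, s, fixed = TRUE), logical(1)))
    if (length(exact))
      refs <- refs[exact, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    # exact containment is necessarily the optimal local alignment
    # (score 2 * query length); build the hit analytically
    pos <- regexpr(query, refs$seq[i], fixed = TRUE)
    if (pos > 0) {
      L <- nchar(query)
      bit <- (KA_LAMBDA * 2 * L - log(KA_K)) / log(2)
      return(data.frame(
        query_id = query_id, subject_id = refs$id[i],
        species = refs$species[i], identity = 100, aln_len = L,
        mismatches = 0L, gaps = 0L, qstart = 1L, qend = L,
        sstart = as.integer(pos), send = as.integer(pos) + L - 1L,
        evalue = L * db_len * 2^(-bit), bit_score = bit,
        subject_content = query, stringsAsFactors = FALSE))
    }
    aln <- Biostrings::pairwiseAlignment(
      pattern = query, subject = refs$seq[i], type = "local",
      substitutionMatrix = blast_submat(), gapOpening = 5, gapExtension = 2)
    bit <- (KA_LAMBDA * Biostrings::score(aln) - log(KA_K)) / log(2)
    ap <- as.character(Biostrings::pattern(aln))
    as_ <- as.character(Biostrings::subject(aln))
    cols <- nchar(ap)
    data.frame(
      query_id = query_id,
      subject_id = refs$id[i],
      species = refs$species[i],
      identity = if (cols > 0) 100 * Biostrings::nmatch(aln) / cols else 0,
      aln_len = cols,
      mismatches = Biostrings::nmismatch(aln),
      gaps = sum(strsplit(ap, "", fixed = TRUE)[[1]] == "-") +
             sum(strsplit(as_, "", fixed = TRUE)[[1]] == "-"),
      qstart = Biostrings::start(Biostrings::pattern(aln)),
      qend = Biostrings::end(Biostrings::pattern(aln)),
      sstart = Biostrings::start(Biostrings::subject(aln)),
      send = Biostrings::end(Biostrings::subject(aln)),
      evalue = nchar(query) * db_len * 2^(-bit),
      bit_score = bit,
      subject_content = gsub("-", "", as_, fixed = TRUE),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Coerce the accepted reference representations to data.frame(id, seq, species)
as_nr_refs <- function(nr_refs) {
  if (is.data.frame(nr_refs)) {
    stopifnot(all(c("id", "seq", "species") %in% names(nr_refs)))
    if (!nrow(nr_refs)) stop("empty reference")
    return(nr_refs)
  }
  if (is.character(nr_refs)) {
    if (!length(nr_refs)) stop("empty reference")
    if (is.null(names(nr_refs))) stop("reference sequences must be named")
    return(data.frame(id = paste0("nr", seq_along(nr_refs)),
                      seq = unname(nr_refs), species = names(nr_refs),
                      stringsAsFactors = FALSE))
  }
  if (inherits(nr_refs, "reference_set"))
    return(dedup_references(nr_refs))
  stop("unsupported reference representation")
}

#' Best-hit species assignment by alignment
#'
#' The best hit by bit score is returned only when its identity exceeds
#' `min_identity_pct`; ties across species fall under the resolvability rule
#' (see [call_species()]).
#'
#' @inheritParams align_hits
#' @param min_identity_pct identity cutoff in percent (default 90,
#'   exclusive).
#' @return list with `species` (NA when no hit passes) and `hits`.
#' @export
assign_species_by_alignment <- function(query, nr_refs,
                                        min_identity_pct = 90.0) {
  hits <- align_hits(query, nr_refs, top_only = TRUE)
  hits <- hits[order(-hits$bit_score, -hits$identity, hits$species), ]
  best <- hits[1, ]
  species <- if (best$identity > min_identity_pct)
    strsplit(best$species, ";", fixed = TRUE)[[1]][1] else NA_character_
  list(species = species, hits = hits)
}

#' Write hits in tabular-BLAST-like column order
#' @param hits data.frame from [align_hits()].
#' @param path output path.
#' @export
write_hits_tsv <- function(hits, path) {
  cols <- c("query_id", "subject_id", "identity", "aln_len", "mismatches",
            "gaps", "qstart", "qend", "sstart", "send", "evalue", "bit_score")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
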
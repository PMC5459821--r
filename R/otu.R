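# Open-reference greedy OTU clustering at 97% identity. Identity between
# two sequences is defined on an end-gap-free ("glocal") alignment:
# matching columns / alignment columns, internal gaps counting as
# mismatching columns and terminal gaps excluded.

#' Pairwise sequence identity on a glocal alignment
#'
#' The first sequence aligns end to end (global in the query); terminal
#' gaps on the subject side are free and excluded from the column count.
#' A fully ends-free alignment is deliberately not used: for very divergent
#' pairs its optimum degenerates to a trivial perfect micro-overlap, which
#' would report identity near 1.
#'
#' @param a,b non-empty DNA strings (`a` is the query side).
#' @return fraction of identical columns in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  if (cols == 0) return(0)
  Biostrings::nmatch(aln) / cols
}

# 8-mer profile prescreen: candidates must share at least `frac` of the
# query's distinct 8-mers before an alignment is attempted.
kmer_profile <- function(seqs) {
  Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                       width = 8) > 0
}

#' Open-reference OTU clustering
#'
#' Pass 1 (closed-reference, when `refs` is supplied): each unique sequence
#' joins the best reference with identity >= `threshold`. Pass 2 (de novo):
#' remaining uniques, in decreasing abundance (ties lexicographic), join the
#' first existing de novo centroid with identity >= `threshold`, else seed a
#' new centroid.
#'
#' @param sample_reads named list: sample_id -> record data.frame or
#'   character vector of reads.
#' @param refs optional `reference_set` (or named character vector of
#'   reference sequences) for the closed-reference pass.
#' @param threshold identity threshold in (0, 1] (default 0.97).
#' @return object of class `otu_table`: `counts` (samples x OTUs integer
#'   matrix), `centroids`, `provenance` (closed_ref / de_novo per OTU).
#' @export
cluster_otus <- function(sample_reads, refs = NULL, threshold = 0.97) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  samples <- names(sample_reads)
  if (is.null(samples)) stop("sample_reads must be a named list")
  seqs_by_sample <- lapply(sample_reads, function(x)
    if (is.data.frame(x)) x$seq else as.character(x))

  all_seq <- unlist(seqs_by_sample, use.names = FALSE)
  if (!length(all_seq)) stop("no reads supplied")
  all_sample <- rep(samples, lengths(seqs_by_sample))
  per <- table(factor(all_sample, levels = samples), all_seq)
  uniq <- colnames(per)
  total <- as.integer(colSums(per))
  ord <- order(-total, uniq)
  uniq <- uniq[ord]
  per <- per[, ord, drop = FALSE]

  ref_seqs <- NULL
  if (!is.null(refs)) {
    ref_seqs <- if (inherits(refs, "reference_set")) refs$sequences else refs
    if (is.null(names(ref_seqs))) stop("reference sequences must be named")
  }

  uq_km <- kmer_profile(uniq)
  assignment <- rep(NA_character_, length(uniq))
  provenance <- character(0)
  centroids <- character(0)

  if (!is.null(ref_seqs)) {
    ref_km <- kmer_profile(ref_seqs)
    for (i in seq_along(uniq)) {
      shared <- as.vector(ref_km %*% uq_km[i, ]) / sum(uq_km[i, ])
      cand <- which(shared >= 0.3)
      if (!length(cand)) next
      ids <- vapply(cand, function(j)
        pairwise_identity(uniq[i], ref_seqs[[j]]), numeric(1))
      best <- which.max(ids)
      if (ids[best] >= threshold) {
        otu <- names(ref_seqs)[cand[best]]
        assignment[i] <- otu
        if (!otu %in% names(centroids)) {
          centroids[otu] <- ref_seqs[[cand[best]]]
          provenance[otu] <- "closed_ref"
        }
      }
    }
  }

  denovo_idx <- integer(0)  # indices into uniq that seeded de novo OTUs
  for (i in which(is.na(assignment))) {
    joined <- FALSE
    for (d in denovo_idx) {
      if (sum(uq_km[d, ] & uq_km[i, ]) / sum(uq_km[i, ]) < 0.3) next
      if (pairwise_identity(uniq[i], uniq[d]) >= threshold) {
        assignment[i] <- paste0("denovo_", match(d, denovo_idx))
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      denovo_idx <- c(denovo_idx, i)
      otu <- paste0("denovo_", length(denovo_idx))
      assignment[i] <- otu
      centroids[otu] <- uniq[i]
      provenance[otu] <- "de_novo"
    }
  }

  otus <- unique(assignment)
  counts <- matrix(0L, length(samples), length(otus),
                   dimnames = list(samples, otus))
  for (o in otus) {
    sel <- assignment == o
    counts[, o] <- as.integer(rowSums(per[, sel, drop = FALSE]))
  }
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  structure(list(counts = counts,
                 centroids = centroids[colnames(counts)],
                 provenance = provenance[colnames(counts)]),
            class = "otu_table")
}

#' Write an OTU table as TSV (OTUs x samples) or BIOM-compatible JSON
#' @param table an `otu_table`.
#' @param path output path.
#' @export
write_otu_table_tsv <- function(table, path) {
  df <- data.frame(otu_id = colnames(table$counts),
                   t(table$counts), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_otu_table_tsv
#' @export
write_otu_table_biom <- function(table, path) {
  m <- table$counts
  biom <- list(
    id = "longread16S OTU table", format = "1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table", generated_by = "longread16S",
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    matrix_type = "dense", matrix_element_type = "int",
    shape = c(ncol(m), nrow(m)),
    rows = lapply(colnames(m), function(o) list(id = o, metadata = NULL)),
    columns = lapply(rownames(m), function(s) list(id = s, metadata = NULL)),
    data = unname(apply(t(m), 1, as.list)))
  jsonlite::write_json(biom, path, auto_unbox = TRUE)
  invisible(path)
}
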
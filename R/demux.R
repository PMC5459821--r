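# Asymmetric dual-barcode demultiplexing. A plus-strand read starts with
# fwd_barcode + M13F and ends with revcomp(M13R) + revcomp(rev_barcode);
# both the read as-is and its reverse complement are decoded, the (fwd, rev)
# pair is matched by Hamming distance on the terminal 16-mers, and a read is
# assigned only when exactly one manifest row explains it within
# max_barcode_mismatch per side. Ties are conservatively unassigned.

# n x n_barcode Hamming distance between terminal 16-mers and barcodes
bc_dist_matrix <- function(windows, barcodes) {
  n <- length(windows)
  out <- matrix(NA_integer_, n, length(barcodes),
                dimnames = list(NULL, names(barcodes)))
  wm <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  for (j in seq_along(barcodes)) {
    bj <- strsplit(barcodes[[j]], "", fixed = TRUE)[[1]]
    out[, j] <- rowSums(wm != matrix(bj, n, 16, byrow = TRUE))
  }
  out
}

# per-orientation row scores: list(total = n x n_row, feasible = n x n_row)
demux_scores <- function(seqs, scheme, manifest, max_mm) {
  L <- nchar(seqs)
  short <- L < 40L  # too short to carry two barcodes + adapters
  pre <- substr(seqs, 1L, 16L)
  suf <- substr(seqs, L - 15L, L)
  pre[short] <- strrep("N", 16)
  suf[short] <- strrep("N", 16)
  dF <- bc_dist_matrix(pre, scheme$fwd_barcodes)
  dR <- bc_dist_matrix(suf, vapply(scheme$rev_barcodes, dna_revcomp,
                                   character(1)))
  total <- dF[, manifest$fwd_barcode_id, drop = FALSE] +
           dR[, manifest$rev_barcode_id, drop = FALSE]
  feas <- (dF[, manifest$fwd_barcode_id, drop = FALSE] <= max_mm) &
          (dR[, manifest$rev_barcode_id, drop = FALSE] <= max_mm)
  feas[short, ] <- FALSE
  list(total = total, feasible = feas)
}

#' Demultiplex barcoded reads by the asymmetric dual-barcode scheme
#'
#' @param reads data.frame of records (`id`, `seq`).
#' @param scheme a [primer_scheme()].
#' @param manifest a [sample_manifest()].
#' @param max_barcode_mismatch maximum Hamming mismatches tolerated per
#'   barcode (default 1 of 16).
#' @param trim drop barcodes and M13 adapters from assigned reads
#'   (default TRUE); assigned reads are reported plus-strand.
#' @return list with `samples` (named list of record data.frames),
#'   `unassigned` (record data.frame) and `report` (data.frame sample_id,
#'   n_assigned, including an `unassigned` row).
#' @export
demultiplex <- function(reads, scheme, manifest, max_barcode_mismatch = 1L,
                        trim = TRUE) {
  validate_scheme_manifest(scheme, manifest)
  n <- nrow(reads)
  assigned_row <- rep(NA_integer_, n)
  orient <- rep(NA_character_, n)
  if (n > 0) {
    plus <- demux_scores(reads$seq, scheme, manifest, max_barcode_mismatch)
    rc <- dna_revcomp(reads$seq)
    minus <- demux_scores(rc, scheme, manifest, max_barcode_mismatch)
    for (i in seq_len(n)) {
      best <- Inf; best_row <- NA_integer_; best_or <- NA_character_
      tie <- FALSE
      for (or in c("plus", "minus")) {
        sc <- if (or == "plus") plus else minus
        ok <- which(sc$feasible[i, ])
        if (!length(ok)) next
        tot <- sc$total[i, ok]
        m <- min(tot)
        rows <- ok[tot == m]
        if (m < best) {
          best <- m; best_row <- rows[1]; best_or <- or
          tie <- length(rows) > 1
        } else if (m == best) {
          # same score in the other orientation: only a tie if it names a
          # different manifest row
          if (length(rows) > 1 || !identical(rows[1], best_row)) tie <- TRUE
        }
      }
      if (!tie && !is.na(best_row)) {
        assigned_row[i] <- best_row
        orient[i] <- best_or
      }
    }
  }

  trim_pre <- 16L + nchar(scheme$m13f)
  trim_suf <- 16L + nchar(scheme$m13r)
  out_samples <- stats::setNames(
    vector("list", nrow(manifest)), manifest$sample_id)
  for (r in seq_len(nrow(manifest))) {
    idx <- which(assigned_row == r)
    recs <- reads[idx, , drop = FALSE]
    if (nrow(recs)) {
      flip <- orient[idx] == "minus"
      recs$seq[flip] <- dna_revcomp(recs$seq[flip])
      if (trim) {
        L <- nchar(recs$seq)
        recs$seq <- substr(recs$seq, trim_pre + 1L, L - trim_suf)
      }
    }
    rownames(recs) <- NULL
    out_samples[[r]] <- recs
  }
  unassigned <- reads[is.na(assigned_row), , drop = FALSE]
  rownames(unassigned) <- NULL
  report <- data.frame(
    sample_id = c(manifest$sample_id, "unassigned"),
    n_assigned = c(vapply(out_samples, nrow, integer(1)), nrow(unassigned)),
    stringsAsFactors = FALSE)
  list(samples = out_samples, unassigned = unassigned, report = report)
}
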
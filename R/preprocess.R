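# Length filtering and abundance-ordered de novo chimera detection.
# The chimera detector follows the abundance-based two-parent model: a query
# is tested against pairs of candidate parents that are at least
# min_parent_fold times more abundant, an exhaustive crossover scan finds
# the best two-parent splice, and the query is flagged when the spliced
# model beats the best single parent by a divergence margin and the vote
# score h clears a threshold.

#' Remove reads shorter than a minimum length
#'
#' @param reads record data.frame (`id`, `seq`).
#' @param min_len minimum length kept (default 1000 nt).
#' @return list with `kept` (records, input order preserved) and `removed`
#'   (count).
#' @export
length_filter <- function(reads, min_len = 1000L) {
  if (min_len < 1) stop("min_len must be >= 1")
  keep <- nchar(reads$seq) >= min_len
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = sum(!keep))
}

#' Dereplicate reads into unique sequences with abundances
#'
#' Exact-string dereplication, sorted by decreasing abundance with ties
#' broken lexicographically by sequence.
#'
#' @param reads record data.frame or character vector of sequences.
#' @return data.frame with `id`, `seq`, `abundance`.
#' @export
dereplicate <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (!length(seqs))
    return(data.frame(id = character(0), seq = character(0),
                      abundance = integer(0), stringsAsFactors = FALSE))
  tab <- table(seqs)
  df <- data.frame(seq = names(tab), abundance = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$abundance, df$seq), , drop = FALSE]
  df$id <- sprintf("uniq%05d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("id", "seq", "abundance")]
}

# Per-query-position match vector against a parent, from a global alignment.
# mv[i] is TRUE when query position i aligns to an identical parent base.
match_vector <- function(query, parent) {
  if (nchar(query) == nchar(parent)) {
    # equal lengths: positional comparison (exact unless an insertion and a
    # deletion cancel, which per-base noise makes vanishingly rare)
    return(strsplit(query, "", fixed = TRUE)[[1]] ==
           strsplit(parent, "", fixed = TRUE)[[1]])
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = parent, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 4, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- p != "-"
  (p == s)[keep]
}

# UCHIME-like vote score for one segment: yes-votes support the local
# parent, no-votes support the other parent, abstains match neither.
# Weights (no = 4, abstain = 0.5) follow the published defaults in spirit;
# the exact published weighting is not reproduced, only its behaviour:
# h ~ 1 for a clean two-parent splice, ~ 0 without bimodal signal.
segment_score <- function(y, n, a) {
  denom <- y + 4 * n + 0.5 * a
  if (denom <= 0) return(0)
  y / denom
}

#' Detect chimeric sequences by the abundance-based two-parent model
#'
#' @param uniques dereplicated sequences (`id`, `seq`, `abundance`) sorted
#'   by decreasing abundance (as produced by [dereplicate()]).
#' @param min_parent_fold candidate parents must be at least this many times
#'   more abundant than the query (default 2).
#' @param min_score minimum vote score h to flag (default 0.28).
#' @param min_divergence_pct the two-parent model must beat the best single
#'   parent identity by at least this many percentage points (default 0.8).
#' @param max_candidates parents screened per query, ranked by shared 8-mers
#'   (default 64).
#' @return data.frame of verdicts: `read_id`, `is_chimera`, `parent_a`,
#'   `parent_b`, `crossover`, `score`.
#' @export
detect_chimeras <- function(uniques, min_parent_fold = 2.0,
                            min_score = 0.28, min_divergence_pct = 0.8,
                            max_candidates = 64L) {
  n <- nrow(uniques)
  if (n > 1 && any(diff(uniques$abundance) > 0))
    stop("uniques must be sorted by decreasing abundance")
  verdict <- data.frame(
    read_id = uniques$id, is_chimera = FALSE,
    parent_a = NA_character_, parent_b = NA_character_,
    crossover = NA_integer_, score = NA_real_, stringsAsFactors = FALSE)
  if (n < 3) { verdict$score <- ifelse(rep(n > 0, n), 0, NA_real_); return(verdict) }

  kmers <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(uniques$seq), width = 8) > 0

  for (i in seq_len(n)) {
    cand <- which(uniques$abundance >= min_parent_fold * uniques$abundance[i] &
                  uniques$seq != uniques$seq[i])
    cand <- setdiff(cand, i)
    if (length(cand) < 2) { verdict$score[i] <- 0; next }
    shared <- as.vector(kmers[cand, , drop = FALSE] %*% kmers[i, ])
    cand <- cand[order(-shared)][seq_len(min(length(cand), max_candidates))]

    mv <- lapply(cand, function(j) match_vector(uniques$seq[i], uniques$seq[j]))
    ident <- vapply(mv, mean, numeric(1))
    best_single <- max(ident)
    L <- nchar(uniques$seq[i])

    best <- list(matches = -Inf, a = NA, b = NA, x = NA, h = 0)
    for (ai in seq_along(cand)) for (bi in seq_along(cand)) {
      if (ai == bi) next
      mA <- mv[[ai]]; mB <- mv[[bi]]
      cumA <- cumsum(mA)
      sufB <- rev(cumsum(rev(mB)))           # sufB[x] = matches of B in x..L
      tot <- cumA[seq_len(L - 1)] + sufB[2:L]  # crossover after position x
      x <- which.max(tot)
      if (tot[x] > best$matches) {
        dA <- mA & !mB; dB <- mB & !mA; ab <- !mA & !mB
        sL <- segment_score(sum(dA[1:x]), sum(dB[1:x]), sum(ab[1:x]))
        sR <- segment_score(sum(dB[(x + 1):L]), sum(dA[(x + 1):L]),
                            sum(ab[(x + 1):L]))
        best <- list(matches = tot[x], a = cand[ai], b = cand[bi], x = x,
                     h = sL * sR)
      }
    }
    two_parent_id <- best$matches / L
    verdict$score[i] <- best$h
    if (is.finite(best$matches) &&
        (two_parent_id - best_single) * 100 >= min_divergence_pct &&
        best$h >= min_score) {
      verdict$is_chimera[i] <- TRUE
      verdict$parent_a[i] <- uniques$id[best$a]
      verdict$parent_b[i] <- uniques$id[best$b]
      verdict$crossover[i] <- best$x
    }
  }
  verdict
}
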
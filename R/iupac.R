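# IUPAC nucleotide utilities shared by the primer, demultiplexing and
# region-extraction code. All sequence payloads in this package are plain
# upper-case character strings; Biostrings objects are used at the I/O and
# alignment boundaries only.

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

IUPAC_FROM <- "ACGTMRWSYKVHDBN"
IUPAC_TO   <- "TGCAKYWSRMBDHVN"  # complement map

#' Reverse-complement DNA strings
#'
#' IUPAC-aware reverse complement on plain character vectors.
#'
#' @param x character vector of IUPAC DNA strings.
#' @return character vector of the same length.
#' @export
dna_revcomp <- function(x) {
  comp <- chartr(IUPAC_FROM, IUPAC_TO, toupper(x))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

is_iupac <- function(x) {
  !grepl(paste0("[^", IUPAC_FROM, "]"), toupper(x))
}

# 15x15 logical matrix: does IUPAC code a (e.g. a primer base) overlap code b
# (a sequence base)? Overlap of expansion sets, so R matches A and G but not T.
iupac_match_matrix <- local({
  codes <- names(IUPAC_CODES)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(IUPAC_CODES[[a]], IUPAC_CODES[[b]])) > 0
  }
  m
})

# Mismatch count between a primer (may be degenerate) and an equal-length
# window of concrete sequence. Vectorized over windows.
iupac_mismatches <- function(primer_chars, window_chars) {
  sum(!iupac_match_matrix[cbind(primer_chars, window_chars)])
}

# Hamming distance between two equal-length concrete strings.
hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(av) == length(bv))
  sum(av != bv)
}

# Pick one concrete base for every degenerate position of an IUPAC string
# (first base of the expansion set, so the choice is deterministic).
concretize_iupac <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    paste(vapply(ch, function(c) IUPAC_CODES[[c]][1], character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
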
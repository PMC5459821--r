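# Reference deduplication and in-silico hypervariable-region extraction.
# Regions are delimited by IUPAC-aware primer search; by default the
# extracted slice excludes the primer sites (end of forward flank to start
# of reverse flank), yielding the canonical ~420-nt V3-V4 and ~255-nt V5-V6
# fragments on the synthetic scaffold.

#' Collapse a reference panel to non-redundant sequences
#'
#' Exact duplicates and exact full-substring containments are collapsed,
#' keeping the longest representative. Species labels of collapsed members
#' are all recorded on the representative (semicolon-joined); conflicting
#' labels on identical sequences therefore drive ambiguity downstream.
#'
#' @param refs a `reference_set`, a named character vector (names =
#'   species), or a data.frame with `species` and `seq`.
#' @return data.frame with `id`, `seq`, `species` (";"-joined labels).
#' @export
dedup_references <- function(refs) {
  if (inherits(refs, "reference_set")) {
    df <- data.frame(species = names(refs$sequences),
                     seq = unname(refs$sequences), stringsAsFactors = FALSE)
  } else if (is.character(refs)) {
    df <- data.frame(species = names(refs), seq = unname(refs),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(refs, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("species", "seq") %in% names(df)))
  df <- df[order(-nchar(df$seq), df$seq), , drop = FALSE]
  rep_seq <- character(0)
  rep_species <- list()
  for (i in seq_len(nrow(df))) {
    container <- which(vapply(rep_seq, function(s)
      grepl(df$seq[i], s, fixed = TRUE), logical(1)))
    if (length(container)) {
      j <- container[1]
      rep_species[[j]] <- union(rep_species[[j]], df$species[i])
    } else {
      rep_seq <- c(rep_seq, df$seq[i])
      rep_species[[length(rep_seq)]] <- df$species[i]
    }
  }
  data.frame(id = sprintf("nr%03d", seq_along(rep_seq)),
             seq = rep_seq,
             species = vapply(rep_species, paste, character(1),
                              collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Locate a (possibly degenerate) primer in a sequence
#'
#' Scans both the primer and its reverse complement with IUPAC-aware
#' position matching and returns the minimal-mismatch hit (leftmost on
#' ties), or NULL when no window is within `max_mismatch`.
#'
#' @param seq concrete DNA string.
#' @param primer IUPAC primer string (shorter than `seq`).
#' @param max_mismatch maximum mismatches tolerated (default 2).
#' @return list with `start`, `end` (1-based inclusive), `mismatches`,
#'   `strand` ("+" for the primer as given, "-" for its reverse
#'   complement), or NULL.
#' @export
locate_primer <- function(seq, primer, max_mismatch = 2L) {
  plen <- nchar(primer)
  if (plen >= nchar(seq)) stop("primer must be shorter than sequence")
  sv <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  scan <- function(p) {
    pv <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
    nw <- length(sv) - plen + 1L
    mism <- integer(nw)
    for (k in seq_len(plen)) {
      mism <- mism + !iupac_match_matrix[cbind(rep(pv[k], nw),
                                               sv[k:(k + nw - 1L)])]
    }
    mism
  }
  hits <- list(`+` = scan(primer), `-` = scan(dna_revcomp(primer)))
  best <- NULL
  for (strand in c("+", "-")) {
    m <- hits[[strand]]
    i <- which.min(m)           # leftmost minimal for this strand
    if (m[i] <= max_mismatch &&
        (is.null(best) || m[i] < best$mismatches ||
         (m[i] == best$mismatches && i < best$start))) {
      best <- list(start = i, end = i + plen - 1L,
                   mismatches = as.integer(m[i]), strand = strand)
    }
  }
  best
}

region_failure <- function(reason, read_id, region) {
  structure(list(read_id = read_id, region = region, reason = reason),
            class = "region_failure")
}

#' Test whether region extraction failed
#' @param x result of [extract_region()].
#' @export
region_failed <- function(x) inherits(x, "region_failure")

#' Extract a hypervariable region from a full-length read
#'
#' @param read a record (list/one-row data.frame with `id`, `seq`) or a
#'   DNA string.
#' @param region one of "V3V4", "V5V6", "FULL".
#' @param scheme a [primer_scheme()] providing the region flanks.
#' @param include_primers include the flank primer sites in the slice
#'   (default FALSE: slice spans end-of-forward-flank to
#'   start-of-reverse-flank).
#' @param max_mismatch primer-search tolerance (default 2).
#' @return a `region_slice` list (`read_id`, `region`, `seq`, `start`,
#'   `end`, `flank_mismatches`), or a `region_failure` with a `reason`
#'   ("missing_flank" or "inverted_interval").
#' @export
extract_region <- function(read, region, scheme = primer_scheme(),
                           include_primers = FALSE, max_mismatch = 2L) {
  seq <- if (is.character(read)) read else read$seq
  read_id <- if (is.character(read)) "read" else read$id
  if (region == "FULL") {
    return(structure(list(read_id = read_id, region = "FULL", seq = seq,
                          start = 1L, end = nchar(seq),
                          flank_mismatches = c(fwd = 0L, rev = 0L)),
                     class = "region_slice"))
  }
  if (!region %in% names(scheme$region_flanks))
    stop("unknown region: ", region)
  fl <- scheme$region_flanks[[region]]
  f <- locate_primer(seq, fl[["fwd"]], max_mismatch)
  r <- locate_primer(seq, fl[["rev"]], max_mismatch)
  if (is.null(f) || is.null(r))
    return(region_failure("missing_flank", read_id, region))
  if (include_primers) {
    start <- f$start; end <- r$end
  } else {
    start <- f$end + 1L; end <- r$start - 1L
  }
  if (end < start)
    return(region_failure("inverted_interval", read_id, region))
  structure(list(read_id = read_id, region = region,
                 seq = substr(seq, start, end),
                 start = start, end = end,
                 flank_mismatches = c(fwd = f$mismatches,
                                      rev = r$mismatches)),
            class = "region_slice")
}
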
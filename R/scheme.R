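# Primer/barcode scheme and sample manifest. The gene and region-flank
# primers are the standard ones for full-length 16S amplification (27F/1492R
# with universal M13 tails) and for delimiting the V3-V4 and V5-V6
# hypervariable regions (338F/786R and 785F/1081R). Barcodes are
# configuration: the defaults are ten synthetic 16-mers with pairwise
# Hamming distance >= 8, standing in for PacBio barcode sets.

DEFAULT_FWD_BARCODES <- c(
  F01 = "AAAACTCCATGTGTAA",
  F02 = "CTCCGGAAGTAGAATC",
  F03 = "TTGCACTCGGCCTTTC",
  F04 = "CATATCTCGTGAACCC",
  F05 = "CCTGCACGCCCTAAAG"
)

DEFAULT_REV_BARCODES <- c(
  R01 = "TACAATTAGGATATTC",
  R02 = "ATCCCTACACTGTATA",
  R03 = "TGCCGAACGTTCTAAT",
  R04 = "AAACGACTTAGCAACA",
  R05 = "AGTCGCCTAGAAAGGT"
)

#' Primer and barcode scheme for barcoded full-length 16S amplicons
#'
#' Bundles the gene-specific primers (27F/1492R), the universal M13 tails
#' used for two-step barcoding, the per-sample 16-base barcodes, and the
#' flanking primers that delimit the V3-V4 and V5-V6 hypervariable regions.
#'
#' @param fwd_barcodes,rev_barcodes named character vectors of 16-mer
#'   barcodes attached to the M13F / M13R primer respectively.
#' @return object of class `primer_scheme`.
#' @export
primer_scheme <- function(fwd_barcodes = DEFAULT_FWD_BARCODES,
                          rev_barcodes = DEFAULT_REV_BARCODES) {
  stopifnot(length(names(fwd_barcodes)) == length(fwd_barcodes),
            length(names(rev_barcodes)) == length(rev_barcodes))
  if (anyDuplicated(names(fwd_barcodes)) || anyDuplicated(names(rev_barcodes)))
    stop("barcode names must be unique")
  all_bc <- c(fwd_barcodes, rev_barcodes)
  if (!all(nchar(all_bc) == 16L)) stop("barcodes must be 16 nt")
  if (!all(is_iupac(all_bc))) stop("barcodes must be IUPAC DNA")
  structure(list(
    gene_fwd = "AGAGTTTGATCMTGGCTCAG",         # 27F
    gene_rev = "TACGGYTACCTTGTTACGACTT",       # 1492R
    m13f = "TGTAAAACGACGGCCAGT",
    m13r = "GGAAACAGCTATGACCATG",
    fwd_barcodes = fwd_barcodes,
    rev_barcodes = rev_barcodes,
    region_flanks = list(
      V3V4 = c(fwd = "ACTCCTACGGGAGGCAGCAG",   # 338F
               rev = "CTACCAGGGTATCTAATC"),    # 786R
      V5V6 = c(fwd = "GGATTAGATACCCTGGTAGTCC", # 785F
               rev = "CTCACGRCACGAGCTGACG")    # 1081R
    )
  ), class = "primer_scheme")
}

#' Sample manifest for asymmetric dual-barcode demultiplexing
#'
#' @param sample_id,site,group character vectors (recycled checks apply).
#' @param fwd_barcode_id,rev_barcode_id barcode names; every (fwd, rev) pair
#'   must be unique and present in the scheme.
#' @param scheme a [primer_scheme()] used for validation.
#' @return data.frame of class `sample_manifest`.
#' @export
sample_manifest <- function(sample_id, site, group,
                            fwd_barcode_id, rev_barcode_id,
                            scheme = primer_scheme()) {
  df <- data.frame(sample_id = as.character(sample_id),
                   site = as.character(site),
                   group = as.character(group),
                   fwd_barcode_id = as.character(fwd_barcode_id),
                   rev_barcode_id = as.character(rev_barcode_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("sample_ids must be unique")
  if (anyDuplicated(df[, c("fwd_barcode_id", "rev_barcode_id")]))
    stop("duplicate (fwd, rev) barcode pairs in manifest")
  if (!all(df$fwd_barcode_id %in% names(scheme$fwd_barcodes)))
    stop("manifest references forward barcodes absent from scheme")
  if (!all(df$rev_barcode_id %in% names(scheme$rev_barcodes)))
    stop("manifest references reverse barcodes absent from scheme")
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Default 18-sample manifest (6 sites x 3 colonies, two geographic groups)
#'
#' Mirrors the survey design emulated by the synthetic-data module: three
#' Gulf-of-Thailand sites (MN, TA, TL) and three Andaman-Sea sites (MT, SM,
#' TC), three samples each, indexed by 18 of the 25 available asymmetric
#' (forward, reverse) barcode combinations.
#'
#' @param scheme a [primer_scheme()].
#' @return a [sample_manifest()] with 18 rows.
#' @export
default_manifest <- function(scheme = primer_scheme()) {
  sites <- c("MN", "TA", "TL", "MT", "SM", "TC")
  groups <- c(MN = "gulf", TA = "gulf", TL = "gulf",
              MT = "andaman", SM = "andaman", TC = "andaman")
  site <- rep(sites, each = 3)
  sample_id <- paste0(site, rep(1:3, times = 6))
  combos <- expand.grid(fwd = names(scheme$fwd_barcodes),
                        rev = names(scheme$rev_barcodes),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$fwd, combos$rev), ][seq_along(sample_id), ]
  sample_manifest(sample_id, site, unname(groups[site]),
                  combos$fwd, combos$rev, scheme)
}

# Scheme-level checks used by demultiplex()
validate_scheme_manifest <- function(scheme, manifest) {
  if (!inherits(scheme, "primer_scheme")) stop("not a primer_scheme")
  if (!inherits(manifest, "sample_manifest")) stop("not a sample_manifest")
  if (!all(manifest$fwd_barcode_id %in% names(scheme$fwd_barcodes)) ||
      !all(manifest$rev_barcode_id %in% names(scheme$rev_barcodes)))
    stop("manifest/scheme mismatch: unknown barcode ids")
  invisible(TRUE)
}
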
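# Published per-sample summary of the coral survey the pipeline mirrors:
# 18 Porites lutea samples from six sites in two seas, with CCS read counts,
# processed-read counts (after chimera and <1000 nt removal), OTU counts and
# alpha-diversity estimates. Shipped as plain TSV; used by the accounting
# acceptance checks and as a realistic design template.

#' Per-sample summary table of the mirrored coral survey
#'
#' @return data.frame with columns sample_id, site, group, n_ccs_reads,
#'   n_processed_reads, n_otus, chao1, simpson, shannon, goods_coverage.
#' @export
plutea_sample_summary <- function() {
  path <- system.file("extdata", "plutea_sample_summary.tsv",
                      package = "longread16S", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Accounting summary of processed-read counts
#'
#' Total, minimum and truncated mean of the per-sample processed-read
#' counts, the arithmetic identities the published per-sample table must
#' satisfy.
#'
#' @param summary data.frame from [plutea_sample_summary()].
#' @return list with `total`, `minimum`, `mean_truncated`,
#'   `total_ccs`.
#' @export
processed_read_accounting <- function(summary = plutea_sample_summary()) {
  n <- summary$n_processed_reads
  list(total = sum(n), minimum = min(n),
       mean_truncated = trunc(mean(n)),
       total_ccs = sum(summary$n_ccs_reads))
}
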
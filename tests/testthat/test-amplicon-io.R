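# FASTA/FASTQ round trips and dual-barcode demultiplexing

test_that("fasta round trip preserves records across dialects", {
  recs <- longread16S:::seq_records(
    c("r1", "r2 with description"), c("ACGT", strrep("ACGTN", 30)))
  recs$id <- c("r1", "r2")
  f <- tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 13)          # wrapped
  expect_identical(read_fasta(f), recs)
  write_fasta(recs, f, width = 0)           # single-line
  expect_identical(read_fasta(f), recs)
})

test_that("fasta edge cases: empty file, bad residues", {
  f <- tempfile(fileext = ".fasta")
  file.create(f)
  expect_equal(nrow(read_fasta(f)), 0)

  writeLines(c(">bad", "ACGZT"), f)
  expect_error(read_fasta(f), "bad.*'Z' at offset 4")
})

test_that("fastq round trip with flat qualities", {
  recs <- longread16S:::seq_records(c("a", "b"), c("ACGT", "GGCC"))
  f <- tempfile(fileext = ".fastq")
  write_fastq(recs, f)
  back <- read_fastq(f)
  expect_identical(back$seq, recs$seq)
  expect_identical(back$qual, c("IIII", "IIII"))
})

test_that("demultiplexing zero-noise reads is exact and conservative", {
  sim <- fix_sim()
  dx <- demultiplex(sim$reads, fix_scheme(), sim$manifest)
  expect_equal(nrow(dx$unassigned), 0)
  truth_counts <- table(sim$truth$sample_id)
  for (s in sim$manifest$sample_id)
    expect_equal(nrow(dx$samples[[s]]), truth_counts[[s]])
  # conservation
  expect_equal(sum(vapply(dx$samples, nrow, integer(1))) +
               nrow(dx$unassigned), nrow(sim$reads))
  # per-read agreement with truth
  for (s in sim$manifest$sample_id) {
    tt <- sim$truth$sample_id[match(dx$samples[[s]]$id, sim$truth$read_id)]
    expect_true(all(tt == s))
  }
})

test_that("demultiplexing is orientation invariant", {
  sim <- fix_sim()
  dx1 <- demultiplex(sim$reads, fix_scheme(), sim$manifest)
  flipped <- sim$reads
  flipped$seq <- dna_revcomp(flipped$seq)
  dx2 <- demultiplex(flipped, fix_scheme(), sim$manifest)
  for (s in sim$manifest$sample_id) {
    expect_identical(sort(dx1$samples[[s]]$id), sort(dx2$samples[[s]]$id))
    # trimmed plus-strand output identical regardless of input orientation
    expect_identical(dx1$samples[[s]]$seq[order(dx1$samples[[s]]$id)],
                     dx2$samples[[s]]$seq[order(dx2$samples[[s]]$id)])
  }
})

test_that("one barcode substitution is tolerated at max mismatch 1", {
  sim <- fix_sim()
  sch <- fix_scheme()
  mutated <- sim$reads
  # substitute position 3 of the forward barcode on every read
  substr(mutated$seq, 3, 3) <- ifelse(substr(mutated$seq, 3, 3) == "A",
                                      "C", "A")
  dx0 <- demultiplex(sim$reads, sch, sim$manifest, max_barcode_mismatch = 1)
  dx1 <- demultiplex(mutated, sch, sim$manifest, max_barcode_mismatch = 1)
  for (s in sim$manifest$sample_id)
    expect_identical(sort(dx0$samples[[s]]$id), sort(dx1$samples[[s]]$id))

  # independent brute-force Hamming decode over all 25 combos
  ham <- function(a, b) longread16S:::hamming(a, b)
  man <- sim$manifest
  for (i in sample(nrow(mutated), 20)) {
    seq <- mutated$seq[i]
    pre <- substr(seq, 1, 16)
    suf <- substr(seq, nchar(seq) - 15, nchar(seq))
    dfwd <- vapply(sch$fwd_barcodes, ham, numeric(1), a = pre)
    drev <- vapply(dna_revcomp(sch$rev_barcodes), ham, numeric(1), a = suf)
    names(drev) <- names(sch$rev_barcodes)
    feas <- which(dfwd[man$fwd_barcode_id] <= 1 & drev[man$rev_barcode_id] <= 1)
    expect_length(feas, 1)
    expected_sample <- man$sample_id[feas]
    got <- names(Filter(function(x) mutated$id[i] %in% x$id, dx1$samples))
    expect_identical(got, expected_sample)
  }
})

test_that("unknown barcode combinations land in unassigned", {
  sim <- fix_sim()
  man <- sim$manifest
  sch <- fix_scheme()
  # craft a read with a (fwd, rev) combo absent from the 6-row manifest
  absent_fwd <- setdiff(names(sch$fwd_barcodes), man$fwd_barcode_id)[1]
  read <- longread16S:::seq_records("x", paste0(
    sch$fwd_barcodes[[absent_fwd]], sch$m13f,
    strrep("ACGT", 100),
    dna_revcomp(sch$m13r),
    dna_revcomp(sch$rev_barcodes[[man$rev_barcode_id[1]]])))
  dx <- demultiplex(read, sch, man)
  expect_equal(nrow(dx$unassigned), 1)
})

test_that("manifest validation catches duplicates and unknown barcodes", {
  expect_error(sample_manifest(c("a", "a"), "s", "g", c("F01", "F02"),
                               c("R01", "R02")), "unique")
  expect_error(sample_manifest(c("a", "b"), "s", "g", c("F01", "F01"),
                               c("R01", "R01")), "duplicate")
  expect_error(sample_manifest("a", "s", "g", "F99", "R01"), "absent")
})

test_that("manifest TSV round trips", {
  man <- default_manifest()
  f <- tempfile(fileext = ".tsv")
  write_manifest_tsv(man, f)
  expect_equal(read_manifest_tsv(f), man, ignore_attr = TRUE)
})
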
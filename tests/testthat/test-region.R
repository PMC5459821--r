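# reference dedup, primer location, region extraction, species calls

test_that("dedup collapses duplicates and containments", {
  expect_equal(nrow(dedup_references(c(SpA = "ACGTACGT",
                                       SpA = "ACGTACGT"))), 1)
  r <- dedup_references(c(Long = "AAACGTACGTTT", Short = "CGTACG"))
  expect_equal(nrow(r), 1)
  expect_identical(r$seq, "AAACGTACGTTT")
  expect_setequal(strsplit(r$species, ";")[[1]], c("Long", "Short"))

  distinct <- dedup_references(c(A = "AAAA", B = "CCCC", C = "GGGG"))
  expect_equal(nrow(distinct), 3)

  # conflicting species labels on identical sequences are both recorded
  conf <- dedup_references(c(X = "ACGTACGTAC", Y = "ACGTACGTAC"))
  expect_equal(nrow(conf), 1)
  expect_setequal(strsplit(conf$species, ";")[[1]], c("X", "Y"))
})

test_that("IUPAC-aware primer search follows the degenerate-base rules", {
  host <- random_dna(60, 12)
  p1081r <- "CTCACGRCACGAGCTGACG"
  seq0 <- paste0(substr(host, 1, 20), "CTCACGACACGAGCTGACG",
                 substr(host, 21, 40))
  hit <- locate_primer(seq0, p1081r)
  expect_equal(hit$mismatches, 0)       # R matches A
  expect_equal(hit$start, 21)
  expect_identical(hit$strand, "+")

  seq1 <- paste0(substr(host, 1, 20), "CTCACGTCACGAGCTGACG",
                 substr(host, 21, 40))
  expect_equal(locate_primer(seq1, p1081r)$mismatches, 1)  # R does not match T

  expect_null(locate_primer(random_dna(80, 3), p1081r, max_mismatch = 2))
  expect_error(locate_primer("ACG", "ACGT"), "shorter")
})

test_that("primer search finds reverse-complement occurrences", {
  host <- random_dna(80, 21)
  p <- "ACTCCTACGGGAGGCAGCAG"
  seq <- paste0(substr(host, 1, 30), dna_revcomp(p), substr(host, 31, 60))
  hit <- locate_primer(seq, p)
  expect_identical(hit$strand, "-")
  expect_equal(hit$start, 31)
})

test_that("region extraction matches construction coordinates", {
  refs <- fix_refs()
  lay <- refs$region_layout
  s <- refs$sequences[[3]]
  for (rg in c("V3V4", "V5V6")) {
    sl <- extract_region(s, rg, fix_scheme())
    expect_s3_class(sl, "region_slice")
    expect_equal(c(sl$start, sl$end), unname(lay[[rg]]))
    expect_identical(sl$seq, substr(s, lay[[rg]][1], lay[[rg]][2]))
  }
  expect_equal(nchar(extract_region(s, "V3V4", fix_scheme())$seq), 420)
  expect_equal(nchar(extract_region(s, "V5V6", fix_scheme())$seq), 255)
  full <- extract_region(s, "FULL", fix_scheme())
  expect_identical(full$seq, s)
})

test_that("extraction failures are reported distinctly", {
  refs <- fix_refs()
  s <- refs$sequences[[3]]
  # remove the V3V4 reverse flank site
  lay <- refs$region_layout
  no_rev <- paste0(substr(s, 1, lay$V3V4[2]), substr(s, 1057, 1450))
  miss <- extract_region(no_rev, "V3V4", fix_scheme())
  expect_true(region_failed(miss))
  expect_identical(miss$reason, "missing_flank")

  # reverse flank site placed before the forward flank: inverted interval
  sch <- fix_scheme()
  fwd <- longread16S:::concretize_iupac(sch$region_flanks$V3V4[["fwd"]])
  revsite <- dna_revcomp(longread16S:::concretize_iupac(
    sch$region_flanks$V3V4[["rev"]]))
  inv <- paste0(random_dna(20, 4), revsite, fwd, random_dna(20, 5))
  bad <- extract_region(inv, "V3V4", sch)
  expect_true(region_failed(bad))
  expect_identical(bad$reason, "inverted_interval")
})

test_that("include_primers grows the slice by both flank lengths", {
  refs <- fix_refs()
  s <- refs$sequences[[2]]
  sch <- fix_scheme()
  bare <- extract_region(s, "V5V6", sch)
  wide <- extract_region(s, "V5V6", sch, include_primers = TRUE)
  expect_equal(nchar(wide$seq) - nchar(bare$seq),
               nchar(sch$region_flanks$V5V6[["fwd"]]) +
               nchar(sch$region_flanks$V5V6[["rev"]]))
})

test_that("species calls follow the tie rule", {
  refs <- fix_refs()
  nr <- dedup_references(refs)
  sch <- fix_scheme()
  cp <- refs$confusable_pairs
  v34_pair <- cp[cp$region == "V3V4", ]

  sl <- extract_region(refs$sequences[[v34_pair$species_a]], "V3V4", sch)
  amb <- call_species(sl, nr)
  expect_identical(amb$verdict, "ambiguous")
  expect_gte(nrow(amb$tied_hits), 2)
  expect_setequal(
    unique(unlist(strsplit(amb$tied_hits$species, ";"))),
    c(v34_pair$species_a, v34_pair$species_b))

  full <- call_species(extract_region(refs$sequences[[v34_pair$species_a]],
                                      "FULL", sch), nr)
  expect_identical(full$verdict, "resolved")
  expect_identical(full$species, v34_pair$species_a)

  lone <- call_species(extract_region(refs$sequences[[7]], "V3V4", sch), nr)
  expect_identical(lone$verdict, "resolved")
  expect_identical(lone$species, "Species_07")

  expect_identical(call_species(random_dna(300, 99), nr)$verdict, "no_hit")
  expect_error(call_species("", nr), "empty")
})

test_that("resolvability report: clean community with no confusion is 1.0", {
  refs <- generate_reference_set(5, 0, "V3V4", seed = 19)
  man <- default_manifest(refs$scheme)[1:2, ]
  class(man) <- c("sample_manifest", "data.frame")
  comp <- lapply(man$sample_id, function(s)
    stats::setNames(rep(0.2, 5), refs$species$species_name))
  names(comp) <- man$sample_id
  cs <- community_spec(man, comp, n_reads = 40, error_rate = 0, seed = 23)
  sim <- simulate_reads(refs, cs)
  dx <- demultiplex(sim$reads, refs$scheme, man)
  rep <- resolvability_report(dx$samples, dedup_references(refs))
  expect_true(all(rep$fraction_resolved == 1.0))
})

test_that("region monotonicity: FULL resolves a superset per read", {
  sim <- fix_sim()
  refs <- fix_refs()
  nr <- dedup_references(refs)
  dx <- demultiplex(sim$reads, fix_scheme(), sim$manifest)
  u <- dereplicate(dx$samples[[1]])
  for (q in u$seq) {
    v_full <- call_species(extract_region(q, "FULL", fix_scheme()), nr)
    for (rg in c("V3V4", "V5V6")) {
      v <- call_species(extract_region(q, rg, fix_scheme()), nr)
      if (v$verdict == "resolved")
        expect_identical(v_full$verdict, "resolved")
    }
  }
})
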
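# synthetic reference and read generators

test_that("reference sets satisfy their structural invariants", {
  refs <- fix_refs()
  expect_length(refs$sequences, 8)
  expect_false(anyDuplicated(names(refs$sequences)) > 0)
  expect_true(all(nchar(refs$sequences) == 1450))

  # declared confusable pairs: identical region slice, distinct full-length
  for (k in seq_len(nrow(refs$confusable_pairs))) {
    cp <- refs$confusable_pairs[k, ]
    rg <- refs$region_layout[[cp$region]]
    a <- refs$sequences[[cp$species_a]]
    b <- refs$sequences[[cp$species_b]]
    expect_identical(substr(a, rg[1], rg[2]), substr(b, rg[1], rg[2]))
    expect_false(a == b)
  }

  # all four flank motifs present exactly (degenerate positions concretized)
  sch <- refs$scheme
  motifs <- c(longread16S:::concretize_iupac(sch$region_flanks$V3V4[["fwd"]]),
              dna_revcomp(longread16S:::concretize_iupac(
                sch$region_flanks$V3V4[["rev"]])),
              longread16S:::concretize_iupac(sch$region_flanks$V5V6[["fwd"]]),
              dna_revcomp(longread16S:::concretize_iupac(
                sch$region_flanks$V5V6[["rev"]])))
  for (s in refs$sequences)
    for (m in motifs) expect_true(grepl(m, s, fixed = TRUE))
})

test_that("single-species and determinism cases behave", {
  one <- generate_reference_set(1, 0, "V3V4", seed = 7)
  expect_length(one$sequences, 1)

  r1 <- generate_reference_set(20, 3, "V5V6", seed = 3)
  r2 <- generate_reference_set(20, 3, "V5V6", seed = 3)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$species, r2$species)

  # non-confusable pairs >= 3% divergent in every region (generator
  # postcondition, revalidated independently here)
  rg <- r1$region_layout$V3V4
  a <- substr(r1$sequences[[5]], rg[1], rg[2])
  b <- substr(r1$sequences[[9]], rg[1], rg[2])
  expect_gte(longread16S:::hamming(a, b) / nchar(a), 0.03)
})

test_that("generator rejects invalid arguments", {
  expect_error(generate_reference_set(0), "n_species")
  expect_error(generate_reference_set(5, 1, "V9"), "region")
  expect_error(generate_reference_set(4, 2, "V3V4"), "2 \\* n_confusable")
})

test_that("zero-noise reads embed their source template exactly", {
  sim <- fix_sim()
  refs <- fix_refs()
  expect_equal(nrow(sim$reads), nrow(sim$truth))
  idx <- sample(nrow(sim$reads), 50)
  for (i in idx) {
    tmpl <- refs$sequences[[sim$truth$species[i]]]
    expect_true(grepl(tmpl, sim$reads$seq[i], fixed = TRUE))
  }
})

test_that("chimera counts follow the binomial oracle", {
  refs <- fix_refs()
  man <- default_manifest(fix_scheme())[1, ]
  class(man) <- c("sample_manifest", "data.frame")
  comp <- list(MN1 = stats::setNames(rep(1 / 8, 8),
                                     refs$species$species_name))
  cs <- community_spec(man, comp, n_reads = 1000, error_rate = 0,
                       chimera_rate = 0.1, seed = 4)
  sim <- simulate_reads(refs, cs)
  n_chim <- sum(sim$truth$is_chimera)
  sd3 <- 3 * sqrt(1000 * 0.1 * 0.9)
  expect_lt(abs(n_chim - 100), sd3)
  # chimeric truth rows carry parents and crossover
  chim <- sim$truth[sim$truth$is_chimera, ]
  expect_false(anyNA(chim$parent_b))
  expect_true(all(chim$crossover >= 0.2 * 1450 - 1 &
                  chim$crossover <= 0.8 * 1450 + 1))
})

test_that("read counts per species follow the multinomial oracle", {
  refs <- fix_refs()
  man <- default_manifest(fix_scheme())[1, ]
  class(man) <- c("sample_manifest", "data.frame")
  comp <- list(MN1 = stats::setNames(
    c(0.8, 0.2, rep(0, 6)), refs$species$species_name))
  cs <- community_spec(man, comp, n_reads = 2000, error_rate = 0, seed = 8)
  sim <- simulate_reads(refs, cs)
  counts <- table(factor(sim$truth$species,
                         levels = refs$species$species_name))
  for (p in c(Species_01 = 0.8, Species_02 = 0.2)) {
    sp <- names(which(c(Species_01 = 0.8, Species_02 = 0.2) == p))[1]
    expect_lt(abs(counts[[sp]] - 2000 * p), 3 * sqrt(2000 * p * (1 - p)))
  }
})

test_that("simulation is a pure function of its arguments", {
  refs <- fix_refs()
  man <- default_manifest(fix_scheme())[1:2, ]
  class(man) <- c("sample_manifest", "data.frame")
  comp <- lapply(man$sample_id, function(s)
    stats::setNames(rep(1 / 8, 8), refs$species$species_name))
  names(comp) <- man$sample_id
  cs <- community_spec(man, comp, n_reads = 30, error_rate = 0.0064,
                       chimera_rate = 0.05, seed = 21)
  s1 <- simulate_reads(refs, cs)
  s2 <- simulate_reads(refs, cs)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
})

test_that("community_spec validates composition and rates", {
  man <- default_manifest()[1, ]
  class(man) <- c("sample_manifest", "data.frame")
  expect_error(community_spec(man, list(MN1 = c(A = 0.5, B = 0.4)), 10),
               "sum to 1")
  expect_error(community_spec(man, list(MN1 = c(A = 1)), 10,
                              error_rate = 1.5), "error_rate")
  expect_error(community_spec(man, list(MN1 = c(A = 1)), 0), "n_reads")
  refs <- fix_refs()
  bad <- community_spec(man, list(MN1 = c(NotASpecies = 1)), 10)
  expect_error(simulate_reads(refs, bad), "unknown species")
})
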
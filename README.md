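# longread16S

Full-length 16S rRNA community profiling from high-accuracy long reads.

## The problem

Most microbiome surveys sequence one or two hypervariable regions (V3-V4,
V5-V6) of the 16S rRNA gene. Short fragments are cheap but often cannot
separate closely related species: two species whose V3-V4 regions are
identical are indistinguishable to a V3-V4 amplicon no matter how deeply it
is sequenced. High-accuracy long reads (circular consensus sequencing,
~1,400 nt, residual error well under 1%) cover all nine hypervariable
regions, restoring species-level resolution.

`longread16S` implements the complete analysis chain for such surveys as a
tested, reusable R package:

* **Synthetic data with known truth** — a generator for type-strain
  reference sets (with species pairs deliberately identical over one
  hypervariable region but not full-length) and for barcoded CCS-like
  community reads with per-base error, PCR chimeras and asymmetric dual
  barcoding. Every downstream stage is testable without any external
  database.
* **Demultiplexing** — asymmetric (forward, reverse) 16-base barcode pairs
  decoded by Hamming distance at the read ends, orientation-aware, with
  conservative tie handling.
* **Preprocessing** — removal of reads `< 1000` nt and abundance-ordered de
  novo chimera detection: each query is tested against candidate parent
  pairs at ≥ 2× its abundance; an exhaustive crossover scan compares the
  best two-parent splice with the best single parent.
* **OTU clustering** — open-reference greedy centroid clustering at 97%
  identity (closed-reference pass against supplied references, then de novo
  in decreasing abundance), with conservation and centroid-identity
  guarantees.
* **Taxonomy** — a bootstrap naive-Bayes k-mer classifier (8-mers, add-half
  smoothing, confidence = fraction of 100 bootstrap resamples of 1/8 of the
  query's words; default assignment threshold 0.8), plus alignment-based
  species assignment with a > 90% identity cutoff.
* **Region resolvability** — the central analysis: in-silico extraction of
  the V3-V4 (338F/786R) and V5-V6 (785F/1081R) regions, alignment of each
  region and the full-length read against a non-redundant reference
  (E-value ≤ 1e-10), and the exact-tie rule: a query whose best hits span
  two or more species with identical E-value, bit score and aligned region
  is *ambiguous* — that region cannot resolve it. Reported per sample and
  region as the fraction of reads resolved.
* **Community statistics** — rarefaction, observed OTUs, Chao1, Shannon,
  Simpson, Good's coverage, Welch's t-test, Euclidean distances on
  rank-aggregated profiles with UPGMA dendrograms, core-microbiome
  membership at 50/75/100% ubiquity, and Dufrêne-Legendre indicator value
  analysis (IndVal = specificity A × fidelity B, permutation p-values).
* **Trees** — neighbor-joining with p-distances and bootstrap supports.

## Worked example

```r
library(longread16S)

# 10 synthetic type strains; two species pairs are indistinguishable over
# one hypervariable region each
refs <- generate_reference_set(10, 2, c("V3V4", "V5V6"), seed = 42)
refs$confusable_pairs
#>    species_a  species_b region
#> 1 Species_01 Species_02   V3V4
#> 2 Species_03 Species_04   V5V6

# a 6-sample, 2-group community sequenced at 300 reads/sample
man <- default_manifest(refs$scheme)[c(1:3, 10:12), ]
cs  <- community_spec_two_groups(refs, man, n_reads = 300,
                                 error_rate = 0, seed = 42)
sim <- simulate_reads(refs, cs)
dx  <- demultiplex(sim$reads, refs$scheme, man)

# species-level resolvability per region (the central comparison)
nr  <- dedup_references(refs)
rep <- resolvability_report(dx$samples, nr)
subset(rep, sample %in% c("MN1", "MT1"))
#>    sample region n_resolved n_ambiguous n_no_hit fraction_resolved
#> 1     MN1   FULL        300           0        0         1.0000000
#> 2     MN1   V3V4        175         125        0         0.5833333
#> 3     MN1   V5V6        218          82        0         0.7266667
#> 10    MT1   FULL        300           0        0         1.0000000
#> 11    MT1   V3V4        272        28          0         0.9066667
#> 12    MT1   V5V6        269        31          0         0.8966667
```

Every full-length read is resolved to species level; the V3-V4 and V5-V6
slices lose exactly the reads drawn from their respective confusable pairs
(MN1 happens to be dominated by the family containing both pairs, so its
short-region resolvability collapses hardest — the pattern the package is
built to quantify).

```r
tab <- cluster_otus(dx$samples, refs = refs)
alpha_diversity_table(tab$counts)[1:3, 1:6]
#>   sample_id s_obs chao1 shannon simpson goods_coverage
#> 1       MN1    10    10    3.00    0.85              1
#> 2       MN2    10    10    2.98    0.85              1
#> 3       MN3    10    10    3.06    0.86              1
```

All 10 species are recovered as closed-reference OTUs; Shannon (base 2) and
Simpson reflect the dominance structure of the simulated groups; Good's
coverage is 1 because no OTU is a singleton at this depth.

## Command line

A thin CLI over the same functions is installed at
`system.file("exec", "longread16s", package = "longread16S")` with
subcommands `demux`, `filter`, `chimera`, `cluster`, `resolve`, `njtree`,
`alpha`, `core`, `indval`.

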
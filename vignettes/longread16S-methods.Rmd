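---
title: "Methods and design notes for longread16S"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for longread16S}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`longread16S` analyses full-length 16S rRNA amplicon surveys from
high-accuracy long reads. The package covers the computational chain from
barcoded reads to community statistics, and its scientific centrepiece is
the *species-level resolvability* comparison: for each read, can its V3-V4
slice, its V5-V6 slice, or only the full-length sequence identify the
source species uniquely against a non-redundant type-strain reference?

The package consumes consensus (CCS-like) reads; raw polymerase-read
consensus calling is out of scope. Real reference databases (RDP,
Greengenes) are also out of scope: the synthetic-data module generates
references with controlled structure instead, so every claim a test makes
is checkable against known truth.

# The synthetic world

`generate_reference_set()` builds ~1,450-nt species sequences on a shared
scaffold that carries the real primer motifs at canonical offsets: 27F at
the 5' end, 338F/786R flanking a 420-nt V3-V4 slice, 785F/1081R flanking a
255-nt V5-V6 slice (785F overlaps the 786R site, as on the real gene), and
1492R at the 3' end. Degenerate primer positions are concretized once
(first base of the IUPAC expansion), so extraction works identically for
every species while the IUPAC-aware search still exercises degenerate
matching.

Outside the motifs, each species mutates 12% of scaffold positions
independently. Two independently mutated species then differ at ~22% of
free positions, so the enforced postcondition — non-confusable pairs differ
by at least 3% in *every* region — holds with enormous margin and is
asserted, not hoped for. Declared confusable pairs are constructed by
copying one species' slice over the other's for the named region; they are
congeneric in the synthetic taxonomy, mirroring the real cases
(*Pseudoalteromonas*, *Bradyrhizobium*) where single-region amplicons fail.

`simulate_reads()` emulates:

* **read structure** `fwd_barcode + M13F + template + revcomp(M13R) +
  revcomp(rev_barcode)` — the product of two-step barcoding with
  M13-tailed gene primers and 16-base barcoded M13 primers;
* **noise**: i.i.d. per-base errors at 0.64% (the residual CCS error rate
  such surveys report), split 90% substitutions / 10% indels. The
  substitution:indel split is a package choice — the residual-error
  composition is not published — and is documented rather than tuned;
* **chimeras**: with probability `chimera_rate`, a read is a two-parent
  splice with crossover uniform on the interior 20–80% of the template,
  giving detectable bimodal structure;
* **design**: 18 samples, six sites, two geographic groups, indexed by 18
  of the 25 asymmetric combinations of 5 forward × 5 reverse barcodes.
  The survey whose published per-sample table ships in `inst/extdata/`
  used exactly this layout.

What the generator does **not** model: pass-number-dependent quality, PCR
amplification bias, real database redundancy and mislabelling. A green
test therefore establishes algorithmic correctness on communities with the
stated statistical structure, not robustness to every artefact of real
surveys.

# Numerical and algorithmic choices

**Demultiplexing.** Terminal 16-mers are compared to the barcode panel by
Hamming distance, in both read orientations; default tolerance 1 of 16.
A read is assigned only when exactly one manifest row explains it at the
minimal score — equal-score ties go to the unassigned bin. This is the
conservative choice; the source protocol does not specify one.

**Chimera detection** follows the abundance-based two-parent model:
candidate parents need ≥ 2× the query's abundance; an exhaustive crossover
scan maximizes left-parent plus right-parent matches; the query is flagged
when the two-parent model beats the best single parent by ≥ 0.8 identity
percentage points *and* the vote score
`h = s_L · s_R`, `s = y / (y + 4n + 0.5a)` (yes/no/abstain votes at
diagnostic positions, per segment) reaches 0.28. The published algorithm's
exact weighting is not reproduced — the weights here are "default-like"
and documented in code — but the detector's behaviour is anchored by an
independent oracle (the crossover scan on constructed triples) and by
sensitivity ≥ 0.9 / false-positive rate ≤ 0.02 on simulator output.
Detection runs per sample, because abundance is a per-sample quantity.

**Identity** for clustering is computed on a query-global/subject-local
("glocal") alignment: matching columns / alignment columns, internal gaps
counted as mismatching columns, terminal subject gaps free and excluded.
A fully ends-free alignment was rejected after it degenerated, for highly
divergent pairs, to a one-column perfect overlap reporting identity 1.0.

**Open-reference clustering** is a closed-reference pass (best reference ≥
97%) followed by greedy de novo clustering in decreasing abundance with
lexicographic tie-breaks (deterministic, UCLUST-style). The historical
subsampled re-clustering refinement of the QIIME protocol is an
implementation detail of that pipeline and is deliberately omitted.

**Classifier.** Naive Bayes over 8-mer words, `P(word | taxon) =
(m + 0.5) / (n + 1)`, votes cast at the species leaf and aggregated up the
lineage; confidence is the fraction of 100 bootstrap resamples (⌈W/8⌉ of
the query's W words, without replacement) won. Both orientations are
scored and compared by best per-word mean log-likelihood — comparing raw
sums would favour the orientation with fewer in-vocabulary words. Species
calls for the resolvability and core-microbiome analyses come from the
alignment track, not the classifier, keeping the two tracks separate.

**BLAST-like scoring.** Local alignments use match +2, mismatch −3, gap
open −5, extend −2; bit scores and E-values use fixed Karlin-Altschul-style
constants (λ = 0.625, K = 0.41). These are configuration, not truth: they
are monotone transforms of the raw score, so rankings and tie structure —
all the resolvability rule consumes — are invariant to them. E-value ties
are compared after rounding to two significant figures (report precision);
bit-score ties exactly.

**The tie rule.** "Identical aligned region" is interpreted as identical
aligned *subject content*, not identical coordinates — coordinates differ
across references trivially, whereas content equality is what makes hits
truly indistinguishable. Equal-score ties with different content (possible
only through score coincidence) are resolved deterministically by identity
then species name, so the ambiguous verdict is reserved for genuine
indistinguishability.

**Region extraction** excludes the flank primer sites by default (the
slice runs from the end of the forward flank to the start of the reverse
flank); `include_primers = TRUE` is available since published fragment
lengths are compatible with either convention. Primer search tolerates 2
mismatches (IUPAC-aware, leftmost minimal-mismatch hit), so residual read
error does not silently drop reads.

**Exact-containment shortcut.** A query contained exactly in a reference
attains the local-alignment score maximum 2·|query|, so no other reference
can outrank it; `align_hits(top_only = TRUE)` exploits this to skip
alignments that cannot reach the top group. This is a pure optimization —
verdicts are proven equal to the brute-force all-reference DP scan in the
acceptance suite.

**Diversity conventions.** Shannon in log base 2 and bias-corrected Chao1
(`S + F1(F1−1)/(2(F2+1))`) by default, both switchable — these follow the
QIIME-1 lineage such surveys used; the sources rarely state them.
Rarefaction subsamples without replacement to exact depth and drops
shallower samples with a warning; the published table's rarefaction depth
(19,074 = its smallest sample) illustrates the "minimum sample sum"
default this package derives when no depth is given. Welch p-values are
reported raw (no multiple-testing correction), IndVal on the 0–1 scale
with `p = (1 + #{permuted max ≥ observed}) / (1 + n_perm)`, and UPGMA
merge heights are half the average inter-cluster distance (ultrametric
convention). Profile distances default to order-level aggregation,
the rank at which such dendrograms are usually drawn; the rank is a
parameter.

**Trees.** NJ uses p-distances on a gap-stripped alignment (trivial for
equal-length synthetic references; `mafft` when lengths differ) and ape's
Q-criterion implementation; bootstrap supports are fractions of column
resamples reproducing each bipartition. The root "node" of an unrooted
tree carries no bipartition and reports `NA`.

# Degenerate inputs and edge policies

* Empty FASTA files parse to zero records; non-IUPAC residues are reported
  with record id and offset.
* `extract_region()` distinguishes `missing_flank` from
  `inverted_interval` failures; both count as `no_hit` in resolvability
  reports.
* Welch's test on two zero-variance equal-mean groups is reported as
  undefined (`NA` with a note), not as a fabricated statistic.
* A species absent everywhere has IndVal 0 and p = 1 in every group.
* Chimera queries with fewer than two eligible parents receive score 0 and
  are never flagged; the most abundant unique of a sample can never be
  flagged (no parent can be 2× more abundant).

# Known limitations

* The UCHIME-style score weights and the Karlin-Altschul constants are
  documented configuration, not fitted to any published implementation.
* The naive-Bayes classifier trains one sequence per species (synthetic
  references); real multi-strain training would change confidence
  calibration though not the mechanics.
* Demultiplexing trims fixed-width barcode/adapter prefixes; indel errors
  inside the adapters can shift the retained insert by a few bases.
* The generator's taxonomy collapses at high ranks for small species
  counts; the classifier therefore requires only ≥ 2 species and ≥ 2
  genera rather than two taxa at every rank.
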
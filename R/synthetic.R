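# Synthetic reference taxonomies and barcoded community read sets with known
# truth. The generator emulates the statistical structure of a full-length
# 16S survey: ~1,450-nt type-strain references carrying the real primer
# motifs at canonical offsets (so in-silico region extraction yields the
# canonical 420-nt V3-V4 and 255-nt V5-V6 fragments), confusable species
# pairs that are identical over one hypervariable region but not full-length,
# CCS-like reads with ~0.64% random error, PCR chimeras, and asymmetric
# 5x5 dual barcoding.

REF_LEN <- 1450L

# 1-based inclusive motif placements on the reference template.
ref_layout <- function(scheme = primer_scheme()) {
  gene_fwd <- concretize_iupac(scheme$gene_fwd)              # 20 nt at 1
  v34f     <- concretize_iupac(scheme$region_flanks$V3V4["fwd"]) # 20 nt
  v56f     <- concretize_iupac(scheme$region_flanks$V5V6["fwd"]) # 22 nt
  v56r     <- dna_revcomp(concretize_iupac(scheme$region_flanks$V5V6["rev"]))
  gene_rev <- dna_revcomp(concretize_iupac(scheme$gene_rev))
  motifs <- list(
    gene_fwd = list(seq = gene_fwd, start = 1L),
    v34_fwd  = list(seq = v34f, start = 341L),
    # 785F placed so that revcomp(786R) is its positions 2..19
    v56_fwd  = list(seq = v56f, start = 780L),
    v56_rev  = list(seq = v56r, start = 1057L),
    gene_rev = list(seq = gene_rev, start = REF_LEN - nchar(gene_rev) + 1L)
  )
  regions <- list(
    V3V4 = c(361L, 780L),   # 420 nt between 338F and 786R sites
    V5V6 = c(802L, 1056L),  # 255 nt between 785F and 1081R sites
    FULL = c(1L, REF_LEN)
  )
  list(motifs = motifs, regions = regions)
}

REGION_NAMES <- c("V3V4", "V5V6", "FULL")

#' Generate a synthetic type-strain reference set
#'
#' Builds `n_species` full-length 16S-like references on a fixed scaffold
#' with the four region-flank primer motifs at canonical offsets. The first
#' `2 * n_confusable_pairs` species form pairs declared identical over one
#' hypervariable region (but differing full-length), emulating congeneric
#' species that short amplicons cannot separate. All non-confusable species
#' pairs differ by at least 3% in every region.
#'
#' @param n_species number of species (>= `2 * n_confusable_pairs + 1`).
#' @param n_confusable_pairs number of region-confusable species pairs.
#' @param region_for_confusion region name(s) in `c("V3V4", "V5V6")`;
#'   recycled across pairs, so a single reference can hold pairs confusable
#'   in different regions.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param mutation_rate per-site probability that a species deviates from
#'   the shared scaffold (default 0.12, giving ~20% typical inter-species
#'   divergence per region).
#' @return object of class `reference_set` with elements `species`
#'   (data.frame of 7-rank taxonomy), `sequences` (named character),
#'   `region_layout`, `confusable_pairs` and `layout`.
#' @export
generate_reference_set <- function(n_species, n_confusable_pairs = 0L,
                                   region_for_confusion = "V3V4",
                                   seed = 1L, mutation_rate = 0.12) {
  if (!is.numeric(n_species) || n_species < 1) stop("n_species must be >= 1")
  n_species <- as.integer(n_species)
  n_confusable_pairs <- as.integer(n_confusable_pairs)
  if (n_confusable_pairs < 0) stop("n_confusable_pairs must be >= 0")
  if (n_confusable_pairs > 0) {
    if (!all(region_for_confusion %in% c("V3V4", "V5V6")))
      stop("unknown or unusable region name: ",
           paste(setdiff(region_for_confusion, c("V3V4", "V5V6")), collapse = ","))
    if (n_species < 2L * n_confusable_pairs + 1L)
      stop("n_species must be >= 2 * n_confusable_pairs + 1")
  }

  scheme <- primer_scheme()
  lay <- ref_layout(scheme)
  bases <- c("A", "C", "G", "T")

  fixed <- rep(FALSE, REF_LEN)
  template <- rep(NA_character_, REF_LEN)
  for (m in lay$motifs) {
    idx <- m$start:(m$start + nchar(m$seq) - 1L)
    template[idx] <- strsplit(m$seq, "", fixed = TRUE)[[1]]
    fixed[idx] <- TRUE
  }
  free <- which(!fixed)

  rng <- local({ set.seed(seed); NULL })  # seed global RNG deterministically
  template[free] <- sample(bases, length(free), replace = TRUE)

  seqs <- matrix(rep(template, n_species), nrow = n_species, byrow = TRUE)
  for (i in seq_len(n_species)) {
    mut <- free[stats::runif(length(free)) < mutation_rate]
    if (length(mut)) {
      cur <- seqs[i, mut]
      seqs[i, mut] <- vapply(cur, function(b)
        sample(setdiff(bases, b), 1L), character(1))
    }
  }

  confusable <- NULL
  if (n_confusable_pairs > 0) {
    regions <- rep_len(region_for_confusion, n_confusable_pairs)
    confusable <- data.frame(
      species_a = character(n_confusable_pairs),
      species_b = character(n_confusable_pairs),
      region = regions, stringsAsFactors = FALSE)
    for (k in seq_len(n_confusable_pairs)) {
      a <- 2L * k - 1L; b <- 2L * k
      rg <- lay$regions[[regions[k]]]
      idx <- rg[1]:rg[2]
      seqs[b, idx] <- seqs[a, idx]
      if (all(seqs[b, ] == seqs[a, ]))
        stop("degenerate draw: confusable pair identical full-length; change seed")
    }
  }

  species_name <- sprintf("Species_%02d", seq_len(n_species))
  genus_idx <- integer(n_species)
  g <- 0L
  for (i in seq_len(n_species)) {
    if (n_confusable_pairs > 0 && i <= 2L * n_confusable_pairs) {
      if (i %% 2L == 1L) g <- g + 1L
      genus_idx[i] <- g
    } else {
      g <- g + 1L
      genus_idx[i] <- g
    }
  }
  family_idx <- (genus_idx - 1L) %/% 2L + 1L
  order_idx  <- (family_idx - 1L) %/% 2L + 1L
  class_idx  <- (order_idx - 1L) %/% 2L + 1L
  phylum_idx <- (class_idx - 1L) %/% 2L + 1L
  species <- data.frame(
    species_name = species_name,
    genus  = sprintf("Genus_%02d", genus_idx),
    family = sprintf("Family_%02d", family_idx),
    order  = sprintf("Order_%02d", order_idx),
    class  = sprintf("Class_%02d", class_idx),
    phylum = sprintf("Phylum_%02d", phylum_idx),
    stringsAsFactors = FALSE)

  sequences <- apply(seqs, 1, paste, collapse = "")
  names(sequences) <- species_name
  if (!is.null(confusable)) {
    confusable$species_a <- species_name[2L * seq_len(n_confusable_pairs) - 1L]
    confusable$species_b <- species_name[2L * seq_len(n_confusable_pairs)]
  }

  refs <- structure(list(
    species = species,
    sequences = sequences,
    region_layout = lay$regions,
    confusable_pairs = confusable,
    scheme = scheme
  ), class = "reference_set")
  validate_reference_set(refs)
  refs
}

# Postcondition checks: confusable slices identical / full-length distinct;
# every other pair >= 3% divergent in every region.
validate_reference_set <- function(refs, min_divergence = 0.03) {
  lay <- refs$region_layout
  sp <- names(refs$sequences)
  n <- length(sp)
  conf_key <- character(0)
  if (!is.null(refs$confusable_pairs) && nrow(refs$confusable_pairs)) {
    cp <- refs$confusable_pairs
    for (k in seq_len(nrow(cp))) {
      rg <- lay[[cp$region[k]]]
      a <- substr(refs$sequences[cp$species_a[k]], rg[1], rg[2])
      b <- substr(refs$sequences[cp$species_b[k]], rg[1], rg[2])
      if (a != b) stop("confusable pair not identical over declared region")
      if (refs$sequences[cp$species_a[k]] == refs$sequences[cp$species_b[k]])
        stop("confusable pair identical full-length")
    }
    conf_key <- paste(cp$species_a, cp$species_b, cp$region)
  }
  if (n < 2) return(invisible(refs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (rn in names(lay)) {
      if (paste(sp[i], sp[j], rn) %in% conf_key ||
          paste(sp[j], sp[i], rn) %in% conf_key) next
      rg <- lay[[rn]]
      a <- substr(refs$sequences[i], rg[1], rg[2])
      b <- substr(refs$sequences[j], rg[1], rg[2])
      d <- hamming(a, b) / nchar(a)
      # a declared pair still has to differ in the OTHER regions, but FULL
      # divergence of a confusable pair is diluted by the shared slice
      lim <- if (any(c(sp[i], sp[j]) %in%
                     c(refs$confusable_pairs$species_a,
                       refs$confusable_pairs$species_b)) && rn == "FULL")
        1 / nchar(a) else min_divergence
      if (d < lim)
        stop(sprintf("species %s/%s under-divergent in %s (%.3f)",
                     sp[i], sp[j], rn, d))
    }
  }
  invisible(refs)
}

#' Specification of a synthetic multi-sample community
#'
#' @param manifest a [sample_manifest()] giving samples, sites, groups and
#'   barcode assignment (the assignment is injective by construction).
#' @param composition named list: `sample_id` -> named numeric vector of
#'   per-species relative abundances summing to 1 (+/- 1e-9).
#' @param n_reads reads per sample (scalar, recycled).
#' @param error_rate per-base error probability (default 0.0064, the
#'   residual CCS error rate the generator emulates).
#' @param chimera_rate fraction of reads that are two-parent PCR chimeras.
#' @param seed integer seed.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(manifest, composition, n_reads,
                           error_rate = 0.0064, chimera_rate = 0,
                           seed = 1L) {
  stopifnot(inherits(manifest, "sample_manifest"))
  if (!all(manifest$sample_id %in% names(composition)))
    stop("composition missing samples: ",
         paste(setdiff(manifest$sample_id, names(composition)), collapse = ","))
  for (s in manifest$sample_id) {
    comp <- composition[[s]]
    if (abs(sum(comp) - 1) > 1e-9)
      stop("composition for sample ", s, " does not sum to 1")
    if (any(comp < 0)) stop("negative abundance in sample ", s)
  }
  if (any(n_reads <= 0)) stop("n_reads must be positive")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0,1]")
  if (chimera_rate < 0 || chimera_rate > 1) stop("chimera_rate must be in [0,1]")
  structure(list(
    manifest = manifest,
    composition = composition,
    n_reads = as.integer(rep_len(n_reads, nrow(manifest))),
    error_rate = error_rate,
    chimera_rate = chimera_rate,
    seed = as.integer(seed)
  ), class = "community_spec")
}

#' Two-group community with group-distinct dominant families
#'
#' Convenience generator for the survey structure the pipeline is tested
#' on: each geographic group is dominated (default 70% of reads) by the
#' species of one family, with the remaining mass spread uniformly over all
#' species. Per-sample proportions are jittered so samples are replicates,
#' not copies.
#'
#' @param refs a `reference_set`.
#' @param manifest a [sample_manifest()] with a `group` column of 2 levels.
#' @param n_reads reads per sample.
#' @param dominant_fraction mass given to the group's dominant family.
#' @param seed integer seed.
#' @inheritParams community_spec
#' @return a [community_spec()].
#' @export
community_spec_two_groups <- function(refs, manifest, n_reads = 500L,
                                      dominant_fraction = 0.7,
                                      error_rate = 0.0064, chimera_rate = 0,
                                      seed = 1L) {
  groups <- unique(manifest$group)
  stopifnot(length(groups) == 2)
  fams <- unique(refs$species$family)
  if (length(fams) < 2) stop("need at least 2 families in the reference")
  dom <- stats::setNames(fams[1:2], groups)
  set.seed(seed)
  composition <- lapply(manifest$sample_id, function(s) {
    g <- manifest$group[manifest$sample_id == s]
    in_dom <- refs$species$family == dom[[g]]
    w <- ifelse(in_dom, dominant_fraction / sum(in_dom),
                (1 - dominant_fraction) / sum(!in_dom))
    w <- w * stats::rgamma(length(w), shape = 25, rate = 25)  # sample jitter
    stats::setNames(w / sum(w), refs$species$species_name)
  })
  names(composition) <- manifest$sample_id
  community_spec(manifest, composition, n_reads, error_rate, chimera_rate,
                 seed = seed)
}

# Apply i.i.d. per-base noise: errors are 90% substitutions, 10% indels
# (split evenly), reflecting the randomly distributed residual CCS errors.
mutate_read <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  err <- which(stats::runif(length(ch)) < error_rate)
  if (!length(err)) return(seq)
  bases <- c("A", "C", "G", "T")
  kind <- sample(c("sub", "ins", "del"), length(err), replace = TRUE,
                 prob = c(0.90, 0.05, 0.05))
  for (k in seq_along(err)) {
    i <- err[k]
    ch[i] <- switch(kind[k],
      sub = sample(setdiff(bases, ch[i]), 1L),
      ins = paste0(ch[i], sample(bases, 1L)),
      del = "")
  }
  paste(ch, collapse = "")
}

#' Simulate barcoded community reads with a truth table
#'
#' Each read is `fwd_barcode + M13F + template + revcomp(M13R) +
#' revcomp(rev_barcode)`, where the template is a full reference sequence
#' (27F site through 1492R site) or, for chimeric reads, a two-parent splice
#' at a crossover drawn uniformly on the interior 20-80% of the template.
#' Per-base noise is applied at `error_rate`.
#'
#' @param refs a `reference_set`.
#' @param cspec a [community_spec()].
#' @param fraction_revcomp fraction of reads emitted reverse-complemented
#'   (default 0; demultiplexing is orientation-aware regardless).
#' @return list with `reads` (data.frame id, seq) and `truth` (data.frame
#'   read_id, sample_id, species, is_chimera, parent_a, parent_b, crossover).
#' @export
simulate_reads <- function(refs, cspec, fraction_revcomp = 0) {
  stopifnot(inherits(refs, "reference_set"), inherits(cspec, "community_spec"))
  scheme <- refs$scheme
  man <- cspec$manifest
  set.seed(cspec$seed)
  m13r_rc <- dna_revcomp(scheme$m13r)
  all_reads <- vector("list", nrow(man))
  all_truth <- vector("list", nrow(man))
  for (si in seq_len(nrow(man))) {
    s <- man$sample_id[si]
    comp <- cspec$composition[[s]]
    if (!all(names(comp) %in% names(refs$sequences)))
      stop("composition references unknown species: ",
           paste(setdiff(names(comp), names(refs$sequences)), collapse = ","))
    n <- cspec$n_reads[si]
    sp <- sample(names(comp), n, replace = TRUE, prob = comp)
    chim <- stats::runif(n) < cspec$chimera_rate
    pa <- sp
    pb <- rep(NA_character_, n)
    xov <- rep(NA_integer_, n)
    templ <- character(n)
    for (i in seq_len(n)) {
      if (chim[i] && length(comp) >= 2) {
        others <- setdiff(names(comp), pa[i])
        pb[i] <- if (length(others) == 1) others else
          sample(others, 1L, prob = comp[others])
        len <- nchar(refs$sequences[[pa[i]]])
        xov[i] <- as.integer(floor(stats::runif(1, 0.2 * len, 0.8 * len)))
        templ[i] <- paste0(substr(refs$sequences[[pa[i]]], 1, xov[i]),
                           substr(refs$sequences[[pb[i]]], xov[i] + 1L, len))
      } else {
        chim[i] <- FALSE
        templ[i] <- refs$sequences[[pa[i]]]
      }
    }
    fwd_bc <- scheme$fwd_barcodes[[man$fwd_barcode_id[si]]]
    rev_bc <- scheme$rev_barcodes[[man$rev_barcode_id[si]]]
    raw <- paste0(fwd_bc, scheme$m13f, templ, m13r_rc, dna_revcomp(rev_bc))
    if (cspec$error_rate > 0)
      raw <- vapply(raw, mutate_read, character(1),
                    error_rate = cspec$error_rate, USE.NAMES = FALSE)
    if (fraction_revcomp > 0) {
      flip <- stats::runif(n) < fraction_revcomp
      raw[flip] <- dna_revcomp(raw[flip])
    }
    ids <- sprintf("%s_read%05d", s, seq_len(n))
    all_reads[[si]] <- seq_records(ids, raw)
    all_truth[[si]] <- data.frame(
      read_id = ids, sample_id = s, species = pa, is_chimera = chim,
      parent_a = ifelse(chim, pa, NA_character_), parent_b = pb,
      crossover = xov, stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, all_reads),
       truth = do.call(rbind, all_truth))
}
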
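# Shared fixtures (built once per test run) and independent oracles.
# Oracles are deliberately naive re-derivations: plain DP, direct
# arithmetic, exhaustive enumeration. They never call the code paths they
# check.

fixture_env <- new.env(parent = emptyenv())

# 8 species, one V3V4-confusable pair and one V5V6-confusable pair
fix_refs <- function() {
  if (is.null(fixture_env$refs))
    fixture_env$refs <- generate_reference_set(
      8, 2, c("V3V4", "V5V6"), seed = 3)
  fixture_env$refs
}

fix_scheme <- function() fix_refs()$scheme

# uniform zero-noise community over 6 samples (2 groups)
fix_sim <- function() {
  if (is.null(fixture_env$sim)) {
    refs <- fix_refs()
    man <- default_manifest(fix_scheme())[c(1:3, 10:12), ]
    class(man) <- c("sample_manifest", "data.frame")
    comp <- lapply(man$sample_id, function(s)
      stats::setNames(rep(1 / 8, 8), refs$species$species_name))
    names(comp) <- man$sample_id
    cs <- community_spec(man, comp, n_reads = 60, error_rate = 0,
                         chimera_rate = 0, seed = 11)
    fixture_env$sim <- c(simulate_reads(refs, cs), list(manifest = man))
  }
  fixture_env$sim
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos, base) {
  for (i in seq_along(pos)) substr(seq, pos[i], pos[i]) <- base[i]
  seq
}

# --- oracle: affine-gap local alignment score (Gotoh), plain R loops -----
# gap of length L costs gap_open + L * gap_ext, matching the package's
# BLAST-like scoring configuration
oracle_local_score <- function(q, s, match = 2, mism = -3,
                               gap_open = 5, gap_ext = 2) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in subject (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in query (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (qv[i - 1] == sv[j - 1]) match else mism
      M[i, j] <- max(0, M[i - 1, j - 1] + sub, Ix[i - 1, j - 1] + sub,
                     Iy[i - 1, j - 1] + sub)
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                      Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                      Iy[i, j - 1] - gap_ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# --- oracle: best two-parent splice by exhaustive crossover scan ---------
# equal-length construction, direct character arithmetic
oracle_best_crossover <- function(query, parent_a, parent_b) {
  qv <- strsplit(query, "", fixed = TRUE)[[1]]
  av <- strsplit(parent_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(parent_b, "", fixed = TRUE)[[1]]
  L <- length(qv)
  ma <- cumsum(qv == av)
  mb <- rev(cumsum(rev(qv == bv)))
  tot <- ma[1:(L - 1)] + mb[2:L]
  list(crossover = which.max(tot), identity = max(tot) / L,
       single_a = ma[L] / L, single_b = sum(qv == bv) / L)
}

# --- oracle: naive UPGMA recomputing cluster-average distances from the
# original matrix at every step --------------------------------------------
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1]) best <- c(avg, i, j)
    }
    heights <- c(heights, best[1] / 2)
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# --- oracle: four-point condition for the 4-taxon NJ topology ------------
oracle_nj_split <- function(d, labels) {
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  sums <- vapply(pairings, function(p)
    d[p[1], p[2]] + d[p[3], p[4]], numeric(1))
  p <- pairings[[which.min(sums)]]
  sort(c(labels[p[1]], labels[p[2]]))
}

# unrooted bipartitions (as sorted label sets of the smaller side)
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  lapply(parts, function(p) sort(tree$tip.label[p]))
}
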
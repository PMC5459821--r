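# Bootstrap naive-Bayes rank classification of OTU centroids, in the style
# of the RDP classifier: overlapping k-mer words, per-taxon word posteriors
# with add-half smoothing, and confidence from bootstrap resamples of 1/8 of
# the query's words. Votes are cast at the species leaf and aggregated up
# the lineage, so every rank gets a label and a confidence.

RANKS <- c("phylum", "class", "order", "family", "genus", "species")

#' Train a naive-Bayes word classifier from a reference set
#'
#' @param refs a `reference_set` (needs >= 2 species and >= 2 genera; small
#'   synthetic taxonomies may legitimately collapse at higher ranks).
#' @param k word size, 6..10 (default 8).
#' @return object of class `nb_classifier`.
#' @export
train_classifier <- function(refs, k = 8L) {
  if (k < 6 || k > 10) stop("k must be in [6, 10]")
  stopifnot(inherits(refs, "reference_set"))
  if (nrow(refs$species) < 2 || length(unique(refs$species$genus)) < 2)
    stop("need at least 2 species and 2 genera to train")
  words <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(refs$sequences), width = k) > 0
  vocab <- which(colSums(words) > 0)
  pres <- words[, vocab, drop = FALSE]
  # each leaf taxon holds one training sequence: P(w|taxon) = (m + 0.5)/(n + 1)
  logp <- log((pres + 0.5) / 2)
  rownames(logp) <- refs$species$species_name
  lineage <- refs$species
  lineage <- lineage[, c("phylum", "class", "order", "family", "genus",
                         "species_name")]
  names(lineage)[6] <- "species"
  structure(list(k = as.integer(k), vocab = colnames(words)[vocab],
                 logp = logp, lineage = lineage),
            class = "nb_classifier")
}

query_words <- function(model, seq) {
  w <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                            width = model$k) > 0
  intersect(names(w)[w], model$vocab)
}

#' Classify a query sequence with bootstrap confidence
#'
#' Both orientations are scored and the better one kept, so classification
#' is invariant to reverse-complementing the query. Confidence at each rank
#' is the fraction of `n_bootstrap` resamples (of `ceiling(W/8)` of the
#' query's `W` words, without replacement) whose winning leaf taxon carries
#' that rank label. Ranks outside the deepest contiguous run with confidence
#' >= `confidence_threshold` are reported as `"unassigned"`.
#'
#' @param model an `nb_classifier`.
#' @param seq query DNA string (length >= k).
#' @param query_id identifier carried into the result.
#' @param n_bootstrap bootstrap resamples (default 100).
#' @param confidence_threshold assignment threshold (default 0.8).
#' @param seed RNG seed for the resampling.
#' @return list of class `taxonomy_assignment`: `query_id`, `labels`,
#'   `confidence`, `effective` (labels with sub-threshold ranks
#'   "unassigned") and `assigned_rank`.
#' @export
classify <- function(model, seq, query_id = "query", n_bootstrap = 100L,
                     confidence_threshold = 0.8, seed = 1L) {
  if (nchar(seq) < model$k) stop("query shorter than k")
  set.seed(seed)
  cand <- list(fwd = query_words(model, seq),
               rev = query_words(model, dna_revcomp(seq)))
  # orientations see different numbers of in-vocabulary words, so compare
  # the best per-word mean log-likelihood, not the raw sum
  full_score <- vapply(cand, function(w)
    if (length(w)) max(rowSums(model$logp[, w, drop = FALSE])) / length(w)
    else -Inf, numeric(1))
  wds <- cand[[which.max(full_score)]]
  labels <- stats::setNames(rep("unassigned", length(RANKS)), RANKS)
  conf <- stats::setNames(rep(0, length(RANKS)), RANKS)
  if (length(wds) == 0) {
    return(structure(list(query_id = query_id, labels = labels,
                          confidence = conf, effective = labels,
                          assigned_rank = NA_character_),
                     class = "taxonomy_assignment"))
  }
  W <- length(wds)
  m <- ceiling(W / 8)
  votes <- integer(nrow(model$logp))
  names(votes) <- rownames(model$logp)
  lp <- model$logp[, wds, drop = FALSE]
  for (b in seq_len(n_bootstrap)) {
    pick <- sample.int(W, m)
    sc <- rowSums(lp[, pick, drop = FALSE])
    votes[which.max(sc)] <- votes[which.max(sc)] + 1L
  }
  vote_frac <- votes / n_bootstrap
  for (r in RANKS) {
    by_label <- tapply(vote_frac, model$lineage[[r]], sum)
    labels[r] <- names(by_label)[which.max(by_label)]
    conf[r] <- max(by_label)
  }
  run <- cumprod(conf >= confidence_threshold) == 1
  assigned_rank <- if (any(run)) RANKS[max(which(run))] else NA_character_
  effective <- labels
  effective[!run] <- "unassigned"
  structure(list(query_id = query_id, labels = labels, confidence = conf,
                 effective = effective, assigned_rank = assigned_rank),
            class = "taxonomy_assignment")
}

#' Write taxonomy assignments as TSV
#' @param assignments list of `taxonomy_assignment` objects.
#' @param path output path.
#' @export
write_taxonomy_assignments_tsv <- function(assignments, path) {
  rows <- lapply(assignments, function(a) {
    data.frame(query = a$query_id,
               t(a$effective), t(stats::setNames(a$confidence,
                                                 paste0(RANKS, "_conf"))),
               assigned_rank = a$assigned_rank, check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
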
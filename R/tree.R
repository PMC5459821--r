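# Distance trees. NJ construction, p-distances and bootstrap bipartition
# counting are delegated to ape; the multiple alignment feeding them is
# trivial for the equal-length synthetic references and otherwise produced
# with mafft when available on PATH.

# character matrix (taxa x columns) from sequences
align_to_matrix <- function(seqs, labels) {
  if (length(unique(nchar(seqs))) == 1L) {
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  } else {
    mafft <- Sys.which("mafft")
    if (!nzchar(mafft))
      stop("sequences differ in length and mafft is not on PATH")
    fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
    write_fasta(seq_records(labels, seqs), fin)
    system2(mafft, c("--auto", "--quiet", fin), stdout = fout)
    rec <- read_fasta(fout)
    rec <- rec[match(labels, rec$id), ]
    m <- do.call(rbind, strsplit(rec$seq, "", fixed = TRUE))
  }
  rownames(m) <- labels
  m
}

#' Neighbor-joining tree with bootstrap support
#'
#' Distances are p-distances on a gap-stripped multiple alignment; the tree
#' is built with the standard Q-criterion (ape's NJ); node supports are the
#' fraction of `n_bootstrap` column resamples reproducing each bipartition,
#' stored in `node.label`.
#'
#' @param seqs named character vector of >= 3 sequences (names = labels).
#' @param n_bootstrap bootstrap replicates (default 1000).
#' @param seed RNG seed for the column resampling.
#' @return an `ape::phylo` tree (unrooted, with branch lengths).
#' @export
build_nj_tree <- function(seqs, n_bootstrap = 1000L, seed = 1L) {
  if (length(seqs) < 3) stop("need at least 3 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  m <- align_to_matrix(unname(seqs), names(seqs))
  bin <- ape::as.DNAbin(tolower(m))
  pdist <- function(x) ape::dist.dna(x, model = "raw",
                                     pairwise.deletion = FALSE)
  tree <- ape::nj(pdist(bin))
  if (n_bootstrap > 0 && length(seqs) >= 4) {
    set.seed(seed)
    counts <- ape::boot.phylo(tree, bin, function(x) ape::nj(pdist(x)),
                              B = n_bootstrap, quiet = TRUE, rooted = FALSE)
    tree$node.label <- counts / n_bootstrap
  }
  tree
}

#' UPGMA (average linkage) dendrogram from a distance matrix
#'
#' Merge heights follow the ultrametric convention: half the average
#' inter-cluster distance, so two samples at distance d join at height d/2.
#'
#' @param d symmetric, zero-diagonal distance matrix (or `dist`).
#' @return list with `tree` (`ape::phylo`), `heights` (merge heights,
#'   increasing), `hclust` and `top_split` (leaf labels of the two clusters
#'   separated by the root).
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d)) || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  k2 <- stats::cutree(hc, k = min(2L, nrow(d)))
  list(tree = ape::as.phylo(hc),
       heights = hc$height / 2,
       hclust = hc,
       top_split = split(names(k2), k2))
}

#' Write a tree to Newick
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
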
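# Alpha diversity, rarefaction, Welch's t-test and taxon-profile distances.
# Conventions follow the QIIME-1 lineage this style of survey used:
# Shannon in log base 2 and bias-corrected Chao1 by default, both
# switchable.

#' Rarefy an OTU table to even depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads;
#' samples with fewer reads are dropped with a warning.
#'
#' @param table an `otu_table` (or samples x OTUs count matrix).
#' @param depth target depth (>= 1).
#' @param seed RNG seed.
#' @return an `otu_table` (all-zero OTU columns dropped).
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (depth < 1) stop("depth must be >= 1")
  counts <- if (inherits(table, "otu_table")) table$counts else table
  set.seed(seed)
  keep <- rowSums(counts) >= depth
  if (any(!keep))
    warning("dropping samples below depth: ",
            paste(rownames(counts)[!keep], collapse = ", "))
  counts <- counts[keep, , drop = FALSE]
  out <- counts
  for (i in seq_len(nrow(counts))) {
    pool <- rep.int(seq_len(ncol(counts)), counts[i, ])
    sub <- if (length(pool) == depth) pool else sample(pool, depth)
    out[i, ] <- tabulate(sub, nbins = ncol(counts))
  }
  out <- out[, colSums(out) > 0, drop = FALSE]
  if (inherits(table, "otu_table")) {
    structure(list(counts = out,
                   centroids = table$centroids[colnames(out)],
                   provenance = table$provenance[colnames(out)]),
              class = "otu_table")
  } else out
}

#' Alpha diversity of one sample
#'
#' Observed OTUs, Chao1 (bias-corrected by default), Shannon (base 2 by
#' default), Simpson (1 - sum p^2), Good's coverage (1 - F1/N).
#'
#' @param counts non-negative integer vector of per-OTU counts.
#' @param base logarithm base for Shannon (default 2).
#' @param chao1_bias_corrected use `S + F1(F1-1)/(2(F2+1))` (default) rather
#'   than the classic `S + F1^2/(2 F2)`.
#' @return data.frame with s_obs, chao1, shannon, simpson, goods_coverage,
#'   f1, f2, n.
#' @export
alpha_diversity <- function(counts, base = 2, chao1_bias_corrected = TRUE) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all-zero count vector")
  nz <- counts[counts > 0]
  s_obs <- length(nz)
  f1 <- sum(nz == 1)
  f2 <- sum(nz == 2)
  chao1 <- if (chao1_bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
           else if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
  p <- nz / n
  data.frame(s_obs = s_obs, chao1 = chao1,
             shannon = -sum(p * log(p, base = base)),
             simpson = 1 - sum(p^2),
             goods_coverage = 1 - f1 / n,
             f1 = f1, f2 = f2, n = n)
}

#' Alpha diversity for every sample of an OTU table
#' @param table an `otu_table` or samples x OTUs matrix.
#' @inheritParams alpha_diversity
#' @return data.frame with one row per sample.
#' @export
alpha_diversity_table <- function(table, base = 2,
                                  chao1_bias_corrected = TRUE) {
  counts <- if (inherits(table, "otu_table")) table$counts else table
  res <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    alpha_diversity(counts[i, ], base, chao1_bias_corrected)))
  cbind(data.frame(sample_id = rownames(counts), stringsAsFactors = FALSE),
        res)
}

#' Welch's two-sample t-test
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return list with `t`, `df`, `p` (two-sided); all NA with
#'   `note = "undefined"` when both groups have zero variance and equal
#'   means.
#' @export
welch_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                  note = "undefined: zero variance in both groups"))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = Inf, p = 0))
  }
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Euclidean distances between taxon-aggregated relative-abundance profiles
#'
#' @param table an `otu_table` or samples x OTUs count matrix.
#' @param taxonomy named character vector mapping otu/column id -> taxon
#'   label at the chosen rank (e.g. order); unmapped OTUs keep their own id.
#' @return symmetric distance matrix (samples x samples).
#' @export
profile_distance <- function(table, taxonomy = NULL) {
  counts <- if (inherits(table, "otu_table")) table$counts else table
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("otu", seq_len(ncol(counts)))
  labels <- colnames(counts)
  if (!is.null(taxonomy)) {
    mapped <- taxonomy[labels]
    labels <- ifelse(is.na(mapped), labels, mapped)
  }
  agg <- t(rowsum(t(counts), group = labels))
  rel <- agg / rowSums(agg)
  as.matrix(stats::dist(rel, method = "euclidean"))
}
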
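# Indicator species analysis (Dufrêne-Legendre IndVal) and core-microbiome
# membership by ubiquity threshold.

#' Dufrêne-Legendre indicator value analysis
#'
#' For species i and group j: specificity `A = mean abundance in j / sum of
#' group mean abundances`, fidelity `B = fraction of group-j samples where
#' the species is present`, `IndVal = A * B` on the 0-1 scale. The p-value
#' compares each observed value against the permutation distribution of the
#' species' maximum IndVal under shuffled group labels:
#' `p = (1 + #{permuted max >= observed}) / (1 + n_perm)`.
#'
#' @param table species x samples abundance matrix (rownames = species,
#'   colnames = samples).
#' @param groups character vector of group labels, one per sample (>= 2
#'   groups, each non-empty).
#' @param n_perm label permutations (default 999).
#' @param seed RNG seed.
#' @param scale_100 report IndVal on the 0-100 scale (default FALSE).
#' @return data.frame: species, group, A, B, indval, p_value.
#' @export
indval <- function(table, groups, n_perm = 999L, seed = 1L,
                   scale_100 = FALSE) {
  table <- as.matrix(table)
  if (ncol(table) != length(groups))
    stop("one group label per sample required")
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 1)) stop("empty group")

  iv_parts <- function(g) {
    meanab <- t(apply(table, 1, function(r) tapply(r, g, mean)))[, lv,
                                                                 drop = FALSE]
    pres <- t(apply(table > 0, 1, function(r) tapply(r, g, mean)))[, lv,
                                                                   drop = FALSE]
    tot <- rowSums(meanab)
    A <- meanab / ifelse(tot > 0, tot, 1)
    A[tot == 0, ] <- 0
    list(A = A, B = pres, iv = A * pres)
  }
  obs <- iv_parts(groups)

  set.seed(seed)
  n_ge <- matrix(0L, nrow(table), length(lv),
                 dimnames = list(rownames(table), lv))
  for (p in seq_len(n_perm)) {
    perm_max <- apply(iv_parts(sample(groups))$iv, 1, max)
    n_ge <- n_ge + (perm_max >= obs$iv)  # column-recycled per species row
  }
  pval <- (1 + n_ge) / (1 + n_perm)

  out <- data.frame(
    species = rep(rownames(table), times = length(lv)),
    group = rep(lv, each = nrow(table)),
    A = as.vector(obs$A), B = as.vector(obs$B),
    indval = as.vector(obs$iv) * if (scale_100) 100 else 1,
    p_value = as.vector(pval),
    stringsAsFactors = FALSE)
  out[order(out$species, out$group), ]
}

#' Core-microbiome membership at a ubiquity threshold
#'
#' A species is a member when present (count >= 1) in at least
#' `ceiling(threshold * n_samples / 100)` samples. Output is sorted by
#' decreasing ubiquity, then mean relative abundance.
#'
#' @param table species x samples abundance matrix.
#' @param ubiquity_threshold_pct threshold in (0, 100].
#' @param sites optional character vector of per-sample site labels for
#'   per-site mean abundances.
#' @return data.frame: species, ubiquity (percent of samples),
#'   mean_rel_abundance (percent), plus one `mean_<site>` column per site.
#' @export
core_microbiome <- function(table, ubiquity_threshold_pct, sites = NULL) {
  table <- as.matrix(table)
  if (!nrow(table) || !ncol(table)) stop("empty table")
  if (ubiquity_threshold_pct <= 0 || ubiquity_threshold_pct > 100)
    stop("threshold must be in (0, 100]")
  n <- ncol(table)
  need <- ceiling(ubiquity_threshold_pct * n / 100)
  pres <- rowSums(table > 0)
  rel <- 100 * t(t(table) / colSums(table))
  member <- pres >= need
  out <- data.frame(
    species = rownames(table)[member],
    ubiquity = 100 * pres[member] / n,
    mean_rel_abundance = rowMeans(rel)[member],
    stringsAsFactors = FALSE)
  if (!is.null(sites)) {
    for (s in unique(sites)) {
      out[[paste0("mean_", s)]] <-
        rowMeans(rel[member, sites == s, drop = FALSE])
    }
  }
  out <- out[order(-out$ubiquity, -out$mean_rel_abundance), ]
  rownames(out) <- NULL
  out
}
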
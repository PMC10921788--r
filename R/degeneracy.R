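# Clone-cluster degeneracy: how many transcriptional states a clone
# occupies (and vice versa), measured by normalized Shannon entropy,
# sqrt-normalized mutual information, Simpson diversity, and a label-
# permutation null for the independence hypothesis. Logarithms are base 2
# throughout; normalization cancels the base for entropy but not for raw
# MI, so the base is fixed and recorded here.

#' Normalized Shannon entropy of category counts
#'
#' Shannon entropy of the occupancy proportions divided by the theoretical
#' maximum `log2(k)` for the number of categories available in the sample,
#' making values comparable across samples. A unit occupying a single
#' category has entropy exactly 0, as does the degenerate `k = 1` case.
#'
#' @param counts non-negative category counts (occupancy of one clone
#'   across clusters, or one cluster across clones).
#' @param k number of categories available in the sample (`>= 1`);
#'   defaults to `length(counts)`.
#' @return numeric in `[0, 1]`, or `NA` when `sum(counts) == 0`.
#' @export
#' @examples
#' normalized_entropy(c(3, 1), k = 2) # 0.8113
normalized_entropy <- function(counts, k = length(counts)) {
  if (any(counts < 0)) stop_fmt("negative counts")
  if (k < 1L) stop_fmt("k must be >= 1")
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  if (k == 1L) return(0)
  p <- counts[counts > 0] / tot
  if (length(p) == 1L) return(0)
  h <- -sum(p * log2(p))
  h / log2(k)
}

#' Sqrt-normalized mutual information between two labelings
#'
#' Mutual information between the clone and cluster partitions of the same
#' cells, normalized by `sqrt(H(clones) * H(clusters))`. Defined as 0 when
#' either marginal entropy is 0 (a single clone or a single cluster carries
#' no information), avoiding 0/0.
#'
#' @param a,b label vectors over the same cells.
#' @return numeric in `[0, 1]`, or `NA` with fewer than 2 cells.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop_fmt("label vectors differ in length")
  if (length(a) < 2L) return(NA_real_)
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  ha <- -sum(pa[pa > 0] * log2(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log2(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
  min(1, max(0, mi / sqrt(ha * hb)))
}

#' Simpson diversity index
#'
#' `1 - sum(p_i^2)` over clone (or cluster) proportions: the probability
#' that two cells drawn at random belong to different clones.
#'
#' @param abundances proportions summing to 1.
#' @return numeric in `[0, 1)`, or `NA` for empty input.
#' @export
simpson_diversity <- function(abundances) {
  if (length(abundances) == 0L) return(NA_real_)
  if (any(abundances < 0)) stop_fmt("negative abundances")
  if (abs(sum(abundances) - 1) > 1e-8)
    stop_fmt("abundances must sum to 1 (got %g)", sum(abundances))
  1 - sum(abundances^2)
}

# Mean normalized clone entropy of one sample: for each clone, the entropy
# of its cluster occupancy, normalized by the sample's cluster count.
mean_clone_entropy <- function(clone, cluster) {
  k <- length(unique(cluster))
  ent <- vapply(split(cluster, clone),
                function(cl) normalized_entropy(as.numeric(table(cl)), k = k),
                numeric(1L))
  mean(ent)
}

#' Permutation null for clone-cluster entropy
#'
#' Tests whether clones occupy fewer transcriptional clusters than expected
#' if mutational and transcriptional states were independent. Within each
#' sample, cluster labels are permuted across cells (clone labels fixed —
#' equivalent in distribution, deterministic for the clone-side statistic),
#' the mean normalized per-clone cluster entropy is recomputed, and a
#' one-sided empirical p value for observed < null is reported as
#' `(1 + #(null <= observed)) / (n_perm + 1)`.
#'
#' @param cells a [cell_table()].
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return data.frame per sample: `sample_id`, `observed`, `null_mean`,
#'   `p`, `n_perm`; the per-sample null distributions are attached as the
#'   `"null"` attribute (named list of numeric vectors).
#' @export
entropy_null <- function(cells, n_perm = 999L, seed = 0L) {
  if (n_perm < 1L) stop_fmt("n_perm must be >= 1")
  samples <- unique(cells$sample_id)
  nulls <- list()
  rows <- with_seed(seed, lapply(samples, function(s) {
    sub <- cells[cells$sample_id == s, , drop = FALSE]
    obs <- mean_clone_entropy(sub$clone_id, sub$cluster_id)
    degenerate <- length(unique(sub$clone_id)) == 1L &&
      length(unique(sub$cluster_id)) == 1L
    null <- vapply(seq_len(n_perm), function(i)
      mean_clone_entropy(sub$clone_id, sample(sub$cluster_id)), numeric(1L))
    nulls[[s]] <<- null
    data.frame(sample_id = s, observed = obs, null_mean = mean(null),
               p = if (degenerate) NA_real_ else
                 (1 + sum(null <= obs + 1e-12)) / (n_perm + 1),
               n_perm = n_perm, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  attr(out, "null") <- nulls
  out
}

#' Per-sample degeneracy report
#'
#' For each sample: mean normalized cluster-occupancy entropy of its clones
#' and clone-occupancy entropy of its clusters, sqrt-normalized mutual
#' information between the two labelings, and Simpson diversity of clone
#' and cluster proportions. Entropies use base-2 logarithms.
#'
#' @param cells a [cell_table()].
#' @param n_perm if `> 0`, also run [entropy_null()] and append its
#'   `null_mean` and `p` columns.
#' @param seed RNG seed for the permutation null.
#' @return data.frame, one row per sample, of class `degeneracy_report`;
#'   per-unit entropies are attached as the `"unit_entropy"` attribute.
#' @export
degeneracy_report <- function(cells, n_perm = 0L, seed = 0L) {
  samples <- unique(cells$sample_id)
  unit_ent <- list()
  rows <- lapply(samples, function(s) {
    sub <- cells[cells$sample_id == s, , drop = FALSE]
    k_clusters <- length(unique(sub$cluster_id))
    k_clones <- length(unique(sub$clone_id))
    clone_ent <- vapply(split(sub$cluster_id, sub$clone_id), function(cl)
      normalized_entropy(as.numeric(table(cl)), k = k_clusters), numeric(1L))
    cluster_ent <- vapply(split(sub$clone_id, sub$cluster_id), function(cl)
      normalized_entropy(as.numeric(table(cl)), k = k_clones), numeric(1L))
    unit_ent[[s]] <<- list(clone = clone_ent, cluster = cluster_ent)
    p_clone <- as.numeric(table(sub$clone_id)) / nrow(sub)
    p_cluster <- as.numeric(table(sub$cluster_id)) / nrow(sub)
    data.frame(sample_id = s, n_cells = nrow(sub), n_clones = k_clones,
               n_clusters = k_clusters,
               clone_entropy = mean(clone_ent),
               cluster_entropy = mean(cluster_ent),
               nmi = nmi(sub$clone_id, sub$cluster_id),
               simpson_clones = simpson_diversity(p_clone),
               simpson_clusters = simpson_diversity(p_cluster),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (n_perm > 0L) {
    nl <- entropy_null(cells, n_perm = n_perm, seed = seed)
    out$null_mean <- nl$null_mean[match(out$sample_id, nl$sample_id)]
    out$entropy_p <- nl$p[match(out$sample_id, nl$sample_id)]
  }
  attr(out, "unit_entropy") <- unit_ent
  class(out) <- c("degeneracy_report", "data.frame")
  out
}
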
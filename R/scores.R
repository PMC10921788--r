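# Per-feature scores: mutation signature score (Jaccard of gene sets),
# transcription module score (signature mean minus expression-matched
# control mean, per cell), and mutated-gene expression score.

#' Mutation signature score (Jaccard)
#'
#' Jaccard index between a clone's mutated-gene set and a predefined
#' signature gene set. When a coding filter (for example the consensus CDS
#' gene list) is supplied both sets are restricted to it first, so
#' non-coding symbols cannot inflate the union. An empty union scores 0.
#'
#' @param clone_genes character vector: the clone's mutated genes.
#' @param signature non-empty character vector: the signature gene set.
#' @param coding_filter optional character vector of permitted gene symbols.
#' @return numeric in `[0, 1]`.
#' @export
#' @examples
#' mutation_signature_score(c("EGFR", "TP53"), c("EGFR", "KRAS", "MET"))
mutation_signature_score <- function(clone_genes, signature,
                                     coding_filter = NULL) {
  if (length(signature) == 0L) stop_fmt("signature gene set is empty")
  a <- unique(norm_genes(clone_genes))
  b <- unique(norm_genes(signature))
  if (!is.null(coding_filter)) {
    cf <- unique(norm_genes(coding_filter))
    a <- intersect(a, cf)
    b <- intersect(b, cf)
  }
  jaccard_index(a, b)
}

# Equal-frequency expression bins over average expression, capped at the
# number of genes.
expression_bins <- function(avg, n_bins) {
  n <- length(avg)
  n_bins <- max(1L, min(n_bins, n))
  r <- rank(avg, ties.method = "first")
  ceiling(r * n_bins / n)
}

#' Transcription module score per cell
#'
#' Module score of a signature against expression-matched controls: genes
#' are binned into `n_bins` equal-frequency bins by average expression
#' across cells; for each signature gene, up to `n_ctrl` control genes are
#' drawn without replacement from its bin (capped at bin occupancy, so tiny
#' matrices use the whole bin and are deterministic); the per-cell score is
#' the mean expression of the signature genes minus the mean over the
#' pooled control draws. Centering against matched controls removes the
#' dependence on overall expression depth that a raw signature mean has.
#'
#' Metabolism-type signatures are skipped (with a warning, returning `NULL`)
#' when fewer than `min_genes` signature genes are present in the matrix;
#' the default `min_genes = 1` applies to cancer signatures, metabolism
#' callers pass 3.
#'
#' @param expr numeric matrix genes x cells (normalized expression).
#' @param signature character vector of gene symbols.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes drawn per signature gene (default 100).
#' @param seed RNG seed for the control draws (default 0); the global RNG
#'   state is left untouched.
#' @param min_genes minimum signature genes that must be present.
#' @return named numeric vector of per-cell scores, or `NULL` if skipped.
#' @export
transcription_module_score <- function(expr, signature, n_bins = 24L,
                                       n_ctrl = 100L, seed = 0L,
                                       min_genes = 1L) {
  rn <- norm_genes(rownames(expr))
  sig <- which(rn %in% unique(norm_genes(signature)))
  if (length(sig) < min_genes) {
    warn_fmt("signature skipped: %d of %d genes present (need >= %d)",
             length(sig), length(unique(signature)), min_genes)
    return(NULL)
  }
  avg <- Matrix::rowMeans(expr)
  bins <- expression_bins(avg, n_bins)
  ctrl <- with_seed(seed, {
    lapply(sig, function(g) {
      pool <- which(bins == bins[g])
      pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
    })
  })
  sig_mean <- Matrix::colMeans(expr[sig, , drop = FALSE])
  # each signature gene's control draw is averaged separately, then the
  # draws are averaged with equal weight; pooling the raw draws instead
  # would weight cells by bin occupancy and bias the score when bins differ
  # in size
  ctrl_mean <- Reduce(`+`, lapply(ctrl, function(g)
    Matrix::colMeans(expr[g, , drop = FALSE]))) / length(ctrl)
  stats::setNames(as.numeric(sig_mean - ctrl_mean), colnames(expr))
}

#' Mutated-gene expression score per cell
#'
#' Mean expression, per cell, over the genes that are both mutated in the
#' clone and members of the signature (and present in the matrix). This is
#' the expression analogue of the mutation Jaccard score: it asks whether
#' the mutated members of a program are actually transcribed. Cells scored
#' should belong to the clone that defines `clone_genes`.
#'
#' An empty intersection returns per-cell `NA` (the feature is missing for
#' that clone). When `metabolism = TRUE` the feature is skipped (`NULL`,
#' with a warning) if fewer than `min_expressed` intersecting genes show
#' non-zero expression.
#'
#' @param expr numeric matrix genes x cells.
#' @param clone_genes the clone's mutated genes.
#' @param signature signature gene set.
#' @param min_expressed minimum expressed intersecting genes for metabolism
#'   sets (default 3).
#' @param metabolism whether the minimum-expressed rule applies.
#' @return named numeric vector per cell (possibly all `NA`), or `NULL` if
#'   skipped.
#' @export
mutated_expression_score <- function(expr, clone_genes, signature,
                                     min_expressed = 3L, metabolism = FALSE) {
  rn <- norm_genes(rownames(expr))
  genes <- which(rn %in% intersect(unique(norm_genes(clone_genes)),
                                   unique(norm_genes(signature))))
  if (length(genes) == 0L)
    return(stats::setNames(rep(NA_real_, ncol(expr)), colnames(expr)))
  if (metabolism) {
    expressed <- sum(Matrix::rowSums(expr[genes, , drop = FALSE] > 0) > 0)
    if (expressed < min_expressed) {
      warn_fmt("metabolism feature skipped: %d expressed intersecting genes (need >= %d)",
               expressed, min_expressed)
      return(NULL)
    }
  }
  stats::setNames(as.numeric(Matrix::colMeans(expr[genes, , drop = FALSE])),
                  colnames(expr))
}

#' Aggregate per-cell scores to clones or cluster/clones
#'
#' Unit score is the mean of the member cells' scores; missing cell scores
#' are excluded from the mean, and a unit with no scored cell gets `NA`.
#' The recorded `n_cells` is the unit's total membership.
#'
#' @param scores named numeric vector, names = cell ids.
#' @param cells a [cell_table()] covering the scored cells.
#' @param unit `"clone"` or `"cluster_clone"` (the intersection of a
#'   transcriptional cluster and a clone, the unit for LR scoring).
#' @return data.frame: `sample_id`, `clone_id` (and `cluster_id` for
#'   cluster_clone), `score`, `n_cells`.
#' @export
aggregate_to_unit <- function(scores, cells, unit = c("clone", "cluster_clone")) {
  unit <- match.arg(unit)
  idx <- match(cells$cell_id, names(scores))
  vals <- scores[idx]
  key_cols <- if (unit == "clone") c("sample_id", "clone_id")
              else c("sample_id", "cluster_id", "clone_id")
  key <- interaction(cells[key_cols], drop = TRUE, sep = "\r")
  agg_mean <- tapply(vals, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  })
  agg_n <- tapply(vals, key, length)
  parts <- do.call(rbind, strsplit(names(agg_mean), "\r", fixed = TRUE))
  out <- as.data.frame(parts, stringsAsFactors = FALSE)
  names(out) <- key_cols
  out$score <- as.numeric(agg_mean)
  out$n_cells <- as.integer(agg_n)
  out[order(out$sample_id, out$clone_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
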
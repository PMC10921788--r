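# Mutated ligand-receptor scoring: mutations falling on the cancer-side
# genes of inferred cancer-TME interactions, aggregated per clone over its
# cluster/clones with cell-count weights.

#' Split / join underscore-delimited gene complexes
#'
#' Ligand and receptor complexes are underscore-joined gene symbols
#' (`"TGFBR1_TGFBR2"`); splitting decomposes them into member genes.
#'
#' @param complex character vector of complex strings.
#' @return `split_complex`: character vector of gene symbols.
#' @export
split_complex <- function(complex) {
  unlist(strsplit(as.character(complex), "_", fixed = TRUE), use.names = FALSE)
}

#' @rdname split_complex
#' @param genes character vector of gene symbols.
#' @return `join_complex`: single underscore-joined string.
#' @export
join_complex <- function(genes) paste(genes, collapse = "_")

#' Cancer-side gene set of interactions with one TME partner
#'
#' Filters the interaction table to rows where the cancer cluster(s) play
#' `cancer_role` and the given partner cell type plays the other role, then
#' takes the union of the decomposed complex genes on the cancer side:
#' ligand genes when cancer is the source, receptor genes when cancer is
#' the target. Partner-side genes are deliberately excluded — the
#' directional readout (ligands produced by vs. receptors displayed on the
#' malignant cells) is the point of the score.
#'
#' @param interactions an [read_interactions()] table.
#' @param cancer_labels cell-type label(s) denoting the malignant clusters.
#' @param cancer_role `"source"` (cancer emits the ligand) or `"target"`
#'   (cancer displays the receptor).
#' @param partner partner cell-type label.
#' @param coding_filter optional permitted gene symbols (e.g. consensus
#'   CDS).
#' @return character vector of gene symbols (possibly empty, with a
#'   warning).
#' @export
interaction_gene_set <- function(interactions, cancer_labels,
                                 cancer_role = c("source", "target"),
                                 partner, coding_filter = NULL) {
  cancer_role <- match.arg(cancer_role)
  if (cancer_role == "source") {
    rows <- interactions$source %in% cancer_labels & interactions$target == partner
    complexes <- interactions$ligand[rows]
  } else {
    rows <- interactions$target %in% cancer_labels & interactions$source == partner
    complexes <- interactions$receptor[rows]
  }
  if (!any(rows)) {
    warn_fmt("no interactions with cancer as %s and partner '%s'",
             cancer_role, partner)
    return(character(0))
  }
  genes <- unique(norm_genes(split_complex(complexes)))
  if (!is.null(coding_filter)) genes <- intersect(genes, norm_genes(coding_filter))
  sort(genes)
}

#' Jaccard between a cluster/clone mutation profile and an interaction set
#'
#' @param mutated_genes the cluster/clone's mutated genes.
#' @param interaction_genes gene set from [interaction_gene_set()].
#' @return numeric in `[0, 1]`, or `NA` when the interaction set is empty.
#' @export
cluster_clone_lr_jaccard <- function(mutated_genes, interaction_genes) {
  if (length(interaction_genes) == 0L) return(NA_real_)
  jaccard_index(norm_genes(mutated_genes), norm_genes(interaction_genes))
}

#' Mutated ligand-receptor score of a clone
#'
#' Cell-count-weighted mean of the per-cluster/clone Jaccard indices:
#' `sum(n_i * J_i) / n_clone`, where i runs over the cluster/clones of the
#' clone and `n_clone = sum(n_i)`. Cluster/clones with a missing Jaccard
#' (for example no overlap with the expression data) are excluded from both
#' numerator and denominator; if none remain the score is `NA`.
#'
#' @param n_cells integer vector of cluster/clone cell counts.
#' @param jaccards numeric vector of matching Jaccard indices.
#' @return numeric in `[0, 1]`, bounded by `min(jaccards)` and
#'   `max(jaccards)`.
#' @export
#' @examples
#' clone_lr_score(c(3, 1), c(0.2, 0.6)) # 0.3
clone_lr_score <- function(n_cells, jaccards) {
  if (length(n_cells) != length(jaccards))
    stop_fmt("n_cells and jaccards differ in length")
  if (sum(n_cells) == 0) stop_fmt("clone has no cells")
  ok <- !is.na(jaccards)
  if (!any(ok)) return(NA_real_)
  sum(n_cells[ok] * jaccards[ok]) / sum(n_cells[ok])
}

#' Per-clone mutated-LR score table
#'
#' For every clone of every sample and every (partner, direction)
#' combination present in the interaction table, computes one Jaccard index
#' per cluster/clone — between the clone's mutated genes and the
#' cancer-side gene set of the interactions involving *that* cluster — and
#' aggregates them with [clone_lr_score()]. Interactions are inferred per
#' transcriptional cluster, so cluster/clones of the same clone can face
#' different interaction gene sets; the cell-count weights then reflect how
#' much of the clone sits in each cluster. A cluster with no interaction
#' for a combination contributes a missing Jaccard and is excluded.
#'
#' @param genotypes clone-level [genotype_matrix()].
#' @param cells a [cell_table()].
#' @param interactions an [read_interactions()] table whose cancer-side
#'   labels are cluster labels.
#' @param cluster_labels named character vector mapping cell-table
#'   `cluster_id` to the label used in the interaction table; an unnamed
#'   vector (or `NULL`) means cluster ids are used verbatim.
#' @param coding_filter optional permitted gene symbols.
#' @return data.frame: `sample_id`, `clone_id`, `partner`, `direction`,
#'   `score`, `n_cells` (the clone's total cell count).
#' @export
lr_score_table <- function(genotypes, cells, interactions,
                           cluster_labels = NULL, coding_filter = NULL) {
  clusters <- unique(cells$cluster_id)
  if (is.null(cluster_labels)) {
    cluster_labels <- stats::setNames(clusters, clusters)
  } else if (is.null(names(cluster_labels))) {
    cluster_labels <- stats::setNames(cluster_labels, clusters)
  }
  cancer_labels <- unname(cluster_labels)
  partners_src <- setdiff(unique(interactions$target[interactions$source %in% cancer_labels]), cancer_labels)
  partners_tgt <- setdiff(unique(interactions$source[interactions$target %in% cancer_labels]), cancer_labels)
  combos <- rbind(
    if (length(partners_src)) data.frame(partner = partners_src, direction = "source",
                                         stringsAsFactors = FALSE),
    if (length(partners_tgt)) data.frame(partner = partners_tgt, direction = "target",
                                         stringsAsFactors = FALSE)
  )
  if (is.null(combos) || nrow(combos) == 0L)
    stop_fmt("no interactions involve the cancer cluster labels")
  cc <- stats::aggregate(cells$cell_id,
                         by = list(sample_id = cells$sample_id,
                                   clone_id = cells$clone_id,
                                   cluster_id = cells$cluster_id),
                         FUN = length)
  names(cc)[4L] <- "n_cells"
  out <- list()
  for (k in seq_len(nrow(combos))) {
    # one cancer-side gene set per cancer cluster for this combination
    gsets <- lapply(stats::setNames(names(cluster_labels), names(cluster_labels)),
                    function(cl) suppressWarnings(
      interaction_gene_set(interactions, cluster_labels[[cl]],
                           cancer_role = combos$direction[k],
                           partner = combos$partner[k],
                           coding_filter = coding_filter)))
    clone_keys <- unique(paste(cc$sample_id, cc$clone_id, sep = "\r"))
    for (key in clone_keys) {
      sub <- cc[paste(cc$sample_id, cc$clone_id, sep = "\r") == key, , drop = FALSE]
      clone <- sub$clone_id[1L]
      if (!clone %in% rownames(genotypes$values)) next
      mg <- mutated_gene_set(genotypes, clone)
      js <- vapply(seq_len(nrow(sub)), function(i)
        cluster_clone_lr_jaccard(mg, gsets[[sub$cluster_id[i]]]), numeric(1L))
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sub$sample_id[1L], clone_id = clone,
        partner = combos$partner[k], direction = combos$direction[k],
        score = if (all(is.na(js))) NA_real_ else clone_lr_score(sub$n_cells, js),
        n_cells = sum(sub$n_cells), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
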
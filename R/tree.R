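# Clonal tree construction. Clones are ordered by a minimum spanning tree
# over pairwise genotype distances, rooted at the most ancestral genotype
# (fewest mutated sites), and root-to-leaf paths provide the ordering used
# by the evolutionary-path statistics.

#' L1 genotype distance over shared non-missing sites
#'
#' Manhattan distance between two genotype vectors, restricted to positions
#' where both values are observed. The 0/1/2 coding orders heterozygous
#' between wild-type and homozygous, which L1 respects. With no overlapping
#' observed site the distance is undefined (`NA`).
#'
#' @param a,b numeric/integer vectors of equal length; `NA` = missing.
#' @return non-negative numeric, or `NA`.
#' @export
#' @examples
#' genotype_distance(c(NA, 1, 2), c(1, 1, 0)) # 2, first site skipped
genotype_distance <- function(a, b) {
  if (length(a) != length(b)) stop_fmt("genotype vectors differ in length")
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(NA_real_)
  sum(abs(as.numeric(a[ok]) - as.numeric(b[ok])))
}

# Pairwise distance matrix over the rows of a genotype_matrix.
genotype_distance_matrix <- function(genotypes) {
  v <- genotypes$values
  n <- nrow(v)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n)) {
    d[i, i] <- 0
    for (j in seq_len(n)[-seq_len(i)]) {
      d[i, j] <- d[j, i] <- genotype_distance(v[i, ], v[j, ])
    }
  }
  d
}

# Kruskal MST with a fixed tie-break: edges sorted by (weight, lexicographic
# id pair). Guarantees one deterministic tree among equal-weight
# alternatives, which library MST implementations do not promise.
kruskal_mst <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  if (n == 1L)
    return(data.frame(a = character(0), b = character(0), weight = numeric(0)))
  pairs <- utils::combn(seq_len(n), 2L)
  ea <- ids[pairs[1L, ]]
  eb <- ids[pairs[2L, ]]
  swap <- ea > eb
  tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
  w <- d[cbind(pairs[1L, ], pairs[2L, ])]
  keep <- !is.na(w)
  ea <- ea[keep]; eb <- eb[keep]; w <- w[keep]
  o <- order(w, ea, eb)
  ea <- ea[o]; eb <- eb[o]; w <- w[o]
  parent <- stats::setNames(seq_len(n), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  sel <- logical(length(w))
  taken <- 0L
  for (k in seq_along(w)) {
    ra <- find(match(ea[k], ids))
    rb <- find(match(eb[k], ids))
    if (ra != rb) {
      parent[ra] <- rb
      sel[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  if (taken < n - 1L)
    stop_fmt("genotype distance graph is disconnected (all-missing clone pair); cannot build a spanning tree")
  data.frame(a = ea[sel], b = eb[sel], weight = w[sel], stringsAsFactors = FALSE)
}

#' Build a rooted clonal tree by minimum spanning tree
#'
#' Computes pairwise L1 genotype distances between clones, takes the
#' deterministic Kruskal MST, and roots it at the clone with the fewest
#' mutated sites (ties broken by larger cell count, then lexicographically
#' smaller clone id). Depth counts edges from the root.
#'
#' @param genotypes clone-level [genotype_matrix()].
#' @param cells optional [cell_table()] restricted to the relevant sample;
#'   used for per-clone cell counts (root tie-break, path filtering).
#'   Alternatively supply `cell_counts`.
#' @param cell_counts optional named integer vector clone id -> cell count.
#' @return object of class `clonal_tree`: list with `nodes` (data.frame
#'   `clone`, `n_cells`, `n_mutations`, `depth`, `parent`), `edges`
#'   (data.frame `parent`, `child`, `weight`), and `root`.
#' @export
build_tree <- function(genotypes, cells = NULL, cell_counts = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  ids <- rownames(genotypes$values)
  if (length(ids) < 1L) stop_fmt("no clones in genotype matrix")
  if (is.null(cell_counts)) {
    if (!is.null(cells)) {
      tb <- table(cells$clone_id)
      cell_counts <- stats::setNames(as.integer(tb), names(tb))
    } else {
      cell_counts <- stats::setNames(rep(1L, length(ids)), ids)
    }
  }
  counts <- stats::setNames(rep(0L, length(ids)), ids)
  known <- intersect(names(cell_counts), ids)
  counts[known] <- as.integer(cell_counts[known])

  nmut <- apply(genotypes$values, 1L, function(v) sum(!is.na(v) & v >= 1L))
  # root: most ancestral genotype; ties -> largest clone, then id order
  ord <- order(nmut, -counts, ids)
  root <- ids[ord[1L]]

  mst <- kruskal_mst(genotype_distance_matrix(genotypes))

  # orient edges away from the root by BFS
  adj <- lapply(stats::setNames(vector("list", length(ids)), ids), identity)
  for (k in seq_len(nrow(mst))) {
    adj[[mst$a[k]]] <- c(adj[[mst$a[k]]], list(c(mst$b[k], mst$weight[k])))
    adj[[mst$b[k]]] <- c(adj[[mst$b[k]]], list(c(mst$a[k], mst$weight[k])))
  }
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  depth[root] <- 0L
  queue <- root
  edges <- data.frame(parent = character(0), child = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  while (length(queue) > 0L) {
    cur <- queue[1L]
    queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      child <- nb[1L]
      if (is.na(depth[child])) {
        depth[child] <- depth[cur] + 1L
        parent[child] <- cur
        edges <- rbind(edges, data.frame(parent = cur, child = child,
                                         weight = as.numeric(nb[2L]),
                                         stringsAsFactors = FALSE))
        queue <- c(queue, child)
      }
    }
  }
  nodes <- data.frame(clone = ids, n_cells = counts[ids],
                      n_mutations = as.integer(nmut[ids]),
                      depth = as.integer(depth[ids]),
                      parent = parent[ids],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges, root = root),
            class = "clonal_tree")
}

#' @export
print.clonal_tree <- function(x, ...) {
  cat(sprintf("clonal_tree: %d clones, root '%s', max depth %d, total weight %g\n",
              nrow(x$nodes), x$root, max(x$nodes$depth), sum(x$edges$weight)))
  invisible(x)
}

tree_children <- function(tree, clone) {
  tree$edges$child[tree$edges$parent == clone]
}

#' Extract root-to-leaf evolutionary paths
#'
#' One path per leaf of the clonal tree, ordered root to leaf. Clones with
#' fewer than `min_cells` cells are removed from each path (a clone too
#' small to score reliably) while surviving clones keep their original tree
#' depths — depth encodes distance from the root, which filtering must not
#' rescale. Paths retaining fewer than 3 clones are dropped, since a
#' two-point rank correlation is always +/-1.
#'
#' @param tree a [build_tree()] result.
#' @param min_cells minimum clone size (default 10).
#' @return list of data.frames (`clone`, `depth`, `n_cells`), possibly
#'   empty.
#' @export
extract_paths <- function(tree, min_cells = 10L) {
  stopifnot(inherits(tree, "clonal_tree"))
  nodes <- tree$nodes
  leaves <- setdiff(nodes$clone, tree$edges$parent)
  paths <- list()
  for (leaf in leaves) {
    seq_ids <- leaf
    cur <- leaf
    while (!is.na(nodes$parent[nodes$clone == cur])) {
      cur <- nodes$parent[nodes$clone == cur]
      seq_ids <- c(cur, seq_ids)
    }
    p <- nodes[match(seq_ids, nodes$clone), c("clone", "depth", "n_cells")]
    p <- p[p$n_cells >= min_cells, , drop = FALSE]
    rownames(p) <- NULL
    if (nrow(p) >= 3L) paths[[length(paths) + 1L]] <- p
  }
  if (length(paths) > 0L)
    names(paths) <- vapply(paths, function(p) p$clone[nrow(p)], character(1L))
  paths
}

#' Spearman correlation between clonal abundance and tree depth
#'
#' Relative clone abundance (cell count / total cells over the tree's
#' clones) against clone depth, pooled over the clones of one sample. `NA`
#' with fewer than 3 clones or zero variance.
#'
#' @param tree a [build_tree()] result with cell counts.
#' @return Spearman coefficient or `NA`.
#' @export
abundance_depth_correlation <- function(tree) {
  stopifnot(inherits(tree, "clonal_tree"))
  n <- tree$nodes
  if (nrow(n) < 3L || sum(n$n_cells) == 0L) return(NA_real_)
  spearman_rho(n$n_cells / sum(n$n_cells), n$depth)
}

#' Export a clonal tree as an edge-list TSV
#'
#' Columns: parent, child, weight, depth (of the child).
#'
#' @param tree a `clonal_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_tsv <- function(tree, path) {
  e <- tree$edges
  e$depth <- tree$nodes$depth[match(e$child, tree$nodes$clone)]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Newick serialization of a clonal tree
#'
#' Clone ids as labels, MST edge weights as branch lengths.
#'
#' @param tree a `clonal_tree`.
#' @return single Newick string terminated by `;`.
#' @export
tree_newick <- function(tree) {
  rec <- function(clone) {
    kids <- tree_children(tree, clone)
    if (length(kids) == 0L) return(clone)
    inner <- vapply(kids, function(k) {
      w <- tree$edges$weight[tree$edges$parent == clone & tree$edges$child == k]
      sprintf("%s:%g", rec(k), w)
    }, character(1L))
    sprintf("(%s)%s", paste(inner, collapse = ","), clone)
  }
  paste0(rec(tree$root), ";")
}
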
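# Readers for the tabular inputs: cell metadata, gene-set collections
# (GMT), expression matrices (dense TSV or MatrixMarket triplet), and
# ligand-receptor interaction tables.

#' Validate a cell metadata table
#'
#' Each cell carries its sample, clone, transcriptional cluster and an
#' optional clinical context label (for example primary/metastasis or
#' PD/PR/SD). Clone and cluster identities are interpreted per sample; all
#' analyses group by `sample_id` and never merge labels across samples.
#'
#' @param df data.frame with columns `cell_id`, `sample_id`, `clone_id`,
#'   `cluster_id` and optionally `context`. Extra columns are dropped.
#' @return a validated data.frame of class `cell_table`.
#' @export
cell_table <- function(df) {
  need <- c("cell_id", "sample_id", "clone_id", "cluster_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_fmt("cell table lacks required column(s): %s", paste(miss, collapse = ", "))
  keep <- c(need, intersect("context", names(df)))
  df <- df[, keep, drop = FALSE]
  for (cl in names(df)) df[[cl]] <- as.character(df[[cl]])
  if (anyDuplicated(df$cell_id))
    stop_fmt("duplicate cell_id: %s",
             paste(utils::head(unique(df$cell_id[duplicated(df$cell_id)]), 5L),
                   collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Read a cell metadata table from TSV
#'
#' @param path TSV with columns `cell_id`, `sample_id`, `clone_id`,
#'   `cluster_id` and optionally `context`.
#' @return a [cell_table()].
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop_fmt("cell table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  cell_table(df)
}

#' Cells per clone within each sample
#'
#' @param cells a [cell_table()].
#' @return data.frame with columns `sample_id`, `clone_id`, `n_cells`.
#' @export
clone_sizes <- function(cells) {
  agg <- stats::aggregate(cells$cell_id,
                          by = list(sample_id = cells$sample_id,
                                    clone_id = cells$clone_id),
                          FUN = length)
  names(agg)[3L] <- "n_cells"
  agg[order(agg$sample_id, agg$clone_id), , drop = FALSE]
}

#' Read a gene-set collection in GMT format
#'
#' Tab-separated: set name, description, then one gene symbol per field.
#' Symbols are upper-cased; empty sets are rejected.
#'
#' @param path GMT file path.
#' @param category category tag attached to every set (for example
#'   `"cancer"` or `"metabolism"`); metabolism sets are subject to the
#'   minimum-shared-gene rule in expression scoring.
#' @return named list of character vectors, with a `category` attribute
#'   (named character vector set -> category).
#' @export
read_gmt <- function(path, category = "cancer") {
  if (!file.exists(path)) stop_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop_fmt("malformed GMT line (need name, description, >=1 gene): %.40s", ln)
    genes <- unique(norm_genes(parts[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop_fmt("empty gene set '%s' in %s", parts[1L], path)
    sets[[parts[1L]]] <- genes
  }
  if (anyDuplicated(names(sets))) stop_fmt("duplicate set names in %s", path)
  attr(sets, "category") <- stats::setNames(rep(category, length(sets)), names(sets))
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a normalized expression matrix
#'
#' Accepts either a dense TSV (genes in rows, first column gene symbol,
#' remaining columns cells) or a MatrixMarket triplet file with sidecar
#' gene/cell name files (one name per line). Values are used as provided —
#' the caller is expected to pass library-normalized, log-scale expression.
#' Gene symbols are upper-cased; duplicated symbols keep their first row.
#'
#' @param path dense TSV or `.mtx` file.
#' @param genes,cells sidecar name files, required for `.mtx` input.
#' @return numeric matrix genes x cells (dense TSV) or `dgCMatrix` (mtx).
#' @export
read_expression <- function(path, genes = NULL, cells = NULL) {
  if (!file.exists(path)) stop_fmt("expression file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes) || is.null(cells))
      stop_fmt("mtx input needs gene and cell name sidecar files")
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    gn <- norm_genes(readLines(genes, warn = FALSE))
    cn <- readLines(cells, warn = FALSE)
    if (length(gn) != nrow(m) || length(cn) != ncol(m))
      stop_fmt("sidecar name counts (%d genes, %d cells) do not match matrix %dx%d",
               length(gn), length(cn), nrow(m), ncol(m))
    dimnames(m) <- list(gn, cn)
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- norm_genes(df[[1L]])
  }
  if (anyDuplicated(rownames(m))) m <- m[!duplicated(rownames(m)), , drop = FALSE]
  if (any(!is.finite(m[is.na(m) == FALSE])) || anyNA(m))
    stop_fmt("expression matrix contains non-finite values")
  if (any(m < 0)) stop_fmt("expression matrix contains negative values")
  m
}

#' Read a ligand-receptor interaction table
#'
#' Tab-separated export in the style of cell-cell-communication tools:
#' columns `source`, `target` (cell-type labels), `ligand`, `receptor`
#' (underscore-joined gene complexes, for example `TGFBR1_TGFBR2`).
#'
#' @param path TSV path.
#' @return data.frame of class `interaction_table`.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop_fmt("interaction table not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  need <- c("source", "target", "ligand", "receptor")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_fmt("interaction table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- df[, need]
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor)))
    stop_fmt("interaction table has empty ligand/receptor complexes")
  class(df) <- c("interaction_table", "data.frame")
  df
}
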
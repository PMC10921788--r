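# Genotype matrices: clone- or cell-level variant calls with a gene-level
# site annotation. Values follow diploid calling semantics: 0 = no mutation,
# 1 = heterozygous, 2 = homozygous; NA = missing/uncallable.

#' Construct a genotype matrix
#'
#' A `genotype_matrix` holds integer genotypes in \{0, 1, 2, NA\} for a set
#' of rows (clones or cells) by variant sites, plus a site-to-gene-symbol
#' map. Sites without a gene symbol are retained but excluded from gene-set
#' scoring.
#'
#' @param values integer matrix with row names (clone/cell ids) and column
#'   names (site ids); entries must be 0, 1, 2 or `NA`.
#' @param genes optional character vector of gene symbols, one per site
#'   (recycled names from `colnames(values)` if unnamed); `NA` marks
#'   unannotated sites. Symbols are upper-cased.
#' @return an object of class `genotype_matrix` with elements `values`
#'   (integer matrix) and `genes` (named character vector, one per site).
#' @export
#' @examples
#' m <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("cl1", "cl2"), c("s1", "s2")))
#' genotype_matrix(m, genes = c(s1 = "EGFR", s2 = "TP53"))
genotype_matrix <- function(values, genes = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_fmt("genotype matrix needs row and column names")
  if (anyDuplicated(rownames(values)))
    stop_fmt("duplicate row ids: %s",
             paste(unique(rownames(values)[duplicated(rownames(values))]),
                   collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_fmt("duplicate site ids")
  storage.mode(values) <- "integer"
  bad <- which(!is.na(values) & !(values %in% 0:2), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_fmt("genotype values must be 0, 1, 2 or NA; offending entry at row '%s', site '%s'",
             rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]])
  if (is.null(genes)) {
    genes <- rep(NA_character_, ncol(values))
    names(genes) <- colnames(values)
  } else {
    if (is.null(names(genes))) {
      if (length(genes) != ncol(values))
        stop_fmt("gene map length (%d) != number of sites (%d)",
                 length(genes), ncol(values))
      names(genes) <- colnames(values)
    }
    missing_sites <- setdiff(colnames(values), names(genes))
    full <- rep(NA_character_, ncol(values))
    names(full) <- colnames(values)
    keep <- intersect(names(genes), colnames(values))
    full[keep] <- as.character(genes[keep])
    genes <- full
    genes[!is.na(genes)] <- norm_genes(genes[!is.na(genes)])
  }
  structure(list(values = values, genes = genes), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d rows x %d sites (%d gene-annotated)\n",
              nrow(x$values), ncol(x$values), sum(!is.na(x$genes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Read a genotype matrix from a tab-separated file
#'
#' The file has a header row of site ids and one row per clone/cell, first
#' column the row id. An optional row whose id is `gene` immediately after
#' the header carries the per-site gene symbols; alternatively a two-column
#' site/gene TSV can be supplied via `gene_map`. Missing genotypes use the
#' token `NA`.
#'
#' @param path path to the genotype TSV.
#' @param gene_map optional path to a two-column (site, gene) TSV, or a
#'   named character vector site -> gene.
#' @return a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, gene_map = NULL) {
  if (!file.exists(path)) stop_fmt("genotype file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", row.names = NULL,
                           na.strings = NULL)
  if (ncol(raw) < 2L) stop_fmt("genotype file needs an id column plus >=1 site")
  ids <- raw[[1L]]
  genes <- NULL
  if (nrow(raw) > 0L && identical(tolower(ids[1L]), "gene")) {
    genes <- as.character(raw[1L, -1L])
    genes[genes %in% c("", "NA")] <- NA_character_
    raw <- raw[-1L, , drop = FALSE]
    ids <- raw[[1L]]
  }
  if (anyDuplicated(ids))
    stop_fmt("duplicate row ids in %s: %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  site_ids <- colnames(vals)
  ok <- vals %in% c("0", "1", "2", "NA", "")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    rc <- arrayInd(bad, dim(vals))
    stop_fmt("invalid genotype value '%s' at row '%s', column '%s' in %s",
             vals[bad], ids[rc[1L]], site_ids[rc[2L]], path)
  }
  vals[vals %in% c("NA", "")] <- NA
  storage.mode(vals) <- "integer"
  dimnames(vals) <- list(ids, site_ids)
  if (!is.null(gene_map)) {
    if (is.character(gene_map) && length(gene_map) == 1L && is.null(names(gene_map))) {
      gm <- utils::read.delim(gene_map, header = FALSE, sep = "\t",
                              colClasses = "character")
      genes2 <- gm[[2L]]
      names(genes2) <- gm[[1L]]
    } else {
      genes2 <- gene_map
    }
    if (!is.null(genes))
      warn_fmt("both embedded gene row and gene_map supplied; gene_map wins")
    genes <- genes2
  } else if (!is.null(genes)) {
    names(genes) <- site_ids
  }
  genotype_matrix(vals, genes = genes)
}

#' Write a genotype matrix to a tab-separated file
#'
#' Inverse of [read_genotype_matrix()]: emits the gene annotation as an
#' embedded `gene` row when any site is annotated, and `NA` for missing
#' genotypes. Round trips are lossless.
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  vals <- x$values
  out <- rbind(colnames(vals), NULL)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(vals)), collapse = "\t"), con)
  if (any(!is.na(x$genes))) {
    g <- ifelse(is.na(x$genes), "NA", x$genes)
    writeLines(paste(c("gene", g), collapse = "\t"), con)
  }
  body <- apply(vals, 1L, function(r) paste(ifelse(is.na(r), "NA", r), collapse = "\t"))
  writeLines(paste(rownames(vals), body, sep = "\t"), con)
  invisible(path)
}

#' Mutated genes of one clone or cell
#'
#' Genes whose mapped site carries genotype >= 1 (heterozygous or
#' homozygous) in the given row. Missing genotypes contribute nothing, and
#' sites without a gene annotation are skipped. Dosage is not distinguished:
#' downstream scores operate on gene sets.
#'
#' @param genotypes a [genotype_matrix()].
#' @param row_id a row identifier.
#' @return character vector of unique gene symbols.
#' @export
mutated_gene_set <- function(genotypes, row_id) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!row_id %in% rownames(genotypes$values))
    stop_fmt("unknown row id '%s'", row_id)
  v <- genotypes$values[row_id, ]
  hit <- !is.na(v) & v >= 1L
  genes <- genotypes$genes[hit]
  sort(unique(genes[!is.na(genes)]))
}

#' Per-clone mutation summary statistics
#'
#' For each row (clone) counts sites with genotype >= 1, the fraction of
#' those mapped to a genic symbol, and the fraction whose site id appears in
#' a caller-supplied known-variant set (for example COSMIC-annotated
#' variants). Fractions are `NA`, not 0, when a clone has no mutations or
#' when the corresponding reference set is absent.
#'
#' @param genotypes a clone-level [genotype_matrix()].
#' @param genic_genes optional character vector of protein-coding gene
#'   symbols (for example the consensus CDS set).
#' @param known_variants optional character vector of known variant site
#'   ids.
#' @return data.frame with columns `clone`, `n_mutations`, `frac_genic`,
#'   `frac_known`.
#' @export
clone_mutation_summary <- function(genotypes, genic_genes = NULL,
                                   known_variants = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!is.null(genic_genes)) genic_genes <- norm_genes(genic_genes)
  res <- lapply(rownames(genotypes$values), function(cl) {
    v <- genotypes$values[cl, ]
    hit <- !is.na(v) & v >= 1L
    n <- sum(hit)
    genes <- genotypes$genes[hit]
    sites <- colnames(genotypes$values)[hit]
    fg <- if (n == 0L || is.null(genic_genes) || length(genic_genes) == 0L)
      NA_real_ else mean(!is.na(genes) & genes %in% genic_genes)
    fk <- if (n == 0L || is.null(known_variants) || length(known_variants) == 0L)
      NA_real_ else mean(sites %in% known_variants)
    data.frame(clone = cl, n_mutations = n, frac_genic = fg, frac_known = fk,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
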
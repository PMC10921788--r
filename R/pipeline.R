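# Workflow orchestration: per-sample tree building and scoring across a
# whole cell table, plus the command-line entry point that ties the
# modules into the tree -> score -> path/selection -> compare workflow.

#' Build one clonal tree per sample
#'
#' Subsets the clone-level genotype matrix to the clones observed in each
#' sample's cells and builds the sample's tree. Clone ids must be unique
#' across the genotype matrix; analyses remain grouped per sample.
#'
#' @param genotypes clone-level [genotype_matrix()].
#' @param cells a [cell_table()].
#' @return named list of `clonal_tree` objects, one per sample.
#' @export
sample_trees <- function(genotypes, cells) {
  samples <- unique(cells$sample_id)
  out <- lapply(samples, function(s) {
    sub <- cells[cells$sample_id == s, , drop = FALSE]
    clones <- intersect(rownames(genotypes$values), unique(sub$clone_id))
    if (length(clones) == 0L)
      stop_fmt("sample '%s': no clone of its cells is in the genotype matrix", s)
    gm <- genotype_matrix(genotypes$values[clones, , drop = FALSE],
                          genes = genotypes$genes)
    build_tree(gm, cells = sub)
  })
  stats::setNames(out, samples)
}

#' Score every clone of every sample against a signature collection
#'
#' Computes, per sample and clone, the mutation signature score for each
#' gene set; with an expression matrix also the per-clone transcription
#' module score and mutated-gene expression score (per-cell scores averaged
#' over the clone's cells). Metabolism-category sets (per the collection's
#' `category` attribute) are subject to the minimum-shared-gene rules.
#'
#' @param genotypes clone-level [genotype_matrix()].
#' @param cells a [cell_table()].
#' @param signatures named list of gene sets (see [read_gmt()]).
#' @param expr optional genes x cells expression matrix.
#' @param coding_filter optional permitted gene symbols for the mutation
#'   score.
#' @param n_bins,n_ctrl,seed module-score parameters.
#' @param min_metab_genes minimum shared/expressed genes for metabolism
#'   sets (default 3).
#' @return long data.frame: `sample_id`, `clone_id`, `kind` (one of
#'   `mutation`, `transcription`, `mutated_expression`), `feature`,
#'   `score`, `n_cells`.
#' @export
score_table <- function(genotypes, cells, signatures, expr = NULL,
                        coding_filter = NULL, n_bins = 24L, n_ctrl = 100L,
                        seed = 0L, min_metab_genes = 3L) {
  category <- attr(signatures, "category")
  if (is.null(category))
    category <- stats::setNames(rep("cancer", length(signatures)), names(signatures))
  sizes <- clone_sizes(cells)
  out <- list()
  emit <- function(sample, clone, kind, feature, score, n) {
    out[[length(out) + 1L]] <<- data.frame(
      sample_id = sample, clone_id = clone, kind = kind, feature = feature,
      score = score, n_cells = n, stringsAsFactors = FALSE)
  }
  # per-feature per-cell transcription scores are shared by all clones
  tscores <- list()
  if (!is.null(expr)) {
    for (f in names(signatures)) {
      min_g <- if (identical(category[[f]], "metabolism")) min_metab_genes else 1L
      tscores[[f]] <- transcription_module_score(expr, signatures[[f]],
                                                 n_bins = n_bins,
                                                 n_ctrl = n_ctrl, seed = seed,
                                                 min_genes = min_g)
    }
  }
  for (i in seq_len(nrow(sizes))) {
    s <- sizes$sample_id[i]
    cl <- sizes$clone_id[i]
    n <- sizes$n_cells[i]
    if (!cl %in% rownames(genotypes$values)) next
    mg <- mutated_gene_set(genotypes, cl)
    cell_ids <- cells$cell_id[cells$sample_id == s & cells$clone_id == cl]
    for (f in names(signatures)) {
      emit(s, cl, "mutation", f,
           mutation_signature_score(mg, signatures[[f]], coding_filter), n)
      if (!is.null(expr)) {
        if (!is.null(tscores[[f]])) {
          v <- tscores[[f]][intersect(cell_ids, names(tscores[[f]]))]
          emit(s, cl, "transcription", f,
               if (length(v) == 0L) NA_real_ else mean(v, na.rm = TRUE), n)
        }
        me <- mutated_expression_score(expr, mg, signatures[[f]],
                                       min_expressed = min_metab_genes,
                                       metabolism = identical(category[[f]],
                                                              "metabolism"))
        if (!is.null(me)) {
          v <- me[intersect(cell_ids, names(me))]
          v <- v[!is.na(v)]
          emit(s, cl, "mutated_expression", f,
               if (length(v) == 0L) NA_real_ else mean(v), n)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- command-line entry point ----------------------------------------------

cli_parse <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_fmt("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop_fmt("option --%s needs a value", key)
    opts[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

cli_need <- function(opts, keys) {
  miss <- setdiff(keys, names(opts))
  if (length(miss) > 0L)
    stop_fmt("missing required option(s): %s",
             paste(paste0("--", gsub("_", "-", miss)), collapse = ", "))
  for (k in keys) {
    if (grepl("genotypes|cells|scores|results|expr|gmt|config|contexts|sig_",
              k) && !file.exists(opts[[k]]))
      stop_fmt("input file not found: %s", opts[[k]])
  }
  opts
}

write_manifest <- function(out_dir, subcommand, opts, warnings = character(0)) {
  inputs <- opts[vapply(opts, function(v) is.character(v) && file.exists(v) &&
                          !dir.exists(v), logical(1L))]
  manifest <- list(
    subcommand = subcommand,
    package = "clonepath",
    version = as.character(utils::packageVersion("clonepath")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = opts,
    input_md5 = if (length(inputs)) as.list(tools::md5sum(unlist(inputs))) else list(),
    warnings = as.character(warnings),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_scores_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = NA)
  need <- c("sample_id", "clone_id", "feature", "score")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop_fmt("score table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"kind" %in% names(df)) df$kind <- "score"
  df
}

#' Run a workflow subcommand
#'
#' Thin command-line orchestration over the package functions. Subcommands:
#' `tree`, `score`, `path`, `selection`, `degeneracy`, `compare`,
#' `overlap`, `simulate`. Each writes its result TSV/JSON files plus a
#' `manifest.json` (package version, parameters, input checksums,
#' accumulated warnings) into the `--out` directory. Progress and warnings
#' go to stderr. See the package vignette for the option list per
#' subcommand; an installed `exec/clonepath` script forwards shell
#' arguments here.
#'
#' @param args character vector: subcommand followed by `--option value`
#'   pairs.
#' @return integer exit status (0 on success), invisibly.
#' @export
run_pipeline <- function(args) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop_fmt(paste("usage: clonepath <tree|score|path|selection|degeneracy|",
                     "compare|overlap|simulate> [--option value ...]", sep = ""))
    subcommand <- args[1L]
    opts <- cli_parse(args[-1L])
    out_dir <- if (!is.null(opts$out)) opts$out else "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    warns <- character(0)
    run <- function(expr) withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      message("WARN: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    seed <- as.integer(if (!is.null(opts$seed)) opts$seed else 0L)
    min_cells <- as.integer(if (!is.null(opts$min_cells)) opts$min_cells else 10L)
    switch(subcommand,
      tree = {
        cli_need(opts, c("genotypes", "cells"))
        gm <- read_genotype_matrix(opts$genotypes, gene_map = opts$gene_map)
        cells <- read_cell_table(opts$cells)
        check_ids(gm, cells)
        trees <- run(sample_trees(gm, cells))
        for (s in names(trees)) {
          message("sample ", s, ": ", nrow(trees[[s]]$nodes), " clones")
          write_tree_tsv(trees[[s]], file.path(out_dir, paste0("tree_", s, ".tsv")))
          writeLines(tree_newick(trees[[s]]),
                     file.path(out_dir, paste0("tree_", s, ".nwk")))
        }
        adc <- vapply(trees, abundance_depth_correlation, numeric(1L))
        write_tsv(data.frame(sample_id = names(trees), abundance_depth_rho = adc),
                  file.path(out_dir, "abundance_depth.tsv"))
      },
      score = {
        cli_need(opts, c("genotypes", "cells", "gmt"))
        gm <- read_genotype_matrix(opts$genotypes, gene_map = opts$gene_map)
        cells <- read_cell_table(opts$cells)
        check_ids(gm, cells)
        sets <- read_gmt(opts$gmt)
        expr <- if (!is.null(opts$expr))
          read_expression(opts$expr, genes = opts$expr_genes,
                          cells = opts$expr_cells)
        coding <- if (!is.null(opts$coding)) readLines(opts$coding, warn = FALSE)
        st <- run(score_table(gm, cells, sets, expr = expr,
                              coding_filter = coding, seed = seed))
        write_tsv(st, file.path(out_dir, "scores.tsv"))
      },
      path = ,
      selection = {
        cli_need(opts, c("scores", "genotypes", "cells"))
        gm <- read_genotype_matrix(opts$genotypes, gene_map = opts$gene_map)
        cells <- read_cell_table(opts$cells)
        check_ids(gm, cells)
        st <- read_scores_tsv(opts$scores)
        trees <- run(sample_trees(gm, cells))
        res <- list()
        for (s in names(trees)) {
          sub <- st[st$sample_id == s, , drop = FALSE]
          for (kind in unique(sub$kind)) {
            ss <- sub[sub$kind == kind, , drop = FALSE]
            tab <- if (subcommand == "path")
              path_result_table(ss, trees[[s]], min_cells = min_cells,
                                sample_id = s)
            else
              selection_result_table(ss, trees[[s]], min_cells = min_cells,
                                     sample_id = s)
            if (nrow(tab) > 0L) {
              tab$kind <- kind
              res[[length(res) + 1L]] <- tab
            }
          }
        }
        if (length(res) == 0L) stop_fmt("no usable paths/clones after filtering")
        write_tsv(do.call(rbind, res),
                  file.path(out_dir, paste0(subcommand, "_results.tsv")))
      },
      degeneracy = {
        cli_need(opts, "cells")
        cells <- read_cell_table(opts$cells)
        n_perm <- as.integer(if (!is.null(opts$n_perm)) opts$n_perm else 0L)
        rep <- run(degeneracy_report(cells, n_perm = n_perm, seed = seed))
        write_tsv(as.data.frame(rep), file.path(out_dir, "degeneracy.tsv"))
      },
      compare = {
        cli_need(opts, c("results", "contexts"))
        res <- utils::read.delim(opts$results, sep = "\t", check.names = FALSE)
        ctx <- utils::read.delim(opts$contexts, sep = "\t", check.names = FALSE,
                                 colClasses = "character")
        if (!all(c("sample_id", "context") %in% names(ctx)))
          stop_fmt("contexts file needs columns sample_id, context")
        if (length(unique(ctx$context)) < 2L)
          stop_fmt("need >= 2 contexts, got %d", length(unique(ctx$context)))
        alpha_q <- as.numeric(if (!is.null(opts$alpha_q)) opts$alpha_q else 0.1)
        kinds <- if ("kind" %in% names(res)) unique(res$kind) else "score"
        if (!"kind" %in% names(res)) res$kind <- "score"
        for (kind in kinds) {
          cmp <- run(compare_contexts(res[res$kind == kind, , drop = FALSE],
                                      ctx, alpha_q = alpha_q))
          write_tsv(as.data.frame(cmp),
                    file.path(out_dir, paste0("compare_", kind, ".tsv")))
        }
      },
      overlap = {
        cli_need(opts, c("sig_a", "sig_b", "universe"))
        a <- readLines(opts$sig_a, warn = FALSE)
        b <- readLines(opts$sig_b, warn = FALSE)
        ov <- overlap_obs_exp_total(a[nzchar(a)], b[nzchar(b)],
                                    as.integer(opts$universe))
        jsonlite::write_json(ov, file.path(out_dir, "overlap.json"),
                             auto_unbox = TRUE, digits = NA)
      },
      simulate = {
        cfg <- if (!is.null(opts$config)) read_sim_config(opts$config)
               else sim_config()
        if (!is.null(opts$seed)) cfg$seed <- seed
        rep <- run(validation_experiment(cfg))
        write_tsv(rep$iterations, file.path(out_dir, "simulation_iterations.tsv"))
        jsonlite::write_json(
          list(mode = rep$mode, median_perfect = rep$median_perfect,
               median_random = rep$median_random, p_value = rep$p_value,
               n_perfect = length(rep$perfect), n_random = length(rep$random),
               settings = unclass(cfg)),
          file.path(out_dir, "simulation_summary.json"),
          auto_unbox = TRUE, digits = NA)
      },
      stop_fmt("unknown subcommand '%s'", subcommand)
    )
    write_manifest(out_dir, subcommand, opts, warns)
    0L
  }, error = function(e) {
    message("ERROR: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# Consistency check between genotype rows and cell-table clone ids: every
# clone referenced by a cell must have a genotype row.
check_ids <- function(genotypes, cells) {
  missing <- setdiff(unique(cells$clone_id), rownames(genotypes$values))
  if (length(missing) > 0L)
    stop_fmt("clone id(s) in cell table without genotype row: %s%s",
             paste(utils::head(missing, 10L), collapse = ", "),
             if (length(missing) > 10L) sprintf(" (+%d more)",
                                                length(missing) - 10L) else "")
  invisible(TRUE)
}
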
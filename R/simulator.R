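# Clonal-tree simulator and the validation experiment: generate a ground-
# truth tree with inherited mutations, observe it through per-entry
# genotype noise (false positives, false negatives, missing entries),
# rebuild the tree from consensus genotypes, and test whether the
# evolutionary-path and clonal-selection statistics separate a depth- (or
# abundance-) correlated signature from a random one.

#' Simulation configuration
#'
#' Defaults are the study conditions of the validation experiment: 20
#' cells, 5 clones, 100 mutation sites, per-entry false positive and false
#' negative rates of 0.2, missing probability 0.2, no unobserved clones,
#' 100 iterations.
#'
#' @param n_cells number of simulated cells (`>= n_clones`).
#' @param n_clones number of clones (`>= 2`).
#' @param n_sites number of mutation sites (`>= n_clones`).
#' @param fpr per-entry probability of observing 1 where the truth is 0.
#' @param fnr per-entry probability of observing 0 where the truth is 1.
#' @param p_missing per-entry probability of masking the observation.
#' @param n_unobserved unobserved clones (kept at 0; inference of
#'   unobserved clones is out of scope).
#' @param n_iterations iterations of the validation experiment.
#' @param seed RNG seed; all randomness in a run flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 20L, n_clones = 5L, n_sites = 100L,
                       fpr = 0.2, fnr = 0.2, p_missing = 0.2,
                       n_unobserved = 0L, n_iterations = 100L, seed = 0L) {
  if (n_clones < 2L) stop_fmt("n_clones must be >= 2")
  if (n_sites < n_clones)
    stop_fmt("n_sites (%d) < n_clones (%d): cannot give each clone a private mutation",
             n_sites, n_clones)
  if (n_cells < n_clones)
    stop_fmt("n_cells (%d) < n_clones (%d): cannot put a cell in every clone",
             n_cells, n_clones)
  for (r in c(fpr, fnr, p_missing))
    if (r < 0 || r > 1) stop_fmt("noise rates must be in [0, 1]")
  if (n_unobserved != 0L) stop_fmt("unobserved clones are not supported")
  structure(list(n_cells = as.integer(n_cells), n_clones = as.integer(n_clones),
                 n_sites = as.integer(n_sites), fpr = fpr, fnr = fnr,
                 p_missing = p_missing, n_unobserved = 0L,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a flat key-value file
#'
#' Keys follow the conventional simulator parameter names: `N.cells`,
#' `N.clones`, `N.sites`, `N.unobs`, `FPR`, `FNR`, `p.missing`,
#' `iterations`, `seed`, one `key value` (or `key=value`) pair per line;
#' `#` starts a comment. Missing keys keep their defaults.
#'
#' @param path config file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "[=[:space:]]+")
  keys <- vapply(kv, `[`, character(1L), 1L)
  vals <- as.numeric(vapply(kv, `[`, character(1L), 2L))
  get <- function(key, default) if (key %in% keys) vals[match(key, keys)] else default
  sim_config(n_cells = get("N.cells", 20), n_clones = get("N.clones", 5),
             n_sites = get("N.sites", 100), fpr = get("FPR", 0.2),
             fnr = get("FNR", 0.2), p_missing = get("p.missing", 0.2),
             n_unobserved = get("N.unobs", 0),
             n_iterations = get("iterations", 100), seed = get("seed", 0))
}

# Build a clonal_tree object directly from a parent vector (1-indexed,
# parent[root] = NA), clone ids, weights and cell counts.
tree_from_parents <- function(parents, ids, weights, counts, nmut) {
  depth <- integer(length(ids))
  for (i in seq_along(ids)) {
    d <- 0L
    j <- i
    while (!is.na(parents[j])) {
      d <- d + 1L
      j <- parents[j]
    }
    depth[i] <- d
  }
  edges <- data.frame(parent = ids[parents[!is.na(parents)]],
                      child = ids[which(!is.na(parents))],
                      weight = weights[!is.na(parents)],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(clone = ids, n_cells = as.integer(counts),
                      n_mutations = as.integer(nmut), depth = depth,
                      parent = ifelse(is.na(parents), NA_character_, ids[parents]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, root = ids[which(is.na(parents))]),
            class = "clonal_tree")
}

# Core generator without seed management (validation_experiment drives many
# draws from one seeded stream).
simulate_truth_impl <- function(config) {
  n <- config$n_clones
  ids <- sprintf("clone%02d", seq_len(n))
  # uniform attachment: clone k+1 picks its parent uniformly from clones 1..k
  parents <- c(NA_integer_,
               vapply(seq_len(n - 1L), function(k) sample.int(k, 1L),
                      integer(1L)))
  # one private site per non-root clone, remaining sites placed uniformly
  origin <- c(seq_len(n)[-1L],
              sample.int(n, config$n_sites - (n - 1L), replace = TRUE))
  origin <- sample(origin)
  ancestors <- lapply(seq_len(n), function(i) {
    a <- i
    while (!is.na(parents[a[1L]])) a <- c(parents[a[1L]], a)
    a
  })
  geno <- matrix(0L, n, config$n_sites,
                 dimnames = list(ids, sprintf("site%03d", seq_len(config$n_sites))))
  for (i in seq_len(n)) geno[i, origin %in% ancestors[[i]]] <- 1L
  # every clone gets at least one cell, the rest assigned uniformly
  assignment <- c(seq_len(n),
                  if (config$n_cells > n)
                    sample.int(n, config$n_cells - n, replace = TRUE))
  assignment <- sample(assignment)
  names(assignment) <- sprintf("cell%03d", seq_len(config$n_cells))
  counts <- tabulate(assignment, nbins = n)
  priv <- tabulate(origin, nbins = n)
  weights <- priv  # child edge weight = child's private sites
  tree <- tree_from_parents(parents, ids, weights, counts, rowSums(geno))
  structure(list(tree = tree, genotypes = geno,
                 assignment = stats::setNames(ids[assignment], names(assignment)),
                 site_origin = stats::setNames(ids[origin], colnames(geno)),
                 config = config),
            class = "ground_truth")
}

#' Simulate a ground-truth clonal tree, genotypes and cell assignment
#'
#' Generates a random rooted tree over `n_clones` by uniform attachment,
#' assigns each of `n_sites` mutations to an originating clone (every
#' non-root clone is guaranteed at least one private site, so all pairwise
#' genotype distances are positive), inherits mutations along the tree, and
#' assigns cells to clones uniformly with every clone receiving at least
#' one cell. Deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `ground_truth` with `tree` (a `clonal_tree`),
#'   `genotypes` (clone x site 0/1 matrix), `assignment` (named cell ->
#'   clone vector), `site_origin`, and the config.
#' @export
simulate_truth <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, simulate_truth_impl(config))
}

add_noise_impl <- function(truth, config) {
  obs <- truth$genotypes[truth$assignment, , drop = FALSE]
  rownames(obs) <- names(truth$assignment)
  nr <- nrow(obs)
  nc <- ncol(obs)
  flip_up <- matrix(stats::runif(nr * nc) < config$fpr, nr, nc)
  flip_dn <- matrix(stats::runif(nr * nc) < config$fnr, nr, nc)
  mask <- matrix(stats::runif(nr * nc) < config$p_missing, nr, nc)
  out <- obs
  out[obs == 0L & flip_up] <- 1L
  out[obs == 1L & flip_dn] <- 0L
  out[mask] <- NA_integer_
  genotype_matrix(out, genes = stats::setNames(colnames(out), colnames(out)))
}

#' Observe simulated genotypes through per-entry noise
#'
#' Each cell's observed genotype is its clone's true genotype with
#' independent per-entry errors: a 0 becomes 1 with probability `fpr`, a 1
#' becomes 0 with probability `fnr`, and any entry is masked (missing) with
#' probability `p_missing`. Deterministic given the seed.
#'
#' @param truth a [simulate_truth()] result.
#' @param config a [sim_config()] supplying the noise rates.
#' @param seed optional override of `config$seed`.
#' @return a cell-level [genotype_matrix()].
#' @export
add_noise <- function(truth, config = truth$config, seed = config$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  with_seed(seed, add_noise_impl(truth, config))
}

#' Rebuild the clonal tree from noisy cell genotypes
#'
#' Collapses cells to clone consensus genotypes by per-site majority vote
#' over the assigned cells (ties vote mutated; an all-missing site counts
#' as 0 for that clone) and rebuilds the tree with [build_tree()]. The
#' ground-truth cell-to-clone assignment is reused deliberately: the
#' clustering step is not under test here, and this isolates the path and
#' selection statistics from clustering error.
#'
#' @param noisy cell-level [genotype_matrix()] from [add_noise()].
#' @param assignment named cell -> clone vector (from the ground truth).
#' @return a `clonal_tree` over the consensus genotypes.
#' @export
reconstruct <- function(noisy, assignment) {
  stopifnot(inherits(noisy, "genotype_matrix"))
  cells <- intersect(rownames(noisy$values), names(assignment))
  if (length(cells) == 0L) stop_fmt("no cells shared between matrix and assignment")
  clones <- sort(unique(assignment[cells]))
  cons <- t(vapply(clones, function(cl) {
    sub <- noisy$values[cells[assignment[cells] == cl], , drop = FALSE]
    frac <- colMeans(sub == 1L, na.rm = TRUE)
    frac[is.nan(frac)] <- 0  # all-missing site column -> 0 for this clone
    as.integer(frac >= 0.5)  # ties vote mutated
  }, integer(ncol(noisy$values))))
  dimnames(cons) <- list(clones, colnames(noisy$values))
  counts <- table(assignment[cells])
  build_tree(genotype_matrix(cons, genes = noisy$genes),
             cell_counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Perfect and random per-clone signatures for a truth tree
#'
#' The perfect signature tracks the ground-truth tree exactly: each clone
#' gets `1 + depth` (root level 1, its children 2, and so on). The random
#' signature assigns each clone an independent uniform value. For the
#' clonal-selection variant (`mode = "selection"`), the perfect signature
#' is instead the clone's relative abundance.
#'
#' @param tree a `clonal_tree` (the ground truth).
#' @param seed RNG seed for the random signature.
#' @param mode `"path"` (depth-correlated) or `"selection"`
#'   (abundance-correlated).
#' @return list with named numeric vectors `perfect` and `random`.
#' @export
make_signatures <- function(tree, seed = 0L, mode = c("path", "selection")) {
  mode <- match.arg(mode)
  n <- tree$nodes
  perfect <- if (mode == "path") stats::setNames(1 + n$depth, n$clone)
             else stats::setNames(n$n_cells / sum(n$n_cells), n$clone)
  random <- with_seed(seed, stats::setNames(stats::runif(nrow(n)), n$clone))
  list(perfect = perfect, random = random)
}

#' Validation experiment: perfect vs random signature recovery
#'
#' Runs `n_iterations` rounds of simulate / add noise / reconstruct, scores
#' a perfect (depth- or abundance-correlated) and a random signature on the
#' reconstructed tree with the evolutionary-path (or clonal-selection)
#' statistic, pools the coefficients, and compares the two pools with a
#' two-sided Wilcoxon rank-sum test. The minimum-clone-size path filter is
#' disabled by default: at the default 20 cells over 5 clones, average
#' clone sizes of ~4 cells would otherwise empty every path.
#'
#' @param config a [sim_config()] (`n_iterations >= 2`).
#' @param mode `"path"` or `"selection"`.
#' @param min_cells clone-size filter passed to path/abundance extraction
#'   (default 0 = disabled).
#' @return list of class `validation_report`: `iterations` (data.frame
#'   iteration, signature, rho), `perfect`, `random` (pooled coefficient
#'   vectors), `median_perfect`, `median_random`, `p_value`, `mode`,
#'   `config`, and `diagnostic` (non-`NULL` when no coefficients could be
#'   computed).
#' @export
validation_experiment <- function(config, mode = c("path", "selection"),
                                  min_cells = 0L) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (config$n_iterations < 2L) stop_fmt("n_iterations must be >= 2")
  rows <- with_seed(config$seed, {
    lapply(seq_len(config$n_iterations), function(it) {
      truth <- simulate_truth_impl(config)
      noisy <- add_noise_impl(truth, config)
      recon <- reconstruct(noisy, truth$assignment)
      sigs <- list(
        perfect = make_signatures(truth$tree, seed = sample.int(2^30, 1L),
                                  mode = mode)$perfect,
        random = stats::setNames(stats::runif(nrow(truth$tree$nodes)),
                                 truth$tree$nodes$clone))
      if (mode == "path") {
        paths <- extract_paths(recon, min_cells = min_cells)
        do.call(rbind, lapply(names(sigs), function(nm) {
          if (length(paths) == 0L) return(NULL)
          data.frame(iteration = it, signature = nm,
                     rho = vapply(paths, function(p)
                       path_correlation(sigs[[nm]], p), numeric(1L)),
                     stringsAsFactors = FALSE, row.names = NULL)
        }))
      } else {
        nodes <- recon$nodes[recon$nodes$n_cells >= min_cells, , drop = FALSE]
        ab <- stats::setNames(nodes$n_cells / sum(nodes$n_cells), nodes$clone)
        do.call(rbind, lapply(names(sigs), function(nm) data.frame(
          iteration = it, signature = nm,
          rho = selection_correlation(sigs[[nm]], ab),
          stringsAsFactors = FALSE, row.names = NULL)))
      }
    })
  })
  iters <- do.call(rbind, rows)
  perfect <- iters$rho[iters$signature == "perfect" & !is.na(iters$rho)]
  random <- iters$rho[iters$signature == "random" & !is.na(iters$rho)]
  diagnostic <- NULL
  if (length(perfect) == 0L || length(random) == 0L) {
    diagnostic <- "no usable path/selection coefficients (all paths shorter than 3 clones?)"
    p <- NA_real_
  } else {
    p <- rank_sum_test(perfect, random)$p.value
  }
  structure(list(iterations = iters, perfect = perfect, random = random,
                 median_perfect = if (length(perfect)) stats::median(perfect) else NA_real_,
                 median_random = if (length(random)) stats::median(random) else NA_real_,
                 p_value = p, mode = mode, config = config,
                 diagnostic = diagnostic),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report (%s): %d iterations\n", x$mode,
              x$config$n_iterations))
  cat(sprintf("  perfect pool: n=%d, median=%.3f\n", length(x$perfect),
              x$median_perfect))
  cat(sprintf("  random pool:  n=%d, median=%.3f\n", length(x$random),
              x$median_random))
  cat(sprintf("  two-sided rank-sum p = %.3g\n", x$p_value))
  if (!is.null(x$diagnostic)) cat("  diagnostic:", x$diagnostic, "\n")
  invisible(x)
}
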
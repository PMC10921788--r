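# Evolutionary-path and clonal-selection statistics: Spearman correlation
# of per-clone feature scores against tree depth (along root-to-leaf paths)
# or against relative clonal abundance, cross-context comparison by
# rank-based tests with Benjamini-Hochberg correction, and the
# observed/expected overlap statistics between significant feature sets.

#' Evolutionary path score
#'
#' Spearman correlation (average ranks) between per-clone feature scores
#' and clone depth along one root-to-leaf path. `NA` when fewer than 3
#' clones on the path carry a score, or when the scores have zero variance.
#'
#' @param scores named numeric vector, names = clone ids.
#' @param path one element of [extract_paths()] (data.frame with `clone`,
#'   `depth`).
#' @return Spearman coefficient in `[-1, 1]`, or `NA`.
#' @export
path_correlation <- function(scores, path) {
  s <- scores[match(path$clone, names(scores))]
  spearman_rho(as.numeric(s), path$depth)
}

#' Clonal selection score
#'
#' Spearman correlation between per-clone feature scores and relative
#' clonal abundance within the sample. Abundances are expected to be
#' computed over the clones that survive the same minimum-cell-count
#' exclusion used for path analysis.
#'
#' @param scores named numeric vector, names = clone ids.
#' @param abundances named numeric vector of relative clone proportions
#'   (summing to 1 over the sample's included clones).
#' @return Spearman coefficient in `[-1, 1]`, or `NA`.
#' @export
selection_correlation <- function(scores, abundances) {
  common <- intersect(names(scores), names(abundances))
  spearman_rho(as.numeric(scores[common]), as.numeric(abundances[common]))
}

#' Two-sample Wilcoxon rank-sum test with exact tie handling
#'
#' For small pooled samples (`length(x) + length(y) <= exact_max`) the
#' two-sided p value is computed by exact enumeration of the permutation
#' distribution of the rank sum with average ranks, which remains exact in
#' the presence of ties; larger samples fall back to the tie-corrected
#' normal approximation of [stats::wilcox.test()].
#'
#' @param x,y numeric vectors.
#' @param exact_max pooled-size threshold for exact enumeration (default
#'   12).
#' @return list with `statistic` (rank sum of `x`) and `p.value`.
#' @export
rank_sum_test <- function(x, y, exact_max = 12L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  m <- length(x)
  n <- length(y)
  if (m == 0L || n == 0L) return(list(statistic = NA_real_, p.value = NA_real_))
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  if (m + n <= exact_max) {
    mu <- m * (m + n + 1) / 2
    idx <- utils::combn(m + n, m)
    w_all <- colSums(matrix(r[idx], nrow = m))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  list(statistic = w_obs, p.value = min(1, p))
}

#' Compare path or selection coefficients across clinical contexts
#'
#' Pools the Spearman coefficients of each feature by context (one
#' observation per path per sample for path analysis; one per sample for
#' selection analysis), tests for a context difference — two-sided Wilcoxon
#' rank-sum for two contexts, Kruskal-Wallis for three or more — and
#' corrects across features by Benjamini-Hochberg. Call it once per score
#' kind and comparison: the features passed in together form one BH family,
#' matching separately reported result panels.
#'
#' @param results data.frame with columns `sample_id`, `feature`, `rho`
#'   (and anything else, ignored); `NA` coefficients are dropped.
#' @param contexts named character vector sample id -> context label, or a
#'   data.frame with columns `sample_id`, `context`.
#' @param alpha_q significance threshold on the BH q value (default 0.1).
#' @param min_obs minimum observations per context per feature (default 2);
#'   features failing it are excluded with a warning.
#' @return data.frame of class `group_comparison`: one row per feature with
#'   `feature`, `n_obs`, `statistic`, `p`, `q`, `enriched` (context with
#'   the larger mean coefficient), `significant`, plus `mean.<context>` and
#'   `se.<context>` columns.
#' @export
compare_contexts <- function(results, contexts, alpha_q = 0.1, min_obs = 2L) {
  if (is.data.frame(contexts))
    contexts <- stats::setNames(as.character(contexts$context),
                                as.character(contexts$sample_id))
  res <- results[!is.na(results$rho), , drop = FALSE]
  res$context <- contexts[as.character(res$sample_id)]
  if (anyNA(res$context))
    stop_fmt("sample(s) without a context label: %s",
             paste(utils::head(unique(res$sample_id[is.na(res$context)]), 10L),
                   collapse = ", "))
  all_ctx <- sort(unique(unname(contexts)))
  if (length(all_ctx) < 2L) stop_fmt("need >= 2 contexts, got %d", length(all_ctx))
  rows <- list()
  for (f in unique(res$feature)) {
    sub <- res[res$feature == f, , drop = FALSE]
    groups <- split(sub$rho, factor(sub$context, levels = all_ctx))
    sizes <- vapply(groups, length, integer(1L))
    if (sum(sizes >= min_obs) < 2L || any(sizes > 0 & sizes < min_obs)) {
      warn_fmt("feature '%s' excluded: fewer than %d observations in some context",
               f, min_obs)
      next
    }
    groups <- groups[sizes >= min_obs]
    if (length(groups) == 2L) {
      tst <- rank_sum_test(groups[[1L]], groups[[2L]])
      stat <- tst$statistic
      p <- tst$p.value
    } else {
      kw <- stats::kruskal.test(groups)
      stat <- unname(kw$statistic)
      p <- kw$p.value
    }
    means <- vapply(groups, mean, numeric(1L))
    ses <- vapply(groups, function(v) stats::sd(v) / sqrt(length(v)), numeric(1L))
    row <- data.frame(feature = f, n_obs = sum(lengths(groups)),
                      statistic = stat, p = p, stringsAsFactors = FALSE)
    for (ctx in names(groups)) {
      row[[paste0("mean.", ctx)]] <- means[[ctx]]
      row[[paste0("se.", ctx)]] <- ses[[ctx]]
    }
    row$enriched <- names(groups)[which.max(means)]
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L)
    stop_fmt("no feature had enough observations in >= 2 contexts")
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(cols, names(r))) r[[cl]] <- NA_real_
    r[cols]
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= alpha_q
  out <- out[order(out$q, out$p, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "alpha_q") <- alpha_q
  out
}

#' Observed/expected overlap of two significant-feature sets
#'
#' Features significant in two analyses (mutational vs transcriptional, or
#' path vs selection) are compared as feature-direction pairs: a feature
#' enriched in different contexts in the two analyses does not overlap.
#' Observed overlap probability is `|A intersect B| / universe`; expected
#' is `(|A|/universe) * (|B|/universe)`; the statistic is their ratio. When
#' either set is empty the value is 0 by convention. The universe is the
#' number of feature-direction pairs evaluated in both analyses.
#'
#' @param sig_a,sig_b character vectors of significant feature-direction
#'   identifiers.
#' @param universe positive integer, the number of evaluated
#'   feature-direction pairs.
#' @return list with `observed`, `expected`, `ratio`.
#' @export
overlap_obs_exp_total <- function(sig_a, sig_b, universe) {
  if (universe < 1L) stop_fmt("universe must be >= 1")
  sig_a <- unique(sig_a)
  sig_b <- unique(sig_b)
  if (length(sig_a) > universe || length(sig_b) > universe)
    stop_fmt("significant set larger than the universe")
  if (length(sig_a) == 0L || length(sig_b) == 0L)
    return(list(observed = 0, expected = 0, ratio = 0))
  observed <- length(intersect(sig_a, sig_b)) / universe
  expected <- (length(sig_a) / universe) * (length(sig_b) / universe)
  if (expected == 0 && observed > 0)
    stop_fmt("inconsistent inputs: zero expected overlap with positive observed overlap")
  list(observed = observed, expected = expected, ratio = observed / expected)
}

#' Conditional observed/expected overlap for a focal enrichment group
#'
#' Overlap between transcriptional-analysis and mutated-gene-expression
#' significant features, conditioned on a focal enrichment group (for
#' example metastasis): observed = overlap within the focal group divided
#' by the focal group's transcription-significant count; expected = overlap
#' across any group divided by the transcription-significant count across
#' any group. Zero denominators yield 0 by convention.
#'
#' @param sig_ts_focal,sig_me_focal significant features in the focal
#'   group, transcription and mutated-expression analyses.
#' @param sig_ts_any,sig_me_any significant features in any group.
#' @return list with `observed`, `expected`, `ratio`.
#' @export
overlap_obs_exp_conditional <- function(sig_ts_focal, sig_me_focal,
                                        sig_ts_any, sig_me_any) {
  sig_ts_focal <- unique(sig_ts_focal)
  sig_me_focal <- unique(sig_me_focal)
  sig_ts_any <- unique(sig_ts_any)
  sig_me_any <- unique(sig_me_any)
  observed <- if (length(sig_ts_focal) == 0L) 0 else
    length(intersect(sig_ts_focal, sig_me_focal)) / length(sig_ts_focal)
  expected <- if (length(sig_ts_any) == 0L) 0 else
    length(intersect(sig_ts_any, sig_me_any)) / length(sig_ts_any)
  ratio <- if (expected == 0) 0 else observed / expected
  list(observed = observed, expected = expected, ratio = ratio)
}

#' Path-analysis result table for one sample
#'
#' Runs [path_correlation()] for every feature over every root-to-leaf path
#' of the sample's clonal tree.
#'
#' @param score_table data.frame from [aggregate_to_unit()] (unit = clone)
#'   with an additional `feature` column, or a named list of per-clone
#'   score vectors (names = features).
#' @param tree the sample's [build_tree()] result.
#' @param min_cells minimum clone size for path membership (default 10).
#' @param sample_id sample identifier recorded in the output.
#' @return data.frame: `sample_id`, `path`, `feature`, `rho`, `n_clones`.
#' @export
path_result_table <- function(score_table, tree, min_cells = 10L,
                              sample_id = NA_character_) {
  feats <- score_list(score_table)
  paths <- extract_paths(tree, min_cells = min_cells)
  out <- list()
  for (pn in names(paths)) {
    p <- paths[[pn]]
    for (f in names(feats)) {
      s <- feats[[f]][match(p$clone, names(feats[[f]]))]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, path = pn, feature = f,
        rho = spearman_rho(as.numeric(s), p$depth),
        n_clones = sum(!is.na(s)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample_id = character(0), path = character(0),
                      feature = character(0), rho = numeric(0),
                      n_clones = integer(0)))
  do.call(rbind, out)
}

#' Selection-analysis result table for one sample
#'
#' Runs [selection_correlation()] for every feature against relative
#' clonal abundance, computed over the clones passing the same
#' minimum-cell-count exclusion as the path analysis.
#'
#' @inheritParams path_result_table
#' @return data.frame: `sample_id`, `feature`, `rho`, `n_clones`.
#' @export
selection_result_table <- function(score_table, tree, min_cells = 10L,
                                   sample_id = NA_character_) {
  feats <- score_list(score_table)
  nodes <- tree$nodes[tree$nodes$n_cells >= min_cells, , drop = FALSE]
  if (nrow(nodes) == 0L || sum(nodes$n_cells) == 0L) {
    ab <- stats::setNames(numeric(0), character(0))
  } else {
    ab <- stats::setNames(nodes$n_cells / sum(nodes$n_cells), nodes$clone)
  }
  out <- lapply(names(feats), function(f) data.frame(
    sample_id = sample_id, feature = f,
    rho = selection_correlation(feats[[f]], ab),
    n_clones = length(intersect(names(feats[[f]])[!is.na(feats[[f]])], names(ab))),
    stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Accepts either a long data.frame (clone_id, feature, score) or a named
# list of per-clone named score vectors; returns the latter.
score_list <- function(score_table) {
  if (is.data.frame(score_table)) {
    need <- c("clone_id", "feature", "score")
    miss <- setdiff(need, names(score_table))
    if (length(miss) > 0L)
      stop_fmt("score table lacks column(s): %s", paste(miss, collapse = ", "))
    lapply(split(score_table, score_table$feature), function(d)
      stats::setNames(d$score, d$clone_id))
  } else if (is.list(score_table)) {
    score_table
  } else {
    stop_fmt("score_table must be a data.frame or a named list")
  }
}
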
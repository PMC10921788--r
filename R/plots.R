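# Base-graphics renderings of the two standard result views: horizontal
# bar plots of top significant features (mean coefficient +/- SE per
# context) and the clonal tree with per-clone cluster-composition pies.

#' Horizontal bar plot of top significant features
#'
#' Shows, for each of the top `k` features at `q <= alpha_q`, the mean
#' Spearman coefficient per context with a standard-error whisker.
#'
#' @param comparison a [compare_contexts()] result.
#' @param k maximum number of features shown (default 10).
#' @param alpha_q significance threshold (defaults to the one stored in
#'   the comparison).
#' @param main plot title.
#' @return invisibly, the features plotted.
#' @export
plot_group_comparison <- function(comparison, k = 10L,
                                  alpha_q = attr(comparison, "alpha_q"),
                                  main = "Top features") {
  sig <- comparison[comparison$q <= alpha_q, , drop = FALSE]
  sig <- utils::head(sig[order(sig$q, sig$p), , drop = FALSE], k)
  if (nrow(sig) == 0L) {
    graphics::plot.new()
    graphics::title(main = main, sub = "no significant features")
    return(invisible(character(0)))
  }
  mcols <- grep("^mean\\.", names(sig), value = TRUE)
  ctxs <- sub("^mean\\.", "", mcols)
  means <- as.matrix(sig[, mcols, drop = FALSE])
  ses <- as.matrix(sig[, paste0("se.", ctxs), drop = FALSE])
  op <- graphics::par(mar = c(4, 10, 3, 1))
  on.exit(graphics::par(op))
  bp <- graphics::barplot(t(means), beside = TRUE, horiz = TRUE,
                          names.arg = sig$feature, las = 1,
                          col = grDevices::gray.colors(length(ctxs)),
                          xlab = "mean Spearman coefficient", main = main,
                          xlim = range(0, means - ses, means + ses, na.rm = TRUE))
  graphics::segments(t(means) - t(ses), bp, t(means) + t(ses), bp)
  graphics::legend("topright", legend = ctxs, bty = "n",
                   fill = grDevices::gray.colors(length(ctxs)))
  invisible(sig$feature)
}

#' Plot a clonal tree with cluster-composition pies
#'
#' Lays the tree out by depth and draws each clone as a pie of its cells'
#' transcriptional-cluster membership, with node diameter proportional to
#' the square root of the clone's cell count.
#'
#' @param tree a `clonal_tree`.
#' @param cells optional [cell_table()] restricted to the sample; without
#'   it nodes are plain circles.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plot_clone_tree <- function(tree, cells = NULL, main = "Clonal tree") {
  nodes <- tree$nodes
  # x: order leaves, parents centered over children
  depth_max <- max(nodes$depth)
  xpos <- stats::setNames(rep(NA_real_, nrow(nodes)), nodes$clone)
  leaves <- setdiff(nodes$clone, tree$edges$parent)
  xpos[leaves] <- seq_along(leaves)
  for (d in sort(unique(nodes$depth), decreasing = TRUE)) {
    for (cl in nodes$clone[nodes$depth == d]) {
      if (is.na(xpos[cl])) {
        kids <- tree_children(tree, cl)
        xpos[cl] <- mean(xpos[kids], na.rm = TRUE)
      }
    }
  }
  y <- stats::setNames(depth_max - nodes$depth, nodes$clone)
  graphics::plot(NA, xlim = range(xpos) + c(-0.6, 0.6),
                 ylim = c(-0.6, depth_max + 0.6), axes = FALSE,
                 xlab = "", ylab = "depth", main = main)
  graphics::axis(2, at = depth_max:0, labels = 0:depth_max, las = 1)
  for (k in seq_len(nrow(tree$edges)))
    graphics::segments(xpos[tree$edges$parent[k]], y[tree$edges$parent[k]],
                       xpos[tree$edges$child[k]], y[tree$edges$child[k]],
                       col = "gray40")
  rmax <- 0.35
  rad <- rmax * sqrt(nodes$n_cells / max(1, max(nodes$n_cells)))
  rad[rad < 0.08] <- 0.08
  cl_levels <- if (!is.null(cells)) sort(unique(cells$cluster_id)) else character(0)
  cols <- if (length(cl_levels)) grDevices::hcl.colors(max(2L, length(cl_levels)),
                                                       "Dark 3")[seq_along(cl_levels)]
  for (i in seq_len(nrow(nodes))) {
    cx <- xpos[nodes$clone[i]]
    cy <- y[nodes$clone[i]]
    if (!is.null(cells)) {
      shares <- table(factor(cells$cluster_id[cells$clone_id == nodes$clone[i]],
                             levels = cl_levels))
      draw_pie(cx, cy, rad[i], as.numeric(shares), cols)
    } else {
      draw_pie(cx, cy, rad[i], 1, "gray80")
    }
    graphics::text(cx, cy + rad[i] + 0.12, nodes$clone[i], cex = 0.7)
  }
  if (length(cl_levels))
    graphics::legend("topright", legend = cl_levels, fill = cols, bty = "n",
                     title = "cluster", cex = 0.7)
  invisible(NULL)
}

draw_pie <- function(x, y, r, shares, cols) {
  if (sum(shares) == 0) shares <- rep(1, length(shares))
  p <- c(0, cumsum(shares) / sum(shares))
  for (i in seq_along(shares)) {
    if (shares[i] == 0) next
    th <- seq(2 * pi * p[i], 2 * pi * p[i + 1], length.out = 60) + pi / 2
    graphics::polygon(c(x, x + r * cos(th)), c(y, y + r * sin(th)),
                      col = cols[i], border = "gray20")
  }
}
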
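# Fixtures built in code and independent oracles used across test files.

# Four-clone genotype matrix whose MST is known by enumeration:
# bitstrings 0000, 1000, 1100, 0001.
k4_genotypes <- function() {
  g <- rbind("0000" = c(0L, 0L, 0L, 0L),
             "1000" = c(1L, 0L, 0L, 0L),
             "1100" = c(1L, 1L, 0L, 0L),
             "0001" = c(0L, 0L, 0L, 1L))
  colnames(g) <- paste0("s", 1:4)
  genotype_matrix(g, genes = c("EGFR", "KRAS", "TP53", "MET"))
}

toy_cells <- function() {
  cell_table(data.frame(
    cell_id = paste0("c", 1:12), sample_id = "S1",
    clone_id = rep(c("0000", "1000", "1100", "0001"), each = 3L),
    cluster_id = rep(c("x", "x", "y", "y"), each = 3L),
    context = "PD", stringsAsFactors = FALSE))
}

# Random clone-level genotype matrix for property tests.
random_genotypes <- function(n_clones, n_sites, p_missing = 0) {
  vals <- matrix(sample(0:2, n_clones * n_sites, replace = TRUE,
                        prob = c(0.6, 0.3, 0.1)),
                 n_clones, n_sites,
                 dimnames = list(sprintf("cl%02d", seq_len(n_clones)),
                                 sprintf("s%03d", seq_len(n_sites))))
  if (p_missing > 0)
    vals[matrix(stats::runif(length(vals)) < p_missing, nrow(vals))] <- NA
  genotype_matrix(vals, genes = sprintf("G%03d", seq_len(n_sites)))
}

# Independent MST oracle: minimum total weight over all spanning trees,
# by exhaustive enumeration of (n-1)-edge subsets.
brute_force_mst_weight <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(0)
  pairs <- utils::combn(n, 2L)
  w <- d[t(pairs)]
  best <- Inf
  for (sel in utils::combn(ncol(pairs), n - 1L, simplify = FALSE)) {
    # spanning check by union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in sel) {
      ra <- find(pairs[1L, e]); rb <- find(pairs[2L, e])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (ok) best <- min(best, sum(w[sel]))
  }
  best
}

# Independent exact rank-sum oracle (two-sided, average ranks).
oracle_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  mu <- m * (m + n + 1) / 2
  ws <- apply(utils::combn(m + n, m), 2L, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Independent mutual-information oracle on a contingency table, base 2.
oracle_nmi_sqrt <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0) mi <- mi + tab[i, j] * log2(tab[i, j] / (pa[i] * pb[j]))
  if (h(pa) == 0 || h(pb) == 0) 0 else unname(mi / sqrt(h(pa) * h(pb)))
}

toy_expression <- function() {
  m <- matrix(c(2, 2, 0, 0), 4, 1,
              dimnames = list(paste0("g", 1:4), "cell1"))
  m
}
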
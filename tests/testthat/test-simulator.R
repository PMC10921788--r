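# Ground-truth simulation, genotype noise, consensus reconstruction, and
# the perfect-vs-random validation experiment.

test_that("config validation enforces structural preconditions", {
  expect_error(sim_config(n_clones = 1L), "n_clones")
  expect_error(sim_config(n_sites = 3L, n_clones = 5L), "private")
  expect_error(sim_config(n_cells = 3L, n_clones = 5L), "every clone")
  expect_error(sim_config(fpr = 1.2), "rates")
  cfg <- sim_config()
  expect_equal(cfg$n_cells, 20L)
  expect_equal(cfg$n_clones, 5L)
  expect_equal(cfg$n_sites, 100L)
  expect_equal(c(cfg$fpr, cfg$fnr, cfg$p_missing), c(0.2, 0.2, 0.2))
})

test_that("flat key-value config files parse with conventional names", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "N.cells 40", "N.clones=4", "N.sites 50",
               "FPR 0.1", "FNR 0.3", "p.missing 0.05", "iterations 7",
               "seed 99"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_cells, 40L)
  expect_equal(cfg$n_clones, 4L)
  expect_equal(cfg$fnr, 0.3)
  expect_equal(cfg$n_iterations, 7L)
  expect_equal(cfg$seed, 99L)
})

test_that("simulated truth: inheritance, private sites, full site assignment", {
  cfg <- sim_config(seed = 5L)
  truth <- simulate_truth(cfg)
  expect_equal(nrow(truth$genotypes), 5L)
  expect_equal(ncol(truth$genotypes), 100L)
  expect_length(truth$site_origin, 100L)  # every site originates in one clone
  # descendant genotype is a superset of its ancestor's, on every edge
  for (k in seq_len(nrow(truth$tree$edges))) {
    p <- truth$tree$edges$parent[k]
    ch <- truth$tree$edges$child[k]
    expect_true(all(truth$genotypes[p, ] <= truth$genotypes[ch, ]))
  }
  # every non-root clone owns at least one private site
  priv <- table(truth$site_origin)
  non_root <- setdiff(rownames(truth$genotypes), truth$tree$root)
  expect_true(all(non_root %in% names(priv)))
  # every clone has at least one cell
  expect_true(all(rownames(truth$genotypes) %in% truth$assignment))
  expect_length(truth$assignment, 20L)
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 8L)
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$genotypes, t2$genotypes)
  expect_identical(t1$assignment, t2$assignment)
  expect_identical(add_noise(t1)$values, add_noise(t2)$values)
  r1 <- validation_experiment(sim_config(n_iterations = 5L, seed = 4L))
  r2 <- validation_experiment(sim_config(n_iterations = 5L, seed = 4L))
  expect_identical(r1$iterations, r2$iterations)
})

test_that("noise model: noiseless identity, saturated complement, FPR calibration", {
  truth <- simulate_truth(sim_config(seed = 2L))
  clean <- add_noise(truth, sim_config(fpr = 0, fnr = 0, p_missing = 0))
  expect_identical(unname(clean$values),
                   unname(truth$genotypes[truth$assignment, ]))
  flipped <- add_noise(truth, sim_config(fpr = 1, fnr = 1, p_missing = 0))
  expect_identical(unname(flipped$values),
                   unname(1L - truth$genotypes[truth$assignment, ]))
  # FPR = 0.2 on an all-zero truth: observed 1-fraction inside binomial 99% CI
  cfg0 <- sim_config(n_cells = 100L, n_clones = 2L, n_sites = 100L,
                     fpr = 0.2, fnr = 0, p_missing = 0, seed = 6L)
  t0 <- simulate_truth(cfg0)
  t0$genotypes[] <- 0L
  obs <- add_noise(t0, cfg0, seed = 6L)
  frac <- mean(obs$values == 1L)
  ci <- stats::qbinom(c(0.005, 0.995), length(obs$values), 0.2) /
    length(obs$values)
  expect_gte(frac, ci[1L])
  expect_lte(frac, ci[2L])
})

test_that("consensus reconstruction: majority vote with mutated tie-break", {
  vals <- rbind(c1 = c(1L, 1L, NA), c2 = c(1L, 0L, NA), c3 = c(0L, NA, NA))
  colnames(vals) <- paste0("s", 1:3)
  noisy <- genotype_matrix(vals, genes = paste0("G", 1:3))
  assign <- c(c1 = "A", c2 = "A", c3 = "A")
  tr <- reconstruct(noisy, assign)
  # site1: (1,1,0) -> 1; site2: (1,0) -> tie -> 1; site3: all missing -> 0
  expect_equal(tr$nodes$n_mutations, 2L)
})

test_that("noiseless reconstruction reproduces the true edge set", {
  for (s in 1:5) {
    cfg <- sim_config(fpr = 0, fnr = 0, p_missing = 0, seed = s)
    truth <- simulate_truth(cfg)
    recon <- reconstruct(add_noise(truth, cfg), truth$assignment)
    canon <- function(e) sort(paste(pmin(e$parent, e$child),
                                    pmax(e$parent, e$child)))
    expect_identical(canon(recon$edges), canon(truth$tree$edges))
  }
})

test_that("perfect signature is depth + 1 and scores 1 on every true path", {
  truth <- simulate_truth(sim_config(seed = 3L))
  sigs <- make_signatures(truth$tree, seed = 1L)
  d <- stats::setNames(truth$tree$nodes$depth, truth$tree$nodes$clone)
  expect_equal(sigs$perfect, 1 + d)
  for (p in extract_paths(truth$tree, min_cells = 0L))
    expect_equal(path_correlation(sigs$perfect, p), 1)
  sel <- make_signatures(truth$tree, seed = 1L, mode = "selection")
  expect_equal(sum(sel$perfect), 1)
})

test_that("random signatures have near-zero mean path correlation", {
  set.seed(61)
  truth <- simulate_truth(sim_config(seed = 12L))
  paths <- extract_paths(truth$tree, min_cells = 0L)
  expect_gt(length(paths), 0L)
  rhos <- unlist(lapply(1:200, function(i) {
    r <- stats::setNames(stats::runif(5), truth$tree$nodes$clone)
    vapply(paths, function(p) path_correlation(r, p), numeric(1L))
  }))
  rhos <- rhos[!is.na(rhos)]
  se <- stats::sd(rhos) / sqrt(length(rhos))
  expect_lt(abs(mean(rhos)), 3 * se)
})

test_that("validation experiment separates perfect from random signatures", {
  expect_error(validation_experiment(sim_config(n_iterations = 1L)),
               "n_iterations")
  rep0 <- validation_experiment(
    sim_config(fpr = 0, fnr = 0, p_missing = 0, n_iterations = 10L, seed = 1L))
  expect_equal(rep0$perfect, rep(1, length(rep0$perfect)), tolerance = 1e-9)
  expect_lt(rep0$p_value, 0.05)
  expect_lt(abs(stats::median(rep0$random)), 0.9)
  # selection mode runs end to end
  sel <- validation_experiment(sim_config(n_iterations = 10L, seed = 2L),
                               mode = "selection")
  expect_true(is.finite(sel$p_value) || !is.null(sel$diagnostic))
})

test_that("perfect-signature recovery degrades monotonically with noise", {
  # the perfect pool mean is the direct power proxy: 1 without noise,
  # shrinking as genotype errors distort the reconstructed tree
  means <- vapply(c(0, 0.25, 0.45), function(noise) {
    rep_ <- validation_experiment(
      sim_config(fpr = noise, fnr = noise, p_missing = 0.2,
                 n_iterations = 25L, seed = 10L))
    mean(rep_$perfect)
  }, numeric(1L))
  expect_gte(means[1L], means[2L] - 0.05)  # sampling-noise tolerance
  expect_gte(means[2L], means[3L] - 0.05)
  expect_equal(means[1L], 1, tolerance = 1e-9)
})
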
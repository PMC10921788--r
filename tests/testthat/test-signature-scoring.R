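# Mutation Jaccard score, transcription module score, mutated-gene
# expression score, and aggregation to clones.

test_that("mutation signature score: Jaccard with optional coding filter", {
  expect_equal(mutation_signature_score(c("EGFR", "TP53"),
                                        c("EGFR", "KRAS", "MET")), 0.25)
  expect_equal(mutation_signature_score(c("A", "B"), c("C", "D")), 0)
  expect_equal(mutation_signature_score(c("A", "B"), c("A", "B")), 1)
  # filter removes the non-coding gene from the union before the Jaccard
  expect_equal(mutation_signature_score(c("EGFR", "XIST"), "EGFR",
                                        coding_filter = c("EGFR", "TP53")), 1)
  expect_error(mutation_signature_score("EGFR", character(0)), "empty")
  # empty union after filtering -> 0, not NaN
  expect_equal(mutation_signature_score("XIST", "TSIX",
                                        coding_filter = "EGFR"), 0)
})

test_that("mutation score is symmetric and monotone in shared genes", {
  set.seed(3)
  pool <- sprintf("G%02d", 1:20)
  for (i in 1:20) {
    a <- sample(pool, sample(1:8, 1L))
    b <- sample(pool, sample(1:8, 1L))
    expect_equal(mutation_signature_score(a, b), mutation_signature_score(b, a))
    shared <- setdiff(pool, union(a, b))[1L]
    expect_gte(mutation_signature_score(c(a, shared), c(b, shared)),
               mutation_signature_score(a, b))
  }
})

test_that("module score: constant matrix gives 0, toy case gives +/-1", {
  const <- matrix(3, 5, 4, dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  ts <- transcription_module_score(const, c("g1", "g2"))
  expect_equal(unname(ts), rep(0, 4))

  e <- toy_expression()  # g1=g2=2, g3=g4=0, one bin, full controls
  expect_equal(unname(transcription_module_score(e, c("g1", "g2"),
                                                 n_bins = 1, n_ctrl = 10)), 1)
  expect_equal(unname(transcription_module_score(e, c("g3", "g4"),
                                                 n_bins = 1, n_ctrl = 10)), -1)
})

test_that("module score is deterministic given seed and skips absent signatures", {
  set.seed(21)
  expr <- matrix(abs(rnorm(200)), 40, 5,
                 dimnames = list(sprintf("g%02d", 1:40), paste0("c", 1:5)))
  a <- transcription_module_score(expr, c("G01", "G05", "G20"), seed = 9)
  b <- transcription_module_score(expr, c("G01", "G05", "G20"), seed = 9)
  expect_identical(a, b)
  expect_warning(out <- transcription_module_score(expr, c("NOPE1", "NOPE2")),
                 "skipped")
  expect_null(out)
  # metabolism-style minimum: two present genes out of a required three
  expect_warning(out3 <- transcription_module_score(expr, c("G01", "G02", "ZZ"),
                                                    min_genes = 3L), "skipped")
  expect_null(out3)
})

test_that("shifting signature genes by +c moves the single-bin score by its share", {
  base <- matrix(1, 6, 3, dimnames = list(paste0("g", 1:6), paste0("c", 1:3)))
  for (c_shift in c(0.5, 2)) {
    e <- base
    e[c("g1", "g2"), ] <- 1 + c_shift
    ts <- transcription_module_score(e, c("g1", "g2"), n_bins = 1, n_ctrl = 10)
    # controls = all genes, so the score is c times the non-signature share
    expect_equal(unname(ts), rep(c_shift * (1 - 2 / 6), 3))
  }
})

test_that("random signatures score zero on average (Monte Carlo)", {
  set.seed(5)
  expr <- matrix(abs(rnorm(50 * 30)), 50, 30,
                 dimnames = list(paste0("G", 1:50), paste0("c", 1:30)))
  means <- vapply(1:200, function(i)
    mean(transcription_module_score(expr, sample(rownames(expr), 5L),
                                    seed = i)), numeric(1L))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("mutated expression score averages the mutated signature genes", {
  e <- matrix(c(2, 4, 9), 3, 1, dimnames = list(c("g1", "g2", "g3"), "c1"))
  s <- mutated_expression_score(e, c("g1", "g2", "g9"), c("g1", "g2", "g8"))
  expect_equal(unname(s), 3)
  # never exceeds the max expression of the intersection
  expect_lte(s, max(e[c("g1", "g2"), ]))
  # empty intersection -> missing
  expect_true(all(is.na(mutated_expression_score(e, "g9", "g1"))))
  # metabolism rule: < 3 expressed intersecting genes -> skipped
  expect_warning(out <- mutated_expression_score(e, c("g1", "g2"), c("g1", "g2"),
                                                 metabolism = TRUE), "skipped")
  expect_null(out)
})

test_that("aggregate_to_unit means cell scores per clone and per cluster/clone", {
  cells <- toy_cells()
  scores <- stats::setNames(c(1, 3, NA, rep(2, 9)), cells$cell_id)
  by_clone <- aggregate_to_unit(scores, cells, unit = "clone")
  expect_equal(by_clone$score[by_clone$clone_id == "0000"], 2)  # mean(1, 3), NA dropped
  expect_equal(by_clone$n_cells[by_clone$clone_id == "0000"], 3L)
  by_cc <- aggregate_to_unit(scores, cells, unit = "cluster_clone")
  expect_true(all(c("cluster_id", "clone_id") %in% names(by_cc)))
  expect_equal(nrow(by_cc), 4L)  # each clone sits in exactly one cluster here
  # unit with zero scored cells -> missing
  scores2 <- scores
  scores2[cells$clone_id == "0001"] <- NA
  by2 <- aggregate_to_unit(scores2, cells, unit = "clone")
  expect_true(is.na(by2$score[by2$clone_id == "0001"]))
})

test_that("score_table combines kinds and respects metabolism exclusions", {
  gm <- k4_genotypes()
  cells <- toy_cells()
  sets <- list(hallmark = c("EGFR", "KRAS"), pathway = c("TP53", "MET", "ZZZ9"))
  attr(sets, "category") <- c(hallmark = "cancer", pathway = "metabolism")
  expr <- matrix(abs(rnorm(4 * 12, 2)), 4, 12,
                 dimnames = list(c("EGFR", "KRAS", "TP53", "MET"),
                                 cells$cell_id))
  st <- suppressWarnings(score_table(gm, cells, sets, expr = expr, seed = 1))
  expect_setequal(unique(st$kind),
                  c("mutation", "transcription", "mutated_expression"))
  # mutation score spot check: clone 1100 mutated {EGFR, KRAS} vs hallmark
  expect_equal(st$score[st$clone_id == "1100" & st$kind == "mutation" &
                          st$feature == "hallmark"], 1)
  expect_true(all(st$score[st$kind == "mutation"] >= 0 &
                    st$score[st$kind == "mutation"] <= 1))
})
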
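# Path/selection correlations, context comparison, overlap statistics.

test_that("path correlation matches hand Spearman including ties", {
  path <- data.frame(clone = c("A", "B", "C"), depth = 0:2)
  expect_equal(path_correlation(c(A = 0.1, B = 0.2, C = 0.3), path), 1)
  expect_equal(path_correlation(c(A = 0.3, B = 0.2, C = 0.1), path), -1)
  # ranks (1.5, 1.5, 3) vs (1, 2, 3)
  expect_equal(path_correlation(c(A = 0.1, B = 0.1, C = 0.3), path),
               sqrt(3) / 2, tolerance = 1e-10)
  # zero variance and too-few clones are missing
  expect_true(is.na(path_correlation(c(A = 1, B = 1, C = 1), path)))
  expect_true(is.na(path_correlation(c(A = 1, B = 2), path[1:2, ])))
})

test_that("selection correlation matches hand Spearman", {
  ab <- c(A = 0.2, B = 0.3, C = 0.5)
  expect_equal(selection_correlation(c(A = 2, B = 3, C = 5), ab), 1)
  expect_equal(selection_correlation(c(A = 5, B = 3, C = 2), ab), -1)
  expect_equal(selection_correlation(c(A = 0.2, B = 0.5, C = 0.1), ab), -0.5)
})

test_that("coefficients are invariant to strictly monotone score transforms", {
  set.seed(19)
  path <- data.frame(clone = LETTERS[1:5], depth = 0:4)
  for (i in 1:10) {
    s <- stats::setNames(stats::rnorm(5), LETTERS[1:5])
    r0 <- path_correlation(s, path)
    expect_equal(path_correlation(exp(2 * s) + 1, path), r0)
    expect_equal(path_correlation(rank(s), path), r0)
  }
})

test_that("rank-sum test equals exact enumeration for small groups", {
  set.seed(23)
  for (i in 1:10) {
    m <- sample(3:6, 1L)
    n <- sample(3:6, 1L)
    x <- stats::rnorm(m)
    y <- stats::rnorm(n)
    expect_equal(rank_sum_test(x, y)$p.value, oracle_ranksum_p(x, y))
    # untied small samples also agree with the classical exact distribution
    expect_equal(rank_sum_test(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # tied case the classical exact method cannot handle: 5 x +0.9 vs 5 x -0.9
  expect_equal(rank_sum_test(rep(0.9, 5), rep(-0.9, 5))$p.value, 2 / 252)
})

test_that("compare_contexts: Wilcoxon for 2 groups, Kruskal for 3, BH across features", {
  res <- data.frame(
    sample_id = rep(paste0("S", 1:10), times = 2),
    feature = rep(c("f1", "f2"), each = 10),
    rho = c(rep(0.9, 5), rep(-0.9, 5), stats::rnorm(10, 0, 0.01)))
  ctx <- stats::setNames(rep(c("PD", "PR"), each = 5), paste0("S", 1:10))
  set.seed(2)
  cmp <- compare_contexts(res, ctx)
  expect_s3_class(cmp, "group_comparison")
  f1 <- cmp[cmp$feature == "f1", ]
  expect_equal(f1$p, 2 / 252)
  expect_identical(f1$enriched, "PD")
  expect_equal(f1$mean.PD, 0.9)
  expect_equal(f1$se.PD, 0)
  expect_equal(cmp$q, stats::p.adjust(cmp$p, method = "BH"))

  # identical distributions -> p near 1
  res2 <- data.frame(sample_id = paste0("S", 1:10), feature = "f",
                     rho = rep(c(0.1, 0.2, 0.3, 0.4, 0.5), 2))
  expect_gt(compare_contexts(res2, ctx)$p, 0.9)

  # three contexts dispatch to Kruskal-Wallis
  ctx3 <- stats::setNames(rep(c("PD", "PR", "SD"), length.out = 10),
                          paste0("S", 1:10))
  cmp3 <- compare_contexts(res, ctx3)
  expect_true(all(cmp3$p >= 0 & cmp3$p <= 1))

  expect_error(compare_contexts(res, stats::setNames(rep("PD", 10),
                                                     paste0("S", 1:10))),
               ">= 2 contexts")
})

test_that("BH correction matches the hand-computed 4-value example", {
  # via the same adjustment the pipeline applies
  expect_equal(stats::p.adjust(c(0.005, 0.01, 0.03, 0.04), method = "BH"),
               c(0.02, 0.02, 0.04, 0.04))
  # and through compare_contexts: q is monotone in p-rank, equal p -> equal q
  res <- data.frame(
    sample_id = rep(paste0("S", 1:8), times = 4),
    feature = rep(paste0("f", 1:4), each = 8),
    rho = stats::rnorm(32))
  ctx <- stats::setNames(rep(c("a", "b"), each = 4), paste0("S", 1:8))
  cmp <- compare_contexts(res, ctx)
  expect_true(all(diff(cmp$q[order(cmp$p)]) >= -1e-12))
  expect_true(all(cmp$q >= cmp$p))
})

test_that("features with too few observations per context are excluded", {
  res <- data.frame(sample_id = c("S1", "S2", "S3", "S4", "S5"),
                    feature = "f", rho = c(0.1, 0.2, 0.3, 0.4, 0.5))
  ctx <- c(S1 = "a", S2 = "a", S3 = "b", S4 = "b", S5 = "c")  # c has 1 obs
  expect_warning(expect_error(compare_contexts(res, ctx), "no feature"),
                 "excluded")
})

test_that("label-permuted contexts give approximately uniform p values", {
  set.seed(11)
  scores <- stats::rnorm(16)
  ps <- replicate(500, {
    idx <- sample(16, 8)
    rank_sum_test(scores[idx], scores[-idx])$p.value
  })
  d <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  expect_lt(d, 0.12)
})

test_that("total overlap statistic follows the observed/expected convention", {
  ov <- overlap_obs_exp_total(paste0("f", 1:4), paste0("f", 3:7), universe = 10)
  expect_equal(ov$observed, 0.2)
  expect_equal(ov$expected, 0.2)
  expect_equal(ov$ratio, 1)
  # one empty comparison set -> 0 by convention
  expect_equal(overlap_obs_exp_total(character(0), paste0("f", 1:3), 10)$ratio, 0)
  # identical sets
  ov2 <- overlap_obs_exp_total(paste0("f", 1:3), paste0("f", 1:3), 10)
  expect_equal(ov2$ratio, 0.3 / 0.09)
  expect_error(overlap_obs_exp_total("a", "a", 0), "universe")
})

test_that("conditional overlap statistic and its zero conventions", {
  ov <- overlap_obs_exp_conditional(
    sig_ts_focal = paste0("t", 1:4), sig_me_focal = c("t1", "t2", "zz"),
    sig_ts_any = paste0("t", 1:8), sig_me_any = c("t1", "t2", "t5", "qq"))
  expect_equal(ov$observed, 0.5)
  expect_equal(ov$expected, 0.375)
  expect_equal(ov$ratio, 0.5 / 0.375)
  # focal = any-group sets -> ratio 1
  ov2 <- overlap_obs_exp_conditional(paste0("t", 1:4), c("t1", "t2"),
                                     paste0("t", 1:4), c("t1", "t2"))
  expect_equal(ov2$ratio, 1)
  # no transcription-significant features in focal group -> 0
  expect_equal(overlap_obs_exp_conditional(character(0), "x",
                                           paste0("t", 1:4), "t1")$ratio, 0)
})

test_that("path and selection result tables cover (path x feature) combinations", {
  gm <- k4_genotypes()
  cells <- toy_cells()
  tr <- build_tree(gm, cells = cells)
  scores <- data.frame(
    sample_id = "S1",
    clone_id = rep(c("0000", "1000", "1100", "0001"), 2),
    feature = rep(c("f1", "f2"), each = 4),
    score = c(0.1, 0.2, 0.3, 0.15, 4, 3, 2, 1))
  pt <- path_result_table(scores, tr, min_cells = 0L, sample_id = "S1")
  # two leaves (1100, 0001) but the 0001 path has 2 clones -> dropped
  expect_equal(nrow(pt), 2L)
  expect_equal(pt$rho[pt$feature == "f1"], 1)
  expect_equal(pt$rho[pt$feature == "f2"], -1)
  st <- selection_result_table(scores, tr, min_cells = 0L, sample_id = "S1")
  expect_equal(nrow(st), 2L)
  expect_true(all(st$rho >= -1 & st$rho <= 1, na.rm = TRUE))
})
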
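ratio_matrix <- function(values, genes, components = "c1") {
  matrix(values, nrow = length(genes),
         dimnames = list(genes, components))
}

test_that("ROC analysis reproduces hand-computed curves", {
  # perfect separation
  m <- ratio_matrix(c(0.2, 0.4, 1.0, 1.0), c("g1", "g2", "g3", "g4"))
  bench <- data.frame(gene_id = c("g1", "g2", "g3", "g4"), component_id = "c1",
                      outcome = c("positive", "positive", "negative", "negative"))
  expect_equal(roc_analysis(m, bench)$auc, 1.0)
  # uninformative classifier: identical ratios
  m2 <- ratio_matrix(rep(1, 4), c("g1", "g2", "g3", "g4"))
  expect_equal(roc_analysis(m2, bench)$auc, 0.5)
  # hand-enumerated 4-point sweep
  m3 <- ratio_matrix(c(0.2, 1.0, 0.5, 1.0), c("g1", "g2", "g3", "g4"))
  expect_equal(roc_analysis(m3, bench)$auc, 0.625)
  # missing classes are named errors
  bench_pos <- transform(bench, outcome = "positive")
  expect_error(roc_analysis(m, bench_pos), "no negative")
  expect_error(roc_analysis(m, transform(bench, outcome = "negative")),
               "no positive")
  expect_error(roc_analysis(m, data.frame(gene_id = "gX", component_id = "c1",
                                          outcome = "positive")),
               "no computed ratio|no negative")
})

test_that("trapezoidal AROC equals the Mann-Whitney rank oracle", {
  set.seed(13)
  for (i in 1:40) {
    n_pos <- sample(3:8, 1); n_neg <- sample(3:8, 1)
    r <- round(stats::runif(n_pos + n_neg), 6)
    if (anyDuplicated(r)) next  # oracle equivalence stated for distinct ratios
    genes <- sprintf("g%d", seq_along(r))
    m <- ratio_matrix(r, genes)
    bench <- data.frame(gene_id = genes, component_id = "c1",
                        outcome = rep(c("positive", "negative"),
                                      c(n_pos, n_neg)))
    expect_equal(roc_analysis(m, bench)$auc,
                 oracle_auc(r[seq_len(n_pos)], r[n_pos + seq_len(n_neg)]),
                 tolerance = 1e-9)
  }
  # with ties the trapezoid still matches the tie-corrected rank statistic
  m <- ratio_matrix(c(0.3, 0.3, 0.3, 0.9), sprintf("g%d", 1:4))
  bench <- data.frame(gene_id = sprintf("g%d", 1:4), component_id = "c1",
                      outcome = c("positive", "positive", "negative", "negative"))
  expect_equal(roc_analysis(m, bench)$auc, oracle_auc(c(0.3, 0.3), c(0.3, 0.9)),
               tolerance = 1e-9)
})

test_that("permutation null centres at 0.5 and is seed-reproducible", {
  set.seed(17)
  genes <- sprintf("g%d", 1:20)
  m <- ratio_matrix(c(rep(0, 6), stats::runif(14, 0.8, 1)), genes)
  bench <- data.frame(gene_id = genes, component_id = "c1",
                      outcome = rep(c("positive", "negative"), c(6, 14)))
  pn <- permutation_null(m, bench, n_trials = 100, seed = 5)
  expect_gte(pn$mean_auc, 0.4)
  expect_lte(pn$mean_auc, 0.6)
  expect_lt(pn$p_value, 0.05)       # observed separation beats chance
  pn2 <- permutation_null(m, bench, n_trials = 100, seed = 5)
  expect_identical(pn$aucs, pn2$aucs)
  pn3 <- permutation_null(m, bench, n_trials = 100, seed = 6)
  expect_false(identical(pn$aucs, pn3$aucs))
  expect_error(permutation_null(m, bench, n_trials = 1, seed = 1), ">= 2")
  # per-gene shuffling variant is available and deterministic
  m2 <- matrix(c(m[, 1], rev(m[, 1])), ncol = 2,
               dimnames = list(genes, c("c1", "c2")))
  pg <- permutation_null(m2, bench, n_trials = 10, seed = 2,
                         granularity = "per_gene")
  expect_length(pg$aucs, 10)
})

test_that("cross-validation recall has exact hypergeometric significance", {
  # population 20, held-out 4, predicted-active 5 containing all 4:
  # p = C(4,4) C(16,1) / C(20,5) = 16/15504
  expect_equal(stats::phyper(3, 4, 16, 5, lower.tail = FALSE), 16 / 15504,
               tolerance = 1e-12)
  b <- built_toy(1)
  expr <- generate_expression(b$toy$model, b$toy$truth$expressed_genes, 40,
                              dropout_prob = 0)
  prof <- expression_profile(expr$rep1, expr$rep2, expr$probe_map)
  cv <- crossval_recall(b$model, prof$gene_values, b$objective_reaction,
                        fraction = 0.2, folds = 5)
  # the held-out genes gate the only objective routes: full recall
  expect_equal(cv$mean_recall, 1)
  expect_true(all(cv$p_adjusted <= 5 * cv$p_values))
  expect_true(all(cv$folds$held_out > 0))
  # p-value decreases with overlap at fixed set sizes
  ps <- vapply(0:4, function(k) stats::phyper(k - 1, 4, 16, 5, lower.tail = FALSE), 0)
  expect_true(all(diff(ps) < 0))
  expect_error(crossval_recall(b$model, prof$gene_values[1:10],
                               b$objective_reaction, folds = 5),
               "smaller than fold count")
})

test_that("three-way activity overlaps enumerate all seven regions", {
  same <- activity_set_overlap(c("a", "b"), c("a", "b"), c("a", "b"))
  expect_equal(unname(same["all_three"]), 2)
  expect_equal(sum(same), 2)
  disj <- activity_set_overlap("a", "b", "c")
  expect_equal(unname(disj[c("predicted_only", "expressed_only", "detected_only")]),
               c(1, 1, 1))
  expect_equal(sum(disj), 3)
  pairw <- activity_set_overlap(c("a", "b"), c("b", "c"), c("c", "a"))
  expect_equal(unname(pairw[c("predicted_expressed", "expressed_detected",
                              "predicted_detected")]), c(1, 1, 1))
  expect_equal(unname(pairw["all_three"]), 0)
})
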
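test_that("global normalization equalizes totals exactly", {
  r1 <- c(p1 = 60, p2 = 40)
  r2 <- c(p1 = 30, p2 = 20)
  out <- global_normalize(r1, r2)
  expect_equal(attr(out, "factor"), 2)
  expect_equal(sum(out), sum(r1))
  expect_equal(as.vector(out), c(60, 40))
  # identical tables: identity
  same <- global_normalize(r1, r1)
  expect_equal(attr(same, "factor"), 1)
  expect_error(global_normalize(r1, c(p1 = 0, p2 = 0)), "non-positive")
})

test_that("lowess smoothing removes a planted intensity-dependent bias", {
  set.seed(5)
  n <- 1000
  base <- 2^stats::runif(n, 6, 12)
  names(base) <- sprintf("p%d", seq_len(n))
  r1 <- base * 2^stats::rnorm(n, 0, 0.05)
  # planted bias: log-ratio proportional to log-average
  a <- log2(base)
  r2 <- r1 / 2^(0.5 * a)
  r2 <- global_normalize(r1, r2)
  m_before <- mean(abs(log2(r1) - log2(r2)))
  sm <- smooth_replicates(r1, r2)
  m_after <- mean(abs(log2(sm$rep1) - log2(sm$rep2)))
  expect_lt(m_after, 0.1 * m_before)
  # proportional replicates are identical after global normalization -> no-op
  r2_flat <- global_normalize(r1, 2 * r1)
  sm2 <- smooth_replicates(r1, r2_flat)
  expect_equal(sm2$rep1, r1, tolerance = 1e-8)
  expect_equal(sm2$rep2, r2_flat, tolerance = 1e-8)
  expect_error(smooth_replicates(r1[1:5], r1[1:5]), ">= 10 shared")
})

test_that("replicate averaging is the per-probeset mean with pass-through", {
  expect_equal(average_replicates(c(p1 = 10), c(p1 = 20)),
               c(p1 = 15))
  r <- c(p1 = 3, p2 = 4)
  expect_equal(average_replicates(r, r), r)
  out <- suppressWarnings(average_replicates(c(p1 = 10, p2 = 6), c(p1 = 20)))
  expect_equal(out[["p2"]], 6)
  expect_warning(average_replicates(c(p1 = 1, p2 = 2), c(p1 = 1)),
                 "single replicate")
})

test_that("gene values take the max over mapped probesets", {
  tab <- c(p1 = 3, p2 = 7, p3 = 100)
  map <- data.frame(probeset_id = c("p1", "p2"), gene_id = c("G", "G"))
  gv <- gene_values_from_probesets(tab, map)
  expect_equal(gv, c(G = 7))  # p3 unmapped, ignored; no-probeset genes absent
})

test_that("reaction scores evaluate GPRs with the no-data rule", {
  p <- parallel_model(gpr1 = "g1 and g2", gpr2 = "g3 or gX")
  sc <- reaction_scores(p, c(g1 = 5, g2 = 3, g3 = 5))
  expect_equal(unname(sc["P1"]), 3)
  expect_equal(unname(sc["P2"]), 5)
  expect_true(is.na(sc["DM_b_c"]))  # empty GPR
})

test_that("significance threshold matches the Gaussian closed form", {
  set.seed(42)
  x <- stats::rnorm(1e5, 500, 100)
  thr <- significance_threshold(x, p = 0.05)
  expect_gt(thr, 660)  # mu + 1.6449 sigma ~ 664.5
  expect_lt(thr, 669)
  # the threshold is an observed value with tail probability <= p
  expect_true(thr %in% x)
  # p = 0.5 gives approximately the mean
  expect_equal(significance_threshold(x, p = 0.5), mean(x), tolerance = 2)
  expect_error(significance_threshold(rep(5, 100)), "zero variance")
  expect_error(significance_threshold(stats::rnorm(10)), ">= 30")
  # monotone decreasing in p
  expect_gt(significance_threshold(x, 0.01), significance_threshold(x, 0.10))
})

test_that("pipeline is scale-covariant", {
  toy <- generate_toy_organ(4)
  expr <- generate_expression(toy$model, toy$truth$expressed_genes, seed = 9)
  p1 <- expression_profile(expr$rep1, expr$rep2, expr$probe_map)
  p2 <- expression_profile(expr$rep1 * 3, expr$rep2 * 3, expr$probe_map)
  expect_equal(p2$threshold, 3 * p1$threshold, tolerance = 1e-9)
  expect_equal(p2$gene_values, 3 * p1$gene_values, tolerance = 1e-9)
})

test_that("planted expressed genes exceed the computed threshold", {
  toy <- generate_toy_organ(5)
  expr <- generate_expression(toy$model, toy$truth$expressed_genes, seed = 10)
  prof <- expression_profile(expr$rep1, expr$rep2, expr$probe_map)
  on <- intersect(expr$expressed_genes, names(prof$gene_values))
  expect_gte(mean(prof$gene_values[on] >= prof$threshold), 0.95)
  # dropped genes are absent and score reactions as no-data
  expect_false(any(expr$dropped_genes %in% names(prof$gene_values)))
})
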
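test_that("component simulation reproduces hand-computable capacities", {
  b <- built_toy(1)
  cfg <- sim_config()
  comp <- function(nm) b$components[b$components$name == nm, ]
  # secretion bottleneck: synthesis capacity 7
  expect_equal(simulate_component(b$model, comp("pgi2"), cfg), 7)
  # reabsorption: direct transporter (10) + indirect catabolic route (5)
  expect_equal(simulate_component(b$model, comp("glc"), cfg), 15)
  # sodium-coupled bypass capped by consumption demand
  expect_equal(simulate_component(b$model, comp("cit"), cfg), 10)
  # all routes blocked -> 0
  dead <- apply_gene_knockout(b$model, c("g_glut2", "g_glut1"))
  dead <- set_bounds(dead, "T_glc", lb = 0, ub = 0)
  expect_equal(simulate_component(dead, comp("glc"), cfg), 0)
  expect_error(simulate_component(b$model, list(name = "x", boundary_id = "EX_nope",
                                                direction = "secretion"), cfg),
               "boundary")
})

test_that("gene deletion scan recovers planted ratios exactly", {
  b <- built_toy(1)
  cfg <- sim_config()
  un <- scan_gene_deletions(b$model, components = b$components, config = cfg)
  truth <- b$toy$truth
  # total losses at ratio 0
  for (i in seq_len(nrow(truth$total_loss))) {
    expect_equal(unname(un[truth$total_loss$gene[i], truth$total_loss$component[i]]),
                 0, tolerance = 1e-6)
  }
  # partial losses at their planted ratios
  for (i in seq_len(nrow(truth$partial))) {
    expect_equal(unname(un[truth$partial$gene[i], truth$partial$component[i]]),
                 truth$partial$ratio[i], tolerance = 1e-6)
  }
  # isozyme and off-route genes produce rows of exact 1s
  for (g in intersect(truth$none, rownames(un))) {
    expect_true(all(un[g, ] >= 1 - 1e-6), label = sprintf("gene %s silent", g))
  }
  # a gene absent from all GPRs yields a row of exact 1s
  un2 <- scan_gene_deletions(b$model, genes = "not_a_gene",
                             components = b$components, config = cfg)
  expect_true(all(un2 == 1))
  # all ratios live in [0, 1]
  expect_true(all(un >= 0 & un <= 1 + 1e-6))
})

test_that("drug target scan handles single targets and the cumulative ALL row", {
  b <- built_toy(1)
  dr <- scan_drug_targets(b$model, b$toy$targets, b$components, sim_config())
  # single-route target: total loss of the secretion (the one-pathway pattern)
  expect_equal(unname(dr["TGT_ptgis", "pgi2"]), 0)
  # isozyme-buffered and off-route targets: rows of 1s
  expect_true(all(dr["TGT_xdh", ] == 1))
  expect_true(all(dr["TGT_alox", ] == 1))
  # cumulative inhibition is at most the elementwise minimum of single rows
  singles <- dr[setdiff(rownames(dr), "ALL"), , drop = FALSE]
  expect_true(all(dr["ALL", ] <= apply(singles, 2, min) + 1e-6))
})

test_that("target maps validate their gene and reaction references", {
  b <- built_toy(1)
  expect_error(target_map(data.frame(target_id = "T1", gene_id = "ghost"),
                          b$model), "unknown ids")
  tm <- target_map(data.frame(target_id = "T1", gene_id = NA,
                              reaction_id = "R_cox"), b$model)
  dr <- scan_drug_targets(b$model, tm, b$components, sim_config())
  expect_equal(unname(dr["T1", "pgi2"]), 0)  # explicit reaction id route
})

test_that("cryptic risk factors require silence untreated and disorder treated", {
  b <- built_toy(1)
  cfg <- sim_config()
  un <- scan_gene_deletions(b$model, components = b$components, config = cfg)
  tr <- scan_gene_deletions(b$model, components = b$components, config = cfg,
                            treatment = b$toy$targets)
  cr <- find_cryptic_risk_factors(un, tr)
  truth <- b$toy$truth$cryptic
  expect_equal(nrow(cr), nrow(truth))
  expect_setequal(paste(cr$gene, cr$component),
                  paste(truth$gene, truth$component))
  # genes already deficient untreated are excluded even if worse when treated
  expect_false(any(cr$gene %in% b$toy$truth$total_loss$gene))
  expect_error(find_cryptic_risk_factors(un, tr[-1, ]), "mismatched")
})

test_that("ratios are monotone in the inhibition fraction", {
  b <- built_toy(2)
  sw <- sensitivity_sweep(b$model, b$toy$targets, b$components,
                          parameter = "inhibition_fraction",
                          grid = c(0, 0.25, 0.5, 0.75, 1),
                          config = sim_config())
  for (p in unique(sw$perturbation)) {
    for (co in unique(sw$component)) {
      r <- sw$ratio[sw$perturbation == p & sw$component == co]
      expect_true(all(diff(r) >= -1e-9),
                  label = sprintf("%s/%s monotone", p, co))
    }
  }
  # full remaining activity means no phenotype anywhere
  expect_true(all(sw$ratio[sw$value == 1] >= 1 - 1e-6))
})

test_that("normalized sensitivity coefficients are bounded and base-anchored", {
  b <- built_toy(1)
  sw <- sensitivity_sweep(b$model, b$toy$targets, b$components,
                          parameter = "sbfc", config = sim_config(),
                          exchange_bounds = b$bounds)
  expect_true(all(sw$nsc >= -1 - 1e-9 & sw$nsc <= 1 + 1e-9))
  expect_true(all(sw$nsc[abs(sw$value - 13.5) < 1e-9] == 0))
  # single-route total loss is insensitive to the boundary constraint
  ptgis <- sw[sw$perturbation == "TGT_ptgis" & sw$component == "pgi2", ]
  expect_true(all(ptgis$ratio == 0))
  expect_true(all(ptgis$nsc == 0))
  # base value must be on the grid
  expect_error(sensitivity_sweep(b$model, b$toy$targets, b$components,
                                 parameter = "sbfc", grid = c(0, 500, 1000),
                                 config = sim_config(), exchange_bounds = b$bounds),
               "not in the sweep grid")
})

test_that("a bypass opening at high sbfc reaches positive unit sensitivity", {
  # hand-built reabsorption: direct route capacity 5 (gene-dependent) plus a
  # co-substrate bypass; consumption capped at 10.  Knocking out the direct
  # route leaves r(base) = 0.5 and r(1000) = 1.0, so NSC(1000) = +1.
  mets <- data.frame(
    id = c("h_b", "h_c", "c_b", "c_c", "w_c"),
    name = c("h_b", "h_c", "c_b", "c_c", "w_c"),
    compartment = c("blood", "cytosol", "blood", "cytosol", "cytosol"))
  rxns <- data.frame(
    id = c("EX_h_b", "EX_c_b", "T_dir", "T_co", "T_byp", "DM_h_c", "DM_w_c"),
    lb = c(-1000, -1000, 0, 0, 0, 0, 0),
    ub = c(13.5, 13.5, 5, 1000, 1000, 10, 1000),
    kind = c("exchange", "exchange", "transport", "transport", "transport",
             "demand", "demand"),
    gpr = c("", "", "g_dir", "", "g_byp", "", ""))
  sto <- list(c(h_b = -1), c(c_b = -1), c(h_b = -1, h_c = 1),
              c(c_b = -1, c_c = 1), c(h_b = -1, c_c = -2, h_c = 1, w_c = 2),
              c(h_c = -1), c(w_c = -1))
  m <- metabolic_model(mets, rxns, sto,
                       compartments = c("blood", "cytosol"))
  comp <- data.frame(name = "h", metabolite_id = "h_c",
                     direction = "reabsorption", exchange_metabolite_id = "h_b",
                     boundary_id = "EX_h_b", compatible = TRUE)
  tm <- target_map(data.frame(target_id = "TGT_dir", gene_id = "g_dir"), m)
  eb <- data.frame(reaction_id = c("EX_h_b", "EX_c_b"),
                   metabolite_id = c("h_b", "c_b"),
                   lb = c(-1000, -1000), ub = c(13.5, 13.5),
                   rule = "free_exchange")
  cfg <- sim_config(sbfc = 10)  # base: bypass carries 10/2 = 5 of the cap 10
  sw <- sensitivity_sweep(m, tm, comp, parameter = "sbfc",
                          grid = c(0, 10, 1000), config = cfg,
                          exchange_bounds = eb)
  at <- function(v) sw[sw$value == v & sw$perturbation == "TGT_dir", ]
  expect_equal(at(10)$ratio, 0.5)
  expect_equal(at(1000)$ratio, 1.0)
  expect_equal(at(1000)$nsc, 1.0)
  expect_equal(at(0)$nsc, -1.0)
})
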
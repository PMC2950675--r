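exchange_fixture <- function() {
  mets <- data.frame(id = c("x_b", "y_u", "z_u", "x_c"),
                     name = c("x_b", "y_u", "z_u", "x_c"),
                     compartment = c("blood", "urine", "urine", "cytosol"))
  rxns <- data.frame(id = c("EX_x_b", "EX_y_u", "EX_z_u", "T_x"),
                     lb = c(-1000, -1000, -1000, 0),
                     ub = c(1000, 1000, 1000, 1000),
                     kind = c("exchange", "exchange", "exchange", "transport"))
  sto <- list(c(x_b = -1), c(y_u = -1), c(z_u = -1), c(x_b = -1, x_c = 1))
  metabolic_model(mets, rxns, sto,
                  compartments = c("blood", "cytosol", "urine"))
}

test_that("exchange bounds follow the biofluid evidence rules", {
  m <- exchange_fixture()
  ev <- data.frame(
    metabolite_id = c("x_b", "y_u", "z_u"),
    in_blood = c(TRUE, FALSE, FALSE),
    in_urine = c(FALSE, TRUE, TRUE),
    in_tissue = c(TRUE, FALSE, TRUE),
    curated_secretion_objective = c(FALSE, FALSE, TRUE))
  b <- derive_exchange_bounds(m, ev, sbfc = 13.5)
  row <- function(id) b[b$reaction_id == id, ]
  # blood + tissue: free exchange, efflux capped at the sbfc
  expect_equal(c(row("EX_x_b")$lb, row("EX_x_b")$ub), c(-1000, 13.5))
  # urine only without tissue: both flags required, stays closed
  expect_equal(c(row("EX_y_u")$lb, row("EX_y_u")$ub), c(0, 0))
  # urine + tissue secretion objective: efflux only, never uptake
  expect_equal(c(row("EX_z_u")$lb, row("EX_z_u")$ub), c(0, 13.5))
  # unknown metabolites in the evidence are skipped with a warning
  ev2 <- rbind(ev, data.frame(metabolite_id = "ghost", in_blood = TRUE,
                              in_urine = FALSE, in_tissue = TRUE,
                              curated_secretion_objective = FALSE))
  expect_warning(derive_exchange_bounds(m, ev2, 13.5), "ghost")
  # curated free exchange opens an otherwise evidence-free metabolite
  ev$curated_free_exchange <- c(FALSE, TRUE, FALSE)
  b2 <- derive_exchange_bounds(m, ev, 13.5)
  expect_equal(b2[b2$reaction_id == "EX_y_u", ]$lb, -1000)
  # a curated-forbidden uptake is never widened
  ev$curated_uptake_forbidden <- c(TRUE, FALSE, FALSE)
  b3 <- derive_exchange_bounds(m, ev, 13.5)
  expect_equal(b3[b3$reaction_id == "EX_x_b", ]$lb, 0)
})

test_that("objective assembly adds boundaries and reports incompatibles", {
  toy <- generate_toy_organ(2)
  m <- apply_exchange_bounds(toy$model,
                             derive_exchange_bounds(toy$model, toy$evidence))
  # add an orphan metabolite with no producing pathway
  m$metabolites <- rbind(m$metabolites,
                         data.frame(id = "orphan_c", name = "orphan_c",
                                    compartment = "cytosol"))
  spec <- toy$objective
  spec$components <- rbind(spec$components,
                           data.frame(name = "orphan", metabolite_id = "orphan_c",
                                      direction = "secretion",
                                      exchange_metabolite_id = "orphan_c",
                                      weight = 1))
  asm <- assemble_objective(m, spec)
  expect_true("orphan" %in% asm$incompatible)
  expect_false("orphan_c" %in% names(asm$model$stoichiometry[[asm$objective_reaction]]))
  # compatible components all enter the combined reaction with unit weights
  st <- asm$model$stoichiometry[[asm$objective_reaction]]
  expect_equal(unname(st[c("pgi2_u", "urate_u", "glc_c", "cit_c")]),
               rep(-1, 4))
  # ATP maintenance term present
  expect_equal(unname(st["atp_c"]), -1)
  expect_equal(unname(st["adp_c"]), 1)
  # per-component boundary reactions exist
  expect_true(all(c("DM_glc_c", "EX_pgi2_u") %in% asm$model$reactions$id))
  expect_error(objective_spec(data.frame()), "no components")
})

test_that("GIMME inactivates redundant low-expression routes only", {
  # two parallel routes, uptake-limited at 10, each route capacity 10:
  # the high-expression route alone attains the optimum
  p <- parallel_model(cap1 = 10, cap2 = 10, ex_ub = 10,
                      gpr1 = "g_hi", gpr2 = "g_lo")
  sc <- reaction_scores(p, c(g_hi = 2000, g_lo = 100))
  g <- run_gimme(p, sc, threshold = 1000, objective_reaction = "DM_b_c")
  expect_equal(unname(g$activity["P2"]), "inactive")
  expect_false(g$activity["P1"] == "inactive")
  # the high route alone attains the optimum, so consistency is perfect
  expect_equal(g$inconsistency_score, 0)
  # objective attainment contract
  expect_gte(unname(g$fluxes["DM_b_c"]), 0.9 * g$objective_max - 1e-6)
})

test_that("GIMME keeps a below-threshold reaction that is the only route", {
  m <- chain_model()
  sc <- reaction_scores(m, c(g1 = 100, gT = 2000))
  g <- run_gimme(m, sc, threshold = 1000, objective_reaction = "DM_b_c")
  expect_equal(unname(g$activity["R1"]), "active")
  expect_gt(g$inconsistency_score, 0)
  expect_gte(unname(g$fluxes["DM_b_c"]), 0.9 * g$objective_max - 1e-6)
})

test_that("GIMME with all scores above threshold has zero inconsistency", {
  p <- parallel_model(gpr1 = "g1", gpr2 = "g2")
  sc <- reaction_scores(p, c(g1 = 5000, g2 = 4000))
  g <- run_gimme(p, sc, threshold = 1000, objective_reaction = "DM_b_c")
  expect_equal(g$inconsistency_score, 0)
  expect_true(all(g$activity != "inactive"))
})

test_that("GIMME inconsistency is non-increasing as the threshold drops", {
  toy <- built_toy(3)
  expr <- generate_expression(toy$toy$model, toy$toy$truth$expressed_genes, 30)
  prof <- expression_profile(expr$rep1, expr$rep2, expr$probe_map)
  sc <- reaction_scores(toy$model, prof$gene_values)
  prev <- Inf
  for (thr in c(prof$threshold, prof$threshold / 2, prof$threshold / 10)) {
    g <- run_gimme(toy$model, sc, thr,
                   objective_reaction = toy$objective_reaction)
    expect_lte(g$inconsistency_score, prev + 1e-9)
    prev <- g$inconsistency_score
  }
  expect_error(run_gimme(toy$model, sc, 100, 0.9, "nope"), "unknown")
})

test_that("model reduction drops dead branches and preserves optima", {
  b <- built_toy(6)
  # without expression-based extraction the side pathways stay flux-capable,
  # so the union is legitimately disconnected and reduce_model says so
  expect_warning(red <- reduce_model(b$model, b$components),
                 "connected components")
  expect_false("R_dead" %in% red$kept)           # dead-end branch excluded
  expect_true(all(abs(red$component_optima$full -
                        red$component_optima$reduced) < 1e-6))
  # single-path model reduces to the path plus boundaries
  m <- chain_model()
  comp <- data.frame(name = "b", metabolite_id = "b_c",
                     direction = "reabsorption",
                     exchange_metabolite_id = "a_b",
                     boundary_id = "EX_a_b", demand_id = "DM_b_c",
                     compatible = TRUE)
  r2 <- reduce_model(m, comp)
  expect_setequal(r2$kept, c("EX_a_b", "T_a", "R1", "DM_b_c"))
})

test_that("GIMME-constrained reduction recovers the planted inactive set", {
  b <- built_toy(7)
  expr <- generate_expression(b$toy$model, b$toy$truth$expressed_genes, 70)
  prof <- expression_profile(expr$rep1, expr$rep2, expr$probe_map)
  sc <- reaction_scores(b$model, prof$gene_values)
  g <- run_gimme(b$model, sc, prof$threshold,
                 objective_reaction = b$objective_reaction)
  # planted-inactive reactions with measured expression are all called inactive
  planted <- intersect(b$toy$truth$inactive_reactions,
                       names(sc)[!is.na(sc)])
  expect_true(all(g$activity[planted] == "inactive"))
  # nothing outside the planted set is inactivated
  extra <- setdiff(names(g$activity)[g$activity == "inactive"],
                   b$toy$truth$inactive_reactions)
  expect_length(extra, 0)
  ctx <- apply_gimme(b$model, g)
  red <- reduce_model(ctx, b$components)
  expect_true(all(abs(red$component_optima$full -
                        red$component_optima$reduced) < 1e-6))
  # the functional sub-model is connected
  expect_equal(length(red$skipped), 0)
  # planted disorder calls are unchanged after extraction and reduction
  un <- scan_gene_deletions(red$model, genes = model_genes(b$toy$model),
                            components = b$components, config = sim_config())
  calls <- disorder_calls(un)
  truth <- b$toy$truth
  expect_setequal(paste(calls$perturbation, calls$component),
                  c(paste(truth$total_loss$gene, truth$total_loss$component),
                    paste(truth$partial$gene, truth$partial$component)))
  for (i in seq_len(nrow(truth$partial))) {
    expect_equal(unname(un[truth$partial$gene[i], truth$partial$component[i]]),
                 truth$partial$ratio[i], tolerance = 1e-6)
  }
})
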
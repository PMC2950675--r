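toy_config <- function(dir, fixture_paths, out_dir = file.path(dir, "out")) {
  list(
    inputs = list(model = fixture_paths$model,
                  expression_rep1 = fixture_paths$rep1,
                  expression_rep2 = fixture_paths$rep2,
                  probe_map = fixture_paths$probe_map,
                  evidence = fixture_paths$evidence,
                  targets = fixture_paths$targets,
                  benchmark = fixture_paths$benchmark),
    objective = list(components = list(
      list(name = "pgi2", metabolite_id = "pgi2_u", direction = "secretion"),
      list(name = "urate", metabolite_id = "urate_u", direction = "secretion"),
      list(name = "glc", metabolite_id = "glc_c", direction = "reabsorption",
           exchange_metabolite_id = "glc_b"),
      list(name = "cit", metabolite_id = "cit_c", direction = "reabsorption",
           exchange_metabolite_id = "cit_b"))),
    out_dir = out_dir,
    permutation_trials = 20,
    seed = 7)
}

test_that("the build command produces a reduced model preserving optima", {
  dir <- tempfile("wf")
  paths <- write_fixture_set(file.path(dir, "fx"), seed = 1)
  cfg <- toy_config(dir, paths)
  built <- run_build(cfg)
  expect_true(file.exists(built$paths$reduced))
  expect_true(all(abs(built$reduced$component_optima$full -
                        built$reduced$component_optima$reduced) < 1e-6))
  # provenance log covers every exchange reaction with its rule
  bounds <- read.delim(built$paths$bounds)
  n_ex <- sum(built$context_model$reactions$kind == "exchange")
  expect_equal(nrow(bounds), n_ex)
  expect_true(all(nzchar(bounds$rule)))
  report <- jsonlite::read_json(file.path(cfg$out_dir, "build", "build_report.json"))
  expect_true(nzchar(report$config_hash))
  expect_gt(report$threshold, 0)
})

test_that("missing config inputs are reported by field name", {
  dir <- tempfile("wf2")
  paths <- write_fixture_set(file.path(dir, "fx"), seed = 2)
  cfg <- toy_config(dir, paths)
  cfg$inputs$evidence <- NULL
  expect_error(run_build(cfg), "inputs\\$evidence")
  cfg2 <- toy_config(dir, paths)
  cfg2$inputs$model <- file.path(dir, "nope.xml")
  expect_error(run_build(cfg2), "missing file")
})

test_that("perturb and validate commands run end to end on fixtures", {
  dir <- tempfile("wf3")
  paths <- write_fixture_set(file.path(dir, "fx"), seed = 1)
  cfg <- toy_config(dir, paths)
  pert <- run_perturb(cfg)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_setequal(paste(pert$cryptic$gene, pert$cryptic$component),
                  paste(truth$cryptic$gene, truth$cryptic$component))
  expect_equal(unname(unclass(pert$drug_targets)["TGT_ptgis", "pgi2"]), 0)
  val <- run_validate(cfg)
  expect_equal(val$roc$auc, 1.0)
  expect_lt(val$permutation$p_value, 0.05)
  rep_path <- file.path(cfg$out_dir, "validate", "roc_report.json")
  expect_true(file.exists(rep_path))
})

test_that("commands are reproducible given config and seed", {
  dir <- tempfile("wf4")
  paths <- write_fixture_set(file.path(dir, "fx"), seed = 3)
  cfg1 <- toy_config(dir, paths, out_dir = file.path(dir, "o1"))
  cfg2 <- toy_config(dir, paths, out_dir = file.path(dir, "o2"))
  v1 <- run_validate(cfg1)
  v2 <- run_validate(cfg2)
  expect_identical(v1$permutation$aucs, v2$permutation$aucs)
  expect_identical(v1$roc$auc, v2$roc$auc)
  # YAML config path round-trips through the same loader
  yml <- file.path(dir, "config.yaml")
  cfg1$out_dir <- file.path(dir, "o3")
  yaml::write_yaml(cfg1, yml)
  v3 <- run_validate(yml)
  expect_identical(v3$roc$auc, v1$roc$auc)
})

test_that("the sensitivity command sweeps both parameters", {
  dir <- tempfile("wf5")
  paths <- write_fixture_set(file.path(dir, "fx"), seed = 1)
  cfg <- toy_config(dir, paths)
  sens <- run_sensitivity(cfg)
  expect_true(all(sens$sbfc$nsc >= -1 - 1e-9 & sens$sbfc$nsc <= 1 + 1e-9))
  expect_true(all(sens$inhibition_fraction$nsc >= -1 - 1e-9 &
                    sens$inhibition_fraction$nsc <= 1 + 1e-9))
  ptgis <- sens$sbfc[sens$sbfc$perturbation == "TGT_ptgis" &
                       sens$sbfc$component == "pgi2", ]
  expect_true(all(ptgis$nsc == 0))
})
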
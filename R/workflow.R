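#' Pipeline orchestration
#'
#' Declarative configuration plus one function per workflow stage: model
#' building (`run_build`), perturbation scanning (`run_perturb`), parameter
#' sensitivity (`run_sensitivity`), benchmark validation (`run_validate`),
#' cross-validation (`run_crossval`) and fixture generation (`run_synth`).
#' Every command is reproducible given config plus seeds, and every output
#' directory carries the config and its hash. A thin command-line front-end
#' over these functions ships in `inst/cli/organfba.R`.
#'
#' @name cli_workflow
NULL

pipeline_defaults <- function() {
  list(p_target = 0.05, span = 0.3, required_fraction = 0.90,
       sbfc = 13.5, inhibition_fraction = 0, disorder_threshold = 1,
       permutation_trials = 100, alpha = 0.05,
       crossval_fraction = 0.20, crossval_folds = 5,
       include_atp_maintenance = TRUE, seed = 1)
}

#' Load and validate a pipeline configuration
#'
#' @param config A named list, or path to a YAML file. Recognized fields:
#'   `inputs` (paths: `model`, `expression_rep1`, `expression_rep2`,
#'   `probe_map`, `evidence`, `targets`, `benchmark`), `objective`
#'   (`components`: list of `name`/`metabolite_id`/`direction`/
#'   `exchange_metabolite_id`; `include_atp_maintenance`), `out_dir`, `seed`
#'   and the numeric parameters (defaults: p_target 0.05, span 0.3,
#'   required_fraction 0.9, sbfc 13.5, inhibition_fraction 0,
#'   disorder_threshold 1, permutation_trials 100, alpha 0.05,
#'   crossval_fraction 0.2, crossval_folds 5).
#' @return Validated config list with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  def <- pipeline_defaults()
  for (k in names(def)) if (is.null(config[[k]])) config[[k]] <- def[[k]]
  if (is.null(config$out_dir)) config$out_dir <- "organfba_out"
  with(config, stopifnot(p_target > 0, p_target < 1, span > 0, span <= 1,
                         required_fraction > 0, required_fraction <= 1,
                         sbfc >= 0, inhibition_fraction >= 0,
                         inhibition_fraction <= 1, permutation_trials >= 2))
  config
}

cfg_input <- function(config, field) {
  path <- config$inputs[[field]]
  if (is.null(path)) {
    stop(sprintf("config is missing required input field 'inputs$%s'", field),
         call. = FALSE)
  }
  if (!file.exists(path)) {
    stop(sprintf("config input 'inputs$%s' points to a missing file: %s",
                 field, path), call. = FALSE)
  }
  path
}

config_hash <- function(config) {
  # multiplicative rolling hash over the canonical JSON rendering
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

read_probe_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(d$intensity, d$probeset_id)
}

write_stage_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg$config_hash <- config_hash(config)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg$config_hash
}

config_objective <- function(config) {
  comps <- config$objective$components
  if (is.null(comps)) {
    stop("config is missing required field 'objective$components'", call. = FALSE)
  }
  if (!is.data.frame(comps)) {
    comps <- do.call(rbind, lapply(comps, function(x)
      data.frame(name = x$name %||% x$metabolite_id,
                 metabolite_id = x$metabolite_id,
                 direction = x$direction,
                 weight = x$weight %||% 1,
                 exchange_metabolite_id = x$exchange_metabolite_id %||% x$metabolite_id,
                 stringsAsFactors = FALSE)))
  }
  objective_spec(comps,
                 include_atp_maintenance = isTRUE(config$include_atp_maintenance))
}

#' Build the context-specific organ model
#'
#' Runs the expression pipeline, derives evidence-based exchange bounds,
#' assembles the objective, extracts the expression-consistent model (GIMME)
#' and reduces it to the functional sub-model. Writes the context and reduced
#' models (SBML), the GIMME report, the exchange-bound provenance log, the
#' expression profile and a JSON build report into `config$out_dir`.
#'
#' @param config A [pipeline_config()] (list or YAML path).
#' @return Invisibly, a list with `context_model`, `reduced`, `gimme`,
#'   `profile`, `components`, `exchange_bounds`, `paths`.
#' @export
run_build <- function(config) {
  config <- pipeline_config(config)
  out <- file.path(config$out_dir, "build")
  hash <- write_stage_config(config, out)
  model <- read_sbml(cfg_input(config, "model"))
  evidence <- utils::read.delim(cfg_input(config, "evidence"),
                                stringsAsFactors = FALSE)
  rep1 <- read_probe_tsv(cfg_input(config, "expression_rep1"))
  rep2 <- read_probe_tsv(cfg_input(config, "expression_rep2"))
  probe_map <- utils::read.delim(cfg_input(config, "probe_map"),
                                 stringsAsFactors = FALSE)
  profile <- expression_profile(rep1, rep2, probe_map,
                                p = config$p_target, span = config$span)
  bounds <- derive_exchange_bounds(model, evidence, sbfc = config$sbfc)
  model <- apply_exchange_bounds(model, bounds)
  asm <- assemble_objective(model, config_objective(config))
  scores <- reaction_scores(asm$model, profile$gene_values)
  gimme <- run_gimme(asm$model, scores, profile$threshold,
                     required_fraction = config$required_fraction,
                     objective_reaction = asm$objective_reaction)
  context <- apply_gimme(asm$model, gimme)
  red <- reduce_model(context, asm$components)
  paths <- list(context = file.path(out, "context_model.xml"),
                reduced = file.path(out, "reduced_model.xml"),
                gimme = file.path(out, "gimme_report.tsv"),
                bounds = file.path(out, "exchange_bounds.tsv"),
                profile = file.path(out, "expression_profile.tsv"),
                report = file.path(out, "build_report.json"))
  write_sbml(context, paths$context)
  write_sbml(red$model, paths$reduced)
  gimme_report(gimme, scores, paths$gimme)
  utils::write.table(bounds, paths$bounds, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_profile_tsv(profile, paths$profile)
  jsonlite::write_json(list(
    config_hash = hash,
    threshold = profile$threshold,
    objective_max = gimme$objective_max,
    inconsistency = gimme$inconsistency_score,
    n_active = sum(gimme$activity != "inactive"),
    n_inactive = sum(gimme$activity == "inactive"),
    n_reduced = nrow(red$model$reactions),
    incompatible_components = asm$incompatible,
    component_optima = red$component_optima),
    paths$report, auto_unbox = TRUE, digits = NA)
  invisible(list(context_model = context, reduced = red, gimme = gimme,
                 profile = profile, components = asm$components,
                 objective_reaction = asm$objective_reaction,
                 exchange_bounds = bounds, paths = paths))
}

load_sim_inputs <- function(config, model_field = "model") {
  model <- read_sbml(cfg_input(config, model_field))
  spec <- config_objective(config)
  if (!"R_organ_objective" %in% model$reactions$id) {
    # raw base model: add per-component boundaries and the combined objective
    asm <- assemble_objective(model, spec)
    model <- asm$model
    comps <- asm$components
  } else {
    # already-built model: the deterministic boundary ids are in place
    comps <- spec$components
    comps$boundary_id <- ifelse(
      comps$direction == "secretion", paste0("EX_", comps$metabolite_id),
      paste0("EX_", comps$exchange_metabolite_id))
    comps$compatible <- NA
  }
  targets <- target_map(utils::read.delim(cfg_input(config, "targets"),
                                          stringsAsFactors = FALSE), model)
  list(model = model, targets = targets, components = comps,
       config = sim_config(sbfc = config$sbfc,
                           inhibition_fraction = config$inhibition_fraction,
                           disorder_threshold = config$disorder_threshold))
}

#' Scan gene deletions and drug targets; report cryptic risk factors
#'
#' @param config A [pipeline_config()]; `inputs$model` should point to the
#'   built (context or reduced) model.
#' @return Invisibly, a list with the three `perturbation_matrix` objects
#'   (`genes_untreated`, `genes_treated`, `drug_targets`) and `cryptic`.
#' @export
run_perturb <- function(config) {
  config <- pipeline_config(config)
  out <- file.path(config$out_dir, "perturb")
  write_stage_config(config, out)
  inp <- load_sim_inputs(config)
  untreated <- scan_gene_deletions(inp$model, components = inp$components,
                                   config = inp$config)
  treated <- scan_gene_deletions(inp$model, components = inp$components,
                                 config = inp$config, treatment = inp$targets)
  drugs <- scan_drug_targets(inp$model, inp$targets, inp$components, inp$config)
  cryptic <- find_cryptic_risk_factors(untreated, treated)
  write_matrix_tsv(untreated, file.path(out, "gene_untreated.tsv"))
  write_matrix_tsv(treated, file.path(out, "gene_treated.tsv"))
  write_matrix_tsv(drugs, file.path(out, "drug_targets.tsv"))
  utils::write.table(cryptic, file.path(out, "cryptic_risk_factors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    disorders_untreated = disorder_calls(untreated),
    disorders_drug = disorder_calls(drugs),
    cryptic = cryptic), file.path(out, "perturb_report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(list(genes_untreated = untreated, genes_treated = treated,
                 drug_targets = drugs, cryptic = cryptic))
}

#' Sweep simulation parameters and report sensitivity coefficients
#'
#' @param config A [pipeline_config()]; needs `inputs$model`, `inputs$targets`
#'   and `inputs$evidence` (for re-deriving boundary caps along the sbfc grid).
#' @return Invisibly, list of the two sweep data.frames (`sbfc`,
#'   `inhibition_fraction`).
#' @export
run_sensitivity <- function(config) {
  config <- pipeline_config(config)
  out <- file.path(config$out_dir, "sensitivity")
  write_stage_config(config, out)
  inp <- load_sim_inputs(config)
  evidence <- utils::read.delim(cfg_input(config, "evidence"),
                                stringsAsFactors = FALSE)
  eb <- derive_exchange_bounds(inp$model, evidence, sbfc = config$sbfc)
  sw1 <- sensitivity_sweep(inp$model, inp$targets, inp$components,
                           parameter = "sbfc", config = inp$config,
                           exchange_bounds = eb)
  sw2 <- sensitivity_sweep(inp$model, inp$targets, inp$components,
                           parameter = "inhibition_fraction", config = inp$config)
  utils::write.table(sw1, file.path(out, "sweep_sbfc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sw2, file.path(out, "sweep_inhibition.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(sbfc = sw1, inhibition_fraction = sw2))
}

#' Validate gene-deficiency predictions against a clinical benchmark
#'
#' @param config A [pipeline_config()]; needs `inputs$model` and
#'   `inputs$benchmark`.
#' @return Invisibly, list with `roc`, `permutation` and the ratio matrix.
#' @export
run_validate <- function(config) {
  config <- pipeline_config(config)
  out <- file.path(config$out_dir, "validate")
  hash <- write_stage_config(config, out)
  inp <- load_sim_inputs(config)
  benchmark <- benchmark_table(utils::read.delim(cfg_input(config, "benchmark"),
                                                 stringsAsFactors = FALSE))
  genes <- unique(c(model_genes(inp$model), benchmark$gene_id))
  ratios <- scan_gene_deletions(inp$model, genes = genes,
                                components = inp$components, config = inp$config)
  roc <- roc_analysis(ratios, benchmark)
  perm <- permutation_null(ratios, benchmark,
                           n_trials = config$permutation_trials,
                           seed = config$seed)
  jsonlite::write_json(list(
    config_hash = hash, auc = roc$auc, mean_tpr = roc$mean_tpr,
    mean_tpr_interior = roc$mean_tpr_interior,
    curve = data.frame(threshold = roc$thresholds, tpr = roc$tpr, fpr = roc$fpr),
    permutation = perm[c("mean_auc", "p_value", "null_mean_tpr",
                         "tpr_p_value", "seed")],
    alpha = config$alpha,
    significant = perm$p_value < config$alpha),
    file.path(out, "roc_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(roc = roc, permutation = perm, ratios = ratios))
}

#' Cross-validate activity recall of highly expressed genes
#'
#' @param config A [pipeline_config()]; `inputs$model` should point to the
#'   preliminary context model (bounds applied, objective assembled), e.g.
#'   the build stage's context model.
#' @param objective_reaction Combined objective reaction id.
#' @return Invisibly, the [crossval_recall()] result.
#' @export
run_crossval <- function(config, objective_reaction = "R_organ_objective") {
  config <- pipeline_config(config)
  out <- file.path(config$out_dir, "crossval")
  write_stage_config(config, out)
  model <- read_sbml(cfg_input(config, "model"))
  if (!objective_reaction %in% model$reactions$id) {
    model <- assemble_objective(model, config_objective(config),
                                objective_id = objective_reaction)$model
  }
  rep1 <- read_probe_tsv(cfg_input(config, "expression_rep1"))
  rep2 <- read_probe_tsv(cfg_input(config, "expression_rep2"))
  probe_map <- utils::read.delim(cfg_input(config, "probe_map"),
                                 stringsAsFactors = FALSE)
  profile <- expression_profile(rep1, rep2, probe_map,
                                p = config$p_target, span = config$span)
  cv <- crossval_recall(model, profile$gene_values, objective_reaction,
                        required_fraction = config$required_fraction,
                        fraction = config$crossval_fraction,
                        folds = config$crossval_folds, p = config$p_target)
  jsonlite::write_json(cv, file.path(out, "crossval_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cv)
}

#' Generate a synthetic fixture set
#'
#' @param config A [pipeline_config()]; uses `out_dir` and `seed`.
#' @return Invisibly, the written paths (see [write_fixture_set()]).
#' @export
run_synth <- function(config) {
  config <- pipeline_config(config)
  out <- file.path(config$out_dir, "synth")
  write_stage_config(config, out)
  invisible(write_fixture_set(out, seed = config$seed))
}
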
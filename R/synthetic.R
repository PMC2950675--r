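#' Synthetic data with planted ground truth
#'
#' Generates toy organ models (three compartments: blood, cytosol, urine),
#' two-replicate probe expression tables, metabolite evidence tables, drug
#' target maps and clinical benchmark tables whose correct analysis results
#' are known by construction, so every pipeline stage can be tested without
#' external data.
#'
#' The planted motifs mirror the structures that drive organ-model phenotype
#' predictions: a secretion with a unique synthesis route (every route gene is
#' a total-loss plant and one drug target reproduces the single-pathway
#' pattern), a reabsorption with direct plus indirect catabolic routes
#' (partial-loss plants with exact expected ratios), an isozyme pair (no
#' phenotype), a primary/backup route pair whose backup gene is a cryptic
#' risk factor against a generated drug target, a co-transport bypass whose
#' capacity tracks the system boundary flux constraint (parameter-sensitive
#' plant), a dead-end branch and low-expression side routes (extraction
#' plants).
#'
#' @name synthetic_data
NULL

#' Generate a toy organ model with planted phenotypes
#'
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @param n_pathways Number of additional random uptake-conversion pathways.
#' @param redundancy_prob Probability that a random pathway step carries an
#'   isozyme pair instead of a single gene.
#' @param depth Chain length of the random pathways.
#' @param sbfc Base system boundary flux constraint used to state the expected
#'   ratio of the boundary-sensitive plant.
#' @return A `toy_organ` list: `model` (raw bounds), `objective` (an
#'   [objective_spec()]), `evidence` (table for [derive_exchange_bounds()]),
#'   `targets` (a [target_map()]), `truth` (ground-truth list: see Details).
#' @details `truth` carries `total_loss` (gene, component), `partial` (gene,
#'   component, expected ratio at the base configuration), `none` (genes whose
#'   single deletion changes nothing), `cryptic` (gene, target, component),
#'   `inactive_reactions` (reactions an expression-guided extraction should
#'   close), `expressed_genes` (the planted high-expression set) and
#'   `safe_pairs` (gene-component pairs guaranteed unaffected, for benchmark
#'   negatives).
#' @export
generate_toy_organ <- function(seed, n_pathways = 8, redundancy_prob = 0.4,
                               depth = 3, sbfc = 13.5) {
  stopifnot(n_pathways >= 2, depth >= 1)
  for (attempt in 0:9) {
    toy <- build_toy_organ(seed + attempt * 100003L, n_pathways,
                           redundancy_prob, depth, sbfc)
    ok <- tryCatch({
      asm <- assemble_objective(apply_exchange_bounds(
        toy$model, derive_exchange_bounds(toy$model, toy$evidence, sbfc)),
        toy$objective)
      all(asm$components$compatible) &&
        maximize_flux(asm$model, asm$objective_reaction)$objective_value > 1e-6
    }, error = function(e) FALSE)
    if (ok) return(toy)
  }
  stop("generate_toy_organ: no feasible model in 10 attempts", call. = FALSE)
}

build_toy_organ <- function(seed, n_pathways, redundancy_prob, depth, sbfc) {
  set.seed(seed)
  mets <- list(); rxns <- list(); sto <- list()
  add_met <- function(id, comp) mets[[id]] <<- data.frame(
    id = id, name = id, compartment = comp, stringsAsFactors = FALSE)
  add_rxn <- function(id, st, lb, ub, gpr = "", kind = "enzymatic",
                      subsystem = "core") {
    rxns[[id]] <<- data.frame(id = id, lb = lb, ub = ub, subsystem = subsystem,
                              kind = kind, gpr = gpr, stringsAsFactors = FALSE)
    sto[[id]] <<- st
  }
  V <- VMAX_DEFAULT

  # --- prostacyclin-like secretion: unique synthesis route ------------------
  for (m in c("ara_b")) add_met(m, "blood")
  for (m in c("ara_c", "pgh2_c", "pgi2_c", "hete_c", "iso_c")) add_met(m, "cytosol")
  for (m in c("pgi2_u", "hete_u")) add_met(m, "urine")
  add_rxn("EX_ara_b", c(ara_b = -1), -V, V, kind = "exchange")
  add_rxn("T_ara", c(ara_b = -1, ara_c = 1), 0, V, "g_slco1 or g_slco2",
          kind = "transport")
  add_rxn("R_cox", c(ara_c = -1, pgh2_c = 1), 0, 7, "g_cox1 and g_cox2")
  add_rxn("R_ptgis", c(pgh2_c = -1, pgi2_c = 1), 0, V, "g_ptgis")
  add_rxn("T_pgi2", c(pgi2_c = -1, pgi2_u = 1), 0, V, "g_pgt", kind = "transport")
  add_rxn("EX_pgi2_u", c(pgi2_u = -1), 0, V, kind = "exchange")
  # low-expression side route and a dead-end branch off the precursor
  add_rxn("R_alox", c(ara_c = -1, hete_c = 1), 0, V, "g_alox")
  add_rxn("T_hete", c(hete_c = -1, hete_u = 1), 0, V, "g_mct1", kind = "transport")
  add_rxn("EX_hete_u", c(hete_u = -1), 0, V, kind = "exchange")
  add_rxn("R_dead", c(ara_c = -1, iso_c = 1), 0, V, "g_cyp2c")

  # --- glucose-like reabsorption: direct (10) + indirect catabolic (5) -----
  add_met("glc_b", "blood")
  for (m in c("glc_c", "glcm_c", "pyr_c")) add_met(m, "cytosol")
  add_rxn("EX_glc_b", c(glc_b = -1), -V, V, kind = "exchange")
  add_rxn("T_glc", c(glc_b = -1, glc_c = 1), 0, 10,
          "g_glut2 and (g_sglt1 or g_sglt2)", kind = "transport")
  add_rxn("T_glcm", c(glc_b = -1, glcm_c = 1), 0, 5, "g_glut1", kind = "transport")
  add_rxn("R_glyc", c(glcm_c = -1, pyr_c = 1), 0, V, "g_hk and g_pk")
  add_rxn("DM_pyr_c", c(pyr_c = -1), 0, V, kind = "demand")

  # --- urate-like secretion: primary/backup isozyme routes (cryptic plant) -
  add_met("hpx_b", "blood")
  for (m in c("hpx_c", "urate_c")) add_met(m, "cytosol")
  add_met("urate_u", "urine")
  add_rxn("EX_hpx_b", c(hpx_b = -1), -V, V, kind = "exchange")
  add_rxn("T_hpx", c(hpx_b = -1, hpx_c = 1), 0, V, "g_slc22", kind = "transport")
  add_rxn("R_xdh", c(hpx_c = -1, urate_c = 1), 0, 10, "g_xdh")
  add_rxn("R_aox", c(hpx_c = -1, urate_c = 1), 0, 10, "g_aox1")
  add_rxn("T_urate", c(urate_c = -1, urate_u = 1), 0, 8, "g_urat1",
          kind = "transport")
  add_rxn("EX_urate_u", c(urate_u = -1), 0, V, kind = "exchange")

  # --- citrate-like reabsorption: sodium-coupled bypass tracks the sbfc ----
  for (m in c("cit_b", "na_b")) add_met(m, "blood")
  for (m in c("cit_c", "na_c", "nax_c")) add_met(m, "cytosol")
  add_rxn("EX_cit_b", c(cit_b = -1), -V, V, kind = "exchange")
  add_rxn("EX_na_b", c(na_b = -1), -V, V, kind = "exchange")
  add_rxn("T_cit", c(cit_b = -1, cit_c = 1), 0, V, "g_nadc1", kind = "transport")
  add_rxn("T_na", c(na_b = -1, na_c = 1), 0, V, "g_enac", kind = "transport")
  add_rxn("T_citna", c(cit_b = -1, na_c = -2, cit_c = 1, nax_c = 2), 0, V,
          "g_nact", kind = "transport")
  add_rxn("DM_cit_c", c(cit_c = -1), 0, 10, kind = "demand")
  add_rxn("DM_nax_c", c(nax_c = -1), 0, V, kind = "demand")

  # --- ATP maintenance module ----------------------------------------------
  add_met("succ_b", "blood")
  for (m in c("succ_c", "atp_c", "adp_c", "pi_c", "h_c", "h2o_c", "co2_c")) {
    add_met(m, "cytosol")
  }
  add_rxn("EX_succ_b", c(succ_b = -1), -V, V, kind = "exchange")
  add_rxn("T_succ", c(succ_b = -1, succ_c = 1), 0, V, "g_sdct", kind = "transport")
  add_rxn("R_atp", c(succ_c = -1, adp_c = -1, pi_c = -1, h_c = -1,
                     atp_c = 1, h2o_c = 1, co2_c = 1), 0, V,
          "g_atp5a and g_atp5b")
  add_rxn("DM_co2_c", c(co2_c = -1), 0, V, kind = "demand")

  # --- random filler pathways (disjoint from the planted routes) -----------
  extra_genes <- character()
  for (i in seq_len(n_pathways)) {
    bm <- sprintf("e%d_b", i)
    add_met(bm, "blood")
    add_rxn(sprintf("EX_e%d_b", i), stats::setNames(-1, bm), -V, V,
            kind = "exchange")
    gt <- sprintf("g_e%dt", i)
    gpr_t <- gt
    if (stats::runif(1) < redundancy_prob) {
      gt2 <- sprintf("g_e%dt2", i)
      gpr_t <- sprintf("%s or %s", gt, gt2)
      extra_genes <- c(extra_genes, gt2)
    }
    extra_genes <- c(extra_genes, gt)
    prev <- bm
    cur <- sprintf("e%d_1_c", i)
    add_met(cur, "cytosol")
    add_rxn(sprintf("T_e%d", i), stats::setNames(c(-1, 1), c(prev, cur)),
            0, V, gpr_t, kind = "transport", subsystem = "filler")
    for (k in seq_len(depth)) {
      nxt <- sprintf("e%d_%d_c", i, k + 1)
      add_met(nxt, "cytosol")
      ga <- sprintf("g_e%d_%da", i, k)
      extra_genes <- c(extra_genes, ga)
      gpr_k <- ga
      if (stats::runif(1) < redundancy_prob) {
        gb <- sprintf("g_e%d_%db", i, k)
        extra_genes <- c(extra_genes, gb)
        gpr_k <- sprintf("%s %s %s", ga, sample(c("and", "or"), 1), gb)
      }
      add_rxn(sprintf("R_e%d_%d", i, k),
              stats::setNames(c(-1, 1), c(cur, nxt)), 0, V, gpr_k,
              subsystem = "filler")
      cur <- nxt
    }
    add_rxn(sprintf("DM_e%d_%d_c", i, depth + 1),
            stats::setNames(-1, cur), 0, V, kind = "demand",
            subsystem = "filler")
  }

  model <- metabolic_model(do.call(rbind, mets), do.call(rbind, rxns), sto,
                           compartments = c("blood", "cytosol", "urine"),
                           id = sprintf("toy_organ_seed%d", seed))

  objective <- objective_spec(data.frame(
    name = c("pgi2", "urate", "glc", "cit"),
    metabolite_id = c("pgi2_u", "urate_u", "glc_c", "cit_c"),
    direction = c("secretion", "secretion", "reabsorption", "reabsorption"),
    exchange_metabolite_id = c(NA, NA, "glc_b", "cit_b"),
    stringsAsFactors = FALSE))

  ex_open <- c("ara_b", "glc_b", "hpx_b", "cit_b", "na_b", "succ_b")
  extra_open <- sprintf("e%d_b", seq(2, n_pathways, by = 2))
  evidence <- data.frame(
    metabolite_id = c(ex_open, extra_open, "pgi2_u", "urate_u", "hete_u"),
    in_blood = c(rep(TRUE, length(ex_open) + length(extra_open)), FALSE, FALSE, FALSE),
    in_urine = c(rep(FALSE, length(ex_open) + length(extra_open)), TRUE, TRUE, TRUE),
    in_tissue = TRUE,
    curated_free_exchange = FALSE,
    curated_secretion_objective = c(rep(FALSE, length(ex_open) + length(extra_open)),
                                    TRUE, TRUE, FALSE),
    curated_uptake_forbidden = FALSE,
    stringsAsFactors = FALSE)

  targets <- target_map(data.frame(
    target_id = c("TGT_ptgis", "TGT_xdh", "TGT_alox"),
    gene_id = c("g_ptgis", "g_xdh", "g_alox"),
    reaction_id = NA_character_, stringsAsFactors = FALSE), model)

  low_core <- c("g_ptgis", "g_alox", "g_mct1", "g_cyp2c")
  expressed <- setdiff(model_genes(model), c(low_core, extra_genes))
  filler_rxns <- model$reactions$id[model$reactions$subsystem == "filler" &
                                      model$reactions$gpr != ""]
  truth <- list(
    total_loss = data.frame(
      gene = c("g_cox1", "g_cox2", "g_ptgis", "g_pgt", "g_slc22", "g_urat1"),
      component = c("pgi2", "pgi2", "pgi2", "pgi2", "urate", "urate"),
      stringsAsFactors = FALSE),
    partial = data.frame(
      gene = c("g_glut2", "g_glut1", "g_hk", "g_pk", "g_nadc1"),
      component = c("glc", "glc", "glc", "glc", "cit"),
      ratio = c(5 / 15, 10 / 15, 10 / 15, 10 / 15, min(10, sbfc / 2) / 10),
      stringsAsFactors = FALSE),
    none = c("g_slco1", "g_slco2", "g_sglt1", "g_sglt2", "g_xdh", "g_aox1",
             "g_nact", "g_enac", "g_sdct", "g_atp5a", "g_atp5b", "g_alox",
             "g_mct1", "g_cyp2c", extra_genes),
    cryptic = data.frame(gene = "g_aox1", target = "TGT_xdh",
                         component = "urate", stringsAsFactors = FALSE),
    inactive_reactions = c("R_alox", "T_hete", "R_dead", filler_rxns),
    expressed_genes = expressed,
    components = c("pgi2", "urate", "glc", "cit"),
    sbfc = sbfc)
  safe_genes <- truth$none
  truth$safe_pairs <- expand.grid(gene = safe_genes,
                                  component = truth$components,
                                  stringsAsFactors = FALSE)
  structure(list(model = model, objective = objective, evidence = evidence,
                 targets = targets, truth = truth, seed = seed),
            class = "toy_organ")
}

#' @export
print.toy_organ <- function(x, ...) {
  cat(sprintf("<toy_organ seed %d> ", x$seed))
  print(x$model)
  invisible(x)
}

#' Generate two-replicate probe expression tables for a model
#'
#' Genes in `expressed_genes` draw probe intensities from
#' `Normal(mu_on, sigma^2)`, all other genes (including `n_background`
#' non-network genes, emulating the rest of the array) from
#' `Normal(mu_off, sigma^2)`; intensities are truncated at zero. Replicate 2
#' is drawn independently, scaled by `scale2` and given an
#' intensity-dependent multiplicative bias (exponent `bias`) to exercise
#' global and lowess normalization. A `dropout_prob` fraction of genes gets
#' no probesets at all, exercising the no-data path.
#'
#' @param model A `metabolic_model`.
#' @param expressed_genes Genes planted as expressed (e.g.
#'   `truth$expressed_genes` from [generate_toy_organ()]).
#' @param seed Integer seed.
#' @param mu_on,mu_off,sigma Gaussian mixture parameters (intensity units).
#' @param probes_per_gene Probesets per gene.
#' @param dropout_prob Fraction of genes with no probesets.
#' @param n_background Non-network genes on the array.
#' @param scale2 Global scale factor of replicate 2.
#' @param bias Intensity-dependent bias exponent planted in replicate 2.
#' @return List: `rep1`, `rep2` (named probe vectors), `probe_map`
#'   (data.frame `probeset_id`, `gene_id`), `expressed_genes` (measured
#'   planted-on genes), `dropped_genes`.
#' @export
generate_expression <- function(model, expressed_genes, seed,
                                mu_on = 2000, mu_off = 400, sigma = 100,
                                probes_per_gene = 2, dropout_prob = 0.05,
                                n_background = 150, scale2 = 0.6, bias = 0.15) {
  stopifnot(mu_on > mu_off, sigma > 0, probes_per_gene >= 1)
  set.seed(seed)
  genes <- c(model_genes(model), sprintf("bg%03d", seq_len(n_background)))
  on <- genes %in% expressed_genes
  dropped <- genes[stats::runif(length(genes)) < dropout_prob]
  keep <- setdiff(genes, dropped)
  on <- stats::setNames(on, genes)[keep]
  probe_map <- data.frame(
    probeset_id = as.vector(vapply(keep, function(g)
      sprintf("ps_%s_%d", g, seq_len(probes_per_gene)),
      character(probes_per_gene))),
    gene_id = rep(keep, each = probes_per_gene),
    stringsAsFactors = FALSE)
  mu <- ifelse(on[probe_map$gene_id], mu_on, mu_off)
  n <- nrow(probe_map)
  rep1 <- pmax(0, stats::rnorm(n, mu, sigma))
  x2 <- pmax(0, stats::rnorm(n, mu, sigma))
  center <- mean(x2[x2 > 0])
  rep2 <- x2 * scale2 * (pmax(x2, 1) / center)^bias
  names(rep1) <- names(rep2) <- probe_map$probeset_id
  list(rep1 = rep1, rep2 = rep2, probe_map = probe_map,
       expressed_genes = intersect(expressed_genes, keep),
       dropped_genes = dropped)
}

#' Generate a clinical-style benchmark table from planted ground truth
#'
#' Positives are the planted disorder pairs (total and partial losses);
#' negatives are sampled from the gene-component pairs the ground truth
#' guarantees unaffected.
#'
#' @param truth Ground-truth list from [generate_toy_organ()].
#' @param n_negatives Number of negative entries to sample.
#' @param seed Integer seed.
#' @return A [benchmark_table()] data.frame.
#' @export
generate_benchmark <- function(truth, n_negatives = 12, seed = 1) {
  set.seed(seed)
  pos <- rbind(truth$total_loss[, c("gene", "component")],
               truth$partial[, c("gene", "component")])
  pool <- truth$safe_pairs
  n_negatives <- min(n_negatives, nrow(pool))
  if (n_negatives < 1) stop("no safe negative pairs available", call. = FALSE)
  neg <- pool[sample(nrow(pool), n_negatives), ]
  benchmark_table(data.frame(
    gene_id = c(pos$gene, neg$gene),
    component_id = c(pos$component, neg$component),
    outcome = c(rep("positive", nrow(pos)), rep("negative", n_negatives)),
    stringsAsFactors = FALSE))
}

#' Write a full synthetic fixture set to disk
#'
#' Emits the model (SBML and TSV), probe tables, probeset map, evidence
#' table, target map, benchmark and ground truth (JSON) in the pipeline's own
#' input formats.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Passed to [generate_toy_organ()].
#' @return Invisibly, the named list of written paths.
#' @export
write_fixture_set <- function(dir, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- generate_toy_organ(seed, ...)
  expr <- generate_expression(toy$model, toy$truth$expressed_genes, seed + 1)
  bench <- generate_benchmark(toy$truth, seed = seed + 2)
  p <- function(f) file.path(dir, f)
  write_sbml(toy$model, p("model.xml"))
  write_model_tsv(toy$model, p("model.tsv"))
  wt <- function(d, f) utils::write.table(d, p(f), sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(data.frame(probeset_id = names(expr$rep1), intensity = unname(expr$rep1)),
     "expression_rep1.tsv")
  wt(data.frame(probeset_id = names(expr$rep2), intensity = unname(expr$rep2)),
     "expression_rep2.tsv")
  wt(expr$probe_map, "probe_map.tsv")
  wt(toy$evidence, "evidence.tsv")
  wt(as.data.frame(toy$targets), "targets.tsv")
  wt(bench, "benchmark.tsv")
  jsonlite::write_json(toy$truth, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(model = p("model.xml"), rep1 = p("expression_rep1.tsv"),
                 rep2 = p("expression_rep2.tsv"), probe_map = p("probe_map.tsv"),
                 evidence = p("evidence.tsv"), targets = p("targets.tsv"),
                 benchmark = p("benchmark.tsv"), truth = p("ground_truth.json")))
}
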
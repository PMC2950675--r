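#' Perturbation simulation
#'
#' Simulates drug off-target inhibition and single-gene deficiencies against
#' each objective component. The phenotype readout is the ratio of the
#' perturbed to the matched unperturbed maximum component flux: a ratio of 1
#' is no phenotype, a ratio below 1 is some degree of disorder, 0 is total
#' loss of function.
#'
#' @name perturbation_sim
NULL

#' Simulation configuration
#'
#' @param sbfc System boundary flux constraint (flux units): the common cap on
#'   boundary fluxes other than the one being optimized. Default 13.5.
#' @param inhibition_fraction Remaining activity fraction of drug-inhibited
#'   reactions; 0 (default) is complete inhibition.
#' @param disorder_threshold Ratio below which a phenotype is called a
#'   disorder (default 1).
#' @param vmax Maximum flux magnitude.
#' @return A `sim_config` list.
#' @export
sim_config <- function(sbfc = 13.5, inhibition_fraction = 0,
                       disorder_threshold = 1, vmax = VMAX_DEFAULT) {
  stopifnot(sbfc >= 0, sbfc <= vmax,
            inhibition_fraction >= 0, inhibition_fraction <= 1,
            disorder_threshold >= 0, disorder_threshold <= 1)
  structure(list(sbfc = sbfc, inhibition_fraction = inhibition_fraction,
                 disorder_threshold = disorder_threshold, vmax = vmax),
            class = "sim_config")
}

#' Maximum flux capacity of one objective component
#'
#' Secretions are simulated by maximizing the component's efflux exchange;
#' reabsorptions by maximizing the uptake magnitude of the component's blood
#' exchange while every other allowed uptake is capped at `config$sbfc`. In
#' both cases the optimized boundary reaction itself is freed to `vmax` in
#' the optimized direction (the boundary cap never applies to the flux being
#' optimized).
#'
#' @param model A `metabolic_model`.
#' @param component One row of the component table from
#'   [assemble_objective()] (needs `boundary_id` and `direction`).
#' @param config A [sim_config()].
#' @return Maximum component flux (nonnegative; 0 when the perturbed model is
#'   infeasible — a dead model secretes nothing).
#' @export
simulate_component <- function(model, component, config = sim_config()) {
  component <- as.list(component)
  bid <- component$boundary_id
  if (is.null(bid) || !bid %in% model$reactions$id) {
    stop(sprintf("component %s has no boundary reaction in the model",
                 component$name %||% "?"), call. = FALSE)
  }
  # the combined objective reaction only serves model extraction; single
  # functions are simulated with it closed
  comb <- model$reactions$kind == "objective"
  model$reactions$lb[comb] <- 0
  model$reactions$ub[comb] <- 0
  bi <- rxn_index(model, bid)
  if (component$direction == "secretion") {
    model$reactions$ub[bi] <- config$vmax
    fs <- maximize_flux(model, bid)
    if (fs$status != "optimal") return(0)
    max(0, fs$objective_value)
  } else {
    ex <- which(model$reactions$kind == "exchange")
    up <- ex[model$reactions$lb[ex] < 0 & ex != bi]
    model$reactions$lb[up] <- pmax(model$reactions$lb[up], -config$sbfc)
    model$reactions$lb[bi] <- -config$vmax
    fs <- maximize_flux(model, bid, minimize = TRUE)
    if (fs$status != "optimal") return(0)
    max(0, -fs$objective_value)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

phenotype_ratio <- function(num, den, tol = 1e-9) {
  if (den <= tol) return(1)  # component already dead in the reference: no added disorder
  r <- num / den
  if (r > 1 && r <= 1 + 1e-6) r <- 1
  if (r < 0 && r >= -1e-6) r <- 0
  r
}

new_perturbation_matrix <- function(mat, components, context, denominators, config) {
  structure(mat, class = c("perturbation_matrix", "matrix"),
            components = components, context = context,
            denominators = denominators, config = config)
}

#' @export
print.perturbation_matrix <- function(x, ...) {
  cat(sprintf("<perturbation_matrix> %d perturbations x %d components, context: %s\n",
              nrow(x), ncol(x), attr(x, "context")))
  print(unclass(x)[seq_len(min(6, nrow(x))), , drop = FALSE])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Long-format view of a perturbation matrix
#'
#' @param x A `perturbation_matrix`.
#' @param ... Unused.
#' @return data.frame `perturbation`, `component`, `context`, `ratio`
#'   (heatmap-ready long format).
#' @export
as.data.frame.perturbation_matrix <- function(x, ...) {
  data.frame(perturbation = rep(rownames(x), times = ncol(x)),
             component = rep(colnames(x), each = nrow(x)),
             context = attr(x, "context"),
             ratio = as.vector(unclass(x)),
             stringsAsFactors = FALSE)
}

#' Write a perturbation matrix as long-format TSV
#' @param x A `perturbation_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scan single-gene deletions against all objective components
#'
#' For each gene, every reaction losing its GPR support is closed and each
#' component's maximum flux is recomputed; the cell value is the ratio to the
#' matched-context unperturbed optimum. With a `treatment`, the drug-target
#' inhibitions are applied to both the perturbed and the reference model
#' (drug-treated context).
#'
#' @param model A `metabolic_model`.
#' @param genes Genes to delete (default: all genes in the model's GPRs).
#' @param components Component table from [assemble_objective()].
#' @param config A [sim_config()].
#' @param treatment Optional [target_map()] applied as drug treatment.
#' @return A `perturbation_matrix` (genes x components).
#' @export
scan_gene_deletions <- function(model, genes = model_genes(model), components,
                                config = sim_config(), treatment = NULL) {
  context <- "untreated"
  if (!is.null(treatment)) {
    rxns <- unique(unlist(lapply(unique(treatment$target_id), target_reactions,
                                 model = model, target_map = treatment)))
    if (length(rxns) > 0) {
      model <- apply_inhibition(model, rxns, config$inhibition_fraction)
    }
    context <- "drug-treated"
  }
  comps <- components[components$compatible %in% c(TRUE, NA), , drop = FALSE]
  den <- vapply(seq_len(nrow(comps)), function(i)
    simulate_component(model, comps[i, ], config), 0)
  mat <- matrix(1, nrow = length(genes), ncol = nrow(comps),
                dimnames = list(genes, comps$name))
  for (g in seq_along(genes)) {
    dead <- knocked_out_reactions(model, genes[g])
    if (length(dead) == 0) next  # no reaction lost: row of exact 1s
    ko <- set_bounds(model, dead, lb = 0, ub = 0)
    for (i in seq_len(nrow(comps))) {
      num <- simulate_component(ko, comps[i, ], config)
      mat[g, i] <- phenotype_ratio(num, den[i])
    }
  }
  new_perturbation_matrix(mat, comps, context,
                          stats::setNames(den, comps$name), config)
}

#' Drug off-target map
#'
#' @param df data.frame with columns `target_id` and at least one of
#'   `gene_id`, `reaction_id` (either may be blank/NA per row): the genes and
#'   reactions inactivated when the drug binds the target.
#' @param model Model used to validate referenced ids.
#' @return Validated `target_map` data.frame.
#' @export
target_map <- function(df, model = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) df$gene_id <- NA_character_
  if (!"reaction_id" %in% names(df)) df$reaction_id <- NA_character_
  df$gene_id[df$gene_id == ""] <- NA_character_
  df$reaction_id[df$reaction_id == ""] <- NA_character_
  stopifnot("target_id" %in% names(df))
  if (!is.null(model)) {
    bad_r <- setdiff(stats::na.omit(df$reaction_id), model$reactions$id)
    bad_g <- setdiff(stats::na.omit(df$gene_id), model_genes(model))
    if (length(bad_r) + length(bad_g) > 0) {
      stop(sprintf("target map references unknown ids: %s",
                   paste(c(bad_r, bad_g), collapse = ", ")), call. = FALSE)
    }
  }
  structure(df, class = c("target_map", "data.frame"))
}

# reactions inactivated by one drug target: explicit reactions plus every
# reaction whose GPR fails when the target's genes are inhibited
target_reactions <- function(model, target_map, tid) {
  rows <- target_map[target_map$target_id == tid, , drop = FALSE]
  genes <- stats::na.omit(rows$gene_id)
  rxns <- stats::na.omit(rows$reaction_id)
  unique(c(rxns, if (length(genes) > 0) knocked_out_reactions(model, genes)))
}

#' Scan drug off-targets against all objective components
#'
#' One row per target, with the reactions it inactivates scaled to
#' `config$inhibition_fraction` of their bounds, plus one `ALL` row applying
#' every target simultaneously (the cumulative drug effect). Ratios are to the
#' untreated normal model.
#'
#' @param model A `metabolic_model`.
#' @param targets A [target_map()].
#' @param components Component table from [assemble_objective()].
#' @param config A [sim_config()].
#' @return A `perturbation_matrix` (targets + `"ALL"` x components).
#' @export
scan_drug_targets <- function(model, targets, components, config = sim_config()) {
  tids <- unique(targets$target_id)
  comps <- components[components$compatible %in% c(TRUE, NA), , drop = FALSE]
  den <- vapply(seq_len(nrow(comps)), function(i)
    simulate_component(model, comps[i, ], config), 0)
  rxn_sets <- lapply(tids, target_reactions, model = model, target_map = targets)
  rxn_sets <- c(rxn_sets, list(unique(unlist(rxn_sets))))
  rows <- c(tids, "ALL")
  mat <- matrix(1, nrow = length(rows), ncol = nrow(comps),
                dimnames = list(rows, comps$name))
  for (t in seq_along(rows)) {
    if (length(rxn_sets[[t]]) == 0) next
    inh <- apply_inhibition(model, rxn_sets[[t]], config$inhibition_fraction)
    for (i in seq_len(nrow(comps))) {
      num <- simulate_component(inh, comps[i, ], config)
      mat[t, i] <- phenotype_ratio(num, den[i])
    }
  }
  new_perturbation_matrix(mat, comps, "drug-vs-untreated",
                          stats::setNames(den, comps$name), config)
}

#' Cryptic genetic risk factors
#'
#' Gene-component pairs with no phenotype in the untreated gene-deficient
#' model (untreated ratio is 1) but a disorder under drug treatment (treated
#' ratio below 1): deficiencies expected to surface only in treated patients.
#'
#' @param untreated,treated Gene-deletion `perturbation_matrix` objects with
#'   identical rows and columns, from [scan_gene_deletions()] without and with
#'   a `treatment`.
#' @param tol Ratio tolerance absorbing LP noise.
#' @return data.frame `gene`, `component`, `untreated_ratio`, `treated_ratio`.
#' @export
find_cryptic_risk_factors <- function(untreated, treated, tol = 1e-6) {
  if (!identical(dimnames(untreated), dimnames(treated))) {
    stop("untreated and treated matrices have mismatched rows/columns", call. = FALSE)
  }
  hit <- which(unclass(untreated) >= 1 - tol & unclass(treated) < 1 - tol,
               arr.ind = TRUE)
  data.frame(gene = rownames(untreated)[hit[, 1]],
             component = colnames(untreated)[hit[, 2]],
             untreated_ratio = unclass(untreated)[hit],
             treated_ratio = unclass(treated)[hit],
             stringsAsFactors = FALSE)
}

#' Parameter sensitivity sweep
#'
#' Recomputes the drug-target phenotype ratios across a grid of one parameter
#' (`sbfc` or `inhibition_fraction`) and expresses each result as a normalized
#' sensitivity coefficient: `NSC = (r - r_base) / max(r_base, 1 - r_base)`,
#' the deviation from the base-case ratio divided by the maximum possible
#' deviation given that ratios live in `[0, 1]`. NSC is bounded in `[-1, 1]`
#' and is 0 at the base grid point.
#'
#' @param model A `metabolic_model` (context model at base bounds).
#' @param targets A [target_map()].
#' @param components Component table from [assemble_objective()].
#' @param parameter `"sbfc"` or `"inhibition_fraction"`.
#' @param grid Numeric grid of parameter values; must contain the base value.
#' @param config Base [sim_config()] (its `sbfc` / `inhibition_fraction` is
#'   the base case).
#' @param exchange_bounds Optional table from [derive_exchange_bounds()];
#'   required for `sbfc` sweeps so the standing efflux caps can be re-derived
#'   at each grid value.
#' @return data.frame `perturbation`, `component`, `parameter`, `value`,
#'   `ratio`, `nsc`.
#' @export
sensitivity_sweep <- function(model, targets, components,
                              parameter = c("sbfc", "inhibition_fraction"),
                              grid = NULL, config = sim_config(),
                              exchange_bounds = NULL) {
  parameter <- match.arg(parameter)
  if (is.null(grid)) {
    grid <- if (parameter == "sbfc") c(0, 13.5, 50, 100, 200, 400, 600, 800, 1000)
            else seq(0, 1, by = 0.1)
  }
  base_value <- config[[parameter]]
  if (!any(abs(grid - base_value) < 1e-12)) {
    stop(sprintf("base value %g of %s is not in the sweep grid", base_value,
                 parameter), call. = FALSE)
  }
  run_at <- function(value) {
    cfg <- config
    cfg[[parameter]] <- value
    m <- model
    if (parameter == "sbfc" && !is.null(exchange_bounds)) {
      eb <- exchange_bounds
      eb$ub[eb$ub > 0] <- value  # standing efflux caps track the sbfc
      m <- apply_exchange_bounds(m, eb)
    }
    scan_drug_targets(m, targets, components, cfg)
  }
  base_mat <- run_at(base_value)
  denom <- pmax(unclass(base_mat), 1 - unclass(base_mat))
  out <- list()
  for (v in grid) {
    mat <- if (abs(v - base_value) < 1e-12) base_mat else run_at(v)
    nsc <- (unclass(mat) - unclass(base_mat)) / denom
    d <- as.data.frame(mat)
    d$context <- NULL
    d$parameter <- parameter
    d$value <- v
    d$nsc <- as.vector(nsc)
    out[[length(out) + 1]] <- d
  }
  do.call(rbind, out)
}

#' Classify disorder phenotypes in a perturbation matrix
#'
#' @param mat A `perturbation_matrix`.
#' @param threshold Ratio threshold (default from the matrix config).
#' @param tol LP-noise tolerance.
#' @return data.frame of `perturbation`, `component`, `ratio` for cells called
#'   a disorder (`ratio < threshold - tol`).
#' @export
disorder_calls <- function(mat, threshold = attr(mat, "config")$disorder_threshold,
                           tol = 1e-6) {
  d <- as.data.frame(mat)
  d[d$ratio < threshold - tol, c("perturbation", "component", "ratio")]
}
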
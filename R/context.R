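#' Context-specific model construction
#'
#' Builds an organ-specific model from a base network: metabolomics-evidence
#' exchange constraints, assembly of a combined secretion/reabsorption
#' objective, expression-guided extraction (GIMME) and reduction to the
#' connected sub-model supporting the organ's functions.
#'
#' @name context_builder
NULL

#' Objective specification for an organ
#'
#' @param components data.frame with columns `metabolite_id` (species consumed
#'   by the combined objective: cytosolic for reabsorptions, the secreted
#'   species for secretions), `direction` (`"secretion"` or `"reabsorption"`),
#'   and optionally `name`, `weight` (default 1) and `exchange_metabolite_id`
#'   (the species whose boundary exchange carries the uptake for a
#'   reabsorption; defaults to `metabolite_id`).
#' @param include_atp_maintenance Include a basic ATP maintenance term
#'   (ATP + H2O -> ADP + Pi + H) in the combined objective.
#' @param atp_ids Named character vector locating the maintenance metabolites
#'   (`atp`, `h2o`, `adp`, `pi`, `h`).
#' @return An `objective_spec`.
#' @export
objective_spec <- function(components, include_atp_maintenance = TRUE,
                           atp_ids = c(atp = "atp_c", h2o = "h2o_c",
                                       adp = "adp_c", pi = "pi_c", h = "h_c")) {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  if (nrow(components) == 0) stop("objective spec has no components", call. = FALSE)
  stopifnot(all(c("metabolite_id", "direction") %in% names(components)),
            all(components$direction %in% c("secretion", "reabsorption")))
  if (!"name" %in% names(components)) components$name <- components$metabolite_id
  if (!"weight" %in% names(components)) components$weight <- 1
  if (!"exchange_metabolite_id" %in% names(components)) {
    components$exchange_metabolite_id <- components$metabolite_id
  }
  i <- is.na(components$exchange_metabolite_id)
  components$exchange_metabolite_id[i] <- components$metabolite_id[i]
  if (any(components$weight <= 0)) stop("component weights must be positive", call. = FALSE)
  structure(list(components = components,
                 include_atp_maintenance = include_atp_maintenance,
                 atp_ids = atp_ids),
            class = "objective_spec")
}

#' Evidence-based exchange bounds
#'
#' Applies the biofluid/tissue detection rules to every exchange reaction:
#' metabolites detected in both blood and organ tissue (or curated as freely
#' exchangeable) may be taken up and effluxed; metabolites detected in urine
#' and tissue only may be effluxed; everything else is closed. Secretion
#' objective metabolites never take up (the organ must synthesize what it
#' secretes), and all allowed effluxes are capped at the system boundary flux
#' constraint `sbfc`.
#'
#' @param model A `metabolic_model`.
#' @param evidence data.frame keyed by `metabolite_id` with logical columns
#'   `in_blood`, `in_urine`, `in_tissue` and optional curated flags
#'   `curated_free_exchange`, `curated_secretion_objective`,
#'   `curated_uptake_forbidden`.
#' @param sbfc System boundary flux constraint (flux units), the common efflux
#'   cap; default 13.5.
#' @return data.frame `reaction_id`, `metabolite_id`, `lb`, `ub`, `rule`
#'   covering all exchange reactions (the constraint provenance log).
#' @export
derive_exchange_bounds <- function(model, evidence, sbfc = 13.5) {
  stopifnot(sbfc >= 0, sbfc <= model$vmax)
  evidence <- as.data.frame(evidence, stringsAsFactors = FALSE)
  for (fl in c("curated_free_exchange", "curated_secretion_objective",
               "curated_uptake_forbidden")) {
    if (!fl %in% names(evidence)) evidence[[fl]] <- FALSE
  }
  ex <- which(model$reactions$kind == "exchange")
  ex_mets <- vapply(model$stoichiometry[ex], function(st) names(st), "")
  unknown <- setdiff(evidence$metabolite_id, ex_mets)
  if (length(unknown) > 0) {
    warning(sprintf("evidence for metabolite(s) without exchange reaction skipped: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  n <- length(ex)
  out <- data.frame(reaction_id = model$reactions$id[ex], metabolite_id = ex_mets,
                    lb = numeric(n), ub = numeric(n), rule = character(n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    row <- evidence[match(ex_mets[k], evidence$metabolite_id), ]
    if (nrow(row) == 0 || is.na(row$metabolite_id)) {
      out$lb[k] <- 0; out$ub[k] <- 0; out$rule[k] <- "no_evidence"
      next
    }
    free <- isTRUE(row$in_blood && row$in_tissue) || isTRUE(row$curated_free_exchange)
    excrete <- isTRUE(row$in_urine && row$in_tissue)
    if (free) {
      lb <- -model$vmax; ub <- sbfc; rule <- "free_exchange"
    } else if (excrete) {
      lb <- 0; ub <- sbfc; rule <- "excretion_only"
    } else {
      lb <- 0; ub <- 0; rule <- "no_evidence"
    }
    if (isTRUE(row$curated_secretion_objective) && lb < 0) {
      lb <- 0; rule <- paste0(rule, "+secretion_no_uptake")
    }
    if (isTRUE(row$curated_uptake_forbidden) && lb < 0) {
      lb <- 0; rule <- paste0(rule, "+uptake_forbidden")
    }
    if (isTRUE(row$curated_secretion_objective) && rule == "no_evidence") {
      # secretion objectives must at least be excretable
      ub <- sbfc; rule <- "secretion_objective"
    }
    out$lb[k] <- lb; out$ub[k] <- ub; out$rule[k] <- rule
  }
  out
}

#' Apply a derived exchange-bounds table to a model
#'
#' @param model A `metabolic_model`.
#' @param bounds Output of [derive_exchange_bounds()].
#' @return Constrained copy of the model.
#' @export
apply_exchange_bounds <- function(model, bounds) {
  i <- rxn_index(model, bounds$reaction_id)
  model$reactions$lb[i] <- bounds$lb
  model$reactions$ub[i] <- bounds$ub
  model
}

component_boundary_id <- function(comp) {
  if (comp$direction == "secretion") paste0("EX_", comp$metabolite_id)
  else paste0("EX_", comp$exchange_metabolite_id)
}

#' Assemble the combined organ objective
#'
#' Adds per-component boundary reactions (a cytosolic demand for each
#' reabsorption target, an efflux exchange for each secretion target) so that
#' single functions can be optimized one at a time, plus one combined
#' objective reaction consuming every compatible component with unit (or
#' specified) weights and, optionally, an ATP maintenance term. Components
#' that cannot carry positive flux even with all exchanges opened are
#' reported incompatible and excluded from the combined reaction.
#'
#' @param model A `metabolic_model`.
#' @param spec An [objective_spec()].
#' @param objective_id Id for the combined reaction.
#' @return List: `model` (augmented), `objective_reaction`, `components`
#'   (with `boundary_id`, `demand_id`, `compatible`), `incompatible` (names).
#' @export
assemble_objective <- function(model, spec, objective_id = "R_organ_objective") {
  stopifnot(inherits(spec, "objective_spec"))
  comps <- spec$components
  comps$boundary_id <- NA_character_
  comps$demand_id <- NA_character_
  for (i in seq_len(nrow(comps))) {
    met <- comps$metabolite_id[i]
    if (!met %in% model$metabolites$id) {
      stop(sprintf("objective component metabolite %s not in model", met), call. = FALSE)
    }
    if (comps$direction[i] == "reabsorption") {
      dm <- paste0("DM_", met)
      if (!dm %in% model$reactions$id) {
        model <- add_boundary_reaction(model, met, "demand", 0, model$vmax)
      }
      comps$demand_id[i] <- dm
      exm <- comps$exchange_metabolite_id[i]
      exid <- paste0("EX_", exm)
      if (!exid %in% model$reactions$id) {
        if (!exm %in% model$metabolites$id) {
          stop(sprintf("exchange metabolite %s for component %s not in model",
                       exm, comps$name[i]), call. = FALSE)
        }
        model <- add_boundary_reaction(model, exm, "exchange", -model$vmax, model$vmax)
      }
      comps$boundary_id[i] <- exid
    } else {
      exid <- paste0("EX_", met)
      if (!exid %in% model$reactions$id) {
        model <- add_boundary_reaction(model, met, "exchange", 0, model$vmax)
      }
      # secretion: the organ synthesizes what it secretes, never takes it up
      j <- rxn_index(model, exid)
      model$reactions$lb[j] <- max(model$reactions$lb[j], 0)
      comps$boundary_id[i] <- exid
    }
  }
  # compatibility: positive flux in the optimized direction with all exchanges open
  open <- model
  ex <- open$reactions$kind == "exchange"
  open$reactions$lb[ex] <- -open$vmax
  open$reactions$ub[ex] <- open$vmax
  sec <- comps$direction == "secretion"
  open$reactions$lb[rxn_index(open, comps$boundary_id[sec])] <- 0
  comps$compatible <- vapply(seq_len(nrow(comps)), function(i) {
    fs <- maximize_flux(open, comps$boundary_id[i],
                        minimize = comps$direction[i] == "reabsorption")
    fs$status == "optimal" && abs(fs$objective_value) > 1e-6
  }, TRUE)
  st <- stats::setNames(-comps$weight[comps$compatible],
                        comps$metabolite_id[comps$compatible])
  st <- tapply(st, names(st), sum)  # merge duplicated metabolites
  st <- stats::setNames(as.numeric(st), names(st))
  if (isTRUE(spec$include_atp_maintenance) &&
      all(spec$atp_ids %in% model$metabolites$id)) {
    atp <- stats::setNames(c(-1, -1, 1, 1, 1),
                           spec$atp_ids[c("atp", "h2o", "adp", "pi", "h")])
    for (m in names(atp)) st[m] <- if (m %in% names(st)) st[m] + atp[m] else atp[m]
  }
  if (length(st) == 0) stop("no compatible objective components", call. = FALSE)
  model$reactions <- rbind(model$reactions, data.frame(
    id = objective_id, lb = 0, ub = model$vmax, reversible = FALSE,
    subsystem = "objective", kind = "objective", gpr = "",
    stringsAsFactors = FALSE))
  model$stoichiometry[[objective_id]] <- st
  model$gprs[[objective_id]] <- gpr_empty()
  validate_model(model)
  list(model = model, objective_reaction = objective_id, components = comps,
       incompatible = comps$name[!comps$compatible])
}

#' Expression-guided model extraction (GIMME)
#'
#' Finds the flux state that attains at least `required_fraction` of the
#' maximum objective flux while minimizing use of reactions whose expression
#' score falls below the significance threshold: minimize
#' `sum_i max(0, threshold - score_i) * |v_i|` subject to `S v = 0`, bounds,
#' and the objective attainment constraint. Reactions without expression data
#' carry zero weight (active without penalty). Below-threshold reactions are
#' classified by probing alternative optima: a reaction that cannot carry
#' flux in any solution whose inconsistency is within `1e-6` of the minimum
#' is inactive.
#'
#' @param model A `metabolic_model` (bounds already context-constrained).
#' @param scores Named reaction score vector from [reaction_scores()].
#' @param threshold Significance threshold from [significance_threshold()].
#' @param required_fraction Minimum fraction of the maximum objective flux.
#' @param objective_reaction Id of the combined objective reaction.
#' @return A `gimme_result`: `activity` (named: `"active"`, `"inactive"`,
#'   `"unpenalized-active"`), `inconsistency_score`, `required_fraction`,
#'   `objective_max`, `weights`, `fluxes`.
#' @export
run_gimme <- function(model, scores, threshold, required_fraction = 0.90,
                      objective_reaction, flux_tol = 1e-6) {
  stopifnot(required_fraction > 0, required_fraction <= 1)
  oi <- rxn_index(model, objective_reaction, "objective reaction")
  base <- maximize_flux(model, objective_reaction)
  if (base$status != "optimal" || base$objective_value <= 1e-9) {
    stop("GIMME: objective is infeasible or has non-positive optimum", call. = FALSE)
  }
  vmax_obj <- base$objective_value
  model$reactions$lb[oi] <- max(model$reactions$lb[oi],
                                required_fraction * vmax_obj)
  lb <- model$reactions$lb; ub <- model$reactions$ub
  w <- pmax(0, threshold - scores[model$reactions$id])
  w[is.na(w)] <- 0
  n <- nrow(model$reactions)
  S <- as.matrix(stoich_matrix(model))
  # split v = v_plus - v_minus so |v| is linear
  A <- cbind(S, -S)
  lbs <- c(pmax(0, lb), pmax(0, -ub))
  ubs <- c(pmax(0, ub), pmax(0, -lb))
  cost <- c(w, w)
  sol <- solve_lp(cost, A, rep(0, nrow(A)), lbs, ubs)
  if (sol$status != "optimal") {
    stop("GIMME: objective attainment constraint is infeasible", call. = FALSE)
  }
  inc_min <- sol$objective
  fluxes <- stats::setNames(sol$x[seq_len(n)] - sol$x[n + seq_len(n)],
                            model$reactions$id)

  activity <- ifelse(w > 0, "active", "unpenalized-active")
  names(activity) <- model$reactions$id
  pen <- which(w > 0)
  if (length(pen) > 0) {
    # penalty-budget row: cost'v + slack = inc_min + flux_tol
    budget <- inc_min + flux_tol
    A2 <- rbind(cbind(A, 0), c(cost, 1))
    lb2 <- c(lbs, 0); ub2 <- c(ubs, budget)
    b2 <- c(rep(0, nrow(A)), budget)
    warm <- NULL
    for (i in pen) {
      cc <- numeric(ncol(A2))
      cc[i] <- 1; cc[n + i] <- 1
      pr <- solve_lp(cc, A2, b2, lb2, ub2, maximize = TRUE, warm = warm)
      if (pr$status == "optimal") {
        warm <- pr$warm
        if (pr$objective <= flux_tol) activity[i] <- "inactive"
      } else {
        activity[i] <- "inactive"
      }
    }
  }
  structure(list(activity = activity, inconsistency_score = inc_min,
                 required_fraction = required_fraction,
                 objective_max = vmax_obj,
                 objective_value = fluxes[objective_reaction],
                 weights = stats::setNames(w, model$reactions$id),
                 fluxes = fluxes),
            class = "gimme_result")
}

#' @export
print.gimme_result <- function(x, ...) {
  tab <- table(x$activity)
  cat(sprintf("<gimme_result> inconsistency %.4f, objective %.4f (>= %.0f%% of max %.4f)\n",
              x$inconsistency_score, x$objective_value,
              100 * x$required_fraction, x$objective_max))
  print(tab)
  invisible(x)
}

#' Constrain a model with GIMME activity calls
#'
#' Sets inactive reactions to zero flux, yielding the full context model.
#'
#' @param model A `metabolic_model`.
#' @param gimme A `gimme_result`.
#' @return Constrained copy of the model.
#' @export
apply_gimme <- function(model, gimme) {
  dead <- names(gimme$activity)[gimme$activity == "inactive"]
  dead <- intersect(dead, model$reactions$id)
  if (length(dead) > 0) model <- set_bounds(model, dead, lb = 0, ub = 0)
  model
}

#' Reduce a context model to its functional sub-model
#'
#' For each objective component, anchors an epsilon flux through its boundary
#' reaction (in the secretion or uptake direction) and computes flux
#' variability; the reduced model is the union of reactions that can carry
#' flux in support of at least one component, together with their
#' metabolites. Because every flux-capable supporting reaction is retained,
#' each component's optimum is identical in the full and reduced models.
#'
#' @param model The full context model (after [apply_gimme()]).
#' @param components Component table from [assemble_objective()] (rows with
#'   `compatible == FALSE` are skipped).
#' @param eps Anchor flux magnitude.
#' @return List: `model` (reduced), `kept` (reaction ids), `skipped`
#'   (infeasible component names), `component_optima` (data.frame comparing
#'   full vs reduced optima).
#' @export
reduce_model <- function(model, components, eps = 1e-6) {
  comps <- components[components$compatible %in% c(TRUE, NA), , drop = FALSE]
  keep <- rep(FALSE, nrow(model$reactions))
  names(keep) <- model$reactions$id
  skipped <- character()
  full_opt <- numeric(nrow(comps))
  for (i in seq_len(nrow(comps))) {
    bid <- comps$boundary_id[i]
    minimize <- comps$direction[i] == "reabsorption"
    fs <- maximize_flux(model, bid, minimize = minimize)
    full_opt[i] <- if (fs$status == "optimal") fs$objective_value else 0
    if (fs$status != "optimal" || abs(full_opt[i]) < eps) {
      skipped <- c(skipped, comps$name[i])
      next
    }
    anch <- list(reaction_id = bid, flux = if (minimize) -eps else eps)
    fva <- flux_variability(model, anchor = anch)
    keep <- keep | (fva$max > 1e-9 | fva$min < -1e-9)
  }
  kept <- model$reactions$id[keep]
  red <- subset_model(model, kept)
  comp_islands <- model_islands(red)
  if (comp_islands > 1) {
    warning(sprintf("reduced model has %d connected components (expected 1); all retained",
                    comp_islands), call. = FALSE)
  }
  red_opt <- vapply(seq_len(nrow(comps)), function(i) {
    if (comps$name[i] %in% skipped) return(0)
    fs <- maximize_flux(red, comps$boundary_id[i],
                        minimize = comps$direction[i] == "reabsorption")
    if (fs$status == "optimal") fs$objective_value else 0
  }, 0)
  list(model = red, kept = kept, skipped = skipped,
       component_optima = data.frame(component = comps$name,
                                     full = full_opt, reduced = red_opt))
}

#' Subset a model to a set of reactions
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions to retain; metabolites not referenced by any
#'   retained reaction are dropped.
#' @return A `metabolic_model`.
#' @export
subset_model <- function(model, reaction_ids) {
  i <- rxn_index(model, reaction_ids)
  i <- sort(i)
  rxns <- model$reactions[i, , drop = FALSE]
  st <- model$stoichiometry[i]
  used <- unique(unlist(lapply(st, names)))
  mets <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
  metabolic_model(mets, rxns, st, compartments = model$compartments,
                  vmax = model$vmax, id = paste0(model$id, "_reduced"))
}

# number of connected components of the reaction-metabolite bipartite graph
model_islands <- function(model) {
  n <- nrow(model$reactions)
  if (n == 0) return(0L)
  met_rxns <- list()
  for (j in seq_len(n)) {
    for (m in names(model$stoichiometry[[j]])) {
      met_rxns[[m]] <- c(met_rxns[[m]], j)
    }
  }
  seen <- rep(FALSE, n)
  islands <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    islands <- islands + 1L
    queue <- s; seen[s] <- TRUE
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      nbr <- unique(unlist(met_rxns[names(model$stoichiometry[[j]])]))
      new <- nbr[!seen[nbr]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  islands
}

#' GIMME report table
#'
#' @param gimme A `gimme_result`.
#' @param scores Reaction score vector used for the run.
#' @param path Optional TSV output path.
#' @return data.frame `reaction`, `score`, `weight`, `class` (written to
#'   `path` when given).
#' @export
gimme_report <- function(gimme, scores, path = NULL) {
  out <- data.frame(reaction = names(gimme$activity),
                    score = unname(scores[names(gimme$activity)]),
                    weight = unname(gimme$weights),
                    class = unname(gimme$activity),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
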
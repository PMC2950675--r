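#' Flux balance analysis
#'
#' FBA computes the flux distribution `v` maximizing a chosen reaction flux
#' subject to steady-state mass balance `S v = 0` and flux bounds
#' `lb <= v <= ub`. Only the optimal objective value is contractually
#' deterministic; flux vectors of degenerate optima are solver-dependent.
#'
#' @name fba
NULL

# dense LP view of a model, reused across repeated solves
model_lp <- function(model) {
  list(S = as.matrix(stoich_matrix(model)),
       lb = model$reactions$lb,
       ub = model$reactions$ub,
       rxn_ids = model$reactions$id)
}

lp_objective <- function(lp, reaction_id) {
  cc <- numeric(length(lp$rxn_ids))
  cc[match(reaction_id, lp$rxn_ids)] <- 1
  cc
}

#' Maximize the flux through one reaction
#'
#' @param model A `metabolic_model`.
#' @param objective_reaction_id Reaction whose flux is maximized.
#' @param minimize Optimize in the negative direction instead (used for
#'   uptake objectives, where reabsorption flux is negative exchange flux).
#' @return A `flux_state`: list with `status` (`"optimal"` or `"infeasible"`),
#'   `objective_value` (`NA` when infeasible) and `fluxes` (named vector).
#' @export
maximize_flux <- function(model, objective_reaction_id, minimize = FALSE) {
  rxn_index(model, objective_reaction_id, "objective reaction")
  lp <- model_lp(model)
  fba_solve(lp, objective_reaction_id, minimize = minimize)
}

fba_solve <- function(lp, objective_reaction_id, minimize = FALSE, warm = NULL) {
  cc <- lp_objective(lp, objective_reaction_id)
  out <- solve_lp(cc, lp$S, rep(0, nrow(lp$S)), lp$lb, lp$ub,
                  maximize = !minimize, warm = warm)
  if (out$status != "optimal") {
    return(structure(list(status = "infeasible", objective_value = NA_real_,
                          fluxes = NULL, warm = NULL), class = "flux_state"))
  }
  structure(list(status = "optimal",
                 objective_value = out$objective,
                 fluxes = stats::setNames(out$x, lp$rxn_ids),
                 warm = out$warm),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("<flux_state> status: %s, objective: %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Flux variability under an anchored objective
#'
#' For each listed reaction, computes the attainable flux range subject to the
#' model constraints plus an anchor constraint on one reaction: the anchor
#' flux is required to be at least `flux` (when `flux >= 0`) or at most `flux`
#' (when `flux < 0`, i.e. a required uptake).
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions to range; defaults to all reactions.
#' @param anchor List or vector with elements `reaction_id` and `flux`.
#' @return data.frame with columns `reaction_id`, `min`, `max`.
#' @export
flux_variability <- function(model, reaction_ids = model$reactions$id,
                             anchor = NULL) {
  idx <- rxn_index(model, reaction_ids)
  if (!is.null(anchor)) {
    aid <- as.character(anchor[["reaction_id"]])
    aflux <- as.numeric(anchor[["flux"]])
    ai <- rxn_index(model, aid, "anchor reaction")
    if (aflux >= 0) {
      if (aflux > model$reactions$ub[ai] + 1e-9) {
        stop(sprintf("anchor %s >= %g is infeasible: upper bound %g",
                     aid, aflux, model$reactions$ub[ai]), call. = FALSE)
      }
      model$reactions$lb[ai] <- max(model$reactions$lb[ai], aflux)
    } else {
      if (aflux < model$reactions$lb[ai] - 1e-9) {
        stop(sprintf("anchor %s <= %g is infeasible: lower bound %g",
                     aid, aflux, model$reactions$lb[ai]), call. = FALSE)
      }
      model$reactions$ub[ai] <- min(model$reactions$ub[ai], aflux)
    }
  }
  lp <- model_lp(model)
  feas <- fba_solve(lp, lp$rxn_ids[1])
  if (feas$status != "optimal") {
    stop(if (is.null(anchor)) "flux_variability: model infeasible" else
      sprintf("flux_variability: model infeasible under anchor on %s",
              anchor[["reaction_id"]]), call. = FALSE)
  }
  warm <- feas$warm
  vmin <- vmax <- numeric(length(idx))
  for (k in seq_along(idx)) {
    rid <- lp$rxn_ids[idx[k]]
    if (lp$lb[idx[k]] == 0 && lp$ub[idx[k]] == 0) {
      vmin[k] <- 0; vmax[k] <- 0
      next
    }
    hi <- fba_solve(lp, rid, warm = warm)
    if (!is.null(hi$warm)) warm <- hi$warm
    lo <- fba_solve(lp, rid, minimize = TRUE, warm = warm)
    if (!is.null(lo$warm)) warm <- lo$warm
    vmax[k] <- hi$objective_value
    vmin[k] <- lo$objective_value
  }
  data.frame(reaction_id = lp$rxn_ids[idx], min = vmin, max = vmax,
             stringsAsFactors = FALSE)
}

#' Constrain a model by single- or multi-gene knockout
#'
#' Every reaction whose GPR rule evaluates false under the deletion set has
#' its bounds set to `[0, 0]`; reactions with isozyme backup or no gene
#' association are untouched. Unknown genes are no-ops.
#'
#' @param model A `metabolic_model`.
#' @param genes Character vector of deleted gene ids.
#' @return Constrained copy of the model.
#' @export
apply_gene_knockout <- function(model, genes) {
  if (length(genes) == 0) return(model)
  dead <- knocked_out_reactions(model, genes)
  if (length(dead) > 0) model <- set_bounds(model, dead, lb = 0, ub = 0)
  model
}

knocked_out_reactions <- function(model, genes) {
  affected <- vapply(model$gprs, function(g) any(gpr_genes(g) %in% genes), TRUE)
  cand <- which(affected)
  dead <- cand[!vapply(model$gprs[cand], evaluate_gpr_knockout, TRUE,
                       deleted_genes = genes)]
  model$reactions$id[dead]
}

#' Constrain a model by partial enzymatic inhibition
#'
#' Scales the bounds of the listed reactions by the remaining activity
#' fraction `f` in `[0, 1]`; `f = 0` is complete inhibition (the default
#' drug-treatment assumption), `f = 1` leaves the model unchanged.
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions catalyzed by the inhibited target(s).
#' @param remaining_fraction Fraction of maximal enzymatic flux retained.
#' @return Constrained copy of the model.
#' @export
apply_inhibition <- function(model, reaction_ids, remaining_fraction) {
  stopifnot(length(remaining_fraction) == 1,
            remaining_fraction >= 0, remaining_fraction <= 1)
  i <- rxn_index(model, reaction_ids)
  model$reactions$lb[i] <- model$reactions$lb[i] * remaining_fraction
  model$reactions$ub[i] <- model$reactions$ub[i] * remaining_fraction
  model
}
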
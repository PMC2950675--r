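#' Compartmentalized stoichiometric metabolic models
#'
#' A `metabolic_model` holds metabolites (with compartments), reactions
#' (stoichiometry, flux bounds, subsystem, kind, GPR tree) and the declared
#' compartment set. Fluxes are dimensionless "flux units" whose magnitude is
#' capped at `Vmax` (default 1000). Exchange and demand reactions touch exactly
#' one metabolite; by convention positive exchange flux is efflux (out of the
#' system) and negative flux is uptake.
#'
#' @name metabolic_model
NULL

#' Default flux bound magnitude (flux units)
#' @export
VMAX_DEFAULT <- 1000

REACTION_KINDS <- c("enzymatic", "transport", "exchange", "demand", "objective")

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `subsystem`,
#'   `kind` and optionally `gpr` (rule strings, parsed on construction).
#' @param stoichiometry list parallel to `reactions`: each element a named
#'   numeric vector of signed coefficients keyed by metabolite id.
#' @param compartments character vector of declared compartments (defaults to
#'   those used by the metabolites).
#' @param vmax flux bound cap; all |bounds| must be `<= vmax`.
#' @param id model identifier.
#' @return A `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            compartments = unique(metabolites$compartment),
                            vmax = VMAX_DEFAULT, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"kind" %in% names(reactions)) reactions$kind <- "enzymatic"
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  gprs <- lapply(reactions$gpr, parse_gpr)
  reactions$gpr <- vapply(gprs, deparse_gpr, "")  # canonical rule text
  reactions$reversible <- reactions$lb < 0
  model <- structure(
    list(id = id,
         metabolites = metabolites,
         reactions = reactions[, c("id", "lb", "ub", "reversible",
                                   "subsystem", "kind", "gpr")],
         stoichiometry = stats::setNames(stoichiometry, reactions$id),
         gprs = stats::setNames(gprs, reactions$id),
         compartments = compartments,
         vmax = vmax),
    class = "metabolic_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids", call. = FALSE)
  if (!all(mets$compartment %in% model$compartments)) {
    stop("metabolite compartment not in declared compartment set", call. = FALSE)
  }
  if (any(rxns$lb > rxns$ub)) stop("reaction with lb > ub", call. = FALSE)
  if (any(abs(c(rxns$lb, rxns$ub)) > model$vmax + 1e-9)) {
    stop(sprintf("flux bound magnitude exceeds Vmax = %g", model$vmax), call. = FALSE)
  }
  if (!all(rxns$kind %in% REACTION_KINDS)) stop("unknown reaction kind", call. = FALSE)
  for (i in seq_len(nrow(rxns))) {
    st <- model$stoichiometry[[i]]
    missing <- setdiff(names(st), mets$id)
    if (length(missing) > 0) {
      stop(sprintf("reaction %s references undeclared metabolite(s): %s",
                   rxns$id[i], paste(missing, collapse = ", ")), call. = FALSE)
    }
    if (rxns$kind[i] %in% c("exchange", "demand") && length(st) != 1) {
      stop(sprintf("boundary reaction %s must touch exactly one metabolite",
                   rxns$id[i]), call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s'> %d metabolites, %d reactions, %d genes, compartments: %s\n",
              x$id, nrow(x$metabolites), nrow(x$reactions),
              length(model_genes(x)), paste(x$compartments, collapse = ", ")))
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return Sparse matrix S (metabolites x reactions) with `dimnames`.
#' @export
stoich_matrix <- function(model) {
  met_idx <- stats::setNames(seq_len(nrow(model$metabolites)), model$metabolites$id)
  ii <- integer(); jj <- integer(); xx <- numeric()
  for (j in seq_along(model$stoichiometry)) {
    st <- model$stoichiometry[[j]]
    if (length(st) == 0) next
    ii <- c(ii, met_idx[names(st)])
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(model$metabolites), nrow(model$reactions)),
                       dimnames = list(model$metabolites$id, model$reactions$id))
}

#' All genes referenced by a model's GPR rules
#' @param model A `metabolic_model`.
#' @return Character vector of gene ids.
#' @export
model_genes <- function(model) {
  unique(unlist(lapply(model$gprs, gpr_genes)))
}

rxn_index <- function(model, reaction_id, what = "reaction") {
  i <- match(reaction_id, model$reactions$id)
  if (anyNA(i)) {
    stop(sprintf("unknown %s id(s): %s", what,
                 paste(reaction_id[is.na(i)], collapse = ", ")), call. = FALSE)
  }
  i
}

#' Add an exchange or demand reaction for a metabolite
#'
#' Boundary reactions get deterministic ids (`EX_<met>` for exchanges,
#' `DM_<met>` for demands) and consume one unit of the metabolite, so positive
#' flux removes it from the system.
#'
#' @param model A `metabolic_model`.
#' @param metabolite_id Metabolite to connect to the boundary.
#' @param kind `"exchange"` or `"demand"`.
#' @param lower,upper Flux bounds.
#' @return The model with one added reaction.
#' @export
add_boundary_reaction <- function(model, metabolite_id, kind = c("exchange", "demand"),
                                  lower = 0, upper = model$vmax) {
  kind <- match.arg(kind)
  if (!metabolite_id %in% model$metabolites$id) {
    stop(sprintf("unknown metabolite id: %s", metabolite_id), call. = FALSE)
  }
  rid <- paste0(if (kind == "exchange") "EX_" else "DM_", metabolite_id)
  if (rid %in% model$reactions$id) {
    stop(sprintf("boundary reaction %s already exists", rid), call. = FALSE)
  }
  model$reactions <- rbind(model$reactions, data.frame(
    id = rid, lb = lower, ub = upper, reversible = lower < 0,
    subsystem = "boundary", kind = kind, gpr = "", stringsAsFactors = FALSE))
  model$stoichiometry[[rid]] <- stats::setNames(-1, metabolite_id)
  model$gprs[[rid]] <- gpr_empty()
  validate_model(model)
  model
}

#' Set flux bounds on named reactions
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reactions to modify.
#' @param lb,ub Replacement bounds, recycled to length.
#' @return Modified copy of the model.
#' @export
set_bounds <- function(model, reaction_ids, lb = NULL, ub = NULL) {
  i <- rxn_index(model, reaction_ids)
  if (!is.null(lb)) model$reactions$lb[i] <- rep_len(lb, length(i))
  if (!is.null(ub)) model$reactions$ub[i] <- rep_len(ub, length(i))
  if (any(model$reactions$lb[i] > model$reactions$ub[i])) {
    stop("set_bounds would leave lb > ub", call. = FALSE)
  }
  model
}

#' Write a one-reaction-per-row TSV dump of a model
#'
#' Columns: id, formula (human-readable equation), lb, ub, gpr, subsystem, kind.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  formula <- vapply(seq_len(nrow(model$reactions)), function(i) {
    st <- model$stoichiometry[[i]]
    lhs <- st[st < 0]; rhs <- st[st > 0]
    term <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                     paste(abs(v), names(v))), collapse = " + ")
    arrow <- if (model$reactions$lb[i] < 0) " <=> " else " --> "
    paste0(term(lhs), arrow, term(rhs))
  }, "")
  out <- data.frame(id = model$reactions$id, formula = formula,
                    lb = model$reactions$lb, ub = model$reactions$ub,
                    gpr = model$reactions$gpr,
                    subsystem = model$reactions$subsystem,
                    kind = model$reactions$kind)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
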
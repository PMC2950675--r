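# Independent oracles and fixture builders used across the suite.

# --- GPR oracles ------------------------------------------------------------

# knockout oracle: translate the rule text to an R logical expression and
# evaluate it with deleted genes bound to FALSE (a path fully independent of
# the package's tree representation)
oracle_gpr_knockout <- function(text, deleted) {
  if (!nzchar(trimws(text))) return(TRUE)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  expr <- vapply(toks, function(tk) {
    if (tk == "(") "(" else if (tk == ")") ")"
    else if (tolower(tk) == "and") "&&"
    else if (tolower(tk) == "or") "||"
    else if (tk %in% deleted) "FALSE" else "TRUE"
  }, "")
  eval(parse(text = paste(expr, collapse = " ")))
}

# expression oracle: plain recursive min/max over a freshly parsed tree,
# written without reference to the package internals
oracle_gpr_expression <- function(tree, values) {
  if (tree$kind == "empty") return(NA_real_)
  if (tree$kind == "gene") {
    if (tree$gene %in% names(values)) return(values[[tree$gene]])
    return(NA_real_)
  }
  vs <- unlist(lapply(tree$children, oracle_gpr_expression, values = values))
  vs <- vs[!is.na(vs)]
  if (length(vs) == 0) return(NA_real_)
  if (tree$kind == "and") min(vs) else max(vs)
}

# random GPR rule text with known gene pool
random_gpr_text <- function(genes, depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.4) return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- vapply(seq_len(k), function(i) random_gpr_text(genes, depth - 1), "")
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}

# --- LP oracle --------------------------------------------------------------

# brute-force vertex enumeration for max c'v s.t. S v = b, lb <= v <= ub;
# returns NA when infeasible
oracle_lp_max <- function(S, b, lb, ub, cc) {
  n <- ncol(S); r <- qr(S)$rank
  nb <- n - r
  best <- -Inf; feas <- FALSE
  if (nb == 0) {
    v <- tryCatch(qr.solve(S, b), error = function(e) NULL)
    if (!is.null(v) && all(v >= lb - 1e-7) && all(v <= ub + 1e-7) &&
        max(abs(S %*% v - b)) < 1e-7) return(sum(cc * v))
    return(NA_real_)
  }
  combs <- utils::combn(n, nb)
  for (j in seq_len(ncol(combs))) {
    N <- combs[, j]; B <- setdiff(seq_len(n), N)
    SB <- S[, B, drop = FALSE]
    if (qr(SB)$rank < r) next
    grid <- expand.grid(rep(list(1:2), nb))
    for (g in seq_len(nrow(grid))) {
      vN <- ifelse(unlist(grid[g, ]) == 1, lb[N], ub[N])
      vB <- tryCatch(qr.solve(SB, b - S[, N, drop = FALSE] %*% vN),
                     error = function(e) NULL)
      if (is.null(vB)) next
      v <- numeric(n); v[N] <- vN; v[B] <- vB
      if (all(v >= lb - 1e-7) && all(v <= ub + 1e-7) &&
          max(abs(S %*% v - b)) < 1e-7) {
        feas <- TRUE
        best <- max(best, sum(cc * v))
      }
    }
  }
  if (!feas) NA_real_ else best
}

# random small single-compartment flux model (<= 8 reactions) for LP fuzzing
random_toy_model <- function(seed) {
  set.seed(seed)
  m <- sample(2:4, 1); n <- sample(4:8, 1)
  repeat {
    S <- matrix(sample(-2:2, m * n, replace = TRUE,
                       prob = c(.1, .25, .3, .25, .1)), m, n)
    if (all(colSums(abs(S)) > 0)) break
  }
  lb <- ifelse(stats::runif(n) < 0.3, -round(stats::runif(n, 0, 100), 1), 0)
  ub <- lb + round(stats::runif(n, 0, 200), 1)
  mets <- data.frame(id = sprintf("m%d", seq_len(m)), name = sprintf("m%d", seq_len(m)),
                     compartment = "cytosol", stringsAsFactors = FALSE)
  rxns <- data.frame(id = sprintf("r%d", seq_len(n)), lb = lb, ub = ub,
                     stringsAsFactors = FALSE)
  sto <- lapply(seq_len(n), function(j) {
    nz <- which(S[, j] != 0)
    stats::setNames(S[nz, j], mets$id[nz])
  })
  metabolic_model(mets, rxns, sto, compartments = "cytosol")
}

# --- hand-built fixture models ---------------------------------------------

# linear chain: EX_a (uptake, capacity ex_ub) -> T -> R1 -> DM_b
chain_model <- function(ex_ub = 10, r1_ub = 1000) {
  mets <- data.frame(id = c("a_b", "a_c", "b_c"),
                     name = c("a_b", "a_c", "b_c"),
                     compartment = c("blood", "cytosol", "cytosol"))
  rxns <- data.frame(id = c("EX_a_b", "T_a", "R1", "DM_b_c"),
                     lb = c(-ex_ub, 0, 0, 0), ub = c(0, 1000, r1_ub, 1000),
                     kind = c("exchange", "transport", "enzymatic", "demand"),
                     gpr = c("", "gT", "g1", ""))
  sto <- list(c(a_b = -1), c(a_b = -1, a_c = 1), c(a_c = -1, b_c = 1),
              c(b_c = -1))
  metabolic_model(mets, rxns, sto, compartments = c("blood", "cytosol"))
}

# two parallel routes of given capacities feeding one demand
parallel_model <- function(cap1 = 10, cap2 = 10, ex_ub = 30,
                           gpr1 = "g1", gpr2 = "g2") {
  mets <- data.frame(id = c("a_b", "a_c", "b_c"),
                     name = c("a_b", "a_c", "b_c"),
                     compartment = c("blood", "cytosol", "cytosol"))
  rxns <- data.frame(id = c("EX_a_b", "T_a", "P1", "P2", "DM_b_c"),
                     lb = c(-ex_ub, 0, 0, 0, 0),
                     ub = c(0, 1000, cap1, cap2, 1000),
                     kind = c("exchange", "transport", "enzymatic",
                              "enzymatic", "demand"),
                     gpr = c("", "", gpr1, gpr2, ""))
  sto <- list(c(a_b = -1), c(a_b = -1, a_c = 1), c(a_c = -1, b_c = 1),
              c(a_c = -1, b_c = 1), c(b_c = -1))
  metabolic_model(mets, rxns, sto, compartments = c("blood", "cytosol"))
}

# --- AROC rank oracle -------------------------------------------------------

# Mann-Whitney formulation: P(ratio_pos < ratio_neg) + 0.5 P(equal)
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p < q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# standard built toy-organ bundle reused by several test files
built_toy <- function(seed = 1, sbfc = 13.5) {
  toy <- generate_toy_organ(seed)
  eb <- derive_exchange_bounds(toy$model, toy$evidence, sbfc)
  asm <- assemble_objective(apply_exchange_bounds(toy$model, eb), toy$objective)
  list(toy = toy, bounds = eb, model = asm$model,
       components = asm$components,
       objective_reaction = asm$objective_reaction)
}
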
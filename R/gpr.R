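#' Gene-protein-reaction (GPR) rule trees
#'
#' A GPR rule links genes to the availability of a reaction: genes joined by
#' `and` form an enzyme complex (all subunits required), genes joined by `or`
#' are isozymes (any one suffices). Rules are represented as trees with node
#' kinds `"gene"`, `"and"`, `"or"` and `"empty"` (no gene association).
#'
#' @name gpr
NULL

gpr_empty <- function() structure(list(kind = "empty"), class = "gpr")
gpr_gene <- function(gene) structure(list(kind = "gene", gene = gene), class = "gpr")
gpr_node <- function(kind, children) {
  structure(list(kind = kind, children = children), class = "gpr")
}

#' Parse a Boolean GPR rule string
#'
#' Accepts gene tokens joined by case-insensitive `and` / `or` operators with
#' parentheses; `and` binds tighter than `or` (the BiGG/COBRA convention).
#' An empty or whitespace-only string yields the empty tree (reaction with no
#' gene association).
#'
#' @param text GPR rule string, e.g. `"(g1 and g2) or g3"`.
#' @return A `gpr` tree.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return(gpr_empty())
  stopifnot(is.character(text), length(text) == 1)
  toks <- gpr_tokenize(text)
  if (nrow(toks) == 0) return(gpr_empty())
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  tree <- gpr_parse_or(state, text)
  if (state$pos <= nrow(state$toks)) {
    stop(sprintf("GPR parse error at position %d in %s: unexpected token '%s'",
                 state$toks$at[state$pos], sQuote(text), state$toks$tok[state$pos]),
         call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  if (m[1] == -1) return(data.frame(tok = character(), at = integer()))
  tok <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  data.frame(tok = tok, at = as.integer(m), stringsAsFactors = FALSE)
}

gpr_peek <- function(state) {
  if (state$pos > nrow(state$toks)) NA_character_ else state$toks$tok[state$pos]
}

gpr_parse_or <- function(state, text) {
  children <- list(gpr_parse_and(state, text))
  while (!is.na(tk <- gpr_peek(state)) && tolower(tk) == "or") {
    state$pos <- state$pos + 1L
    children <- c(children, list(gpr_parse_and(state, text)))
  }
  if (length(children) == 1) children[[1]] else gpr_node("or", children)
}

gpr_parse_and <- function(state, text) {
  children <- list(gpr_parse_atom(state, text))
  while (!is.na(tk <- gpr_peek(state)) && tolower(tk) == "and") {
    state$pos <- state$pos + 1L
    children <- c(children, list(gpr_parse_atom(state, text)))
  }
  if (length(children) == 1) children[[1]] else gpr_node("and", children)
}

gpr_parse_atom <- function(state, text) {
  tk <- gpr_peek(state)
  at <- if (state$pos <= nrow(state$toks)) state$toks$at[state$pos] else nchar(text) + 1L
  if (is.na(tk) || tolower(tk) %in% c("and", "or") || tk == ")") {
    stop(sprintf("GPR parse error at position %d in %s: expected gene or '('",
                 at, sQuote(text)), call. = FALSE)
  }
  if (tk == "(") {
    state$pos <- state$pos + 1L
    inner <- gpr_parse_or(state, text)
    if (is.na(gpr_peek(state)) || gpr_peek(state) != ")") {
      stop(sprintf("GPR parse error in %s: unbalanced parenthesis opened at position %d",
                   sQuote(text), at), call. = FALSE)
    }
    state$pos <- state$pos + 1L
    return(inner)
  }
  state$pos <- state$pos + 1L
  gpr_gene(tk)
}

#' Render a GPR tree back to rule text
#'
#' @param tree A `gpr` tree.
#' @return A string logically equivalent to the parsed input (`""` for empty).
#' @export
deparse_gpr <- function(tree) {
  stopifnot(inherits(tree, "gpr"))
  switch(tree$kind,
    empty = "",
    gene = tree$gene,
    and = paste(vapply(tree$children, deparse_gpr_wrap, "", parent = "and"),
                collapse = " and "),
    or = paste(vapply(tree$children, deparse_gpr_wrap, "", parent = "or"),
               collapse = " or ")
  )
}

deparse_gpr_wrap <- function(tree, parent) {
  s <- deparse_gpr(tree)
  if (tree$kind %in% c("and", "or") && tree$kind != parent) paste0("(", s, ")") else s
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", if (x$kind == "empty") "(no gene association)" else deparse_gpr(x), "\n")
  invisible(x)
}

#' Evaluate a GPR tree under gene deletions
#'
#' A reaction survives a deletion set when its Boolean rule still evaluates
#' true with the deleted genes set to FALSE. The empty tree always evaluates
#' true (spontaneous / non-gene-associated reaction).
#'
#' @param tree A `gpr` tree.
#' @param deleted_genes Character vector of deleted gene ids.
#' @return Logical scalar: does the reaction retain catalytic capability?
#' @export
evaluate_gpr_knockout <- function(tree, deleted_genes) {
  stopifnot(inherits(tree, "gpr"))
  switch(tree$kind,
    empty = TRUE,
    gene = !(tree$gene %in% deleted_genes),
    and = all(vapply(tree$children, evaluate_gpr_knockout, TRUE,
                     deleted_genes = deleted_genes)),
    or = any(vapply(tree$children, evaluate_gpr_knockout, TRUE,
                    deleted_genes = deleted_genes))
  )
}

#' Evaluate a GPR tree against gene expression values
#'
#' Complexes (`and`) take the minimum over subunits, isozymes (`or`) the
#' maximum, following the standard reaction-score convention. Genes missing
#' from `gene_values` carry no data and are excluded from the aggregation;
#' a subtree with no data at all evaluates to `NA` (scored as "no data",
#' unpenalized downstream).
#'
#' @param tree A `gpr` tree.
#' @param gene_values Named numeric vector of expression values per gene.
#' @return Numeric scalar, or `NA_real_` when no constituent gene has data.
#' @export
evaluate_gpr_expression <- function(tree, gene_values) {
  stopifnot(inherits(tree, "gpr"))
  switch(tree$kind,
    empty = NA_real_,
    gene = if (tree$gene %in% names(gene_values))
      unname(gene_values[[tree$gene]]) else NA_real_,
    and = {
      v <- vapply(tree$children, evaluate_gpr_expression, 0,
                  gene_values = gene_values)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    },
    or = {
      v <- vapply(tree$children, evaluate_gpr_expression, 0,
                  gene_values = gene_values)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }
  )
}

#' Genes whose expression is most limiting for a reaction
#'
#' Walks the min/max-selecting paths of the rule and returns every leaf gene
#' whose value equals the evaluated tree value; ties return all tied genes.
#'
#' @inheritParams evaluate_gpr_expression
#' @return Character vector of limiting gene ids (empty when the tree has no
#'   expression data).
#' @export
limiting_genes <- function(tree, gene_values) {
  stopifnot(inherits(tree, "gpr"))
  val <- evaluate_gpr_expression(tree, gene_values)
  if (is.na(val)) return(character())
  limiting_rec(tree, gene_values)
}

limiting_rec <- function(tree, gene_values) {
  switch(tree$kind,
    empty = character(),
    gene = if (tree$gene %in% names(gene_values)) tree$gene else character(),
    {
      v <- vapply(tree$children, evaluate_gpr_expression, 0,
                  gene_values = gene_values)
      sel <- if (tree$kind == "and") {
        which(!is.na(v) & v == min(v, na.rm = TRUE))
      } else {
        which(!is.na(v) & v == max(v, na.rm = TRUE))
      }
      unique(unlist(lapply(tree$children[sel], limiting_rec,
                           gene_values = gene_values)))
    }
  )
}

#' All gene ids appearing in a GPR tree
#'
#' @param tree A `gpr` tree.
#' @return Character vector of unique gene ids.
#' @export
gpr_genes <- function(tree) {
  stopifnot(inherits(tree, "gpr"))
  switch(tree$kind,
    empty = character(),
    gene = tree$gene,
    unique(unlist(lapply(tree$children, gpr_genes)))
  )
}
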
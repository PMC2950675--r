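#' Expression processing pipeline
#'
#' Turns two replicate background-subtracted probe-intensity tables into
#' gene-level values, per-reaction expression scores (via GPR evaluation) and
#' a Gaussian-fit significance threshold. A probe table is a named numeric
#' vector keyed by probeset id.
#'
#' @name expression_pipeline
NULL

check_probe_table <- function(x, what) {
  if (length(x) == 0) stop(sprintf("%s is empty", what), call. = FALSE)
  if (is.null(names(x)) || any(names(x) == "")) {
    stop(sprintf("%s must be named by probeset id", what), call. = FALSE)
  }
  if (any(!is.finite(x))) stop(sprintf("%s has non-finite intensities", what), call. = FALSE)
  invisible(x)
}

#' Global normalization of the second replicate
#'
#' Rescales replicate 2 by the factor `sum(rep1) / sum(rep2)` so the total
#' probe intensity of the two arrays matches exactly.
#'
#' @param rep1,rep2 Named probe intensity vectors.
#' @return `rep2` rescaled; the factor is attached as attribute `"factor"`.
#' @export
global_normalize <- function(rep1, rep2) {
  check_probe_table(rep1, "rep1"); check_probe_table(rep2, "rep2")
  s1 <- sum(rep1); s2 <- sum(rep2)
  if (s1 <= 0 || s2 <= 0) {
    stop("global_normalize: replicate with non-positive total intensity", call. = FALSE)
  }
  f <- s1 / s2
  structure(rep2 * f, factor = f)
}

#' Lowess smoothing of replicate log-ratios
#'
#' Removes intensity-dependent bias between the replicates: on shared,
#' positive probesets, the log-ratio M = log2(rep1/rep2) is regressed on the
#' log-average A = (log2 rep1 + log2 rep2)/2 with `stats::lowess`, and the
#' fitted trend is subtracted symmetrically from the two arrays (each moves
#' half the correction). Probesets present in one table only, or non-positive,
#' pass through unchanged.
#'
#' @param rep1,rep2 Named probe intensity vectors (after global normalization).
#' @param span Lowess smoother span (fraction of points).
#' @param iter Lowess robustness iterations.
#' @return List with elements `rep1` and `rep2`.
#' @export
smooth_replicates <- function(rep1, rep2, span = 0.3, iter = 1) {
  check_probe_table(rep1, "rep1"); check_probe_table(rep2, "rep2")
  shared <- intersect(names(rep1), names(rep2))
  if (length(shared) < 10) {
    stop(sprintf("smooth_replicates requires >= 10 shared probesets, got %d",
                 length(shared)), call. = FALSE)
  }
  usable <- shared[rep1[shared] > 0 & rep2[shared] > 0]
  if (length(usable) >= 10) {
    a <- (log2(rep1[usable]) + log2(rep2[usable])) / 2
    m <- log2(rep1[usable]) - log2(rep2[usable])
    fit <- stats::lowess(a, m, f = span, iter = iter)
    mhat <- stats::approx(fit$x, fit$y, xout = a, rule = 2, ties = "ordered")$y
    rep1[usable] <- 2^(a + (m - mhat) / 2)
    rep2[usable] <- 2^(a - (m - mhat) / 2)
  }
  list(rep1 = rep1, rep2 = rep2)
}

#' Average two normalized replicates
#'
#' Per-probeset arithmetic mean; probesets present in only one replicate pass
#' through at their own value (maximizing gene coverage).
#'
#' @param rep1,rep2 Named probe intensity vectors.
#' @return Merged named vector over the union of probesets.
#' @export
average_replicates <- function(rep1, rep2) {
  check_probe_table(rep1, "rep1"); check_probe_table(rep2, "rep2")
  ids <- union(names(rep1), names(rep2))
  only1 <- setdiff(names(rep1), names(rep2))
  only2 <- setdiff(names(rep2), names(rep1))
  if (length(only1) + length(only2) > 0) {
    warning(sprintf("%d probeset(s) present in a single replicate pass through unaveraged",
                    length(only1) + length(only2)), call. = FALSE)
  }
  v1 <- rep1[ids]; v2 <- rep2[ids]
  out <- rowMeans(cbind(v1, v2), na.rm = TRUE)
  stats::setNames(out, ids)
}

#' Collapse probeset intensities to gene values
#'
#' A gene's value is the maximum over its mapped probesets. Probesets absent
#' from the map are ignored; genes with no measured probeset are absent from
#' the output (they are scored as "no data" downstream and never penalized).
#'
#' @param table Named probe intensity vector.
#' @param probe_map data.frame with columns `probeset_id`, `gene_id`.
#' @return Named numeric vector of gene values.
#' @export
gene_values_from_probesets <- function(table, probe_map) {
  check_probe_table(table, "table")
  stopifnot(all(c("probeset_id", "gene_id") %in% names(probe_map)))
  hit <- probe_map[probe_map$probeset_id %in% names(table), , drop = FALSE]
  if (nrow(hit) == 0) return(stats::setNames(numeric(0), character(0)))
  vals <- tapply(table[hit$probeset_id], hit$gene_id, max)
  stats::setNames(as.numeric(vals), names(vals))
}

#' Per-reaction expression scores from gene values
#'
#' Evaluates each reaction's GPR rule against the gene values (min across
#' complexes, max across isozymes); reactions with no gene association or no
#' measured genes score `NA` ("no data").
#'
#' @param model A `metabolic_model`.
#' @param gene_values Named numeric vector of gene expression values.
#' @return Named numeric vector over reactions (`NA` = no data).
#' @export
reaction_scores <- function(model, gene_values) {
  vapply(model$gprs, evaluate_gpr_expression, 0, gene_values = gene_values)
}

#' Gaussian-fit significance threshold
#'
#' Fits a normal distribution to the values by moments, computes per-value
#' upper-tail probabilities `1 - pnorm((x - mean)/sd)`, and returns the
#' observed value whose upper-tail probability is closest to but not
#' exceeding `p` (i.e. the smallest observed value with tail probability
#' `<= p`).
#'
#' @param values Numeric vector (at least 30 values).
#' @param p Target upper-tail probability (default 0.05).
#' @return The threshold, an observed data value.
#' @export
significance_threshold <- function(values, p = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 30) {
    stop("significance_threshold requires >= 30 values", call. = FALSE)
  }
  mu <- mean(values)
  sigma <- stats::sd(values)
  if (sigma == 0) stop("significance_threshold: zero variance", call. = FALSE)
  tail_p <- 1 - stats::pnorm((values - mu) / sigma)
  ok <- values[tail_p <= p]
  if (length(ok) == 0) {
    stop(sprintf("no observed value has upper-tail probability <= %g", p), call. = FALSE)
  }
  min(ok)
}

#' Run the full expression pipeline
#'
#' Global normalization, lowess smoothing, replicate averaging, gene
#' collapsing and threshold estimation in one call.
#'
#' @param rep1,rep2 Named probe intensity vectors.
#' @param probe_map data.frame with columns `probeset_id`, `gene_id`.
#' @param model Optional `metabolic_model`; when given, reaction scores are
#'   included in the result.
#' @param p Threshold upper-tail probability.
#' @param span Lowess span.
#' @return An `expression_profile`: list with `gene_values`, `threshold`,
#'   `threshold_p`, `probe_table` and (optionally) `reaction_scores`.
#' @export
expression_profile <- function(rep1, rep2, probe_map, model = NULL,
                               p = 0.05, span = 0.3) {
  rep2 <- global_normalize(rep1, rep2)
  sm <- smooth_replicates(rep1, rep2, span = span)
  merged <- suppressWarnings(average_replicates(sm$rep1, sm$rep2))
  gv <- gene_values_from_probesets(merged, probe_map)
  out <- list(gene_values = gv,
              threshold = significance_threshold(gv, p = p),
              threshold_p = p,
              probe_table = merged)
  if (!is.null(model)) out$reaction_scores <- reaction_scores(model, gv)
  structure(out, class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d genes, threshold %.4f (p <= %g), %d above threshold\n",
              length(x$gene_values), x$threshold, x$threshold_p,
              sum(x$gene_values >= x$threshold)))
  invisible(x)
}

#' Export gene values with above-threshold flags
#'
#' @param profile An `expression_profile`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- data.frame(gene = names(profile$gene_values),
                    value = unname(profile$gene_values),
                    above_threshold = unname(profile$gene_values >= profile$threshold))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
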
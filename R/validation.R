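#' Benchmark validation
#'
#' Compares simulated disorder phenotypes against a clinical benchmark of
#' positive/negative (gene, component) outcomes: ROC analysis over the full
#' range of disorder ratio thresholds, a permutation null, cross-validation of
#' gene activity predictions and activity-set overlaps.
#'
#' @name validation
NULL

#' Benchmark table constructor
#'
#' @param df data.frame with columns `gene_id`, `component_id`, `outcome`
#'   (`"positive"` = clinically observed disorder, `"negative"` = clinically
#'   confirmed absence).
#' @return Validated benchmark data.frame.
#' @export
benchmark_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "component_id", "outcome") %in% names(df)),
            all(df$outcome %in% c("positive", "negative")))
  if (anyDuplicated(df[, c("gene_id", "component_id")])) {
    stop("benchmark has duplicated (gene, component) pairs", call. = FALSE)
  }
  df
}

benchmark_ratios <- function(ratios, benchmark) {
  mat <- unclass(ratios)
  i <- match(benchmark$gene_id, rownames(mat))
  j <- match(benchmark$component_id, colnames(mat))
  if (anyNA(i) || anyNA(j)) {
    bad <- benchmark[is.na(i) | is.na(j), ]
    stop(sprintf("no computed ratio for benchmark pair(s): %s",
                 paste(paste(bad$gene_id, bad$component_id, sep = "/"),
                       collapse = ", ")), call. = FALSE)
  }
  mat[cbind(i, j)]
}

#' ROC analysis of disorder predictions
#'
#' Sweeps the disorder ratio threshold over all observed ratios plus the
#' endpoints 0 and 1; at each threshold `t` a pair is called a disorder when
#' its ratio is strictly below `t`. The area under the TPR-vs-FPR curve is
#' computed by the trapezoidal rule.
#'
#' @param ratios A `perturbation_matrix` (or plain matrix with gene rownames
#'   and component colnames).
#' @param benchmark A [benchmark_table()].
#' @return A `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`, `mean_tpr`
#'   (over the whole sweep) and `mean_tpr_interior` (endpoints excluded).
#' @export
roc_analysis <- function(ratios, benchmark) {
  benchmark <- benchmark_table(benchmark)
  r <- benchmark_ratios(ratios, benchmark)
  pos <- benchmark$outcome == "positive"
  if (!any(pos)) stop("benchmark has no positive entries", call. = FALSE)
  if (all(pos)) stop("benchmark has no negative entries", call. = FALSE)
  thresholds <- sort(unique(c(0, r, 1)))
  tpr <- vapply(thresholds, function(t) mean(r[pos] < t), 0)
  fpr <- vapply(thresholds, function(t) mean(r[!pos] < t), 0)
  # threshold 1+ closes the curve at (1, 1)
  thresholds <- c(thresholds, Inf)
  tpr <- c(tpr, 1)
  fpr <- c(fpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
                 mean_tpr = mean(tpr),
                 mean_tpr_interior = mean(tpr[-c(1, length(tpr))])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AROC %.4f over %d thresholds, mean TPR %.4f\n",
              x$auc, length(x$thresholds), x$mean_tpr))
  invisible(x)
}

#' Permutation null for the AROC
#'
#' Shuffles the computed ratio values across matrix cells (globally by
#' default, or within each gene row) and recomputes the AROC per trial. The
#' observed AROC is compared to the null distribution with a one-sample
#' left-tailed t-test (null aucs tested against the observed value).
#'
#' @param ratios A `perturbation_matrix`.
#' @param benchmark A [benchmark_table()].
#' @param n_trials Number of permutation trials (default 100).
#' @param seed RNG seed (required, for reproducibility).
#' @param granularity `"global"` (all cells pooled) or `"per_gene"` (shuffle
#'   within each gene's row).
#' @return List: `observed_auc`, `aucs`, `mean_auc`, `p_value`,
#'   `observed_mean_tpr`, `null_mean_tpr`, `tpr_p_value`, `seed`.
#' @export
permutation_null <- function(ratios, benchmark, n_trials = 100, seed,
                             granularity = c("global", "per_gene")) {
  granularity <- match.arg(granularity)
  if (n_trials < 2) stop("permutation_null requires n_trials >= 2", call. = FALSE)
  if (missing(seed)) stop("permutation_null requires a seed", call. = FALSE)
  obs <- roc_analysis(ratios, benchmark)
  mat <- unclass(ratios)
  set.seed(seed)
  aucs <- numeric(n_trials)
  tprs <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    sh <- mat
    if (granularity == "global") {
      sh[] <- sample(as.vector(mat))
    } else {
      for (i in seq_len(nrow(sh))) sh[i, ] <- sample(mat[i, ])
    }
    rr <- roc_analysis(sh, benchmark)
    aucs[k] <- rr$auc
    tprs[k] <- rr$mean_tpr
  }
  left_t <- function(x, mu) {
    # degenerate null (all trials identical) has no t-statistic
    if (stats::sd(x) == 0) return(if (mean(x) < mu) 0 else 1)
    stats::t.test(x, mu = mu, alternative = "less")$p.value
  }
  list(observed_auc = obs$auc, aucs = aucs, mean_auc = mean(aucs),
       p_value = left_t(aucs, obs$auc),
       observed_mean_tpr = obs$mean_tpr, null_mean_tpr = mean(tprs),
       tpr_p_value = left_t(tprs, obs$mean_tpr),
       seed = seed)
}

#' Genes predicted active by a GIMME result
#'
#' A gene is predicted active when it is the expression-limiting gene of at
#' least one non-inactive reaction, or when it has no expression data but is
#' associated with a non-inactive reaction (activity without penalty).
#'
#' @param model A `metabolic_model`.
#' @param gimme A `gimme_result` for that model.
#' @param gene_values Named gene expression vector (may omit genes).
#' @return Character vector of predicted-active gene ids.
#' @export
predicted_active_genes <- function(model, gimme, gene_values) {
  act <- names(gimme$activity)[gimme$activity != "inactive"]
  act <- intersect(act, model$reactions$id)
  out <- character()
  for (rid in act) {
    tree <- model$gprs[[rid]]
    gs <- gpr_genes(tree)
    if (length(gs) == 0) next
    lim <- limiting_genes(tree, gene_values)
    nodata <- gs[!gs %in% names(gene_values)]
    out <- c(out, lim, nodata)
  }
  unique(out)
}

#' Cross-validation of gene activity recall
#'
#' Splits the most highly expressed `fraction` of network-associated genes
#' into `folds` parts; each fold's expression data is withheld, the context
#' model is rebuilt (threshold, reaction scores, GIMME) and the recall of the
#' held-out genes among the predicted-active genes is measured. Significance
#' is a hypergeometric upper tail (population = network-associated measured
#' genes, successes = held-out set, draws = predicted-active set), Bonferroni
#' multiplied by the fold count.
#'
#' @param model Preliminary context model (bounds applied, objective added).
#' @param gene_values Full named gene expression vector.
#' @param objective_reaction Combined objective reaction id.
#' @param required_fraction GIMME objective attainment fraction.
#' @param fraction Top-expressed fraction to hold out overall (default 0.20).
#' @param folds Number of folds (default 5).
#' @param p Threshold upper-tail probability.
#' @return List: `folds` (per-fold data.frame), `mean_recall`, `p_values`,
#'   `p_adjusted`.
#' @export
crossval_recall <- function(model, gene_values, objective_reaction,
                            required_fraction = 0.90, fraction = 0.20,
                            folds = 5, p = 0.05) {
  network_genes <- intersect(model_genes(model), names(gene_values))
  n_top <- floor(length(network_genes) * fraction)
  if (n_top < folds) {
    stop(sprintf("held-out pool (%d genes) smaller than fold count %d",
                 n_top, folds), call. = FALSE)
  }
  vals <- sort(gene_values[network_genes], decreasing = TRUE)
  top <- names(vals)[seq_len(n_top)]
  fold_of <- rep_len(seq_len(folds), n_top)  # interleave by expression rank
  res <- data.frame(fold = seq_len(folds), held_out = 0L, predicted = 0L,
                    overlap = 0L, recall = 0, p_value = 1)
  for (f in seq_len(folds)) {
    held <- top[fold_of == f]
    if (length(held) == 0) stop(sprintf("fold %d is empty", f), call. = FALSE)
    gv <- gene_values[setdiff(names(gene_values), held)]
    thr <- significance_threshold(gv, p = p)
    sc <- reaction_scores(model, gv)
    gr <- run_gimme(model, sc, thr, required_fraction, objective_reaction)
    pred <- intersect(predicted_active_genes(model, gr, gv), network_genes)
    ov <- length(intersect(pred, held))
    res$held_out[f] <- length(held)
    res$predicted[f] <- length(pred)
    res$overlap[f] <- ov
    res$recall[f] <- ov / length(held)
    res$p_value[f] <- stats::phyper(ov - 1, length(held),
                                    length(network_genes) - length(held),
                                    length(pred), lower.tail = FALSE)
  }
  list(folds = res, mean_recall = mean(res$recall), p_values = res$p_value,
       p_adjusted = pmin(1, res$p_value * folds))
}

#' Three-way activity set overlap
#'
#' Counts the seven disjoint regions of the Venn diagram of predicted-active
#' genes, significantly expressed genes and proteomically detected genes.
#'
#' @param predicted_active,expressed,detected_proteins Character vectors.
#' @return Named integer vector of the 7 region counts.
#' @export
activity_set_overlap <- function(predicted_active, expressed, detected_proteins) {
  a <- unique(predicted_active); b <- unique(expressed); c_ <- unique(detected_proteins)
  all_ids <- unique(c(a, b, c_))
  ina <- all_ids %in% a; inb <- all_ids %in% b; inc <- all_ids %in% c_
  c(predicted_only = sum(ina & !inb & !inc),
    expressed_only = sum(!ina & inb & !inc),
    detected_only = sum(!ina & !inb & inc),
    predicted_expressed = sum(ina & inb & !inc),
    predicted_detected = sum(ina & !inb & inc),
    expressed_detected = sum(!ina & inb & inc),
    all_three = sum(ina & inb & inc))
}
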
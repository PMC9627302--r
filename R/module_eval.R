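#' Density-based module preservation in the other condition
#'
#' Re-evaluates a detected module's co-expression in the opposite
#' condition: counts the module-gene pairs whose correlation is significant
#' (`|r| > r_cut`, `p < p_cut`) in that condition's pooled samples, and
#' compares densities. By default the other-condition density is computed
#' over the genes that participate in at least one significant edge there
#' (the count that a module's surviving subnetwork actually spans);
#' `denominator = "module"` uses the full module size instead.
#'
#' @param module an `mcode_complex` from [predict_complexes()].
#' @param corr_other a [correlate()] result for the opposite condition.
#' @param r_cut,p_cut significance criteria, identical to the network stage.
#' @param denominator `"participating"` (default) or `"module"`.
#' @param preserved_fold_cut the module is called preserved when the density
#'   fold-change is below this value (default 1.5).
#' @return list of class `preservation_report` with fields `module_genes`,
#'   `n_genes_module`, `edges_primary`, `density_primary`,
#'   `genes_with_significant_edges_other`, `edges_other`, `density_other`,
#'   `fold_change` (`Inf` when no other-condition edge survives) and
#'   `preserved`.
#' @export
module_preservation <- function(module, corr_other, r_cut = 0.8, p_cut = 0.05,
                                denominator = c("participating", "module"),
                                preserved_fold_cut = 1.5) {
  stopifnot(inherits(module, "mcode_complex"), inherits(corr_other, "coexpr_corr"))
  denominator <- match.arg(denominator)
  missing <- setdiff(module$genes, corr_other$genes)
  if (length(missing)) {
    stop("module gene(s) absent from the other condition's correlations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- module$genes
  r <- corr_other$r[g, g, drop = FALSE]
  p <- corr_other$p[g, g, drop = FALSE]
  sig <- upper.tri(r) & abs(r) > r_cut & p < p_cut
  edges_other <- sum(sig, na.rm = TRUE)
  part <- sig | t(sig)
  participating <- sum(rowSums(part, na.rm = TRUE) > 0)
  n_other <- if (denominator == "participating") participating else length(g)
  density_other <- if (n_other >= 2) network_density(n_other, edges_other) else 0
  density_primary <- module$density
  fold <- if (density_other > 0) density_primary / density_other else Inf
  structure(list(
    module_genes = g,
    n_genes_module = length(g),
    edges_primary = nrow(module$edges),
    density_primary = density_primary,
    genes_with_significant_edges_other = participating,
    edges_other = edges_other,
    density_other = density_other,
    fold_change = fold,
    preserved = is.finite(fold) && fold < preserved_fold_cut
  ), class = "preservation_report")
}

#' @export
print.preservation_report <- function(x, ...) {
  cat(sprintf(
    "preservation_report: %d module genes, %d edges (density %.3f) in primary;\n  %d significant edges among %d participating genes (density %.3f) in other;\n  density fold-change %s -> %s\n",
    x$n_genes_module, x$edges_primary, x$density_primary,
    x$edges_other, x$genes_with_significant_edges_other, x$density_other,
    if (is.finite(x$fold_change)) sprintf("%.1f", x$fold_change) else "Inf",
    if (x$preserved) "preserved" else "NOT preserved"))
  invisible(x)
}

#' Paired correlation table for a module across conditions
#'
#' All module gene pairs with their Pearson correlation in both conditions;
#' input to circle-matrix style comparison plots.
#'
#' @param module an `mcode_complex`.
#' @param corr_primary,corr_other [correlate()] results.
#' @return data.frame `gene_i`, `gene_j`, `r_primary`, `r_other` over all
#'   `C(n, 2)` pairs, in lexicographic order.
#' @export
correlation_circle_table <- function(module, corr_primary, corr_other) {
  g <- sort(module$genes)
  for (corr in list(corr_primary, corr_other)) {
    missing <- setdiff(g, corr$genes)
    if (length(missing)) {
      stop("module gene(s) missing from correlations: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  pairs <- t(utils::combn(g, 2))
  data.frame(
    gene_i = pairs[, 1], gene_j = pairs[, 2],
    r_primary = corr_primary$r[pairs],
    r_other = corr_other$r[pairs],
    stringsAsFactors = FALSE
  )
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' `auc_raw` is the probability that a random disease sample's value exceeds
#' a random control's, with half-credit for ties — computed from the rank
#' sum, with disease as the positive class and higher expression calling
#' positive. `auc_oriented = max(auc_raw, 1 - auc_raw)` removes the
#' direction of regulation. ROC curve points are emitted over all observed
#' thresholds.
#'
#' @param values_disease,values_control numeric vectors (non-empty).
#' @return list with `auc_raw`, `auc_oriented` and `curve`
#'   (data.frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(values_disease, values_control) {
  n_d <- length(values_disease); n_c <- length(values_control)
  if (n_d == 0 || n_c == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(values_disease, values_control)
  rk <- rank(pooled)  # average ranks give the tie half-credit
  u <- sum(rk[seq_len(n_d)]) - n_d * (n_d + 1) / 2
  auc_raw <- u / (n_d * n_c)
  thr <- sort(unique(pooled), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(values_disease >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(values_control >= t), numeric(1))
  curve <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
                 data.frame(threshold = thr, fpr = fpr, tpr = tpr))
  list(auc_raw = auc_raw, auc_oriented = max(auc_raw, 1 - auc_raw),
       curve = curve)
}

#' Screen genes as diagnostic biomarkers by AUC
#'
#' Computes, for every gene, the per-study AUC and the AUC over the pooled
#' samples of all studies; a gene passes when its pooled orientation-free
#' AUC reaches `auc_cut`.
#'
#' @param datasets list of [expr_dataset()] objects.
#' @param genes gene ids to screen (must be present in every dataset).
#' @param auc_cut oriented-AUC pass threshold (default 0.7).
#' @return data.frame `gene_id`, `auc_raw`, `auc_oriented`, `passes`
#'   (pooled-sample values); per-study AUCs in attribute `"per_study"`
#'   (data.frame `gene_id`, `study_id`, `auc_raw`, `auc_oriented`).
#' @export
screen_biomarkers <- function(datasets, genes, auc_cut = 0.7) {
  for (d in datasets) {
    missing <- setdiff(genes, rownames(d$expr))
    if (length(missing)) {
      stop("gene(s) missing from study '", d$study_id, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  per_study <- do.call(rbind, lapply(datasets, function(d) {
    dis <- d$expr[genes, d$condition == "disease", drop = FALSE]
    ctl <- d$expr[genes, d$condition == "control", drop = FALSE]
    res <- lapply(genes, function(g) roc_auc(dis[g, ], ctl[g, ]))
    data.frame(gene_id = genes, study_id = d$study_id,
               auc_raw = vapply(res, `[[`, numeric(1), "auc_raw"),
               auc_oriented = vapply(res, `[[`, numeric(1), "auc_oriented"),
               stringsAsFactors = FALSE)
  }))
  dis_all <- do.call(cbind, lapply(datasets, function(d)
    d$expr[genes, d$condition == "disease", drop = FALSE]))
  ctl_all <- do.call(cbind, lapply(datasets, function(d)
    d$expr[genes, d$condition == "control", drop = FALSE]))
  pooled <- lapply(genes, function(g) roc_auc(dis_all[g, ], ctl_all[g, ]))
  out <- data.frame(
    gene_id = genes,
    auc_raw = vapply(pooled, `[[`, numeric(1), "auc_raw"),
    auc_oriented = vapply(pooled, `[[`, numeric(1), "auc_oriented"),
    stringsAsFactors = FALSE
  )
  out$passes <- out$auc_oriented >= auc_cut
  rownames(per_study) <- NULL
  attr(out, "per_study") <- per_study
  out
}
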
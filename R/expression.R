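#' Two-condition expression dataset
#'
#' Bundles a gene-by-sample log2 expression matrix with per-sample condition
#' labels and a study identifier. This is the unit of study input for the
#' differential-expression stage: one `expr_dataset` per study (e.g. one per
#' GEO series in a meta-analysis).
#'
#' @param expr numeric matrix, rows = genes (rownames = gene ids, duplicates
#'   allowed until [collapse_duplicates()] is applied), columns = samples
#'   (colnames = sample ids). Values are assumed to be on the log2 scale.
#' @param condition character vector of length `ncol(expr)` with values
#'   `"control"` or `"disease"`, in column order.
#' @param study_id single string naming the study.
#'
#' @return An object of class `expr_dataset`: a list with elements `expr`,
#'   `condition` (named by sample id) and `study_id`.
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
#' ds <- expr_dataset(m, c("control", "control", "disease", "disease"), "demo")
#' @export
expr_dataset <- function(expr, condition, study_id) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("`expr` must have gene rownames and sample colnames", call. = FALSE)
  }
  if (anyNA(expr)) {
    stop("expression matrix contains missing values; impute before constructing ",
         "the dataset (see `read_expression(impute = \"row-mean\")`)", call. = FALSE)
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(expr)) {
    stop("`condition` must have one label per sample column", call. = FALSE)
  }
  bad <- setdiff(unique(condition), c("control", "disease"))
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(condition, levels = c("control", "disease")))
  if (any(tab < 2)) {
    stop("each condition needs >= 2 samples; got control=", tab[["control"]],
         ", disease=", tab[["disease"]], call. = FALSE)
  }
  names(condition) <- colnames(expr)
  structure(
    list(expr = expr, condition = condition, study_id = as.character(study_id)[1]),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("expr_dataset '%s': %d genes x %d samples (%d control, %d disease)\n",
              x$study_id, nrow(x$expr), ncol(x$expr),
              tab[["control"]], tab[["disease"]]))
  invisible(x)
}

#' Collapse duplicated gene ids to their mean profile
#'
#' Rows sharing a gene id are replaced by their per-sample arithmetic mean.
#' Row order follows the first occurrence of each gene id. Microarray inputs
#' frequently carry several probes per gene symbol; downstream correlation
#' and network stages require a unique gene universe.
#'
#' @param dataset an [expr_dataset()].
#' @return An `expr_dataset` with unique gene rownames.
#' @export
collapse_duplicates <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  ids <- rownames(dataset$expr)
  if (!anyDuplicated(ids)) return(dataset)
  first <- !duplicated(ids)
  keep_order <- ids[first]
  summed <- rowsum(dataset$expr, group = ids, reorder = FALSE)
  counts <- as.vector(table(factor(ids, levels = rownames(summed))))
  collapsed <- summed / counts
  collapsed <- collapsed[keep_order, , drop = FALSE]
  expr_dataset(collapsed, dataset$condition, dataset$study_id)
}

#' Pool one condition's samples across studies
#'
#' Restricts every dataset to a shared gene universe (typically the common
#' DEGs) and column-concatenates the samples of the requested condition
#' across studies, reproducing the "pooled disease" / "pooled healthy"
#' matrices on which condition-specific co-expression is computed.
#'
#' @param datasets list of [expr_dataset()] objects.
#' @param condition `"control"` or `"disease"`.
#' @param genes character vector giving the gene universe to restrict to;
#'   defaults to the genes of the first dataset.
#' @return An `expr_dataset` tagged with `study_id = "pooled"` whose columns
#'   are the condition's samples from all studies, in study order.
#' @export
pool_condition <- function(datasets, condition = c("disease", "control"),
                           genes = NULL) {
  condition <- match.arg(condition)
  stopifnot(length(datasets) >= 1)
  if (is.null(genes)) genes <- rownames(datasets[[1]]$expr)
  mats <- lapply(datasets, function(d) {
    missing <- setdiff(genes, rownames(d$expr))
    if (length(missing)) {
      stop("study '", d$study_id, "' lacks gene(s): ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) ", ...", call. = FALSE)
    }
    d$expr[genes, d$condition == condition, drop = FALSE]
  })
  pooled <- do.call(cbind, mats)
  lab <- rep(condition, ncol(pooled))
  # expr_dataset requires both conditions; pooled matrices are single-condition
  # by construction, so build the object directly.
  names(lab) <- colnames(pooled)
  structure(list(expr = pooled, condition = lab, study_id = "pooled"),
            class = "expr_dataset")
}
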
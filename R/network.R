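#' Quantile-normalize an expression matrix
#'
#' Classic quantile normalization: every column is forced onto the common
#' reference distribution given by the across-column means of the sorted
#' values; ties within a column receive the mean of the reference values at
#' their tied ranks.
#'
#' @param mat numeric matrix (genes x samples), no missing values.
#' @return Matrix of the same shape with identical sorted values in every
#'   column.
#' @export
quantile_normalize <- function(mat) {
  if (anyNA(mat)) stop("matrix contains missing values", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Pairwise Pearson correlations with asymptotic significance
#'
#' Computes the full gene-by-gene Pearson correlation matrix over samples
#' and two-sided asymptotic p-values from
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#' Perfect correlations (`|r| = 1`) are assigned `p = 0`. Genes with zero
#' variance are excluded with a warning.
#'
#' @param mat numeric matrix, rows = genes, columns = samples (`n >= 3`).
#' @return list of class `coexpr_corr`: `genes`, `r` (correlation matrix),
#'   `p` (p-value matrix, diagonal `NA`), `n_samples`.
#' @export
correlate <- function(mat) {
  n <- ncol(mat)
  if (n < 3) stop("need >= 3 samples for asymptotic correlation p-values",
                  call. = FALSE)
  v <- apply(mat, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)", call. = FALSE)
    mat <- mat[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(mat))
  r[r > 1] <- 1; r[r < -1] <- -1
  denom <- 1 - r^2
  tt <- abs(r) * sqrt(n - 2) / sqrt(pmax(denom, 0))
  p <- 2 * stats::pt(-tt, df = n - 2)
  p[denom <= 0] <- 0
  diag(p) <- NA_real_
  structure(list(genes = rownames(mat), r = r, p = p, n_samples = n),
            class = "coexpr_corr")
}

#' Threshold correlations into a condition-specific co-expression network
#'
#' An edge joins every gene pair with `|r| > r_cut` and `p < p_cut`;
#' its sign is `+` for `r > r_cut` and `-` for `r < -r_cut`. Isolated genes
#' are not nodes. The network is undirected and simple (no loops, no
#' duplicate edges); edges are stored in deterministic lexicographic order.
#'
#' @param corr a [correlate()] result.
#' @param r_cut absolute correlation cutoff (default 0.8).
#' @param p_cut asymptotic p-value threshold (default 0.05).
#' @param condition tag, `"disease"` or `"control"`.
#' @return list of class `coexpr_network`: `condition`, `nodes`, `edges`
#'   (data.frame `gene_a`, `gene_b`, `r`, `p`, `sign`), `r_cut`, `p_cut`.
#' @export
build_network <- function(corr, r_cut = 0.8, p_cut = 0.05,
                          condition = c("disease", "control")) {
  stopifnot(inherits(corr, "coexpr_corr"))
  condition <- match.arg(condition)
  g <- corr$genes
  idx <- which(upper.tri(corr$r) & abs(corr$r) > r_cut & corr$p < p_cut,
               arr.ind = TRUE)
  if (nrow(idx)) {
    a <- g[idx[, 1]]; b <- g[idx[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    edges <- data.frame(
      gene_a = a, gene_b = b,
      r = corr$r[idx], p = corr$p[idx],
      sign = ifelse(corr$r[idx] > 0, "+", "-"),
      stringsAsFactors = FALSE
    )
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        r = numeric(), p = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  structure(list(condition = condition, nodes = nodes, edges = edges,
                 r_cut = r_cut, p_cut = p_cut),
            class = "coexpr_network")
}

#' @export
print.coexpr_network <- function(x, ...) {
  cat(sprintf("coexpr_network (%s): %d nodes, %d edges (|r| > %g, p < %g), density %.3f\n",
              x$condition, length(x$nodes), nrow(x$edges), x$r_cut, x$p_cut,
              if (length(x$nodes) >= 2)
                network_density(length(x$nodes), nrow(x$edges)) else NA_real_))
  invisible(x)
}

#' Density of a simple undirected graph
#'
#' `2 E / (N (N - 1))` for `N` nodes and `E` edges, loops excluded.
#'
#' @param n_nodes node count (>= 2).
#' @param n_edges edge count.
#' @return Density in \[0, 1\] (full precision; round to 3 decimals for
#'   reporting).
#' @export
network_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("density needs >= 2 nodes", call. = FALSE)
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Degree-ranked hub genes
#'
#' Ranks nodes by degree and returns the top `ceiling(fraction * n_nodes)`
#' genes, extended to include every node tied with the k-th ranked degree.
#'
#' @param network a [build_network()] result.
#' @param fraction fraction of nodes to take (default 0.05).
#' @return data.frame `gene`, `degree`, ordered by decreasing degree then
#'   gene id.
#' @export
select_hubs <- function(network, fraction = 0.05) {
  stopifnot(inherits(network, "coexpr_network"))
  if (length(network$nodes) == 0) stop("network is empty", call. = FALSE)
  deg <- node_degrees(network)
  k <- ceiling(fraction * length(network$nodes))
  ord <- order(-deg$degree, deg$gene)
  deg <- deg[ord, , drop = FALSE]
  cutoff <- deg$degree[k]
  out <- deg[deg$degree >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node degrees of a co-expression network
#'
#' @param network a [build_network()] result.
#' @return data.frame `gene`, `degree` in node order.
#' @export
node_degrees <- function(network) {
  counts <- table(factor(c(network$edges$gene_a, network$edges$gene_b),
                         levels = network$nodes))
  data.frame(gene = network$nodes, degree = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a network as SIF and extended edge-list TSV
#'
#' Writes Cytoscape-compatible interchange files: `<prefix>.sif`
#' (`geneA pp geneB`) and `<prefix>_edges.tsv` (`gene_a`, `gene_b`, `r`,
#' `p`, `sign`), plus a node table `<prefix>_nodes.tsv` (`gene`, `degree`,
#' `is_hub`). Edge order is deterministic (lexicographic).
#'
#' @param network a [build_network()] result.
#' @param prefix output path prefix.
#' @param hub_fraction hub fraction used to flag hubs in the node table.
#' @return Named character vector of written paths.
#' @export
export_edge_list <- function(network, prefix, hub_fraction = 0.05) {
  stopifnot(inherits(network, "coexpr_network"))
  sif <- paste0(prefix, ".sif")
  tsv <- paste0(prefix, "_edges.tsv")
  nodes_tsv <- paste0(prefix, "_nodes.tsv")
  e <- network$edges
  writeLines(if (nrow(e)) paste(e$gene_a, "pp", e$gene_b, sep = "\t") else character(),
             sif)
  utils::write.table(e, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  deg <- node_degrees(network)
  deg$is_hub <- if (nrow(deg)) deg$gene %in% select_hubs(network, hub_fraction)$gene
                else logical()
  utils::write.table(deg, nodes_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  c(sif = sif, edges = tsv, nodes = nodes_tsv)
}

#' Re-import a network from its edge-list TSV
#'
#' @param path an `_edges.tsv` file written by [export_edge_list()].
#' @param condition,r_cut,p_cut network metadata (not stored in the TSV).
#' @return A `coexpr_network`.
#' @export
read_edge_list <- function(path, condition = c("disease", "control"),
                           r_cut = 0.8, p_cut = 0.05) {
  condition <- match.arg(condition)
  e <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "numeric",
                                        "numeric", "character"))
  e <- e[order(e$gene_a, e$gene_b), , drop = FALSE]
  rownames(e) <- NULL
  nodes <- sort(unique(c(e$gene_a, e$gene_b)))
  structure(list(condition = condition, nodes = nodes, edges = e,
                 r_cut = r_cut, p_cut = p_cut),
            class = "coexpr_network")
}
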
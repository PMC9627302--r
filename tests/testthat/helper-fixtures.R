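# shared fixture builders: tiny expression sets and hand-built graphs

make_dataset <- function(mat, n_control, study_id = "s1") {
  cond <- rep(c("control", "disease"), c(n_control, ncol(mat) - n_control))
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("%s_%02d", study_id, seq_len(ncol(mat)))
  }
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("G%03d", seq_len(nrow(mat)))
  expr_dataset(mat, cond, study_id)
}

random_dataset <- function(n_genes = 30, n_control = 5, n_disease = 5,
                           study_id = "s1") {
  m <- matrix(rnorm(n_genes * (n_control + n_disease), 8, 1),
              nrow = n_genes)
  make_dataset(m, n_control, study_id)
}

# build a coexpr_network straight from an edge list (r/p filled in as
# passing values); for topology-only tests
make_network <- function(pairs, condition = "disease") {
  e <- data.frame(gene_a = as.character(pairs[, 1]),
                  gene_b = as.character(pairs[, 2]),
                  stringsAsFactors = FALSE)
  swap <- e$gene_a > e$gene_b
  tmp <- e$gene_a[swap]; e$gene_a[swap] <- e$gene_b[swap]; e$gene_b[swap] <- tmp
  e <- unique(e[order(e$gene_a, e$gene_b), , drop = FALSE])
  e$r <- rep(0.9, nrow(e)); e$p <- rep(1e-6, nrow(e))
  e$sign <- rep("+", nrow(e))
  rownames(e) <- NULL
  structure(list(condition = condition,
                 nodes = sort(unique(c(e$gene_a, e$gene_b))),
                 edges = e, r_cut = 0.8, p_cut = 0.05),
            class = "coexpr_network")
}

complete_graph_pairs <- function(ids) t(combn(ids, 2))

# random G(n, p) edge list over letter-ish ids
random_graph_pairs <- function(n, p_edge = 0.25) {
  ids <- sprintf("v%02d", seq_len(n))
  all_pairs <- t(combn(ids, 2))
  keep <- runif(nrow(all_pairs)) < p_edge
  all_pairs[keep, , drop = FALSE]
}

# small, fast simulation for pipeline-level tests
small_sim_config <- function(seed = 1) {
  simulation_config(
    n_studies = 2, genes_total = 150,
    samples_control = c(12, 12), samples_disease = c(12, 12),
    frac_de = 0.2, module_size = 10, module_neg_fraction = 0.3,
    seed = seed
  )
}
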
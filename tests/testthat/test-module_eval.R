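# brute-force AUC: mean over all disease-control pairs of the win indicator
brute_auc <- function(d, c) {
  mean(outer(d, c, function(a, b) (a > b) + 0.5 * (a == b)))
}

test_that("rank AUC equals the brute-force pairwise indicator mean", {
  expect_equal(roc_auc(c(3, 4, 5), c(1, 2))$auc_raw, 1)
  expect_equal(roc_auc(c(1, 2), c(1, 2))$auc_raw, 0.5)
  expect_equal(roc_auc(c(1, 2, 3), c(2, 3, 4))$auc_raw,
               brute_auc(c(1, 2, 3), c(2, 3, 4)))
  set.seed(12)
  for (i in 1:200) {
    nd <- sample(2:12, 1); nc <- sample(2:12, 1)
    d <- sample(1:8, nd, replace = TRUE) + sample(c(0, 0.5), nd, replace = TRUE)
    c <- sample(1:8, nc, replace = TRUE)
    expect_identical(roc_auc(d, c)$auc_raw, brute_auc(d, c))
  }
  expect_error(roc_auc(numeric(), 1:3), "non-empty")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(13)
  d <- rnorm(15, 1); c <- rnorm(10)
  a0 <- roc_auc(d, c)$auc_raw
  expect_equal(roc_auc(exp(d), exp(c))$auc_raw, a0)
  expect_equal(roc_auc(d^3 + 2 * d, c^3 + 2 * c)$auc_raw, a0)
  # constant gene: pure ties -> 0.5
  expect_equal(roc_auc(rep(2, 5), rep(2, 7))$auc_raw, 0.5)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  d <- rnorm(20, 0.8); c <- rnorm(15)
  a <- roc_auc(d, c)
  ref <- pROC::roc(response = rep(c(1, 0), c(20, 15)), predictor = c(d, c),
                   quiet = TRUE, direction = "<")
  expect_equal(a$auc_raw, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("ROC curve points trace FPR/TPR over all thresholds", {
  a <- roc_auc(c(3, 4, 5), c(1, 2))
  expect_equal(a$curve$fpr[1], 0)
  expect_equal(a$curve$tpr[nrow(a$curve)], 1)
  expect_true(all(diff(a$curve$fpr) >= 0))
  expect_true(all(diff(a$curve$tpr) >= 0))
})

test_that("module preservation reproduces the density-ratio arithmetic", {
  # module: 17 genes, 125 induced edges -> density 0.919; other condition
  # keeps 33 significant pairs among 13 participating genes -> 0.423, fold 2.2
  set.seed(15)
  genes <- sprintf("m%02d", 1:17)
  all_pairs <- t(combn(genes, 2))
  module_pairs <- all_pairs[sample(nrow(all_pairs), 125), ]
  nw <- make_network(module_pairs)
  cx <- predict_complexes(nw, mcode_params(haircut = FALSE))
  mod <- top_module(cx)
  expect_length(mod$genes, 17)
  expect_equal(nrow(mod$edges), 125)
  expect_equal(round(mod$density, 3), 0.919)

  # synthetic other-condition correlations: 33 significant pairs among 13 genes
  r <- diag(17); dimnames(r) <- list(genes, genes)
  p <- matrix(1, 17, 17, dimnames = list(genes, genes))
  participating <- genes[1:13]
  sub_pairs <- t(combn(participating, 2))[seq_len(33), ]
  for (i in seq_len(33)) {
    a <- sub_pairs[i, 1]; b <- sub_pairs[i, 2]
    r[a, b] <- r[b, a] <- 0.85
    p[a, b] <- p[b, a] <- 1e-6
  }
  corr_other <- structure(list(genes = genes, r = r, p = p, n_samples = 34),
                          class = "coexpr_corr")
  rep <- module_preservation(mod, corr_other)
  expect_equal(rep$edges_other, 33)
  expect_equal(rep$genes_with_significant_edges_other, 13)
  expect_equal(round(rep$density_other, 3), 0.423)
  expect_equal(round(rep$fold_change, 1), 2.2)
  expect_false(rep$preserved)
  # full-module denominator variant
  rep2 <- module_preservation(mod, corr_other, denominator = "module")
  expect_equal(rep2$density_other, network_density(17, 33))
})

test_that("preservation identity and degenerate branches behave", {
  tri <- make_network(complete_graph_pairs(c("a", "b", "c")))
  mod <- top_module(predict_complexes(tri))
  r <- matrix(0.9, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(r) <- 1
  p <- matrix(1e-8, 3, 3, dimnames = dimnames(r)); diag(p) <- NA
  corr_same <- structure(list(genes = c("a", "b", "c"), r = r, p = p,
                              n_samples = 30), class = "coexpr_corr")
  rep <- module_preservation(mod, corr_same)
  expect_equal(rep$fold_change, 1)
  expect_true(rep$preserved)
  # zero significant other-condition edges -> density 0, fold Inf
  p0 <- matrix(1, 3, 3, dimnames = dimnames(r))
  corr_none <- structure(list(genes = c("a", "b", "c"), r = r * 0.1, p = p0,
                              n_samples = 30), class = "coexpr_corr")
  rep0 <- module_preservation(mod, corr_none)
  expect_equal(rep0$density_other, 0)
  expect_identical(rep0$fold_change, Inf)
  expect_false(rep0$preserved)
  # absent gene errors by name
  corr_small <- structure(list(genes = c("a", "b"), r = r[1:2, 1:2],
                               p = p[1:2, 1:2], n_samples = 30),
                          class = "coexpr_corr")
  expect_error(module_preservation(mod, corr_small), "correlations: c")
})

test_that("correlation circle table covers all module pairs symmetrically", {
  tri <- make_network(complete_graph_pairs(c("a", "b", "c")))
  mod <- top_module(predict_complexes(tri))
  r <- matrix(c(1, .5, -.2, .5, 1, .9, -.2, .9, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cr <- structure(list(genes = c("a", "b", "c"), r = r, p = r * 0 + 1e-6,
                       n_samples = 10), class = "coexpr_corr")
  tab <- correlation_circle_table(mod, cr, cr)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$r_primary, tab$r_other)
  expect_equal(tab$r_primary[tab$gene_i == "a" & tab$gene_j == "b"], 0.5)
  # TSV round-trip preserves values
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(f)
  expect_equal(back$r_primary, tab$r_primary, tolerance = 1e-12)
})

test_that("biomarker screening passes planted-shift genes and rejects noise", {
  passes_shift <- logical(10); noise_auc <- numeric(10)
  for (s in 1:10) {
    set.seed(700 + s)
    mk <- function(n_c, n_d, id) {
      m <- matrix(rnorm(2 * (n_c + n_d)), 2,
                  dimnames = list(c("shift", "noise"),
                                  sprintf("%s_%d", id, seq_len(n_c + n_d))))
      m["shift", (n_c + 1):(n_c + n_d)] <- m["shift", (n_c + 1):(n_c + n_d)] + 2
      make_dataset(m, n_c, id)
    }
    studies <- list(mk(12, 13, "a"), mk(12, 12, "b"), mk(10, 53, "c"))
    tab <- screen_biomarkers(studies, c("shift", "noise"))
    passes_shift[s] <- tab$passes[tab$gene_id == "shift"]
    noise_auc[s] <- tab$auc_raw[tab$gene_id == "noise"]
  }
  expect_true(all(passes_shift))       # 2-SD shift: theory AUC approx 0.92
  expect_lt(abs(mean(noise_auc) - 0.5), 0.1)
  per_study <- attr(tab, "per_study")
  expect_equal(nrow(per_study), 6)
  expect_error(screen_biomarkers(studies, "missing_gene"), "missing_gene")
})
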
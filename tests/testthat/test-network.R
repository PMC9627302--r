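test_that("quantile normalization maps columns onto the mean reference", {
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(out[, 1], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(out[, 2], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  # single column unchanged
  one <- matrix(c(3, 1, 2), ncol = 1)
  expect_equal(quantile_normalize(one), one, ignore_attr = TRUE)
  # rank equivariance: permuting a column's rows permutes its output
  set.seed(4)
  m2 <- matrix(rnorm(60), 12, 5)
  q2 <- quantile_normalize(m2)
  perm <- sample(12)
  m3 <- m2; m3[, 2] <- m2[perm, 2]
  q3 <- quantile_normalize(m3)
  expect_equal(q3[, 2], q2[perm, 2], ignore_attr = TRUE)
  # all columns share identical sorted values
  sorted <- apply(q2, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("correlate matches a brute-force per-pair loop", {
  set.seed(5)
  m <- matrix(rnorm(80), 10, 8, dimnames = list(sprintf("g%d", 1:10), NULL))
  res <- correlate(m)
  for (i in 1:9) for (j in (i + 1):10) {
    ct <- cor.test(m[i, ], m[j, ])
    expect_equal(res$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[i, j], ct$p.value, tolerance = 1e-12)
  }
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 10))
})

test_that("correlation p-values follow the t-approximation with clamps", {
  # r = 0.8 at n = 34: t = 0.8*sqrt(32)/0.6, p approx 1.3e-8
  n <- 34
  tt <- 0.8 * sqrt(n - 2) / sqrt(1 - 0.64)
  p_expect <- 2 * pt(-tt, df = n - 2)
  expect_equal(p_expect, 1.3e-8, tolerance = 0.05)
  # construct data with an exact r = 1 pair and an r approx 0 pair
  x <- seq_len(6)
  m <- rbind(a = x, b = 2 * x + 3, c = c(1, -1, 1, -1, 1, -1))
  colnames(m) <- paste0("s", 1:6)
  res <- correlate(m)
  expect_equal(res$r["a", "b"], 1)
  expect_equal(res$p["a", "b"], 0)
  expect_error(correlate(m[, 1:2]), ">= 3 samples")
  expect_warning(correlate(rbind(m, d = rep(5, 6))), "zero-variance")
  # p strictly decreasing in |r| at fixed n
  rs <- seq(0.1, 0.95, by = 0.05)
  ps <- 2 * pt(-rs * sqrt(30) / sqrt(1 - rs^2), df = 30)
  expect_true(all(diff(ps) < 0))
})

test_that("build_network applies both gates and records signs", {
  set.seed(6)
  n <- 20
  z <- rnorm(n)
  m <- rbind(a = z + rnorm(n, sd = 0.2),
             b = z + rnorm(n, sd = 0.2),
             c = -z + rnorm(n, sd = 0.2),
             d = rnorm(n))
  colnames(m) <- paste0("s", 1:n)
  res <- correlate(m)
  nw <- build_network(res, condition = "disease")
  expect_true(all(abs(nw$edges$r) > 0.8 & nw$edges$p < 0.05))
  expect_false("d" %in% nw$nodes)
  neg <- nw$edges[nw$edges$gene_b == "c" | nw$edges$gene_a == "c", ]
  expect_true(all(neg$sign == "-"))
  expect_true(all(nw$edges$gene_a < nw$edges$gene_b))
  # edge count nonincreasing in r_cut and in decreasing p_cut
  e1 <- nrow(build_network(res, 0.5, 0.05, "disease")$edges)
  e2 <- nrow(build_network(res, 0.9, 0.05, "disease")$edges)
  e3 <- nrow(build_network(res, 0.5, 1e-6, "disease")$edges)
  expect_lte(e2, e1)
  expect_lte(e3, e1)
})

test_that("network density follows 2E/(N(N-1))", {
  expect_equal(round(network_density(17, 125), 3), 0.919)
  expect_equal(round(network_density(13, 33), 3), 0.423)
  expect_equal(network_density(2, 1), 1)
  for (n in c(3, 5, 9)) {
    expect_equal(network_density(n, choose(n, 2)), 1)
    expect_equal(network_density(n, 0), 0)
  }
  expect_error(network_density(1, 0), ">= 2 nodes")
})

test_that("hub selection takes the top 5% extended by degree ties", {
  # star: center is the single hub
  star <- make_network(cbind("ctr", sprintf("l%d", 1:5)))
  hubs <- select_hubs(star)
  expect_identical(hubs$gene, "ctr")
  expect_identical(hubs$degree, 5L)
  # 24 nodes: k = 2, three nodes tied at the 2nd-ranked degree -> 4 hubs
  ids <- sprintf("n%02d", 1:24)
  pairs <- rbind(
    cbind(ids[1], ids[2:11]),              # n01 degree 10
    cbind(ids[2], ids[12:18]),             # n02 degree 7 + 1 = 8
    cbind(ids[3], ids[c(12:17, 19)]),      # n03 degree 8
    cbind(ids[4], ids[c(13:18, 20)]),      # n04 degree 8
    matrix(c(ids[21], ids[22], ids[23], ids[24]), 2, 2, byrow = TRUE)
  )
  nw <- make_network(pairs)
  expect_length(nw$nodes, 24)
  got <- select_hubs(nw)                   # k = ceiling(0.05 * 24) = 2 + ties
  expect_setequal(got$gene, c("n01", "n02", "n03", "n04"))
  expect_equal(nrow(got), 4)
  # 20 nodes with unique degrees -> exactly the single top node
  chain <- cbind(sprintf("c%02d", 1:19), sprintf("c%02d", 2:20))
  hub1 <- select_hubs(make_network(rbind(chain, cbind("c01", sprintf("c%02d", 3:8)))))
  expect_identical(hub1$gene, "c01")
})

test_that("edge lists round-trip through SIF/TSV export", {
  set.seed(8)
  nw <- make_network(random_graph_pairs(12, 0.3), condition = "control")
  prefix <- file.path(tempdir(), "nw_export")
  paths <- export_edge_list(nw, prefix)
  expect_true(all(file.exists(paths)))
  sif <- readLines(paths["sif"])
  expect_length(sif, nrow(nw$edges))
  expect_match(sif[1], "\tpp\t")
  back <- read_edge_list(paths["edges"], condition = "control")
  expect_equal(back$edges, nw$edges)
  expect_identical(back$nodes, nw$nodes)
  # empty network -> header-only TSV, zero SIF lines
  empty <- structure(list(condition = "control", nodes = character(),
                          edges = nw$edges[0, ], r_cut = 0.8, p_cut = 0.05),
                     class = "coexpr_network")
  p2 <- export_edge_list(empty, file.path(tempdir(), "nw_empty"))
  expect_length(readLines(p2["sif"]), 0)
  expect_equal(nrow(read.delim(p2["edges"])), 0)
})

test_that("pooling restricts to the shared universe and concatenates columns", {
  sim <- generate_study_set(simulation_config(seed = 1))
  coll <- lapply(sim$datasets, collapse_duplicates)
  pooled_c <- pool_condition(coll, "control")
  pooled_d <- pool_condition(coll, "disease")
  expect_equal(ncol(pooled_c$expr), 34)
  expect_equal(ncol(pooled_d$expr), 78)
  # single study -> that study's condition submatrix
  one <- pool_condition(coll[1], "control")
  expect_equal(one$expr,
               coll[[1]]$expr[, coll[[1]]$condition == "control"])
  # restriction to a subset reorders rows to the subset
  sub <- rownames(coll[[1]]$expr)[5:1]
  expect_identical(rownames(pool_condition(coll, "disease", genes = sub)$expr),
                   sub)
  expect_error(pool_condition(coll, "disease", genes = c(sub, "NOPE")),
               "NOPE")
})
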
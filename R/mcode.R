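#' MCODE-style complex-detection parameters
#'
#' Parameterization of the seeded, density-based complex detection
#' algorithm. Defaults are the standard choices for co-expression module
#' mining: degree threshold 2, node score cutoff 0.2, k-core threshold 2,
#' maximum depth 100, haircut on, fluff off.
#'
#' @param degree_threshold minimum degree for a gene to seed a complex.
#' @param node_score_cutoff admission slack in \[0, 1\]: a neighbor joins a
#'   complex iff its weight is at least `(1 - node_score_cutoff)` times the
#'   seed's weight.
#' @param k_core_threshold complexes whose highest k-core is below this are
#'   discarded.
#' @param max_depth maximum breadth-first expansion depth from the seed.
#' @param haircut iteratively remove complex members with fewer than two
#'   within-complex connections.
#' @param fluff add neighborhood-dense boundary nodes after the haircut.
#' @param fluff_density_cutoff closed-neighborhood density above which a
#'   boundary node is fluffed in (unused when `fluff = FALSE`).
#' @return list of class `mcode_params`.
#' @export
mcode_params <- function(degree_threshold = 2, node_score_cutoff = 0.2,
                         k_core_threshold = 2, max_depth = 100,
                         haircut = TRUE, fluff = FALSE,
                         fluff_density_cutoff = 0.2) {
  if (node_score_cutoff < 0 || node_score_cutoff > 1) {
    stop("node_score_cutoff must be in [0, 1]", call. = FALSE)
  }
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (degree_threshold < 0 || k_core_threshold < 0) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  structure(list(degree_threshold = degree_threshold,
                 node_score_cutoff = node_score_cutoff,
                 k_core_threshold = k_core_threshold,
                 max_depth = max_depth, haircut = haircut, fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff),
            class = "mcode_params")
}

# adjacency list (gene -> sorted character neighbors) from a coexpr_network
# or an edge data.frame; the graph is treated as unsigned and simple.
.adjacency <- function(network) {
  e <- if (inherits(network, "coexpr_network")) network$edges else network
  nodes <- sort(unique(c(e$gene_a, e$gene_b)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) adj[[nd]] <- character()
  if (nrow(e)) {
    nb <- split(c(e$gene_b, e$gene_a), c(e$gene_a, e$gene_b))
    for (nd in names(nb)) adj[[nd]] <- sort(unique(nb[[nd]]))
  }
  adj
}

# count induced edges among `members` given a full adjacency list
.induced_edge_count <- function(members, adj) {
  if (length(members) < 2) return(0L)
  memb <- members
  sum(vapply(memb, function(m) sum(adj[[m]] %in% memb), integer(1))) %/% 2L
}

# k-core of the subgraph induced by `members`: iteratively prune nodes with
# induced degree < k until stable (own implementation; igraph::coreness is
# used only as an independent oracle in the tests)
.kcore_members <- function(members, adj, k) {
  repeat {
    if (length(members) == 0) return(character())
    deg <- vapply(members, function(m) sum(adj[[m]] %in% members), integer(1))
    keep <- deg >= k
    if (all(keep)) return(members)
    members <- members[keep]
  }
}

# highest k-core of the induced subgraph: returns list(k = max k with a
# non-empty core, members = that core); k = 0 for an edgeless vertex set
.highest_kcore <- function(members, adj) {
  best_k <- 0L
  best <- members
  k <- 1L
  repeat {
    core <- .kcore_members(members, adj, k)
    if (length(core) == 0) break
    best_k <- k
    best <- core
    members <- core
    k <- k + 1L
  }
  list(k = best_k, members = best)
}

.loop_free_density <- function(n, e) if (n < 2) 0 else 2 * e / (n * (n - 1))

#' MCODE vertex weight
#'
#' Weights a gene by the local density of its neighborhood: take the closed
#' neighborhood (the gene, its neighbors, and all induced edges), find the
#' highest k-core of that subgraph, and return `k_max` times the
#' loop-excluded density of that core. Isolated vertices score 0.
#'
#' @param network a [build_network()] result (or any edge data.frame with
#'   `gene_a`/`gene_b` columns).
#' @param gene gene id present in the network.
#' @return Non-negative weight.
#' @export
vertex_weight <- function(network, gene) {
  adj <- .adjacency(network)
  if (!gene %in% names(adj)) stop("gene not in network: ", gene, call. = FALSE)
  .vertex_weight_adj(adj, gene)
}

.vertex_weight_adj <- function(adj, gene) {
  nb <- adj[[gene]]
  if (length(nb) == 0) return(0)
  members <- c(gene, nb)
  hk <- .highest_kcore(members, adj)
  if (hk$k == 0) return(0)
  e <- .induced_edge_count(hk$members, adj)
  hk$k * .loop_free_density(length(hk$members), e)
}

#' Detect complexes by seeded greedy expansion
#'
#' Vertices are weighted by [vertex_weight()]; seeds are visited in
#' decreasing weight order (ties broken by lexicographic gene id), skipping
#' genes already absorbed into a complex and genes of degree below
#' `degree_threshold`. Each complex grows breadth-first from its seed up to
#' `max_depth` layers, admitting an unvisited neighbor iff its weight is at
#' least `weight(seed) * (1 - node_score_cutoff)`; admitted genes are marked
#' visited, so complexes are vertex-disjoint. With haircut on, members with
#' fewer than two within-complex connections are removed iteratively; with
#' fluff on, boundary neighbors whose closed-neighborhood density exceeds
#' `fluff_density_cutoff` are appended afterwards. Complexes whose highest
#' k-core falls below `k_core_threshold` are discarded. Survivors are scored
#' by loop-excluded density times node count and ranked by decreasing score
#' (ties by seed id).
#'
#' @param network a [build_network()] result or edge data.frame.
#' @param params a [mcode_params()] list.
#' @return List of `mcode_complex` objects (possibly empty), each with
#'   `genes`, `edges` (induced, loop-free), `seed_gene`, `score`, `density`,
#'   `rank`.
#' @export
predict_complexes <- function(network, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  adj <- .adjacency(network)
  nodes <- names(adj)
  if (length(nodes) == 0) return(list())
  w <- vapply(nodes, function(g) .vertex_weight_adj(adj, g), numeric(1))
  deg <- vapply(nodes, function(g) length(adj[[g]]), integer(1))
  order_idx <- order(-w, nodes)
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  complexes <- list()

  for (i in order_idx) {
    seed <- nodes[i]
    if (visited[[seed]] || deg[[seed]] < params$degree_threshold) next
    w_min <- w[[seed]] * (1 - params$node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < params$max_depth) {
      nxt <- character()
      for (f in frontier) {
        for (v in adj[[f]]) {
          if (!visited[[v]] && w[[v]] >= w_min) {
            visited[v] <- TRUE
            nxt <- c(nxt, v)
          }
        }
      }
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    if (params$haircut) members <- .kcore_members(members, adj, 2L)
    if (params$fluff && length(members)) {
      boundary <- setdiff(sort(unique(unlist(adj[members]))), members)
      fluffed <- boundary[vapply(boundary, function(v) {
        cm <- c(v, adj[[v]])
        d <- .loop_free_density(length(cm), .induced_edge_count(cm, adj))
        d > params$fluff_density_cutoff
      }, logical(1))]
      members <- c(members, fluffed)
    }
    if (length(members) == 0) next
    hk <- .highest_kcore(members, adj)
    if (hk$k < params$k_core_threshold) next
    members <- sort(members)
    n_e <- .induced_edge_count(members, adj)
    dens <- .loop_free_density(length(members), n_e)
    complexes[[length(complexes) + 1L]] <- structure(
      list(genes = members,
           edges = .induced_edges(network, members),
           seed_gene = seed,
           score = dens * length(members),
           density = dens,
           rank = NA_integer_),
      class = "mcode_complex")
  }

  if (length(complexes)) {
    scores <- vapply(complexes, `[[`, numeric(1), "score")
    seeds <- vapply(complexes, `[[`, character(1), "seed_gene")
    ord <- order(-scores, seeds)
    complexes <- complexes[ord]
    for (j in seq_along(complexes)) complexes[[j]]$rank <- j
  }
  complexes
}

# induced edge table among `members`
.induced_edges <- function(network, members) {
  e <- if (inherits(network, "coexpr_network")) network$edges else network
  keep <- e$gene_a %in% members & e$gene_b %in% members
  out <- e[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.mcode_complex <- function(x, ...) {
  cat(sprintf("mcode_complex (rank %s): %d genes, %d edges, density %.3f, score %.3f, seed %s\n",
              ifelse(is.na(x$rank), "?", x$rank), length(x$genes),
              nrow(x$edges), x$density, x$score, x$seed_gene))
  invisible(x)
}

#' Top-scoring complex
#'
#' @param complexes list from [predict_complexes()].
#' @return The rank-1 `mcode_complex` (maximum score; score ties broken by
#'   lexicographic seed id).
#' @export
top_module <- function(complexes) {
  if (length(complexes) == 0) {
    stop("no complexes detected; cannot select a top module", call. = FALSE)
  }
  complexes[[1]]
}
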
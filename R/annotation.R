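#' Read a GMT gene-set collection
#'
#' @param path GMT file (tab-separated: set name, description, member genes).
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Gene-set collection with explicit background
#'
#' Restricts every set to the background universe; sets left empty by the
#' restriction are dropped with a warning.
#'
#' @param sets named list of character gene vectors (e.g. from [read_gmt()]).
#' @param background character vector: the gene universe against which
#'   enrichment is assessed.
#' @return list of class `gene_set_collection` (`sets`, `background`).
#' @export
gene_set_collection <- function(sets, background) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  background <- unique(as.character(background))
  sets <- lapply(sets, function(s) unique(intersect(s, background)))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " set(s) empty after background restriction",
            call. = FALSE)
    sets <- sets[!empty]
  }
  if (length(sets) == 0) stop("no gene set overlaps the background", call. = FALSE)
  structure(list(sets = sets, background = background),
            class = "gene_set_collection")
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' For each set, the p-value is the upper-tail hypergeometric probability of
#' drawing at least the observed overlap when `|query|` genes are sampled
#' from the background without replacement. P-values are BH-adjusted across
#' all sets in the collection.
#'
#' @param query character vector of genes of interest; genes outside the
#'   background are dropped with a warning.
#' @param collection a [gene_set_collection()].
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return data.frame `set`, `set_size`, `overlap`, `p`, `p_adj`,
#'   `significant`, ordered by increasing `p`.
#' @export
hypergeometric_enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$background)
  if (length(outside)) {
    warning("dropping ", length(outside), " query gene(s) outside the background",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) {
    stop("query empty after restriction to the background", call. = FALSE)
  }
  n_bg <- length(collection$background)
  n_q <- length(query)
  res <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, length(set), n_bg - length(set), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build the miRNA-target regulatory network over module genes
#'
#' Restricts an interaction table to edges targeting module genes and keeps
#' only miRNAs whose resulting degree reaches `degree_cut` (`">="`
#' semantics by default; `">"` also available since database conventions
#' differ on whether a "degree cut-off" is inclusive).
#'
#' @param interactions data.frame with columns `mirna`, `gene`.
#' @param module_genes character vector of module gene ids.
#' @param degree_cut miRNA degree cutoff (default 3).
#' @param semantics `"ge"` (keep degree >= cut, default) or `"gt"`.
#' @return list of class `mirna_network`: `edges` (data.frame `mirna`,
#'   `gene`), `mirna_degree`, `gene_degree` (named integer vectors),
#'   `module_genes`.
#' @export
build_mirna_network <- function(interactions, module_genes, degree_cut = 3,
                                semantics = c("ge", "gt")) {
  semantics <- match.arg(semantics)
  stopifnot(all(c("mirna", "gene") %in% names(interactions)))
  e <- unique(interactions[interactions$gene %in% module_genes,
                           c("mirna", "gene"), drop = FALSE])
  deg <- table(e$mirna)
  keep <- if (semantics == "ge") names(deg)[deg >= degree_cut]
          else names(deg)[deg > degree_cut]
  e <- e[e$mirna %in% keep, , drop = FALSE]
  e <- e[order(e$mirna, e$gene), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(
    edges = e,
    mirna_degree = if (nrow(e)) vapply(split(e$gene, e$mirna), length, integer(1))
                   else stats::setNames(integer(), character()),
    gene_degree = if (nrow(e)) vapply(split(e$mirna, e$gene), length, integer(1))
                  else stats::setNames(integer(), character()),
    module_genes = unique(as.character(module_genes))
  ), class = "mirna_network")
}

#' Top miRNA regulators by target count
#'
#' miRNAs regulating at least `min_targets` module genes, annotated with the
#' percentage of the module gene set each covers (rounded half-up to the
#' nearest integer).
#'
#' @param network a [build_mirna_network()] result.
#' @param min_targets minimum target count (default 7).
#' @return data.frame `mirna`, `degree`, `coverage_pct`, ordered by
#'   decreasing degree then miRNA id.
#' @export
top_regulators <- function(network, min_targets = 7) {
  stopifnot(inherits(network, "mirna_network"))
  deg <- network$mirna_degree
  deg <- deg[deg >= min_targets]
  if (length(deg) == 0) {
    return(data.frame(mirna = character(), degree = integer(),
                      coverage_pct = integer(), stringsAsFactors = FALSE))
  }
  n_mod <- length(network$module_genes)
  out <- data.frame(
    mirna = names(deg), degree = as.integer(deg),
    coverage_pct = as.integer(floor(100 * as.integer(deg) / n_mod + 0.5)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$degree, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of module genes covered by a group of miRNAs
#'
#' @param network a [build_mirna_network()] result.
#' @param mirnas miRNA ids (present in the network).
#' @return Percentage (half-up integer) of module genes targeted by at least
#'   one of the miRNAs.
#' @export
target_coverage <- function(network, mirnas) {
  stopifnot(inherits(network, "mirna_network"))
  unknown <- setdiff(mirnas, names(network$mirna_degree))
  if (length(unknown)) {
    stop("unknown miRNA id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  covered <- unique(network$edges$gene[network$edges$mirna %in% mirnas])
  as.integer(floor(100 * length(covered) / length(network$module_genes) + 0.5))
}

#' Genes shared by a group of miRNAs
#'
#' @param network a [build_mirna_network()] result.
#' @param mirnas miRNA ids (present in the network).
#' @return Sorted character vector: the intersection of the miRNAs' target
#'   sets.
#' @export
shared_targets <- function(network, mirnas) {
  stopifnot(inherits(network, "mirna_network"))
  unknown <- setdiff(mirnas, names(network$mirna_degree))
  if (length(unknown)) {
    stop("unknown miRNA id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  targets <- lapply(mirnas, function(m) network$edges$gene[network$edges$mirna == m])
  sort(Reduce(intersect, targets))
}
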
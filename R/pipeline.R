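#' Pipeline configuration
#'
#' Assembles and validates the configuration for an end-to-end run. Either
#' supply `input` (paths to expression/annotation TSVs) or a `simulation`
#' block; defaults run the bundled simulator. Threshold defaults are the
#' standard analysis values: DEG adjusted-p 0.01 and fold-change 2,
#' correlation cutoff 0.8 at p < 0.05, hub fraction 5%, AUC 0.7, miRNA
#' degree cut 3, enrichment alpha 0.05.
#'
#' @param simulation a [simulation_config()] (used when `input` is NULL).
#' @param input optional list with `expression` (character vector of TSV
#'   paths) and `annotation` (single TSV path).
#' @param thresholds named list overriding any of `alpha_deg`, `fc_cut`,
#'   `r_cut`, `p_cut`, `hub_fraction`, `auc_cut`, `mirna_degree_cut`,
#'   `enrich_alpha`, `preserved_fold_cut`.
#' @param mcode a [mcode_params()] block.
#' @param mirna_interactions optional data.frame (`mirna`, `gene`) or TSV path.
#' @param gene_sets optional GMT path or named list of gene sets.
#' @param out_dir output directory.
#' @param seed master seed governing all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input = NULL,
                            thresholds = list(),
                            mcode = mcode_params(),
                            mirna_interactions = NULL,
                            gene_sets = NULL,
                            out_dir = tempfile("dcoexnet_run_"),
                            seed = 1L) {
  defaults <- list(alpha_deg = 0.01, fc_cut = 2, r_cut = 0.8, p_cut = 0.05,
                   hub_fraction = 0.05, auc_cut = 0.7, mirna_degree_cut = 3,
                   enrich_alpha = 0.05, preserved_fold_cut = 1.5)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown)) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  th <- utils::modifyList(defaults, thresholds)
  chk <- function(ok, what) if (!ok) stop("invalid threshold: ", what, call. = FALSE)
  chk(th$alpha_deg > 0 && th$alpha_deg <= 1, "alpha_deg must be in (0, 1]")
  chk(th$fc_cut >= 1, "fc_cut must be >= 1")
  chk(th$r_cut >= 0 && th$r_cut <= 1, "r_cut must be in [0, 1]")
  chk(th$p_cut > 0 && th$p_cut <= 1, "p_cut must be in (0, 1]")
  chk(th$hub_fraction > 0 && th$hub_fraction <= 1, "hub_fraction must be in (0, 1]")
  chk(th$auc_cut >= 0.5 && th$auc_cut <= 1, "auc_cut must be in [0.5, 1]")
  chk(th$mirna_degree_cut >= 0, "mirna_degree_cut must be >= 0")
  chk(th$enrich_alpha > 0 && th$enrich_alpha <= 1, "enrich_alpha must be in (0, 1]")
  chk(th$preserved_fold_cut > 0, "preserved_fold_cut must be > 0")
  stopifnot(inherits(mcode, "mcode_params"))
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_config"))
  structure(list(simulation = simulation, input = input, thresholds = th,
                 mcode = mcode, mirna_interactions = mirna_interactions,
                 gene_sets = gene_sets, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [pipeline_config()]
#' arguments (`simulation`, `input`, `thresholds`, `mcode`, `out_dir`,
#' `seed`, `mirna_interactions`, `gene_sets`) and builds a validated config.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulation_config, y$simulation)
         else if (is.null(y$input)) simulation_config() else NULL
  mc <- if (!is.null(y$mcode)) do.call(mcode_params, y$mcode) else mcode_params()
  pipeline_config(
    simulation = sim, input = y$input,
    thresholds = if (is.null(y$thresholds)) list() else y$thresholds,
    mcode = mc,
    mirna_interactions = y$mirna_interactions,
    gene_sets = y$gene_sets,
    out_dir = if (is.null(y$out_dir)) tempfile("dcoexnet_run_") else y$out_dir,
    seed = if (is.null(y$seed)) 1L else y$seed
  )
}

#' Read expression matrices and sample annotation from TSV
#'
#' Expression TSV: first column `gene_id` (duplicates allowed; they are kept
#' for [collapse_duplicates()] to handle), one column per sample, header row
#' of sample ids. Annotation TSV: columns `sample_id`, `study_id`,
#' `condition` (`control`/`disease`). One dataset is built per study.
#'
#' @param paths character vector of expression TSV paths.
#' @param annotation_path sample annotation TSV path.
#' @param impute `"none"` (default: missing values are an error) or
#'   `"row-mean"` (replace NAs by the gene's row mean).
#' @return List of [expr_dataset()] objects, one per study in annotation
#'   order.
#' @export
read_expression <- function(paths, annotation_path, impute = c("none", "row-mean")) {
  impute <- match.arg(impute)
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("sample_id", "study_id", "condition")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(ann$condition), c("control", "disease"))
  if (length(bad)) {
    stop("unknown condition label(s) in annotation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mats <- lapply(paths, function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 2 || names(df)[1] != "gene_id") {
      stop("expression TSV must start with a 'gene_id' column: ", p, call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad_cell <- which(is.na(suppressWarnings(
        matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric value in %s at row %d, column '%s'",
                   p, bad_cell[1], colnames(m)[bad_cell[2]]), call. = FALSE)
    }
    if (anyNA(m)) {
      if (impute == "none") {
        stop("missing values in ", p,
             "; re-run with impute = \"row-mean\" to fill them", call. = FALSE)
      }
      for (i in which(rowSums(is.na(m)) > 0)) {
        m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
      }
    }
    rownames(m) <- df$gene_id
    m
  })
  all_samples <- unlist(lapply(mats, colnames))
  unknown <- setdiff(all_samples, ann$sample_id)
  if (length(unknown)) {
    stop("sample(s) missing from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  lapply(unique(ann$study_id), function(sid) {
    smp <- ann$sample_id[ann$study_id == sid]
    holder <- Filter(function(m) any(smp %in% colnames(m)), mats)
    if (length(holder) == 0) stop("no expression data for study ", sid, call. = FALSE)
    m <- holder[[1]][, intersect(colnames(holder[[1]]), smp), drop = FALSE]
    cond <- ann$condition[match(colnames(m), ann$sample_id)]
    expr_dataset(m, cond, sid)
  })
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full differential co-expression pipeline
#'
#' Orchestrates every stage from one configuration: (1) simulate or read the
#' study datasets; (2) per-study differential expression and common-DEG
#' intersection; (3) condition-pooled, quantile-normalized correlation and
#' network construction for disease and control; (4) hub extraction and
#' complex detection in both networks; (5) preservation of the top disease
#' module in the control condition; (6) ROC biomarker screening of module
#' genes; (7) optional miRNA-network and gene-set enrichment stages. All
#' stage outputs are written as plain-text TSV/JSON/SIF under
#' `config$out_dir` and summarized in a run manifest.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_manifest`: `config_hash`, `versions`, `files`
#'   (named md5 digests), `summary` (per-stage counts), `timestamp`, plus a
#'   `results` element holding the in-memory stage objects.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  datasets <- .stage("data", {
    if (!is.null(config$input)) {
      read_expression(config$input$expression, config$input$annotation)
    } else {
      sim_cfg <- config$simulation
      sim_cfg$seed <- config$seed
      sim <- generate_study_set(sim_cfg)
      truth <- sim$truth
      sim$datasets
    }
  })

  degs <- .stage("diffexpr", {
    tabs <- lapply(datasets, deg_table)
    names(tabs) <- vapply(datasets, function(d) d$study_id, character(1))
    for (sid in names(tabs)) {
      utils::write.table(tabs[[sid]],
                         file.path(out_dir, paste0("deg_", sid, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tabs
  })
  deg_sets <- lapply(degs, select_degs, alpha = th$alpha_deg, fc_cut = th$fc_cut)
  common <- .stage("common_degs", {
    cm <- intersect_common(deg_sets)
    writeLines(cm, file.path(out_dir, "common_degs.txt"))
    cm
  })
  if (length(common) < 3) {
    stop("pipeline stage 'common_degs' failed: only ", length(common),
         " common DEG(s); cannot build a co-expression network", call. = FALSE)
  }

  collapsed <- lapply(datasets, collapse_duplicates)
  nets <- list(); corrs <- list()
  for (cond in c("disease", "control")) {
    corrs[[cond]] <- .stage(paste0("correlate_", cond), {
      # quantile-normalize over the full gene universe (RMA-style, whole-array
      # normalization), then restrict to the common DEGs for correlation
      pooled <- pool_condition(collapsed, cond)
      correlate(quantile_normalize(pooled$expr)[common, , drop = FALSE])
    })
    nets[[cond]] <- .stage(paste0("network_", cond), {
      nw <- build_network(corrs[[cond]], th$r_cut, th$p_cut, cond)
      export_edge_list(nw, file.path(out_dir, paste0("network_", cond)),
                       th$hub_fraction)
      nw
    })
  }

  hubs <- lapply(nets, function(nw) {
    if (length(nw$nodes)) select_hubs(nw, th$hub_fraction)
    else data.frame(gene = character(), degree = integer())
  })

  complexes <- .stage("mcode", lapply(nets, predict_complexes, params = config$mcode))
  module <- .stage("top_module", top_module(complexes$disease))
  jsonlite::write_json(
    lapply(complexes$disease, function(cx)
      list(genes = cx$genes, seed = cx$seed_gene, score = cx$score,
           density = cx$density, rank = cx$rank)),
    file.path(out_dir, "complexes_disease.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  preservation <- .stage("preservation", {
    rep <- module_preservation(module, corrs$control, th$r_cut, th$p_cut,
                               preserved_fold_cut = th$preserved_fold_cut)
    jsonlite::write_json(unclass(rep), file.path(out_dir, "preservation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })

  roc <- .stage("roc", {
    tab <- screen_biomarkers(collapsed, module$genes, th$auc_cut)
    utils::write.table(tab, file.path(out_dir, "biomarker_auc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })
  biomarkers <- roc$gene_id[roc$passes]

  mirna <- NULL
  if (!is.null(config$mirna_interactions)) {
    mirna <- .stage("mirna", {
      ia <- config$mirna_interactions
      if (is.character(ia)) ia <- utils::read.delim(ia, stringsAsFactors = FALSE)
      nw <- build_mirna_network(ia, biomarkers, th$mirna_degree_cut)
      utils::write.table(nw$edges, file.path(out_dir, "mirna_network.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      nw
    })
  }

  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- .stage("enrichment", {
      sets <- config$gene_sets
      if (is.character(sets)) sets <- read_gmt(sets)
      coll <- gene_set_collection(sets, rownames(collapsed[[1]]$expr))
      tab <- hypergeometric_enrich(common, coll, th$enrich_alpha)
      utils::write.table(tab, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
  }

  summary <- list(
    n_studies = length(datasets),
    degs_per_study = vapply(deg_sets, nrow, integer(1)),
    n_common_degs = length(common),
    network = lapply(nets, function(nw)
      list(nodes = length(nw$nodes), edges = nrow(nw$edges))),
    n_hubs = vapply(hubs, nrow, integer(1)),
    module_size = length(module$genes),
    module_density = module$density,
    preservation_fold = preservation$fold_change,
    n_biomarkers = length(biomarkers)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_file <- tempfile(fileext = ".rds")
  saveRDS(config[setdiff(names(config), "out_dir")], cfg_file, version = 2)
  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  manifest <- structure(list(
    config_hash = unname(tools::md5sum(cfg_file)),
    versions = list(dcoexnet = as.character(utils::packageVersion("dcoexnet")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    files = stats::setNames(unname(tools::md5sum(files)),
                            basename(files)),
    summary = summary,
    timestamp = format(Sys.time(), tz = "UTC"),
    results = list(datasets = datasets, truth = truth, degs = degs,
                   common_degs = common, correlations = corrs,
                   networks = nets, hubs = hubs, complexes = complexes,
                   module = module, preservation = preservation, roc = roc,
                   mirna = mirna, enrichment = enrichment)
  ), class = "run_manifest")
  unlink(cfg_file)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  s <- x$summary
  cat("dcoexnet run manifest\n")
  cat(sprintf("  studies: %d; common DEGs: %d\n", s$n_studies, s$n_common_degs))
  cat(sprintf("  disease network: %d nodes / %d edges; control: %d / %d\n",
              s$network$disease$nodes, s$network$disease$edges,
              s$network$control$nodes, s$network$control$edges))
  cat(sprintf("  top module: %d genes, density %.3f; preservation fold %s\n",
              s$module_size, s$module_density,
              if (is.finite(s$preservation_fold))
                sprintf("%.1f", s$preservation_fold) else "Inf"))
  cat(sprintf("  biomarkers passing AUC gate: %d\n", s$n_biomarkers))
  invisible(x)
}
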
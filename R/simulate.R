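#' Configuration for the multi-study expression simulator
#'
#' Defines the study conditions the generator emulates: several independent
#' two-group microarray studies over a shared gene universe, a planted set of
#' differentially expressed genes, and a disease-only latent-factor
#' co-expression module mixing positively and negatively loaded genes.
#'
#' Defaults mirror a three-study serous-adenocarcinoma-style meta-analysis
#' design: per-study group sizes 12/13, 12/12 and 10/53 (control/disease,
#' pooling to 34 control and 78 disease samples), a 17-gene module of which
#' 4 genes load negatively, and a factor loading of three noise standard
#' deviations so that planted within-module correlations sit near
#' \eqn{\lambda^2 / (\lambda^2 + \sigma^2) = 0.9}, above the 0.8 network
#' cutoff.
#'
#' @param n_studies number of studies (>= 1).
#' @param genes_total size of the shared gene universe.
#' @param gene_ids optional character vector of gene ids; auto-generated
#'   `"G0001"...` otherwise.
#' @param samples_control,samples_disease integer vectors of per-study group
#'   sizes (length `n_studies`, all >= 2).
#' @param frac_de fraction of genes with a planted fold-change, in \[0, 1\].
#' @param log2fc_magnitude planted |log2 fold-change| in disease (log2 units).
#' @param module_size number of genes in the planted co-expression module.
#'   Must not exceed `genes_total * frac_de`: module genes are all DE, so
#'   they survive to the network stage after the common-DEG intersection.
#' @param module_neg_fraction fraction of module genes with negative factor
#'   loading, in \[0, 1).
#' @param factor_loading positive loading of module genes on the per-sample
#'   latent factor (log2 units per factor SD).
#' @param noise_sd independent per-measurement noise SD (log2 units), > 0.
#' @param baseline_mean center of the gene baseline distribution (log2 units).
#' @param gene_baseline_sd SD of per-gene baseline levels around
#'   `baseline_mean` (log2 units, >= 0). Genes on real arrays span several
#'   log2 units of constitutive expression; spreading baselines keeps every
#'   column's value distribution dense, so quantile normalization is a
#'   near-identity map as it is on whole-array data.
#' @param seed master integer seed; per-study streams are derived from it by
#'   fixed offsets so adding a study does not perturb earlier ones.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_studies = 3,
                              genes_total = 500,
                              gene_ids = NULL,
                              samples_control = c(12, 12, 10),
                              samples_disease = c(13, 12, 53),
                              frac_de = 0.2,
                              log2fc_magnitude = 3,
                              module_size = 17,
                              module_neg_fraction = 4 / 17,
                              factor_loading = 1.5,
                              noise_sd = 0.5,
                              baseline_mean = 8,
                              gene_baseline_sd = 2,
                              seed = 1L) {
  cfg <- list(
    n_studies = as.integer(n_studies), genes_total = as.integer(genes_total),
    gene_ids = gene_ids,
    samples_control = as.integer(samples_control),
    samples_disease = as.integer(samples_disease),
    frac_de = frac_de, log2fc_magnitude = log2fc_magnitude,
    module_size = as.integer(module_size),
    module_neg_fraction = module_neg_fraction,
    factor_loading = factor_loading, noise_sd = noise_sd,
    baseline_mean = baseline_mean, gene_baseline_sd = gene_baseline_sd,
    seed = as.integer(seed)
  )
  fail <- function(msg) stop("invalid simulation_config: ", msg, call. = FALSE)
  if (cfg$n_studies < 1) fail("n_studies must be >= 1")
  if (cfg$genes_total < 2) fail("genes_total must be >= 2")
  if (length(cfg$samples_control) != cfg$n_studies ||
      length(cfg$samples_disease) != cfg$n_studies) {
    fail("samples_control and samples_disease must have one entry per study")
  }
  if (any(c(cfg$samples_control, cfg$samples_disease) < 2)) {
    fail("all per-study group sizes must be >= 2")
  }
  if (cfg$frac_de < 0 || cfg$frac_de > 1) fail("frac_de must be in [0, 1]")
  if (cfg$module_size < 2) fail("module_size must be >= 2")
  if (cfg$module_size > cfg$genes_total * cfg$frac_de) {
    fail("module_size exceeds genes_total * frac_de (module genes must all be DE)")
  }
  if (cfg$module_neg_fraction < 0 || cfg$module_neg_fraction >= 1) {
    fail("module_neg_fraction must be in [0, 1)")
  }
  if (cfg$noise_sd <= 0) fail("noise_sd must be > 0")
  if (cfg$gene_baseline_sd < 0) fail("gene_baseline_sd must be >= 0")
  if (cfg$factor_loading < 0) fail("factor_loading must be >= 0")
  if (cfg$log2fc_magnitude < 0) fail("log2fc_magnitude must be >= 0")
  if (!is.null(gene_ids)) {
    if (length(gene_ids) != cfg$genes_total || anyDuplicated(gene_ids)) {
      fail("gene_ids must be genes_total unique identifiers")
    }
  }
  structure(cfg, class = "simulation_config")
}

# fixed per-study offset for derived RNG streams; < 2^31 for any sane seed
.study_seed <- function(seed, study) (seed + 99991L * study) %% .Machine$integer.max

#' Simulate a multi-study two-condition expression set with ground truth
#'
#' Every gene is baseline plus independent Gaussian noise. Planted DE genes
#' are shifted by their signed log2 fold-change in disease samples. Module
#' genes additionally receive `sign_g * factor_loading * z_s` in disease
#' samples only, where `z_s ~ N(0, 1)` is a latent factor shared by all
#' module genes within a sample (drawn independently per study). Control
#' samples are pure noise, so the planted module is not preserved in the
#' control condition.
#'
#' @param config a [simulation_config()].
#' @return A list with elements
#'   \describe{
#'     \item{datasets}{list of [expr_dataset()] objects, one per study;}
#'     \item{truth}{ground-truth record: `de_genes` (per-study named vectors of
#'       signed log2 fold-changes), `module_genes`, `module_signs` (named +1/-1),
#'       and `seed`.}
#'   }
#' @export
generate_study_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- config$gene_ids
  if (is.null(ids)) {
    ids <- sprintf("G%04d", seq_len(config$genes_total))
  }
  n_de <- round(config$genes_total * config$frac_de)

  # global design choices (which genes are DE / in the module) use the master
  # seed; the same DE set is planted in every study so that the module
  # survives the cross-study intersection.
  set.seed(config$seed)
  de_idx <- sort(sample.int(config$genes_total, n_de))
  de_genes <- ids[de_idx]
  module_genes <- sort(sample(de_genes, config$module_size))
  n_neg <- round(config$module_size * config$module_neg_fraction)
  neg_genes <- sample(module_genes, n_neg)
  module_signs <- stats::setNames(rep(1, config$module_size), module_genes)
  module_signs[neg_genes] <- -1
  de_signs <- stats::setNames(sample(c(-1, 1), n_de, replace = TRUE), de_genes)
  # module genes' DE direction follows their loading sign (up-regulated genes
  # load positively), keeping the planted structure interpretable
  de_signs[module_genes] <- module_signs[module_genes]
  de_lfc <- de_signs * config$log2fc_magnitude
  # per-gene constitutive levels, shared by all studies and both conditions
  baselines <- stats::rnorm(config$genes_total, config$baseline_mean,
                            config$gene_baseline_sd)

  datasets <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    set.seed(.study_seed(config$seed, s))
    n_c <- config$samples_control[s]
    n_d <- config$samples_disease[s]
    n <- n_c + n_d
    study_id <- sprintf("study%d", s)
    smp <- sprintf("%s_%s%02d", study_id,
                   rep(c("C", "D"), c(n_c, n_d)),
                   c(seq_len(n_c), seq_len(n_d)))
    cond <- rep(c("control", "disease"), c(n_c, n_d))
    x <- baselines + matrix(stats::rnorm(config$genes_total * n,
                                         mean = 0, sd = config$noise_sd),
                            nrow = config$genes_total, ncol = n,
                            dimnames = list(ids, smp))
    dis <- which(cond == "disease")
    x[de_genes, dis] <- x[de_genes, dis] + de_lfc[de_genes]
    z <- stats::rnorm(n_d)  # latent factor, one value per disease sample
    x[module_genes, dis] <- x[module_genes, dis] +
      config$factor_loading * outer(module_signs[module_genes], z)
    datasets[[s]] <- expr_dataset(x, cond, study_id)
  }

  truth <- list(
    de_genes = stats::setNames(
      rep(list(de_lfc), config$n_studies),
      vapply(datasets, function(d) d$study_id, character(1))),
    module_genes = module_genes,
    module_signs = module_signs,
    seed = config$seed
  )
  list(datasets = datasets, truth = truth)
}

#' Simulate a miRNA-target interaction table
#'
#' Builds a bipartite interaction fixture: miRNA `i` targets exactly
#' `degree_profile[i]` distinct genes, sampled without replacement from
#' `module_genes`. Deterministic for a fixed seed.
#'
#' @param module_genes character vector of target gene ids.
#' @param n_mirnas number of miRNAs.
#' @param degree_profile integer vector (length `n_mirnas`) of per-miRNA
#'   target counts; each must be <= `length(module_genes)`.
#' @param seed integer seed.
#' @return data.frame with columns `mirna`, `gene`.
#' @export
generate_mirna_interactions <- function(module_genes, n_mirnas, degree_profile,
                                        seed = 1L) {
  if (length(degree_profile) != n_mirnas) {
    stop("degree_profile must have one entry per miRNA", call. = FALSE)
  }
  if (any(degree_profile > length(module_genes))) {
    stop("degree_profile entries must not exceed the number of target genes",
         call. = FALSE)
  }
  if (any(degree_profile < 0)) stop("degrees must be >= 0", call. = FALSE)
  set.seed(seed)
  rows <- lapply(seq_len(n_mirnas), function(i) {
    k <- degree_profile[i]
    if (k == 0) return(NULL)
    data.frame(mirna = sprintf("miR-%03d", i),
               gene = sample(module_genes, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna = character(), gene = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write simulated datasets and ground truth to plain-text fixtures
#'
#' Writes one expression TSV per study (first column `gene_id`, then one
#' column per sample), a single sample-annotation TSV (`sample_id`,
#' `study_id`, `condition`) and the ground truth as JSON. The files
#' round-trip through [read_expression()].
#'
#' @param datasets list of [expr_dataset()] objects (non-empty).
#' @param truth ground-truth record from [generate_study_set()].
#' @param out_dir output directory (created if needed).
#' @return Named list of written file paths (`expression`, `annotation`,
#'   `truth`).
#' @export
write_fixtures <- function(datasets, truth, out_dir) {
  if (length(datasets) == 0) stop("no datasets to write", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir, call. = FALSE)
  expr_paths <- vapply(datasets, function(d) {
    p <- file.path(out_dir, paste0("expression_", d$study_id, ".tsv"))
    df <- data.frame(gene_id = rownames(d$expr), d$expr,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  ann <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(sample_id = colnames(d$expr), study_id = d$study_id,
               condition = unname(d$condition), stringsAsFactors = FALSE)
  }))
  ann_path <- file.path(out_dir, "samples.tsv")
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(expression = unname(expr_paths), annotation = ann_path,
       truth = truth_path)
}
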
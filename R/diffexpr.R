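#' Two-group linear fit per gene
#'
#' Ordinary least squares for the two-group design: per-gene log2
#' fold-change (disease mean minus control mean), pooled within-group
#' residual variance, and residual degrees of freedom.
#'
#' @param dataset an [expr_dataset()] with unique gene ids.
#' @return data.frame with columns `gene_id`, `log2fc`, `s_sq` (pooled
#'   residual variance) and `df` (residual degrees of freedom,
#'   `n_control + n_disease - 2`, identical for every gene).
#' @export
fit_two_group <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  ctrl <- dataset$expr[, dataset$condition == "control", drop = FALSE]
  dis <- dataset$expr[, dataset$condition == "disease", drop = FALSE]
  n_c <- ncol(ctrl); n_d <- ncol(dis)
  if (n_c < 2 || n_d < 2) {
    stop("each condition needs >= 2 samples to estimate variance", call. = FALSE)
  }
  mu_c <- rowMeans(ctrl); mu_d <- rowMeans(dis)
  ss_c <- rowSums((ctrl - mu_c)^2)
  ss_d <- rowSums((dis - mu_d)^2)
  df <- n_c + n_d - 2L
  data.frame(
    gene_id = rownames(dataset$expr),
    log2fc = mu_d - mu_c,
    s_sq = (ss_c + ss_d) / df,
    df = df,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# invert the (strictly decreasing) trigamma function: find x with
# trigamma(x) = y, by bisection on (1e-6, 1e7) to relative tolerance 1e-8.
.trigamma_inverse <- function(y) {
  lo <- 1e-6; hi <- 1e7
  if (y >= trigamma(lo)) return(lo)
  if (y <= trigamma(hi)) return(Inf)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if ((hi - lo) / hi < 1e-8) break
  }
  sqrt(lo * hi)
}

#' Empirical-Bayes prior for gene-wise variances
#'
#' Fits the scaled inverse chi-square prior `s_g^2 ~ s0^2 d0 / chisq(d0)`
#' by method of moments on the log variances: with
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom solve `trigamma(d0/2) = var(e_g) - trigamma(d_g/2)` (right side
#' floored at zero; trigamma is strictly decreasing so the root is found by
#' bisection), and `s0^2 = exp(mean(e_g) + digamma(d0/2) - log(d0/2))`. When
#' the observed spread of log variances does not exceed its sampling
#' expectation, `d0 = Inf` and `s0^2` is the pooled (arithmetic mean)
#' variance.
#'
#' @param s_sq numeric vector of per-gene residual variances (>= 10 positive
#'   values required).
#' @param df residual degrees of freedom (scalar, or vector per gene).
#' @param tol threshold below which the excess spread is treated as zero.
#' @return list of class `moderation_prior` with elements `d0` and `s0_sq`.
#' @export
estimate_prior <- function(s_sq, df, tol = 1e-8) {
  if (all(s_sq <= 0)) {
    stop("all gene variances are zero; apply a variance floor or check input",
         call. = FALSE)
  }
  pos <- s_sq > 0
  if (sum(pos) < 10) {
    stop("need >= 10 genes with positive variance to fit the prior", call. = FALSE)
  }
  s_sq <- s_sq[pos]
  d <- if (length(df) == 1) rep(df, length(s_sq)) else df[pos]
  e <- log(s_sq) - digamma(d / 2) + log(d / 2)
  rhs <- max(0, stats::var(e) - mean(trigamma(d / 2)))
  if (rhs <= tol) {
    d0 <- Inf
    s0_sq <- mean(s_sq)  # no excess spread: pool the variances directly
  } else {
    d0 <- 2 * .trigamma_inverse(rhs)
    if (d0 >= 1e7) {
      d0 <- Inf
      s0_sq <- mean(s_sq)
    } else {
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

#' Moderated t-statistic and p-value
#'
#' Shrinks each gene's variance toward the prior,
#' `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` (equal to `s0^2` when
#' `d0 = Inf`), and tests `log2fc = 0` with
#' `t = log2fc / sqrt(s_tilde^2 (1/n_c + 1/n_d))` on `d0 + d_g` degrees of
#' freedom (a normal tail when `d0 = Inf`).
#'
#' @param log2fc,s_sq numeric vectors from [fit_two_group()].
#' @param df residual degrees of freedom.
#' @param prior a [estimate_prior()] result.
#' @param n_control,n_disease group sizes.
#' @return data.frame with columns `t_mod`, `p_raw` and logical
#'   `zero_variance` flagging degenerate genes (moderated variance exactly
#'   zero, for which `p_raw = 0` with a warning).
#' @export
moderated_t <- function(log2fc, s_sq, df, prior, n_control, n_disease) {
  stopifnot(inherits(prior, "moderation_prior"))
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (is.infinite(d0)) {
    s_tilde <- rep(s0, length(s_sq))
    df_total <- Inf
  } else {
    s_tilde <- (d0 * s0 + df * s_sq) / (d0 + df)
    df_total <- d0 + df
  }
  se <- sqrt(s_tilde * (1 / n_control + 1 / n_disease))
  zero <- se == 0
  t_mod <- ifelse(zero, ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
                  log2fc / ifelse(zero, 1, se))
  p <- if (is.infinite(d0)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  p[zero & log2fc != 0] <- 0
  p[zero & log2fc == 0] <- 1
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero moderated variance; p set to 0/1",
            call. = FALSE)
  }
  data.frame(t_mod = t_mod, p_raw = p, zero_variance = zero,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment controlling the false discovery rate, applied across
#' all genes of one study.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-study differential expression table
#'
#' Runs the full single-study pipeline: collapse duplicate gene ids, fit the
#' two-group model, estimate the variance prior, compute moderated (or
#' Welch) t-statistics, and adjust p-values by Benjamini-Hochberg across all
#' genes of the study.
#'
#' @param dataset an [expr_dataset()].
#' @param stat `"moderated"` (empirical-Bayes moderated t, default) or
#'   `"welch"` (unequal-variance t as a robustness fallback).
#' @return data.frame with one row per gene: `gene_id`, `log2fc`, `t_mod`,
#'   `p_raw`, `p_adj`, `direction` (`"up"` iff `log2fc > 0`).
#' @export
deg_table <- function(dataset, stat = c("moderated", "welch")) {
  stat <- match.arg(stat)
  dataset <- collapse_duplicates(dataset)
  fit <- fit_two_group(dataset)
  n_c <- sum(dataset$condition == "control")
  n_d <- sum(dataset$condition == "disease")
  if (stat == "moderated") {
    prior <- estimate_prior(fit$s_sq, fit$df[1])
    mt <- moderated_t(fit$log2fc, fit$s_sq, fit$df, prior, n_c, n_d)
    t_stat <- mt$t_mod; p_raw <- mt$p_raw
  } else {
    ctrl <- dataset$expr[, dataset$condition == "control", drop = FALSE]
    dis <- dataset$expr[, dataset$condition == "disease", drop = FALSE]
    v_c <- apply(ctrl, 1, stats::var) / n_c
    v_d <- apply(dis, 1, stats::var) / n_d
    se <- sqrt(v_c + v_d)
    t_stat <- ifelse(se == 0, 0, fit$log2fc / se)
    df_w <- (v_c + v_d)^2 / (v_c^2 / (n_c - 1) + v_d^2 / (n_d - 1))
    p_raw <- 2 * stats::pt(-abs(t_stat), df = df_w)
    p_raw[se == 0 & fit$log2fc != 0] <- 0
    p_raw[se == 0 & fit$log2fc == 0] <- 1
  }
  data.frame(
    gene_id = fit$gene_id,
    log2fc = fit$log2fc,
    t_mod = t_stat,
    p_raw = p_raw,
    p_adj = bh_adjust(p_raw),
    direction = ifelse(fit$log2fc > 0, "up", "down"),
    stringsAsFactors = FALSE
  )
}

#' Apply significance and fold-change gates to a DEG table
#'
#' A gene is a DEG iff `p_adj < alpha` and its linear-scale fold change
#' `2^|log2fc|` is at least `fc_cut` (at the default `fc_cut = 2` this is
#' `|log2fc| >= 1`).
#'
#' @param records a [deg_table()] result.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param fc_cut linear fold-change cutoff (default 2).
#' @return The subset of `records` passing both gates.
#' @export
select_degs <- function(records, alpha = 0.01, fc_cut = 2) {
  stopifnot(all(c("gene_id", "log2fc", "p_adj") %in% names(records)))
  keep <- records$p_adj < alpha & 2^abs(records$log2fc) >= fc_cut
  records[keep, , drop = FALSE]
}

#' Intersect DEG sets across studies
#'
#' Exact set intersection of gene ids over two or more studies. By default
#' the intersection is direction-agnostic (a gene's regulation direction may
#' differ between studies and is recorded, not filtered); with
#' `concordant = TRUE` only genes sharing the same direction in every study
#' are kept.
#'
#' @param deg_sets list (one per study) of either character gene-id vectors
#'   or [select_degs()] data.frames. Data.frames are required when
#'   `concordant = TRUE`.
#' @param concordant require the same up/down direction in every study.
#' @return Character vector of common gene ids (sorted). Empty with a
#'   warning if the intersection is empty.
#' @export
intersect_common <- function(deg_sets, concordant = FALSE) {
  if (length(deg_sets) < 2) stop("need >= 2 studies to intersect", call. = FALSE)
  ids <- lapply(deg_sets, function(s) {
    if (is.data.frame(s)) s$gene_id else as.character(s)
  })
  common <- sort(Reduce(intersect, ids))
  if (concordant) {
    if (!all(vapply(deg_sets, is.data.frame, logical(1)))) {
      stop("concordant intersection needs DEG tables with a direction column",
           call. = FALSE)
    }
    dirs <- sapply(deg_sets, function(s) {
      s$direction[match(common, s$gene_id)]
    })
    if (length(common) == 1) dirs <- matrix(dirs, nrow = 1)
    same <- apply(dirs, 1, function(r) length(unique(r)) == 1)
    common <- common[same]
  }
  if (length(common) == 0) {
    warning("no common DEGs across studies", call. = FALSE)
  }
  common
}
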
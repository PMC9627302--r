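---
title: "Differential co-expression module discovery and biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression module discovery and biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcoexnet)
```

# The analysis

`dcoexnet` implements a differential gene co-expression workflow for
two-condition transcriptome data, of the kind used to mine candidate
biomarkers from multi-study microarray meta-analyses. The premise is that a
disease state can rewire the *co-variation* between genes even where single
gene shifts are unremarkable: a group of genes that is tightly
inter-correlated in tumors but uncoupled in healthy tissue is a candidate
disease module, and its members candidate diagnostic markers.

The pipeline runs in six stages:

1. **Per-study differential expression.** Each study is a log2 gene-by-sample
   matrix with control/disease labels. Duplicate gene ids (multiple probes
   per symbol) are collapsed to their mean profile. A two-group linear model
   gives each gene a log2 fold-change and a pooled residual variance;
   variances are shrunk toward an empirical-Bayes prior and tested with
   moderated t-statistics (see below). P-values are Benjamini–Hochberg
   adjusted per study, and genes pass with adjusted p < 0.01 and linear
   fold-change ≥ 2. The **common DEGs** are the exact intersection of the
   per-study DEG sets (direction-agnostic by default; a direction-concordant
   variant is available via `intersect_common(concordant = TRUE)`).
2. **Condition-specific co-expression networks.** Samples of each condition
   are pooled across studies, the pooled matrix is quantile-normalized, and
   Pearson correlations are computed between all common-DEG pairs. An edge
   requires |r| > 0.8 with asymptotic p < 0.05
   (t = r√(n−2)/√(1−r²) on n−2 df). Edge signs are stored, but all topology
   (degree, density, module detection) treats the graph as unsigned.
3. **Hubs and modules.** Hubs are the top 5% of nodes by degree, extended
   through ties. Dense modules are found with a from-scratch implementation
   of the MCODE seeded complex-detection algorithm (vertex weighting by the
   highest k-core of the closed neighborhood, greedy weighted expansion,
   haircut post-processing, loop-excluded scoring) at parameters 2 / 0.2 /
   2 / 100 with haircut on and fluff off.
4. **Module preservation.** The top disease module's gene pairs are
   re-tested in the control condition under the same significance criteria.
   The preservation verdict compares densities: the control-side density is
   computed over the genes participating in at least one significant
   control-side edge, and the module counts as non-preserved when the
   disease/control density ratio is at least 1.5.
5. **Biomarker screening.** Each module gene is scored by the area under
   the ROC curve for separating disease from control samples, computed by
   the rank (Mann–Whitney) formulation with half-credit for ties.
   Orientation-free AUC = max(AUC, 1 − AUC) ≥ 0.7 passes, so up- and
   down-regulated markers are treated symmetrically.
6. **Annotation.** Passing genes can be mapped to miRNA regulators
   (bipartite network filtered at a degree cutoff of 3, top regulators at
   ≥ 7 targets) and tested for gene-set enrichment with the hypergeometric
   upper tail and BH correction against a user-supplied GMT collection.

`run_all()` executes all stages from one `pipeline_config()` and writes
plain-text artifacts (TSV/JSON/SIF) plus a manifest of file digests so
reruns can be verified byte-for-byte.

# The moderated t-statistic

For gene $g$ with pooled two-group variance $s_g^2$ on $d_g$ degrees of
freedom, the prior $s_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ is fit by method of
moments on $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$:
$\mathrm{trigamma}(d_0/2) = \max(0, \mathrm{var}(e_g) -
\mathrm{trigamma}(d_g/2))$, inverted by bisection on $(10^{-6}, 10^7)$
(relative tolerance $10^{-8}$; roots beyond $10^7$ are treated as
$d_0 = \infty$), and $s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$.
When the log-variance spread does not exceed its sampling expectation the
prior degrees of freedom are infinite and $s_0^2$ is the arithmetic mean of
the variances — every gene is then tested against the common variance with
a normal tail. Otherwise the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ enters
$t_g = \hat\beta_g / \sqrt{\tilde s_g^2 (1/n_c + 1/n_d)}$ on $d_0 + d_g$
degrees of freedom. Genes with exactly zero moderated variance are flagged
rather than dividing by zero. A Welch-t fallback (`deg_table(stat =
"welch")`) is available as a robustness check.

# What the synthetic generator emulates

`generate_study_set()` produces the multi-study two-condition design the
pipeline expects, with full ground truth. Its defaults define the study
conditions used throughout the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| `n_studies` | 3 | independent studies over a shared gene universe |
| `samples_control` / `samples_disease` | 12/12/10 and 13/12/53 | per-study group sizes; pooling gives 34 control and 78 disease samples |
| `genes_total` | 500 | gene universe |
| `frac_de` | 0.2 | fraction of genes with a planted fold-change |
| `log2fc_magnitude` | 3 | planted \|log2 FC\| in disease |
| `module_size` | 17 | planted co-expression module (all module genes are DE) |
| `module_neg_fraction` | 4/17 | module genes with negative factor loading |
| `factor_loading` | 1.5 | loading on the per-sample latent factor |
| `noise_sd` | 0.5 | independent measurement noise |
| `baseline_mean`, `gene_baseline_sd` | 8, 2 | per-gene constitutive levels |

Every value is baseline + Gaussian noise; DE genes get a signed constant
shift in disease; module genes additionally receive
$\mathrm{sign}_g \cdot \lambda \cdot z_s$ in **disease samples only**,
where $z_s \sim N(0,1)$ is shared by all module genes of a sample and drawn
independently per study. Two same-signed module genes therefore correlate
at $\lambda^2/(\lambda^2+\sigma^2) = 0.9$ in disease (opposite signs at
−0.9), while control samples are independent noise, so the module is
non-preserved by construction. Per-study RNG streams are derived from the
master seed by fixed offsets, so adding a study never perturbs earlier
ones, and a fixed seed reproduces matrices bit-for-bit.

Three defaults deserve their rationale:

* **`log2fc_magnitude = 3`.** The latent factor moves a whole sign-group's
  *estimated* fold-change by $\lambda \bar z$, whose SD reaches ≈ 0.43 at
  n = 12. The planted shift must dominate that term (and the
  factor-inflated within-group variance) so that module genes reliably
  clear the adjusted-p 0.01 / FC 2 gates in *every* study — the generator's
  contract is that planted module genes are DE and survive to the network
  stage.
* **`gene_baseline_sd = 2`.** Genes on real arrays span several log2 units
  of constitutive expression. Spreading baselines keeps each column's value
  distribution dense, so quantile normalization behaves as it does on
  whole-array data. With all baselines equal, the module genes alone occupy
  the sparse distribution tails and quantile normalization clips precisely
  the latent-factor signal being planted.
* **Normalization order.** `run_all()` quantile-normalizes the pooled
  matrix over the **full gene universe** and only then restricts rows to
  the common DEGs for correlation. This mirrors RMA-style processing, where
  quantile normalization acts on whole arrays before any gene selection;
  normalizing the ~100-gene restricted matrix instead makes the map between
  a column's ranks and the reference distribution so coarse that planted
  correlations of 0.9 routinely fall below the 0.8 edge threshold.

What the generator does **not** emulate: probe-level effects, batch and
platform artifacts, correlated background co-expression, heavy-tailed
noise, or missingness. Passing tests therefore demonstrate that the
pipeline recovers the structure it targets under a clean generative model,
not that any particular real dataset will yield stable modules.

# Numerical and design choices

* **Correlation degeneracies.** |r| = 1 yields p = 0 rather than a division
  error; zero-variance genes are excluded from correlation with a warning;
  fewer than three pooled samples is an error.
* **Density.** Always 2E/(N(N−1)) on the simple loop-free graph; reports
  round to 3 decimals, internal values keep full precision.
* **Preservation denominator.** The control-side density divides by the
  count of module genes *participating* in significant control-side edges
  (a 17-gene module with 33 surviving edges among 13 participating genes
  scores 2·33/(13·12) = 0.423, 2.2-fold below a 0.919 disease density);
  `denominator = "module"` switches to the full module size.
* **MCODE determinism.** Seed order is by decreasing vertex weight with
  lexicographic gene-id tie-breaks; score ties rank by seed id; results are
  invariant to edge-list order. `max_depth` counts BFS layers (100 is
  effectively unlimited at this scale); complexes whose highest k-core is
  below 2 — including everything smaller than a triangle — are discarded.
* **Hub ties.** k = ⌈0.05·N⌉ top-degree nodes, extended to all nodes tied
  with the k-th degree, so hub counts can exceed the nominal 5% whenever
  the degree distribution is tied at the cut.
* **miRNA degree cutoff.** "Degree cutoff 3" is read inclusively
  (keep degree ≥ 3); strict `>` semantics are available, since database
  conventions differ. Coverage percentages round half-up.
* **BH scope.** Adjustment is per study across all genes of that study's
  matrix (matching independent per-dataset analyses), and per collection
  for enrichment.
* **Missing values.** Ingest fails by default; `read_expression(impute =
  "row-mean")` opts into imputation.

# Problem sizes

The bundled tests and the acceptance script run entirely on simulated
data: three studies of 500 genes × 25–63 samples for the default
conditions (seconds per run), 150-gene two-study configurations for smoke
tests, a 20-seed recovery study, a 20-seed null-calibration study of 1,000
genes at 12 vs 12, and a 5,000-gene prior-recovery simulation. A full
`run_all()` at the default conditions takes well under a second of compute.

# Known limitations

* Two-group designs only — no covariates, pairing, or multi-factor models.
* Pearson correlation only; no partial correlation, soft-thresholding, or
  information-theoretic association.
* Preservation is a density ratio with an operational 1.5-fold cutoff, not
  a permutation statistic with a null distribution.
* Enrichment requires a user-supplied GMT; no database access is attempted,
  so external-database pathway hit-lists are not reproduced numerically.
* The latent-factor module model is single-factor and disease-only by
  design; overlapping or partially preserved modules are not generated.
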
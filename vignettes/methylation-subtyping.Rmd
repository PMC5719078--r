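---
title: "Methylation subtyping with methsub: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation subtyping with methsub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methsub)
```

`methsub` discovers and classifies DNA-hypomethylation subtypes of tumors
from Illumina 450k/27k beta-value matrices, integrating expression,
somatic mutation and GISTIC copy-number calls. This vignette is the
package's account of its statistical machinery: the models, the tunable
parameters and why their defaults are what they are, what the synthetic
cohort generator does and does not emulate, and the numerical decisions a
maintainer should know about.

## The beta-mixture model of abnormal methylation

A beta value $\beta \in [0,1]$ is the methylated fraction of a CpG site
in a bulk sample. Within a gene, neighboring CpG probes are strongly
co-methylated, so probes are first collapsed into *gene clusters*:
complete-linkage hierarchical clustering on the distance
$d = 1 - r$ (Pearson correlation across samples), cut at height 0.4.
Complete linkage guarantees every pair inside a cluster correlates at
least $1 - 0.4 = 0.6$; the cut height is exposed (`cut_height`) because
it trades resolution against multiple testing. Probes mapping to several
genes are duplicated into each gene's pool, since genes are modelled
independently. A zero-variance probe has no defined correlation and is
parked in its own singleton cluster with a warning.

For each gene cluster the tumor distribution of mean beta values is
modelled as a mixture of Beta densities,

$$ f(\beta) = \sum_{c=1}^{K} \pi_c \,
   \mathrm{Beta}(\beta;\,\alpha_c, \beta_c), \qquad K \in \{1,2,3\}, $$

fitted by EM. $K$ is selected by BIC with $p = 3K - 1$ free parameters
($\alpha_c,\beta_c$ per component plus $K-1$ mixing proportions). Model
assumptions worth stating: tumors are a mixture of discrete methylation
*states* (not a continuum), states are shared across patients, and
normal-tissue methylation is unimodal. Up to three components suffice
because a gene can be hypomethylated, normal-like and hypermethylated at
once but rarely more.

The **DM value** of component $c$ is
$\mu_c - \bar\beta_{\text{normal}}$ with
$\mu_c = \alpha_c / (\alpha_c + \beta_c)$: the shift of that tumor state
relative to matched normal tissue. A cluster is *abnormal* only if

* some component has $|DM| \ge$ `dm_min` (default **0.10** — half the
  classical 0.2 "differentially methylated" beta difference, chosen so
  that moderate shifts survive the additional expression filter), and
* methylation is inversely coupled to the gene's expression across
  tumors: Pearson $r \le$ `r_max` (default **−0.3**) with $p <$ `p_max`
  (default **0.05**). The coupling requirement is what separates
  functional methylation changes from passenger drift.

Each tumor is then assigned its maximum-posterior component; its state is
`hypo` when the assigned component's DM $\le -$`dm_min`, `hyper` when
$\ge +$`dm_min`, `normal` otherwise. States are invariant to component
relabeling because they depend only on the assigned component's DM.

### Numerical choices

* Beta values are clamped to $[10^{-6}, 1 - 10^{-6}]$ so the likelihood
  is finite at the boundaries.
* EM initialization is deterministic: the sorted values are split into
  $K$ quantile blocks and moment-matched. Three seeded, jittered restarts
  (short-run to 10 iterations, best polished to convergence) guard
  against local optima while keeping results reproducible given a seed.
* The M-step solves the weighted Beta maximum-likelihood problem on
  $(\log\alpha, \log\beta)$ by a safeguarded Newton iteration with
  step-halving, warm-started at the current parameters. Because the inner
  objective never decreases, the procedure is a generalized EM and the
  observed log-likelihood is non-decreasing (a property the test suite
  asserts to $10^{-8}$).
* Convergence: $|\Delta \log L| < 10^{-6}$, at most 500 iterations;
  non-convergence returns the best iterate, flagged.
* Shape parameters are bounded in $[10^{-2}, 10^{5}]$; a starved
  component (weight $< 10^{-8}$) keeps its parameters.
* Candidate fits in which two component means lie within 0.05 are treated
  as over-parameterized and excluded from BIC selection; this implements
  component merging by parsimony (the $K-1$ model is always available)
  and keeps the parameter count exact.
* Fewer than 10 tumor values is an error; per-cluster fit failures inside
  `call_states()` are logged and skipped, never fatal.

## Missingness filtering and imputation

Features and samples with excessive missingness are removed before
modelling: rows whose missing fraction strictly exceeds the threshold
first, then columns, repeated to a fixed point (removing columns can push
a remaining row back over threshold; iterating makes the operation
idempotent and the output guarantee unconditional). Defaults follow array
practice: **20%** for methylation, **10%** for expression. Remaining gaps
are filled by row-wise KNN imputation (k = **15**, a standard default for
array data): neighbors ranked by Euclidean distance over co-observed
columns, the imputed cell being the mean of the k nearest rows observed
at that column. When none of the neighbors observes the column the row
mean, then the column mean, serves as fallback. Observed cells are never
modified.

## Consensus subtyping

Subtypes are discovered on the DM-value matrix of abnormal clusters
(`normal` states encoded 0, the alternative $\{-1,0,+1\}$ state encoding
is available by option). For each $k \in 2..10$, 1000 k-means runs on
random 80% sample subsets accumulate a consensus matrix
$M_k(i,j) = \Pr(\text{co-clustered} \mid \text{co-sampled})$. k-means
uses k-means++ seeding — a single seeded run per resample; the resampling
itself averages over initializations, and further restarts measurably
changed nothing but runtime. Final assignments cut an average-linkage
tree of $1 - M_k$.

The number of clusters minimizes the **PAC** (proportion of ambiguous
clustering: consensus entries in (0.1, 0.9)), an automated surrogate for
visual inspection of consensus CDFs — automation being a requirement for
a testable pipeline; the CDFs remain available via `consensus_cdf()`.
Two degenerate regimes return $k = 2$ with an explicit warning rather
than a confident answer: a near-flat PAC profile (range < 0.05) and a
profile in which no $k$ reaches PAC ≤ 0.3 (on structureless data PAC
*decreases* monotonically in $k$, so "minimum PAC" alone would
manufacture spurious large $k$).

## Nearest-shrunken-centroid classification

The subtype classifier operates on probe-level beta values of abnormal
gene regions. With class centroids $\bar x_{ik}$, overall centroid
$\bar x_i$, pooled within-class standard deviation $s_i$ and offset
$s_0 = \mathrm{median}_i(s_i)$, the standardized differences
$d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k (s_i + s_0))$ are
soft-thresholded, $d'_{ik} = \mathrm{sign}(d_{ik})\max(|d_{ik}| - \Delta, 0)$,
and classification uses squared standardized distance to the shrunken
centroids minus twice the log prior. $\Delta$ is chosen by inner
cross-validation minimizing error, taking the **largest** $\Delta$ on
ties (fewest probes). Priors default to **equal** — subtype prevalence is
cohort-specific and should not leak into cross-cohort transfer — with
empirical priors available by option.

Performance is the 10-fold stratified cross-validated AUC. Because
"the AUC of cross-validation" is ambiguous, both conventions are
reported: the AUC of the pooled held-out posteriors and the mean of
per-fold AUCs; a bootstrap (2000 resamples) gives the CI of the pooled
AUC. Transfer to a second cohort restricts to features both cohorts
share (in practice: probes present on both the 450k and 27k platforms);
model features absent from the target cohort are imputed with the
overall centroid value, with a warning. Calls obey the
confidence-abstention rule with *strict* inequalities: positive if
$p > 0.60$, other if $p < 0.40$, abstain in between —
$p = 0.60$ abstains. `minimal_panel()` raises $\Delta$ until at most the
requested number of probes survives, then reports the restricted model's
cross-validated AUC and per-fold selection stability.

## Lesion, overlap and signature statistics

* **Lesion score** = nonsilent driver mutation count $+$ (−GISTIC
  score): an approximate count of inactivated alleles (GISTIC −2 = deep
  deletion contributes +2). The formula is applied literally, so an
  amplification (GISTIC > 0) *reduces* the score; this is surprising
  enough that the function warns when it happens rather than silently
  clamping.
* **Overlap index** = |patient's hypomethylated CpGs ∩ signature| /
  |patient's hypomethylated CpGs|, the hypomethylated set being all
  probes of gene clusters in state `hypo` for that patient. Patients
  with empty hypo sets have no defined index and are excluded with a
  warning. The **random overlap index** replaces the signature by
  uniform random probe sets of the same size (default **10** draws,
  averaged); its expectation is exactly $m/N$ (hypergeometric), which
  the tests verify to within 3 standard errors.
* The lesion–overlap association is an ordinary least-squares slope with
  its two-sided p-value; under a simulated null its rejection rate at
  $\alpha = 0.05$ is calibrated (~5%).
* **SAM statistics**: $d_i = (\bar x_{i1} - \bar x_{i2})/(s_i + s_0)$
  with $s_0$ the median of the per-feature pooled standard errors
  (configurable quantile), null distributions from label permutations
  (default 200; below 50 a warning flags unstable q-values), and
  q-values by the median-false-positive convention — the median across
  permutations of the number of null $|d^*|$ exceeding the feature's
  $|d_i|$, divided by the observed count, clamped to $[0,1]$ and made
  monotone in $|d|$. With $s_0 = 0$ the statistic reduces exactly to the
  two-sample pooled-variance t statistic (asserted against `t.test`).
* Wilcoxon rank-sum comparisons use the exact distribution when both
  groups have ≤ 20 observations and no ties, the tie-corrected normal
  approximation otherwise; fully tied data returns p = 1. Multiple
  Wilcoxon panels are corrected by Benjamini–Hochberg.
* The **T-cell score** is the unweighted mean expression of 13 T-cell
  transcripts (shipped in `inst/extdata/tcell_signature_genes.txt`);
  genes absent from a matrix are reported and skipped.

## The synthetic cohort generator

`generate_cohort()` plants the exact structure the analysis assumes, with
full ground truth. Defaults describe a realistic mid-sized cohort:
**400 tumors, 40 normals, 500 genes with 1–5 probes each, 3 subtypes**
(prevalences 0.2/0.4/0.4, subtype 1 carrying the driver lesions).
Beta values are drawn from Beta components parameterized by
(mean, precision) with $\alpha = \mu\phi$, $\beta = (1-\mu)\phi$ and
precision $\phi = 30$ (beta-value standard deviation ≈ 0.08 at
$\mu = 0.5$, typical of array replicates). Planted states use
$\mu_{\text{normal}} = 0.7$, $\mu_{\text{hypo}} = 0.2$,
$\mu_{\text{hyper}} = 0.9$: gene-body/promoter levels that give DM values
of −0.5/+0.2, comfortably outside measurement noise. Subtype 1 plants 80
hypomethylated and 10 hypermethylated genes, subtypes 2 and 3 plant 30
hypomethylated genes each — so the driver subtype has an elevated
hypomethylated-genes-per-patient count, as observed in such tumors.

Expression at planted genes follows
$e = b - \lambda(\beta - \mu_{\text{normal}}) + \varepsilon$ on the
log2 scale with coupling $\lambda = 4$ and noise
$\varepsilon \sim N(0, 0.5^2)$, giving the strong inverse coupling the
abnormality filter requires; setting $\lambda = 0$ switches the coupling
off and should (and does, in tests) suppress abnormal calls. Driver
mutations hit 60% of subtype-1 patients versus 5% elsewhere; GISTIC
deletions −2/−1 with probabilities 0.10/0.45 inside the subtype versus
0.01/0.14 outside, echoing the mutation–deletion co-occurrence seen in
real cohorts. Silent mutation rows are added so the filtering stage has
work to do. The signature (200 CpGs) draws a configurable fraction
(default 0.5) from subtype-1 planted hypomethylated CpGs and fills the
rest uniformly; carriage of signature-pool genes rises with the
patient's lesion score (0.2 + 0.18 × score, clamped), planting the
positive lesion–overlap association. 60% of probes are flagged as shared
between platforms. The gene/probe scaffold is drawn from a fixed RNG
stream, so different seeds change the data, never the shapes.

What the generator deliberately does **not** emulate: type I/II probe
chemistry and measurement error models, tumor purity and stromal
contamination, batch effects, CpG-island/shore spatial structure,
clinical covariates, and realistic mutation spectra. Green tests
therefore demonstrate that the estimators recover the structure they
model — not that the model captures everything in real arrays.

## Problem sizes used by the test suite

The acceptance-level tests run the full pipeline once at the generator's
default scale (400 tumors / 500 genes; about 1200 gene clusters), which
the remaining checks share: mixture recovery uses 50 replicates at
n = 200; the permutation-null AUC uses 20 relabelings; transfer
enrichment uses one full-scale shared-signature cohort and ten 200-tumor
cohorts with disjoint signatures; overlap calibration uses 200 resampled
means and 500 null regressions. Unit tests use 40–120-sample cohorts.

## Known limitations

* The EM likelihood surface for K = 3 with weak separation can retain
  local optima despite restarts; BIC then conservatively prefers fewer
  components.
* PAC-based selection inherits PAC's known bias toward small k on weak
  structure; the `inspect` warning marks exactly those runs.
* Because signature-gene carriage rises with lesion load, the planted
  driver subtype contains genuine substructure; depending on the seed,
  PAC may prefer to split it into a fourth cluster, while the agreement
  with the planted three-way partition stays high.
* The classifier assumes feature-wise (diagonal) covariance, as any
  nearest-centroid method does; correlated probe blocks make the
  posterior overconfident, which is why transfer uses the abstention
  band rather than the raw argmax.
* `filter_missing()` applies thresholds feature-first; a sample barely
  over threshold can survive if offending features are removed first.
  The order is documented and tested rather than configurable.
* Batch correction is out of scope; `load_cohort()` reserves a
  `batch_column` hook that currently raises "not implemented".
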
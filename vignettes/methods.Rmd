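---
title: "Models and methods behind ipscvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ipscvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ipscvar` implements the statistical workflow for case/control bulk RNA-seq
studies of hiPSC-derived neural progenitor cells (NPCs) and neurons, where
every donor contributes several clonal lines and two culture cell types.
Such designs have two defining features: observations are *repeated
measures* (samples from one donor are correlated), and bulk profiles are
*mixtures* (every culture is a blend of cell types whose proportions vary
between differentiations). Both features, if ignored, either inflate false
positives or bury the donor-specific signal that case/control comparisons
depend on. This vignette describes each model in the package, the
parameters that matter, the numerical choices, and what the synthetic-data
validation does and does not establish.

## The synthetic cohort generator

All validation runs on cohorts from `simulate_cohort()`, which emulates the
structure of a childhood-onset schizophrenia hiPSC cohort: by default 11
case and 11 control donors, two clonal lines per donor, each profiled as
NPC and neuron (88 samples). For gene $g$ in sample $s$ from donor $d$ the
log2-scale mean is

$$\mu_{gs} = \log_2\!\Big(\textstyle\sum_c \pi_{sc}\,S_{gc} + \varepsilon\Big)
  + u_{gd} + \beta_g\,[d\ \mathrm{is\ case}] + e_{gs},$$

with mixing proportions $\pi_s \sim \mathrm{Dirichlet}(\alpha_{t(s)})$ over
the reference profiles of the signature panel $S$, donor effects
$u_{gd} \sim N(0, \sigma_d^2)$, diagnosis effects $\beta_g$ nonzero for a
configurable fraction of genes, and residual noise
$e_{gs} \sim N(0, \sigma_{res}^2)$. Counts are negative binomial with
library-size-scaled means and dispersion $\phi$
($\mathrm{Var} = \mu + \phi\mu^2$).

Key calibration choices:

* **Donor effect.** `icc_donor` is defined against the Gaussian residual
  component only: $\sigma_d^2 = \rho\,\sigma_{res}^2 / (1 - \rho)$ with
  $\sigma_{res} = 0.5$ by default. Counting noise ($\approx \phi$ on the
  squared-log scale at high counts) and Dirichlet mixing variability add
  further residual variance, so the *realized* donor fraction of log-CPM is
  below the nominal $\rho$ unless dispersion is small and mixing is tight.
  Recovery tests therefore use concentrated Dirichlet parameters and
  $\phi \approx 0.005$, which isolates the documented calibration; under
  the default $\phi = 0.1$ the same identity holds against the enlarged
  residual. The default donor effect is 0.022, the median value such
  cohorts show; 0.488, reported for undifferentiated hiPSC panels, is used
  in design examples.
* **eQTL genes.** A configurable fraction of genes (default 0.2) is flagged
  as eQTL genes and receives a donor standard deviation multiplied by 3,
  encoding the empirical fact that donor-variable genes are enriched for
  genetic regulation. This is a construction for the truth channel, not an
  estimate of any real effect size.
* **Sex signal.** The XIST-like gene and six chrY genes switch between a
  well-expressed level (median gene level + 2 on log2) and a silenced level
  (median − 12, i.e. below 1 CPM); "intermediate" samples are a 50/50
  linear mixture of the two states, mimicking contamination or aberrant
  X-inactivation.
* **Invented defaults.** Library sizes are log-normal (mean $\ln 2\times
  10^7$, sd 0.25), batches are three random labels with no effect, and the
  sendai covariate is exponential on a configurable donor subset: the
  source study does not state distributions for these nuisance variables,
  so these are this package's own choices, fixed once.

Passing tests on these cohorts shows the estimators recover the generative
parameters under the stated model; it does not certify behavior under
features the generator lacks (outlier samples, GC/length biases, batch
effects correlated with diagnosis, isoform-level variation).

## Normalization and QC

Filtering retains genes with CPM above 1 (computed from raw library sizes,
before any between-sample scaling) in at least 30% of samples; a tie at
exactly 30% counts as retained. TMM factors are weighted trimmed means of
gene-wise log ratios against a reference sample (the one whose 75th CPM
percentile is closest to the mean of those percentiles), with genes zero in
either sample excluded, double trimming (30% on M-values, 5% on A-values)
and inverse-delta-method weights; factors are rescaled to geometric mean 1,
and log2-CPM uses a prior count of 0.5. The implementation reproduces the
standard edgeR algorithm to numerical precision on test matrices, and the
tests keep edgeR as an independent oracle.

Sex inference thresholds (female: XIST ≥ 2 and mean chrY < 1 log2-CPM;
male: the reverse with cutoffs 1 and 2) are this package's choice — the
underlying bimodality makes calls insensitive to the exact values, and
anything between the bands is reported as "intermediate" rather than
forced. CNV z-scores residualize log2-CPM on culture cell type before
standardizing each gene across samples, so cell-type shifts do not
masquerade as dosage effects; genes with residual s.d. below $10^{-12}$ get
z = 0 and a flag instead of NaN. BED regions are treated as 0-based
half-open and gene coordinates as 1-based inclusive.

## Composition scores and residualization

Reference-based composition scoring solves, per sample, a non-negative
least-squares fit of linear-scale expression over the panel's marker genes
(top 50 per profile by fold over the mean of the other profiles) against
the profile signatures; profile coefficients are summed within cell types
and renormalized to sum 1. Genes are weighted by the inverse of their
standard deviation across profiles. Weighting by the inverse s.d. (rather
than full centering and scaling) keeps two properties exact: a noise-free
mixture of profiles is recovered exactly, and rescaling a sample's
expression leaves scores unchanged after the final renormalization. The
scores are comparative — the absolute scale of reference-based
deconvolution is sensitive to the panel and is deliberately ignored; any
externally computed score table can be supplied in its place.

Residualization is per-gene OLS on an intercept plus the chosen scores,
with a rank check that names collinear columns; residuals are orthogonal to
every covariate to machine precision.

## Variance partitioning

For each gene, a linear mixed model (REML, via `lme4`) assigns a variance
component to every categorical variable (cell type, donor, diagnosis, sex
— each a random intercept) and a fixed slope to every continuous one (the
composition scores). The fraction for a random effect is
$\hat\sigma_k^2 / \hat\sigma_{tot}^2$; for a fixed effect it is the
empirical variance of $X_k\hat\beta_k$ across samples over the total; the
residual completes the sum to 1. Diagnosis is nested within donor, yet both
are fitted as separate components — with few donors the two are partially
confounded and the diagnosis fraction should be read as a lower bound.
Genes with total variance below $10^{-12}$ are skipped and counted. For a
single balanced random effect the REML fraction coincides with the one-way
ANOVA moment estimator truncated at zero, which the tests exploit as a
closed-form oracle. Non-converging genes are returned as NA with the
reason, never silently dropped.

## eQTL fold enrichment

The enrichment curve takes the per-gene variance fractions for one
variable, 40 quantile-spaced cutoffs, and an eQTL gene list (the top 2000
by default). At each cutoff with more than 100 genes passing, fold
enrichment is the observed overlap divided by the mean overlap across
10,000 permutations of the fraction vector over genes, with a 90%
permutation interval; the curve truncates at the first cutoff where 100 or
fewer genes pass. Because cutoffs are quantile-based, the curve depends
only on fraction ranks. Under permutation the passing set is a uniform
random subset, so the mean permuted overlap must match the hypergeometric
expectation $n_{pass} \cdot |top| / |universe|$ — the tests verify this
cross-oracle identity within Monte-Carlo error, and one shuffled indicator
with a cumulative sum serves all cutoffs of a permutation, keeping the
10,000 permutations cheap.

## Repeated-measures differential expression

The DE model chain is: (1) *precision weights* from a lowess fit of
$\sqrt{s_g}$ against mean log2 count, evaluated at each observation's
fitted log-count and inverted to the fourth power — low counts, whose
log-scale variance is inflated, are down-weighted; (2) a *consensus
intra-donor correlation*: per-gene one-way moment estimates of the
intra-block correlation of the fixed-design residuals, pooled by a
15%-trimmed mean on the Fisher-z scale; (3) per-gene *generalized least
squares* under block compound symmetry at the consensus $\rho$ (with
$|\rho|$ capped at 0.99 to keep the covariance invertible), which reduces
exactly to OLS at $\rho = 0$; (4) *empirical-Bayes moderation*: the prior
$(d_0, s_0^2)$ is fit by moment matching on $\log s_g^2$ (with the digamma/
trigamma bias corrections), each gene's variance is shrunk to
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and t, p and the
standard error $|\hat\beta / t|$ use $d_0 + d_g$ degrees of freedom. When
the variances show no excess spread the prior degrees of freedom are
infinite and the pooled mean variance is used. (5) FDR control by
Benjamini–Hochberg and by Storey q-values with $\hat\pi_0$ from a cubic
smoothing spline over $\lambda \in \{0.05, \dots, 0.95\}$ evaluated at
$\lambda = 0.95$.

The point of the chain is calibration: on null cohorts with donor
correlation 0.3 and two lines per donor, donor-ignorant OLS runs an
empirical type-I error near 8% at $\alpha = 5\%$, while the GLS chain sits
at 5% — the acceptance suite checks exactly this contrast on 5000 genes.
The consensus-correlation estimator shares the known small-sample downward
bias of its per-gene moment estimates (at two samples per donor it
recovers ≈0.27 for a true 0.3); this matches the reference implementation
of the same statistic and does not disturb calibration, because the type-I
error is controlled at the *estimated* correlation.

## Concordance and clustering

Cross-cohort concordance is the Spearman (and Pearson) correlation of
per-gene t statistics over the gene intersection, with a one-sided
t-approximation p-value for positive correlation. In the regime of a small
repeated-measures cohort against a large independent reference sharing
half the true effects, the expected rank correlation is small (0.05–0.3)
yet decisively nonzero — the package's simulations reproduce that regime
rather than any particular real-data value. Category-level clustering
quantile-normalizes the merged samples to a sorted-mean reference,
computes $1 - r$ sample distances, summarizes category pairs by the median
cross-pair distance, and clusters the summary matrix with complete
linkage; the tree serializes to Newick. Classical MDS delegates to
`stats::cmdscale` on the same $1 - r$ distance; the distance transform of
the correlation matrix is this package's choice.

## Coexpression modules

Adjacency is the unsigned $|r|^\beta$ with $\beta = 9$; the topological
overlap matrix combines direct adjacency and shared neighbors,
$\mathrm{TOM}_{ij} = (\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$, and is cross-checked against a brute-force
double loop to $10^{-12}$. Modules come from average-linkage clustering of
$1 - \mathrm{TOM}$ with a *static cut at 0.99 of the tallest merge height*
followed by merging branches below 20 genes into "grey". A cut placed at a
quantile of the merge-height distribution was tried first and rejected: on
planted two-block data it reduces to separating only the top one or two
merges and swallows noise genes into one giant cluster, whereas the
fraction-of-maximum cut (the convention of the dynamic tree-cut default)
recovers planted blocks exactly and sends independent genes to grey.
Unsigned adjacency was chosen because the source procedure specifies only
a power transform of the correlation matrix. Labels follow the
conventional color order by decreasing size; assignments are invariant to
gene input order (genes are processed in sorted-id order). Module/gene-set
enrichment is hypergeometric against the clustered genes, Bonferroni over
modules × sets, and grey is tested like any other label — in underpowered
case/control designs the differentially expressed genes tend to land
there, which is a finding, not an artifact.

## Effective sample size and design

With $k_i$ correlated samples per donor and donor effect $\rho$, the
compound-symmetry design effect gives
$\mathrm{ESS} = \sum_i k_i / (1 + (k_i - 1)\rho)$: a new donor adds exactly
one unit at any $\rho$; a second line adds $2/(1+\rho) - 1$ — 0.96 units
when $\rho = 0.022$ but only 0.34 when $\rho = 0.488$. `optimize_design()`
searches uniform designs (m donors × k lines, plus leftover budget spent
on single extra lines) under a budget or donor-count constraint; because
ESS is Schur-concave in the replicate counts at fixed total, the
uniform-plus-remainder family contains an optimum, which the tests confirm
against exhaustive enumeration. Ties go to fewer total lines, then to more
donors — replicate clones never beat independent donors on a tie. The
practical upshot the calculator encodes: with equal per-line and per-donor
costs, one line per donor is always optimal; replicates only pay when
lines are much cheaper than donors *and* the donor effect is small.

## Problem sizes and reproducibility

The test and acceptance workloads use scaled-down but structurally
faithful problems — a few hundred to a few thousand genes, 16–44 donors,
2000–10,000 permutations, 10–50 simulation replicates — sizes chosen so
the full validation runs in minutes while keeping Monte-Carlo error well
inside the asserted tolerances. Every stochastic step is seeded; the
pipeline writes a manifest with parameters, seed and output checksums, and
identical inputs plus seed reproduce every table byte for byte.
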
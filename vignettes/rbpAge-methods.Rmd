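---
title: "Methods: age/sex association screening and network centrality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age/sex association screening and network centrality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbpAge)
```

## The problem

Post-transcriptional regulators — RNA-binding proteins (RBPs) in
particular — change expression across the human lifespan and between the
sexes, and liver is a tissue where both axes matter clinically.
`rbpAge` implements a screening pipeline for this question: given one or
more expression cohorts with continuous donor ages and recorded sex, it
identifies genes whose expression is associated with age and/or sex,
asks whether those genes sit in an unusually dense and central part of
the protein–protein interaction (PPI) network, and tests whether the
age trends reproduce in a rodent developmental stage series.

Because the motivating cohorts are microarray studies behind external
repositories, the package ships a synthetic-data module that emulates
their statistical structure with known ground truth. Every stage of the
pipeline runs, and is tested, without downloads.

## Preprocessing

Two protocols cover the common single-channel designs:

* **three_step** (Agilent-style raw intensities): per-array
  normal-plus-exponential ("normexp") background correction with offset
  50, quantile normalization between arrays, then log2.
* **quantile_only** (BeadStudio-style summarized data): quantile
  normalization alone; log2 is applied when the input looks unlogged
  (maximum value above 100), since summarized bead data arrive in either
  scale.

The normexp model treats an observed intensity as $X = B + S$ with
Gaussian background $B \sim N(\mu, \sigma^2)$ and exponential signal
$S$ with mean $\alpha$. Parameters are estimated by the method of
moments — the exponential is the only skewed component, so
$\alpha = (m_3/2)^{1/3}$ from the third central moment, then
$\mu = \bar{x} - \alpha$ and $\sigma^2 = \max(s^2 - \alpha^2,
\varepsilon)$. The corrected value is the posterior mean
$E[S \mid X = x] + \text{offset}$, evaluated through a log-scale Mills
ratio so extreme arguments never produce NaN. A closed-form moment fit
was chosen over likelihood maximisation for robustness and
transparency; when the moments are infeasible (non-positive skew) a
documented fallback is used with a warning. One identifiability caveat
is inherent to the model, not the estimator: $\sigma^2$ enters the
moments only as $s^2 - \alpha^2$, so when
$\sigma \ll \alpha$ the background SD cannot be pinned down from any
realistic sample — the tests check $\mu$ and $\alpha$ recovery in that
regime and full recovery where $\sigma/\alpha = 0.5$.

Quantile normalization forces every array onto the common reference
distribution (row-wise means of sorted columns). Ties receive the mean
of the tied reference values, which makes the transform deterministic
and idempotent. Missing values are disallowed; probe-to-gene collapse
(when real platform data are used) keeps the probe with the highest
mean intensity, a deterministic convention.

## Association screening

For each gene the model is an analysis of covariance fitted by ordinary
least squares:

$$y = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,I(\mathrm{male}) + \varepsilon$$

with two-sided $t$ tests on $\beta_1$ and $\beta_2$ ($n-3$ residual df,
equivalent to each term's partial $F$ test). The design matrix is shared
across genes, so `assoc_screen()` solves one QR decomposition for the
whole matrix; per-gene results agree with `lm()` to floating-point
precision (tested). Joint OLS with coefficient tests was preferred over
sequential sums of squares because it is order-independent.

Multiple testing is controlled per covariate and per cohort with the
Benjamini–Hochberg step-up procedure. A gene is called significant when
**both** its raw p-value is below 0.001 (strict) **and** its q-value is
at or below 5% — the conjunctive reading of the two stated constraints.
Spearman correlation of expression with age supplies the direction of
significant age calls; its p-value is an exact permutation enumeration
for $n \le 9$ and the $t$ approximation with $n-2$ df otherwise.

Cohort screens are merged into a non-redundant set: a (gene, covariate)
pair is kept when significant in at least one cohort. When cohorts
disagree on direction the larger absolute effect decides ($|\rho|$ for
age, $|\hat\beta_2|$ for sex, mirroring the age rule); exact ties yield
direction 0 with a warning. Class enrichment (e.g. RBPs versus
transcription factors) is a two-sided Fisher exact test on the
2×2 associated-by-class table.

For presentation, samples are binned into half-open 20-year age
intervals (the last bin closed at 120 y) and the age-increasing and
age-decreasing gene groups are clustered on their bin-mean profiles
with average-linkage agglomeration under the distance
$1 - \text{Pearson correlation}$ of row z-scores; rows are processed in
lexicographic gene order so results are deterministic, and constant
rows go to a residual cluster.

## Network centrality against an edge-subsampled null

The PPI network of the associated genes is the induced subgraph over
the interactome (nodes left without internal edges are dropped). Four
node measures are computed: degree; local clustering coefficient
(degree-<2 nodes scored 0 by default so every node enters pooled
distributions — an NA mode is available); closeness; and Brandes
betweenness (plus edge betweenness). Disconnected node pairs enter
distance calculations at $|V| - 1$, one less than the maximum node
count, which keeps closeness finite on fragmented subnetworks; the
convention does not apply to betweenness, whose dependencies accumulate
only along realized paths. Graph algorithms are delegated to igraph
and verified in the test suite against exhaustive shortest-path
enumeration on hundreds of small random graphs.

The null model is deliberately **edge subsampling**, not degree-
preserving rewiring: from the interactome of non-associated genes,
each of 100 control networks draws exactly $x$ edges uniformly without
replacement, where $x$ is the observed subnetwork's edge count. Within
each network (observed and each member) every measure is divided by its
network maximum, and member values are pooled. Pooling (rather than
per-member medians) is the default because the comparison yields a
single p-value per measure; a per-member summary can be assembled from
the pooled table's `member` column. Observed versus pooled-null values
are compared with a two-sided Mann–Whitney test (`stats::wilcox.test`:
exact below 50 untied observations, normal approximation with tie
correction otherwise — ties are pervasive in pooled centralities, so
the approximation is the operative branch at realistic sizes).

A note on calibration of the subsampler: each source edge's inclusion
count across 100 members is Binomial(100, $x/|E|$) marginally. A
"within 3 SDs for every edge" check therefore fails by chance in ~5% of
correctly sampled ensembles once a few dozen edges are tested, so the
package's tests apply that per-edge band across 10 independent
ensembles and require it to hold in at least 8.

## Cross-species concordance

Human age directions are transferred through a one-to-one ortholog map
to a rodent stage series (at least three strictly increasing stage
ages; the synthetic default mirrors a 2/6/21/104-week liver design).
A gene's rodent trend is the sign of the Spearman correlation of
expression with stage order, called only when $|\rho| \ge 0.5$ — the
threshold is exposed because no canonical criterion exists; 0.5 demands
a consistent monotone pattern over four stages without requiring
perfect monotonicity. Enrichment of direction-concordant genes is the
upper-tail hypergeometric probability $P(X \ge k)$; the universe
defaults to mapped orthologs with a determinate trend (the smallest
defensible universe; all mapped orthologs is selectable). Probabilities
below machine precision are reported as the bound `< 2.2e-16`, never
literal zero. The qPCR validation arithmetic is the standard
$\Delta\Delta C_t$: fold change $2^{-\Delta\Delta C_t}$ against a
housekeeping gene and reference timepoint, summarized as mean ± SEM
over replicates.

## The synthetic generator

`gen_cohort()` draws ages uniformly on a configured range, sexes as
Bernoulli, per-gene baselines as $N(8, 2^2)$ on the log2 scale, and adds
planted linear age slopes and additive sex shifts (random sign) plus
i.i.d. Gaussian noise. Defaults emulate the target cohort structure:
1344 genes, 206 donors aged 1–85 with ~64% males (the companion cohort
uses 149 donors), 6.5% of genes age-associated and ~3.3%
sex-associated. Effect magnitudes are not published for these cohorts,
so the defaults — slope 0.05 expression-units/year, sex shift 1, noise
SD 1 — were fixed once for testability: at $n \approx 150$ they give
essentially complete power at $p < 0.001$, so recovery tests measure
the pipeline's bookkeeping and error control rather than borderline
power. `gen_interactome()` plants a dense module (edge probability
`p_in = 0.3` among associated genes versus `p_out = 0.02` elsewhere),
and `gen_stage_series()` produces `slope × stage-age` plus noise, so the
noise-free trend sign equals the planted sign.

What the generator does **not** emulate: probe-level array noise,
batch and ancestry structure, count noise of RNA-seq, correlated gene
modules, non-linear age trajectories, and degree-heterogeneous (scale-
free) interactomes. Passing tests therefore demonstrate correctness of
the statistics and plumbing under the stated model, not robustness to
those real-data complications.

## Numerical and design choices

* Significance boundary: strict `p < 0.001`, inclusive `q ≤ 0.05`.
* Sex is encoded as an indicator for male with female as reference;
  p-values are unaffected by the choice.
* Child seeds for pipeline stages derive from the master seed as
  `(seed + i·10007) mod (2^31 − 1)`, keeping stages independently
  reproducible.
* Zero-variance genes are skipped with a warning rather than failing a
  whole screen; constant series give trend 0; all-zero centrality
  vectors are returned unnormalized with a warning.
* Problem sizes used by the packaged checks: 5000-gene null cohorts and
  20 × 1000-gene recovery replicates for calibration/recovery, 600-node
  interactomes with 100-member ensembles for the network contrast —
  sizes at which the binomial/KS bounds quoted above are sharp while a
  full run completes in seconds.

## Limitations

* ANCOVA assumes linear age effects and homoscedastic Gaussian noise;
  strongly non-linear trajectories will be under-called (the binned
  cluster summaries help inspect shape post hoc).
* The edge-subsampled null preserves edge count but not degree
  sequence; conclusions are about density/modularity relative to
  uniformly thinned interactomes, not rewired ones.
* With two cohorts the union merge doubles the opportunity for false
  positives; the conjunctive p-and-q rule keeps the empirical false
  discovery proportion near 1–2% in the packaged recovery checks.
* Probe-level handling of real arrays (annotation, CDF versions) is out
  of scope; users supply summarized gene × sample matrices.
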
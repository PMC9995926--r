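---
title: "Methods: integrating mRNA expression and DNA methylation in small two-group cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating mRNA expression and DNA methylation in small two-group cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmeth)
```

## The problem

Case-control molecular studies of psychiatric and other complex disorders are
often tiny: the motivating design here is four cases versus five controls,
each subject contributing both an RNA-seq count profile and an array
methylation profile (beta values per CpG position). `coexmeth` implements the
complete integrative workflow for such a design: screen each layer for
differential features, connect the two layers through a bipartite Pearson
co-expression network, rank methylation positions by network degree to
nominate hub genes, quantify gene-level overlap and gene-set enrichment, and
check selected transcripts by qPCR relative quantification.

At this sample size every modelling decision matters. The package therefore
leans on two standard small-sample devices: empirical-Bayes variance
shrinkage for the per-feature tests, and an extremely stringent correlation
cutoff (|r| >= 0.95 across nine samples) for declaring a
methylation-expression link.

## Differential screening

### Expression

Counts are normalized with median-of-ratios size factors: for each gene with
positive counts in every sample, divide counts by the gene's geometric mean
and take the per-sample median of the ratios. FPKM
(`1e9 * K / (L * N)`) is available for length-normalized reporting.

The reported effect is

\[
\log_2\mathrm{FC} = \log_2\frac{\bar{x}_{\text{case}} + c}{\bar{x}_{\text{control}} + c},
\qquad c = 0.5,
\]

on normalized counts. The pseudocount keeps zero-count genes finite; 0.5 is
the conventional half-count. P-values come from a moderated t test on
`log2(normalized + c)` (below). The screen keeps features with
`|log2FC| > 1` and raw `p < 0.05`, both strict inequalities; FDR
(Benjamini-Hochberg) is reported alongside, and an optional FDR cap is
exposed but off by default, since the screen is defined on raw p. Duplicate
gene symbols are resolved by seeded uniform random deletion, preserving row
order.

### Methylation

Probes failing the detection p-value (`> 0.01` in *any* sample) are removed
first. Between-sample quantile normalization (rank means, ties shared) then
aligns the beta distributions; it is a deliberately plain normalization for
the beta scale and can be switched off. The pipeline fixes the order
*filter, normalize, test* — testing before subsetting would change the
shrinkage fit, so the order is part of the contract and asserted by tests.

The effect size is always deltaBeta, the case-minus-control difference of
group mean betas, reported on the beta scale because it is directly
interpretable as a methylation-fraction change. Testing happens by default
on M-values, `log2(beta/(1-beta))` with betas clipped to
`[1e-3, 1 - 1e-3]`: the logit transform approximately stabilizes the
variance, which matters with 7 residual degrees of freedom. The screen keeps
`p < 0.01` (strict). **Direction convention:** `up` (hyper-methylated in
cases) is *defined* as deltaBeta > 0. Published tables in this literature
are not always internally consistent about sign conventions, so the package
pins one and states it.

### The moderated t test

Both layers share one engine. For feature \(g\) with group sizes \(n_A, n_B\)
and pooled residual variance \(s_g^2\) on \(d = n_A + n_B - 2\) degrees of
freedom, the prior \((d_0, s_0^2)\) is fitted across features by moment
matching on \(e_g = \log s_g^2 - \psi(d/2) + \log(d/2)\):

\[
\psi'(d_0/2) = \max\{\mathrm{var}(e) - \psi'(d/2),\ 0\},
\qquad
s_0^2 = \exp\{\bar{e} + \psi(d_0/2) - \log(d_0/2)\},
\]

with \(\psi, \psi'\) the digamma and trigamma functions. Because trigamma is
strictly decreasing, \(d_0\) is found by bisection on \((10^{-6}, 10^6)\) to a
residual tolerance of \(10^{-10}\); when the between-feature spread of
\(e\) does not exceed its sampling noise the fit returns \(d_0 = \infty\)
(complete shrinkage, normal reference). The test statistic uses the
posterior variance

\[
\tilde{s}_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},
\qquad
t_g = \frac{\bar{x}_A - \bar{x}_B}{\tilde{s}_g \sqrt{1/n_A + 1/n_B}},
\]

referred two-sided to \(t_{d + d_0}\). At \(d_0 = 0\) this reduces exactly to
the classical pooled t test (a tested identity). Degenerate inputs follow
fixed rules: zero posterior variance with equal means gives \(t = 0, p = 1\);
with unequal means the p-value is the smallest representable positive number
and the result is flagged degenerate.

The expression stage's engine is thus a moderated t on log-normalized
counts, not a negative-binomial GLM; the choice is recorded in the output
table's `engine` attribute. On the simulated cohorts used for validation the
engine is well calibrated (see *Validation by simulation*), but it is not a
drop-in reimplementation of count-GLM inference, and users comparing against
count-model pipelines should expect p-values to differ feature by feature.

Note one property of the prior-variance formula worth knowing: for a panel
whose \(s_g^2\) are exactly equal, \(s_0^2 = s^2 \exp\{\log(d/2) -
\psi(d/2)\}\), slightly above \(s^2\). That is the correct log-scale
unbiasedness correction, not a defect. Benjamini-Hochberg adjustment is the
standard step-up procedure; note that BH is *not* idempotent (re-adjusting
an adjusted vector can increase values), so adjusted values are computed
once from raw p-values only.

## The bipartite co-expression network

Every (methylation position, mRNA) pair is scored by the sample Pearson
correlation; an edge requires \(|r| \ge 0.95\) (non-strict, both signs).
Correlations are computed by default between probe M-values and
`log2(normalized counts + 0.5)`, the same scales used for testing. Pairs
where either vector is constant have undefined correlation; they are
skipped and counted, never propagated as NaN — with 4-5 samples per group,
constant vectors are a realistic occurrence, which is why `pearson_r`
returns an explicit `NA` sentinel.

Hubs are nodes with degree at least `hub_min_degree` (default 25), ranked
by degree descending, truncated to `hub_top_n` (default 41); ties at the
cut are broken by node id ascending, a deterministic rule chosen because no
field convention exists. A second, tighter screen (degree >= 30, top 13) is
exposed for visualization-sized subnetworks. The hub-gene roster finally
restricts hub nodes to methylation positions that passed the differential
screen and attaches their gene annotation and p-value.

With nine samples the |r| >= 0.95 cutoff corresponds to a nominal pairwise
p of about 1e-4; `build_network` warns below ten samples rather than
silently proceeding, and the threshold is a config knob, not a constant.

## Overlap, enrichment, clustering, qPCR

Gene-level overlap between the two screened layers is an exact,
case-sensitive set intersection after whitespace trimming (no alias
resolution: symbol alias maps are database-version dependent and out of
scope). Enrichment of a gene list against a user-supplied GMT collection
uses the one-sided hypergeometric (Fisher exact) upper tail,
\(P(X \ge k)\), with BH across sets. The default universe is all features
tested in the corresponding differential stage — the conservative choice
when no universe is stated — and is overridable.

Heatmap orderings come from two-way agglomerative clustering with distance
\(1 - r\) and average linkage, applied independently to rows and columns;
linkage and distance are pinned by config because display conventions vary.
Constant features are placed last with a warning.

qPCR fold changes use the \(2^{-\Delta\Delta Ct}\) method: replicates are
averaged on the Ct scale (the conventional reading), \(\Delta Ct\) is
target minus reference per sample, \(\Delta\Delta Ct\) is the case-mean
minus control-mean difference, and `log2_fold` is exactly
\(-\Delta\Delta Ct\), positive when expression is higher in cases —
matching the expression-stage convention.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design rather than any one dataset:

* **Design:** 4 cases, 5 controls, cases first (fixed order so size factors
  and tests reproduce exactly).
* **Counts:** negative binomial with shared dispersion 0.05 around per-gene
  base means drawn log-uniformly over \(2^4\)-\(2^{10}\) — the
  moderately-to-well-expressed regime a post-filter count matrix contains.
  A fraction (default 10%) of genes receives a planted log2 fold change of
  magnitude 1.5-8, matching the effect scale such small cohorts report.
* **Methylation:** Beta-distributed with concentration 30 (between-subject
  beta sd roughly 0.05-0.09), base means uniform on (0.1, 0.9), values
  clipped to (0.01, 0.99). A fraction (default 5%) of probes receives a
  planted deltaBeta of magnitude 0.15-0.55, sign-flipped when infeasible.
* **Hub coupling:** each hub probe (a planted DM probe) drives 30 planted DE
  genes: the gene's log2 expression is linear in the probe's *realised*
  per-sample M-value plus Gaussian noise (`hub_noise_sd`, default 0.25
  log2 units), with the slope chosen so the implied group fold change equals
  the gene's planted log2FC. Coupling on the logit/log scales keeps Pearson
  r interpretable; at zero noise the coupling is exact up to count rounding.
* **Detection p:** uniform on (0, 0.005) except a configurable 1% of probes
  that fail in one random sample.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: mean-dispersion trends, batch and
cell-composition effects, probe-type chemistry, genomic coordinates, and
correlated null features. The shared-dispersion NB is the smallest model
that exercises the pipeline; it is a documented limitation, not a claim
about real RNA-seq noise.

## Validation by simulation

Three simulation experiments back the test suite (all sizes chosen as
standard desk-scale panels; each runs in seconds):

1. **Null calibration.** 2,000 genes and 2,000 probes with no planted
   effects: the fraction of features passing `p < 0.05` (expression) and
   `p < 0.01` (methylation) must fall within the binomial 99% interval of
   the nominal rate.
2. **Planted recovery, pipeline operating point.** Default generator
   settings: the expression screen attains sensitivity >= 0.8 at realized
   false-discovery proportion <= 0.1 against the planted truth.
3. **Hub recovery.** A recovery experiment that isolates the hub mechanism:
   every DE gene is hub-driven and every DM probe is a hub (2,000 x 2,000
   panel, 5 hubs x 30 links). At zero coupling noise each hub then has
   degree >= 30 while no competitor node can reach the degree-25 screen, so
   100% recovery is guaranteed by construction and verified; recovery
   degrades monotonically across noise levels 0 / 0.5 / 2 (five seeds
   each). Under the *full* default conditions zero-noise recovery is high
   but not guaranteed: planted group effects make strong DM probes and DE
   genes correlate through the shared 4-vs-5 group structure, and such
   "step-correlation" nodes can legitimately crowd a fixed-size hub list.
   That phenomenon is real — it is the same mechanism that makes
   small-cohort co-expression networks dense — and the isolated experiment
   exists precisely to separate mechanism recovery from it.

## Numerical and degenerate-input choices

* Bisection for \(d_0\): interval \((10^{-6}, 10^6)\), trigamma-residual
  tolerance \(10^{-10}\); beyond the upper bound the fit returns the
  complete-shrinkage sentinel.
* Beta clipping for M-values: \([10^{-3}, 1 - 10^{-3}]\), config-pinned.
* Zero-effect features get direction `none`, never an arbitrary sign.
* Hub ties: degree descending, then node id ascending.
* Network exports order edges lexicographically by (probe, gene) and write r
  at full double precision (`%.15g`) so a written network reloads to within
  1e-12; writers are byte-deterministic given identical input.
* Missing values are rejected, not imputed: with n = 9, imputation would do
  more harm than transparency.

## Known limitations

The expression test is a log-scale moderated t, not a count GLM; no
mean-variance trend or robust shrinkage variants; no region-level (DMR)
methylation calling; no probe-type correction beyond quantile
normalization; enrichment is set-based Fisher only, with exact symbol
matching. All are deliberate scope boundaries of a small, auditable
pipeline.
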
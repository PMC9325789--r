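---
title: "Methods: unified dependency screens and survival-based target prioritisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unified dependency screens and survival-based target prioritisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## The problem

Large-scale genetic perturbation screens (CRISPR knockout, shRNA knockdown)
assign each gene, in each cancer cell line, a preprocessed *gene effect*
score: more negative means the line grows worse when the gene is lost.
`depscreen` turns a pair of such screens plus patient expression/survival
cohorts into a ranked shortlist of lineage-specific candidate drug targets.
The motivating application is multiple myeloma (MM): find genes essential in
MM cell lines but not in the pan-cancer background, then ask whether tumour
expression of those genes stratifies patient survival.

The pipeline has four stages:

1. **Unification.** The two platforms measure the same latent dependency
   with different noise and scale. After aligning gene/line grids, entries
   missing on one platform are imputed from the other by a per-cell-line
   loess of observed score pairs across genes. The unified score is the
   weighted average \(S^\theta = \theta S^C + (1-\theta) S^R\) with mixing
   ratio \(\theta\).
2. **Essentiality.** Per gene, *efficacy* \(E\) is the score of the
   \(X\)-th-percentile most sensitive cell line in a group (the \(k\)-th
   order statistic, \(k = \max(1, \lfloor nX/100 \rfloor)\)). A Gaussian is
   fitted to the kernel density of all genes' efficacies; genes whose
   efficacy falls below the fitted lower-tail \(p = 0.001\) quantile
   \(T = \mu + \sigma\,\Phi^{-1}(0.001)\) are called essential. Calls are
   made separately in the target-lineage group (default \(X = 25\), suited
   to small panels) and the background group (default \(X = 1\)); the
   lineage-specific set is the set difference.
3. **Selectivity.** *Dispersion* \(D\) is the spread between the
   \((100-X)\)-th and \(X\)-th percentile of a gene's scores. \(D\) is
   approximately linear in \(E\) for commonly essential and inert genes; an
   OLS line \(\hat D = a + bE\) is fitted across genes and selectivity is
   the normalised residual \(U = (D - \hat D)/\hat D\). Genes with large
   \(U\) are cell-line-selective dependencies — the interesting ones.
4. **Survival.** For each shortlisted gene and cohort, patients are split at
   the empirical expression quartiles (bottom 25% = low, top 25% = high,
   middle excluded). Low vs high is compared by Kaplan–Meier/log-rank and by
   a Cox proportional-hazards model adjusted for age, sex and ISS stage
   (low is the indicator, so HR > 1 means low expression is adverse).
   Per-cohort log hazard ratios are pooled by DerSimonian–Laird
   random-effects meta-analysis with Cochran's Q for heterogeneity, and
   Benjamini–Hochberg control is applied across genes within each endpoint
   (overall survival, progression-free survival).

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `theta` | 0.6 | CRISPR weight in the unified score. The first principal axis of the pooled \((S^C, S^R)\) cloud gives a data-driven ratio \(\theta^* = v_C/(v_C+v_R)\) (reported by `unify_screens()` as `theta_pca`), but the applied default stays at the round 60:40 weighting; inspect, then fix. |
| `x_target` | 25 | Efficacy percentile in the target lineage. 25 suits panels of a few dozen lines: with 34 lines it reads the 8th most sensitive line, robust to single outliers. |
| `x_background` | 1 | Efficacy percentile in the large background panel (449 lines → the 4th most sensitive line). |
| `tail_p` | 0.001 | Lower-tail probability defining the essentiality threshold; uses the exact quantile \(\Phi^{-1}(0.001) = -3.0902\), not a \(z=3\) rule of thumb. |
| `span` | 0.5 | Loess span for cross-platform imputation, fitted per cell line across genes; mid-range and stable at genome scale. |
| `fdr` | 0.05 | BH target rate for the survival screen. |

## Numerical choices

**Gaussian threshold fit.** The efficacy distribution is a near-Gaussian
bulk (non-essential majority) with a left tail of essential genes, so a
plain mean/sd would be dragged left. Instead the kernel density (Gaussian
kernel, Silverman bandwidth, 512-point grid over the data range ±1
bandwidth) is computed, and a scaled normal \(c\,\varphi((s-\mu)/\sigma)\)
is least-squares fitted to the KDE *between the two half-maximum crossings
around its mode* — the region the essential tail cannot reach. The grid
argmax seeds \(\mu\) but the location is refined inside the least-squares
fit: the raw argmax of a KDE is noisy where the density is flat (its
sampling error is several times the grid spacing even at \(10^5\) points),
while the joint fit averages over the whole half-max window. If no
half-maximum crossing brackets the mode (strong multimodality at the chosen
bandwidth) the fit aborts and advises a larger bandwidth. Essential calls
use a strict inequality (`efficacy < threshold`).

**Selectivity denominator.** The residual is normalised by the *fitted*
dispersion, \(U = (D-\hat D)/\hat D\); genes with \(\hat D \le 0\) get
undefined \(U\) and are excluded from ranking. Normalising by the observed
\(D\) instead (available via `denominator = "observed"`) is algebraically
inconsistent with treating \(U\) as a relative residual, but is kept as an
option because both conventions circulate.

**Imputation.** Loess predictions are clamped to the observed predictor
range (local quadratics are meaningless extrapolated), a line needs at
least 30 doubly observed genes to be fitted, and entries missing on *both*
platforms are never invented: they stay missing, are reported, and any gene
still carrying one after imputation is dropped by `unify()` with a message.

**Ties and quartiles.** Expression cutoffs use the linear-interpolation
percentile definition; boundary ties go to the extreme groups, so under
heavy ties (common in microarray data) the low/high groups can exceed their
nominal 25% — a warning reports the sizes. Cox models use Efron tie
handling, the better default for month-resolution event times. Patients
with missing ISS are dropped from adjusted fits (complete case) and
counted. A monotone partial likelihood (e.g. a group with no events) yields
a flagged result with an unstable CI rather than an error, and flagged
fits are excluded from meta-analysis pooling.

**Meta-analysis.** DerSimonian–Laird with fixed weights \(w_i = 1/se_i^2\),
\(Q = \sum w_i (y_i - \bar y_{FE})^2\),
\(\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\big)\),
random weights \(1/(se_i^2+\tau^2)\), two-sided normal p-value on the
pooled estimate. A single cohort passes through unchanged with
\(\tau^2 = 0\). With \(\tau^2 = 0\) the pooled estimate equals
fixed-effects inverse-variance pooling exactly.

## The synthetic-data generator

`simulate_screens()` emulates the structure the essentiality stage assumes:
genes are non-essential, commonly essential, or lineage-essential (10%,
2.5% by default); the latent effect per gene × line is the class mean (−1.5
for essential pairs, 0 otherwise) plus N(0, 0.25) biological noise; each
platform reads the latent effect with its own N(0, 0.25) measurement noise,
the shRNA platform through a linear coupling (slope 1 by default); entries
are masked missing independently at 1%. One RNG stream per call, keyed by
the mandatory seed. The 1% missingness reflects preprocessed gene-effect
releases, which are nearly complete; it matters because unified scores drop
any gene with an entry missing on both platforms, so independent per-entry
missingness compounds across hundreds of lines.

`simulate_cohort()` draws standard-normal expression, exponential event
times with hazard \(\lambda_0 \exp(\text{lp})\) where the linear predictor
carries a planted low-expression (bottom-quartile) contrast per chosen gene
plus age (0.02/yr), sex (0.1) and ISS (0.3/stage) effects — plausible MM
demographics: age N(65, 10), sex Bernoulli(0.5), ISS uniform on {1,2,3}.
Censoring is independent exponential with its rate solved numerically so
the expected censored fraction hits the target (default 30%). PFS is the
minimum of the death time and a progression time with 1.5× the baseline
rate, so PFS ≤ OS by construction.

What the generator does *not* emulate: genome-scale correlation between
genes (co-essential complexes), lineage-specific score scale differences,
platform-specific off-target structure (seed effects in shRNA), informative
censoring, or cohort-specific expression platforms (RNA-seq vs microarray
normalisation). Passing parameter-recovery tests therefore demonstrates
that the statistical machinery is correct under the stated model, not that
real-screen artefacts are handled.

## Study sizes used by the test suite

The recovery suites run at 2000 genes with 40 target-lineage + 400
background cell lines (10 seeds) for the screens arm, and three cohorts of
roughly 800/550/150 patients with 23 genes (50 seeds) for the survival arm;
null calibration uses 1000 simulated cohorts of 2000 patients. These sizes
are large enough that the binomial noise of the measured rates is small
against the thresholds being checked, while a full run of the suite stays
in the minutes range.

## Known limitations

- With only \(k = 3\) cohorts, the DerSimonian–Laird normal p-value is
  mildly anti-conservative in the far tail and the \(\tau^2\) estimate is
  noisy; consequently "the planted gene is the *sole* discovery" is a
  fragile event — even with uniform null p-values and perfect power its
  probability is capped near \((1 - 2\alpha/m)^{m-1} \approx 0.91\) for
  \(m = 23\) genes at \(\alpha = 0.05\). Treat sole-discovery rates as a
  descriptive summary, not a calibrated one. Knapp–Hartung adjustment
  would temper the small-\(k\) tails but is deliberately not the default,
  to keep the plain normal-theory convention.
- The \(\theta\) mapping from the first principal axis,
  \(\theta^* = v_C/(v_C+v_R)\), is the weighting that makes the unified
  axis parallel to the principal direction; it is undefined when the
  platforms are anti-correlated (the fit errors out).
- Gene identity is the symbol; two columns sharing a symbol are an error,
  never a silent merge. Entrez ids ride along as annotation.
- Annotation terms are tested as given; no ontology-hierarchy propagation
  is performed before over-representation testing, and the universe
  defaults to the annotated scored genes supplied by the caller.
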
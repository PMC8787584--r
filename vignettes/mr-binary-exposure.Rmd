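---
title: "Two-sample MR for a binary exposure: models, estimators and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR for a binary exposure: models, estimators and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabilityMR)
```

## The problem

Observational epidemiology repeatedly reports that people with a common
binary condition (the running example in this package is sleep apnea) carry
a substantially higher risk of a second disease (here, glaucoma). Such
associations are vulnerable to confounding, reverse causation and selection.
Two-sample Mendelian randomization (MR) re-asks the question with genetic
instruments: variants robustly associated with the exposure in one GWAS are
looked up in an independent GWAS of the outcome, and the per-variant
"Wald ratios"

$$\hat\theta_i = \frac{\hat\beta_{Y,i}}{\hat\beta_{X,i}},\qquad
  \mathrm{se}(\hat\theta_i) \approx \frac{\mathrm{se}(\hat\beta_{Y,i})}{|\hat\beta_{X,i}|}$$

are combined into a causal estimate of the outcome log-odds per unit of
exposure liability. Because alleles are fixed at meiosis, the design is
immune to classical confounding and reverse causation, at the price of
three assumptions: relevance (strong instruments), independence from
confounders, and no horizontal pleiotropy. The package operationalizes the
full workflow — harmonization, instrument-strength QC, outlier filtering,
six estimators, rescaling and comparison with observational estimates — and
ships a simulator with known ground truth so that every stage is testable.

## Harmonization and instrument QC

Summary tables from two studies rarely encode alleles identically.
`harmonizeInstruments()` aligns the outcome rows to the exposure's effect
allele: reversed allele pairs flip the sign of the outcome beta, strand
flips are resolved through the base complement, and palindromic variants
(A/T, G/C) — whose alleles carry no strand information — are oriented by
allele frequency, or dropped when the minor-allele frequency in either
study exceeds `palindromeMafLimit` (default 0.42, where frequency-based
inference becomes unreliable). Every removal is recorded with a reason
code. Instruments are assumed pre-clumped for linkage disequilibrium; the
upstream clumping threshold is provenance metadata only.

`filterInstruments()` applies the genome-wide significance filter with a
strict inequality (`p < 5e-8` by default; a variant sitting exactly at the
threshold is removed) and an optional replication mask.

Instrument strength uses the observed-scale variance explained per variant,

$$R^2_i = \frac{2\beta_i^2 f_i(1-f_i)}
  {2\beta_i^2 f_i(1-f_i) + \mathrm{se}(\beta_i)^2\, 2 n_i f_i (1-f_i)},$$

with \(f_i\) the minor-allele frequency (the effect-allele frequency is
folded before use; the expression is symmetric in \(f\) vs \(1-f\)), and the
combined F statistic

$$F = \frac{R^2 (n - 1 - k)}{(1 - R^2)\,k},$$

where \(R^2\) is the simple sum of the per-variant values (independent
instruments). When per-variant sample sizes differ, each variant uses its
own \(n\) and the combined F uses the median — a total-function fallback
for tables mixing cohort releases. F is reported, never used to prune;
values above 10 are conventionally read as "strong".

## The six estimators

All estimators operate on a harmonized `InstrumentSet`.

**IVW (multiplicative random effects).** The zero-intercept weighted
regression of outcome on exposure betas with weights
\(w_i = 1/\mathrm{se}(\hat\beta_{Y,i})^2\):
\(\hat b = \sum w_i x_i y_i / \sum w_i x_i^2\), fixed-effect
\(\mathrm{se} = (\sum w_i x_i^2)^{-1/2}\), rescaled by
\(\sqrt{Q/(k-1)}\) with Cochran's \(Q = \sum w_i (y_i - \hat b x_i)^2\).
The multiplicative model is applied strictly — the factor is *not* floored
at 1, so an under-dispersed panel yields a smaller SE than the fixed-effect
fit; `floorDispersion = TRUE` switches to the common floored variant.

**MR-Egger.** The same weighted regression with a free intercept after
orienting all exposure betas positive. The intercept estimates average
directional pleiotropy; the slope remains consistent under the InSIDE
assumption. Standard errors carry the \(\sqrt{Q/(k-2)}\) scaling (again
unfloored — this is exactly the weighted-least-squares sigma, so the fit
goes through `stats::lm`), and p-values use the t distribution on
\(k-2\) degrees of freedom, the standard small-k practice for the
intercept-including fit.

**Weighted median.** The weighted median of the Wald ratios (weights
\(1/\mathrm{se}(\hat\theta_i)^2\)) with linear interpolation across the 50%
cumulative-weight boundary; consistent while invalid instruments carry
less than half the weight. SE by seeded parametric bootstrap,
\(\theta_i^\ast \sim N(\hat\theta_i, \mathrm{se}_i)\).

**Simple and weighted mode.** A Gaussian-kernel density over the ratios —
equal weights or inverse-variance weights — with bandwidth
\(\varphi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,k^{-1/5}\)
(\(\varphi\) = `bandwidthFactor`, default 1). The estimate is the density
argmax on a 10,000-point grid spanning the ratios ± 3 bandwidths; exact
ties break toward the grid value nearest the weighted median. SEs share
the weighted-median bootstrap.

**GSMR-style estimator.** HEIDI outlier filtering (below) followed by a
precision-weighted mean of the ratios whose variance keeps the
second-order delta term for the exposure beta,

$$\mathrm{var}(\hat\theta_i) \approx
  \frac{\mathrm{se}_{Y,i}^2}{\hat\beta_{X,i}^2} +
  \frac{\hat\beta_{Y,i}^2 \mathrm{se}_{X,i}^2}{\hat\beta_{X,i}^4},$$

which is what distinguishes it from plain fixed-effect IVW on the ratios —
the two coincide exactly as \(\mathrm{se}_{X}\to 0\).

**HEIDI filtering.** Iteratively, the current panel's IVW estimate is the
reference; each variant's deviation \(d_i = \hat\theta_i - \hat b\) is
tested as a 1-df chi-square against
\(\mathrm{var}(\hat\theta_i) + \mathrm{var}(\hat b)\) (the reference
variance uses the dispersion-scaled IVW SE), and the single most extreme
variant with \(p < 0.01\) is removed before refitting, stopping when
nothing falls below the threshold or only three instruments remain. The
threshold is configurable; note that at 0.01 a homogeneous panel of k
variants still flags roughly \(k/100\) of them per round, so about a
quarter of clean 34-variant panels lose one variant — an intrinsic cost of
the threshold, not a defect of a particular dataset.

## Scaling and comparison with observational estimates

For a binary exposure the instrument–exposure betas are log-odds, so the
raw causal estimate is "per unit log-odds liability". For interpretability
all reported ORs are rescaled to the effect per *doubling of the odds* of
exposure by multiplying beta and SE by \(\ln 2 \approx 0.693\) and
exponentiating; 95% bounds use the conventional 1.96 (configurable). The
identity `unscale(scale(x)) = x` holds to machine precision.

Published observational ratios with 95% CIs convert to log-scale betas via
\(\beta = \ln(\mathrm{OR})\),
\(\mathrm{se} = (\ln \mathrm{hi} - \ln \mathrm{lo})/3.92\) (hazard ratios
are treated as OR-like for the comparison), and the difference test is

$$Z = \frac{\beta_{\mathrm{MR}} - \beta_{\mathrm{Obs}}}
  {\sqrt{\mathrm{se}_{\mathrm{MR}}^2 + \mathrm{se}_{\mathrm{Obs}}^2}},
  \qquad p = 2\Phi(-|Z|).$$

The MR side enters on the doubling-of-odds scale by default; the published
analyses this package emulates do not state which scale entered their
test, so `zDifference()` also accepts an unscaled estimate. The package
ships a four-row observational table (two meta-analytic odds ratios, one
time-to-event hazard ratio, one matched-cohort odds ratio) used by the
pipeline's forest-plot export.

## What the simulator emulates

`simulatePanel()` generates both summary tables from a known truth:

* `k = 39` independent instruments, minor-allele frequencies uniform on
  0.05–0.5 (the reported effect allele is randomly the minor or major one,
  so MAF folding is exercised);
* true exposure effects \(b_i = 0.015 + |N(0, 0.015)|\). Rationale: the
  panel emulates *replicated genome-wide-significant* hits from a very
  large case-control exposure GWAS (default \(n = 1{,}477{,}325\)); a
  plain half-normal would leave ~20% of draws below significance, which no
  curated instrument set contains. The floor-plus-half-normal keeps every
  instrument significant at that sample size while calibrating a 34-SNP
  panel to explain about 1% of observed-scale variance — matching the
  scale of the real analyses this workflow targets;
* standard errors from the binary-trait approximation
  \(\mathrm{se} = 1/\sqrt{2 n f (1-f)}\), observed betas Normal around
  truth, two-sided normal p-values (floored at 1e-300 to respect the
  \(p \in (0,1]\) contract at extreme Z);
* outcome effects \(\beta_{Y,i} = b\, b_i + \alpha_i\) with pleiotropy
  \(\alpha_i\) absent, balanced \(N(0,\delta)\) or directional
  \(N(\delta, \delta/2)\); planted heterogeneous outliers are displaced by
  `outlierSize` (default 15) outcome-SEs with random sign;
* optional allele-reversed / strand-flipped re-encodings of outcome rows
  (`propReversed`, `propFlipped`) to exercise harmonization, and an
  optional winner's-curse mode that re-draws observed exposure betas until
  they pass the significance threshold (off by default, matching a
  replication-based two-sample design; configs where acceptance is rarer
  than 1e-4 per variant are refused rather than sampled).

Identical seed and configuration reproduce output files byte-for-byte.
What the simulator deliberately does **not** model: linkage disequilibrium
between instruments, case-control ascertainment, allele-frequency
mismatch between studies, multi-allelic sites, and liability-scale
subtleties of the outcome trait. Passing tests therefore demonstrate
correctness of the estimators and plumbing under the stated generative
model, not robustness to every pathology of real GWAS data.

## Numerical and design choices

* **Dispersion without flooring.** Both IVW-MRE and Egger report strictly
  multiplicative random-effects SEs; a config switch restores flooring.
* **Bootstrap SEs are conservative for median/mode.** The parametric
  bootstrap resamples around the *observed* ratios, convolving realized
  noise with fresh noise. For smooth statistics this is innocuous; for
  order and mode statistics it inflates the SE (about 16% for the
  weighted median and 23–35% for the modes at k = 34 under the simulator's
  null), so their nominal 95% intervals cover in roughly 97–99.6% of null
  replicates while the analytic-SE estimators (IVW ~93–94%, Egger ~95%,
  GSMR ~94%) sit at nominal level. This conservatism is a documented
  property of these estimators, kept as prescribed.
* **Small finite-precision bias of the GSMR weighting.** Because the
  second-order variance uses the observed outcome beta, weights correlate
  with realized errors; at the simulator's defaults this biases the
  estimate by about −0.5% to −1% relative (measured −0.0011 ± 0.0002
  against IVW at true beta 0.2, 1500 paired replicates). Regression
  dilution from exposure-beta noise contributes a further ~−0.25% shared
  with IVW. Both are negligible for applied work but visible to
  high-precision Monte Carlo checks.
* **HEIDI reference variance.** The deviation variance adds the
  dispersion-scaled IVW SE of the reference; the positive correlation
  between a ratio and the reference it contributes to is ignored, making
  the per-variant test slightly conservative in stated variance but
  slightly anticonservative in realized rate (~0.8% at nominal 1%).
* **Degenerate inputs.** Exact-interpolation fits (zero residuals) floor
  the SE at 1e-300 rather than reporting zero; all-equal ratios make the
  mode bandwidth zero, in which case the common value is returned.
* **Problem sizes in the test suite.** Monte Carlo checks use 200–1000
  replicates with 100–200 bootstrap resamples and a 512–2000-point mode
  grid; these sizes give MC standard errors comfortably inside the
  asserted tolerances while keeping the suite quick. The acceptance
  script's single pipeline run uses 1000 bootstrap resamples and a
  4000-point grid.

## Worked example

```{r example, eval = FALSE}
sim <- simulatePanel(k = 39, trueBeta = 0, nOutliers = 5, seed = 7)
dir <- tempfile()
writeSimulatedPanel(sim, dir)
res <- runPipeline(file.path(dir, "exposure.tsv"),
                   file.path(dir, "outcome.tsv"),
                   outDir = file.path(dir, "out"), seed = 3)
res$summary$counts       # 39 candidates, 5 HEIDI-excluded, 34 analyzed
res$scaled$ivw_mre       # doubling-of-odds OR with 95% CI
res$comparisons[[1]]     # Z test vs the first observational estimate
```

## Limitations

The estimators assume independent instruments; correlated panels need an
LD-aware extension that is out of scope here. MR-PRESSO, multivariable MR
and Steiger filtering are not implemented. Hazard ratios are compared as
if they were odds ratios, as the emulated analyses do. The doubling-of-odds
scaling is an interpretability device for binary exposures, not a
liability-scale transformation; conclusions about effect *presence* are
scale-invariant, effect *size* statements inherit the scaling convention.
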
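---
title: "Methods: two-sample MR of gut microbial taxa on disease risk"
author: "taxaMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of gut microbial taxa on disease risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxaMR)
```

## The causal question and the model

taxaMR estimates the causal effect of the relative abundance of a gut
bacterial taxon on the risk of a binary disease outcome using
two-sample Mendelian randomization (MR): genetic variants associated
with taxon abundance serve as instrumental variables, with their
abundance effects taken from one GWAS (effects per standard deviation
of abundance, sample size $n$) and their disease effects from an
independent case-control GWAS (effects on the log-odds scale). Because
alleles are assigned at conception, a variant that satisfies the three
instrumental-variable assumptions — (1) associated with the exposure,
(2) independent of confounders, (3) affecting the outcome only through
the exposure — identifies the causal effect $\theta$ (log-OR of disease
per SD of abundance) free of reverse causation and, in expectation, of
confounding.

For instrument $j$ with aligned effect estimates
$(\hat\beta_{xj}, \hat\beta_{yj})$ and standard errors
$(\sigma_{xj}, \sigma_{yj})$, the per-variant Wald ratio is
$\hat\theta_j = \hat\beta_{yj}/\hat\beta_{xj}$ with first-order
standard error $\sigma_{yj}/|\hat\beta_{xj}|$. The estimators combine
these as follows.

* **IVW** (primary): the weighted least-squares slope of
  $\hat\beta_y$ on $\hat\beta_x$ through the origin with weights
  $w_j = \sigma_{yj}^{-2}$,
  $\hat\theta = \sum_j w_j \hat\beta_{xj}\hat\beta_{yj} /
  \sum_j w_j \hat\beta_{xj}^2$. Valid when all instruments are valid
  or pleiotropy is balanced.
* **MR-Egger**: the same regression with an intercept, after orienting
  every variant so $\hat\beta_{xj} \ge 0$. The slope is robust to
  directional pleiotropy under the InSIDE assumption; the intercept
  estimates the average pleiotropic effect and is the basis of the
  intercept test.
* **Weighted median**: the 50% weighted quantile of the ordered Wald
  ratios; consistent while at least half the total weight comes from
  valid instruments.
* **Maximum likelihood**: the joint model
  $\hat\beta_{xj} \sim N(\gamma_j, \sigma_{xj}^2)$,
  $\hat\beta_{yj} \sim N(\theta\gamma_j, \sigma_{yj}^2)$, maximized
  over $(\theta, \gamma_1,\dots,\gamma_J)$; accounts for sampling
  error in the exposure effects and reduces to fixed-effect IVW as
  $\sigma_{xj} \to 0$.

Estimates are reported as odds ratios $e^{\hat\theta}$ with normal
confidence intervals $e^{\hat\theta \pm z\,\mathrm{se}}$.

## Instrument selection

Per exposure taxon, the pipeline screens variants at
$p < 10^{-5}$ (the conventional relaxation for molecular/microbiome
exposures, where genome-wide-significant hits are too few), then
performs greedy LD clumping against a reference dosage panel: the
smallest-p variant becomes an index and removes every variant on the
same chromosome within ±500 kb with squared dosage correlation
$r^2 \ge 0.01$; the process repeats on the remainder. Instrument
strength is summarized by the variance explained
$R^2_j = 2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)\beta_j^2$ and the
set-level statistic
$F = R^2 (n - k - 1) / \big(k (1 - R^2)\big)$, $R^2 = \sum_j R^2_j$,
with $k$ instruments; sets with $F \le 10$ are flagged weak and
excluded from MR. The $F$ formula contains $k$, so one aggregate $F$
per set is the literal reading adopted here; per-variant
$(\beta/\mathrm{se})^2$ is reported as a diagnostic alongside.

Choices where conventions differ, fixed here and exposed as arguments:

* *Clumping ties* (equal p): broken by chromosome, then position, then
  variant id, making the output invariant to input order.
* *"distance = 500 kb"* is a half-window: ±500 kb around the index.
* *Variants absent from the panel* (or lacking position) pass through
  unclumped with a logged warning — dropping them would silently
  shrink $k$.

## Harmonization

Exposure and outcome records are matched by variant id and aligned to
the exposure's effect allele: same alleles are kept, swapped alleles
negate the outcome effect (and complement its EAF), strand-complement
matches are resolved the same way after complementing (disable with
`strand_complement = FALSE`), and anything else is dropped as
incompatible. Palindromic A/T and C/G variants are dropped
unconditionally — no allele-frequency rescue — since their strand
cannot be resolved from alleles alone. Every non-kept instrument
appears in the exclusion log with its reason, so kept + excluded
always accounts for the full instrument set.

## Sensitivity analyses

* **Cochran's Q** on the Wald ratios with df $J-1$ (IVW form) and
  Rücker's $Q'$ with df $J-2$ (Egger form), referenced to chi-square.
* **Egger intercept test**: two-sided normal test of the intercept;
  $p < 0.05$ flags the pair as pleiotropic and the pipeline discards
  its causal claim.
* **MR-PRESSO**: observed residual sum of squares
  $\sum_j w_j(\hat\beta_{yj} - \hat\theta_{(-j)}\hat\beta_{xj})^2$
  with leave-one-out IVW slopes, against a parametric null simulated
  by redrawing both effect vectors; the global p uses the add-one
  estimator $(1 + \#\{RSS^* \ge RSS_{obs}\})/(n_{sim}+1)$ so it is
  never exactly zero. Per-variant outlier p-values are Bonferroni
  corrected by $J$; the distortion test (estimate shift after outlier
  removal against random same-size removals) is advisory only.
* **Leave-one-out** IVW and **funnel coordinates** (Wald ratio vs
  precision) are emitted as tables, not figures.

## Multiplicity

IVW (and each sensitivity method's) p-values are BH-adjusted within
one family per method × taxonomic level × outcome. The genus level of
the taxon panel this package emulates has 119 taxa, and the published
FDR values for that panel reproduce only under $m = 119$ (not the 195
taxa of all levels pooled), so `bh_adjust()` accepts a family size
`m` larger than the supplied p-vector and `annotate_fdr()` can force
it via `group_m = c(genus = 119)` when only a subset of rows is at
hand. A pair is reported *significant* when its IVW FDR < 0.05 and
neither the pleiotropy nor the heterogeneity flag is raised — the
conservative composition of the separate published rules.

## The synthetic-data generator

`simulate_mr_dataset()` emulates the structure of the real inputs —
a multi-taxon abundance GWAS feeding a shared case-control outcome
GWAS — with known ground truth:

* instrument effects $\gamma_j \sim N(0, \sigma_\gamma^2)$ (zero for
  background variants), observed
  $\hat\beta_{xj} \sim N(\gamma_j, \sigma_{xj}^2)$ with the
  quantitative-trait standard error
  $\sigma_{xj} = 1/\sqrt{2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)\,n}$;
* outcome effects
  $\hat\beta_{yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{yj}^2)$
  with the case-control approximation
  $\sigma_{yj} = 1/\sqrt{2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)\,
  n_{\mathrm{eff}}\,\varphi(1-\varphi)}$, $\varphi$ the case fraction
  (any constant misfit in this approximation rescales all outcome SEs
  uniformly and does not affect method behavior);
* pleiotropy regimes: `none`, `balanced`
  ($\alpha_j \sim N(0,\sigma_\alpha^2)$), `directional`
  ($\alpha_j \sim N(\mu_\alpha,\sigma_\alpha^2)$), `outlier`
  (a chosen count of instruments displaced by a chosen multiple of
  their outcome SE). In the directional regime the instrument effects
  are drawn half-normal ($\gamma_j \ge 0$): with signed $\gamma$,
  MR-Egger's $\beta_x \ge 0$ orientation would flip the sign of
  $\alpha_j$ for half the instruments and turn directional pleiotropy
  into balanced, making $\mu_\alpha$ unrecoverable by construction —
  "directional" is therefore defined relative to the
  exposure-increasing allele;
* allele labels drawn at random with a configurable palindromic
  fraction (default 0.1), and outcome records randomly allele-swapped
  and strand-flipped (defaults 0.25 each) so harmonization is
  exercised end to end.

Defaults mirror the emulated study: 119 genus-level taxa, exposure
$n = 18{,}340$, outcome 69,501 cases / 105,974 controls, MAF uniform
on (0.05, 0.5), $\sigma_\gamma = 0.05$ (giving $F$ statistics in the
tens at these sample sizes, matching the 13–167 range typical of such
panels), 10 instruments per taxon (the published per-taxon counts run
8–14). Calibration studies use $\sigma_\gamma = 0.1$ as the "strong
instrument" scenario.

`simulate_reference_panel()` draws each individual's two haplotypes
per LD block from a shared latent allele copied with probability
$\sqrt r$, so within-block dosage correlation is approximately $r$
and across-block correlation is zero; block positions are spaced 2 Mb
apart (outside any clumping window) with 10 kb within-block spacing.

What the generator does **not** emulate: real LD between instruments
of different taxa, compositional covariance between taxon abundances,
assortative mating or population stratification, and winner's-curse
selection in the exposure GWAS. Passing calibration tests therefore
demonstrates correctness of the estimators under their own model, not
robustness to these real-data complications.

## Numerical choices

* All p-values use the normal reference (not $t$), and the 95% CI uses
  the exact quantile 1.959964, not 1.96; documented because $J$ is
  often small and conventions differ across toolkits.
* IVW and Egger default to a *multiplicative floor* residual scale:
  the fixed-effect SE is multiplied by $\max(1, \sqrt{Q/\mathrm{df}})$
  so excess heterogeneity widens intervals but can never narrow them.
  Fixed-effect mode is available by flag; the null-calibration studies
  use it because the floor truncation makes p-values mildly
  conservative under exact homogeneity.
* The weighted-median SE is a parametric bootstrap (default 1000
  replicates) with an explicit seed; results are bit-reproducible.
* The maximum-likelihood optimizer is coordinate ascent with
  convergence at successive-$\theta$ change $< 10^{-10}$, a 10,000
  iteration cap (a convergence error carries the last iterate), and
  SE from the numerically differentiated profile-likelihood curvature.
* Q degrees of freedom are $J-1$ (IVW) and $J-2$ (Egger) throughout.
  Some published sensitivity tables are numerically consistent with
  df $= J$ instead; the standard convention is fixed here regardless.
* MR-PRESSO requires $J \ge 4$, Egger and the weighted median
  $J \ge 3$, IVW $J \ge 2$ (with a logged Wald-ratio fallback at
  $J = 1$); inapplicable methods are skipped with a note, never
  silently approximated.

## Problem sizes used in validation

The test-suite and acceptance-script Monte Carlos use: 1,000
replicates for IVW bias/coverage ($J = 100$, $\theta = 0.1$) and null
calibration ($J = 10$); 500 replicates for Egger intercept recovery;
200 seeded runs for MR-PRESSO power ($J = 10$, one instrument
displaced by $10\sigma_y$, $n_{sim} = 500$) and for the null
false-outlier rate; 50 runs for the weighted-median breakdown sweep.
These sizes put Monte-Carlo error comfortably inside the asserted
tolerances while keeping a full run in tens of seconds.

## Known limitations

rsID-only matching during harmonization (no chrom/pos cross-check);
no LD-proxy lookup for instruments missing from the outcome; no
Steiger directionality filtering, MR-RAPS, mode-based or multivariable
estimators; LD clumping assumes a panel of the relevant ancestry is
supplied; the F filter applies the aggregate formula, so a set mixing
one strong and many weak instruments can pass while individual
variants are weak — inspect the per-variant diagnostic in such cases.
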
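---
title: "Methods: summary-statistics Mendelian randomization in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics Mendelian randomization in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (say,
gastroesophageal reflux disease) on an outcome (say, stroke or
intracranial aneurysm) from GWAS summary statistics alone. A variant is a
valid instrument if it is associated with the exposure (relevance), shares
no confounder with the exposure-outcome relationship (independence), and
affects the outcome only through the exposure (exclusion). `mrpipe`
implements the full two-sample workflow at the summary level: instrument
selection, allele harmonization, the standard estimator battery,
sensitivity diagnostics, multivariable MR, and two-step mediation
decomposition, together with a synthetic GWAS generator so that every
stage is testable without consortium downloads.

Throughout, SNP *j* contributes an aligned pair of association estimates:
$(\hat\gamma_j, \sigma_{x,j})$ for the exposure and
$(\hat\Gamma_j, \sigma_{y,j})$ for the outcome, giving the ratio estimate
$r_j = \hat\Gamma_j / \hat\gamma_j$ and the first-order weight
$w_j = \hat\gamma_j^2 / \sigma_{y,j}^2$.

## Instrument selection

The selection pipeline applies, in order:

1. **Genome-wide significance**, strict: $p < 5\times10^{-8}$.
2. **LD clumping**: greedy on ascending p; a retained index SNP discards
   every other SNP with $r^2 \ge 0.001$ lying strictly within a
   10,000 kb window on the same chromosome. Clumping requires an explicit
   LD lookup (`ld_info`); a pair inside the window with no LD entry is a
   hard error — independence is never silently assumed. Pairs on
   different chromosomes, or beyond the window, are never clumped.
3. **Frequency and palindrome filters**: minor allele frequency
   $\le 0.01$ is excluded (inclusive bound, matching the convention the
   pipeline mirrors), as is any A/T or C/G pair, whose strand cannot be
   resolved from alleles alone. Palindromic SNPs are dropped outright,
   never frequency-inferred.
4. **Instrument strength**: the per-SNP F-statistic
   $F_j = \hat\gamma_j^2/\sigma_{x,j}^2$; SNPs with $F_j < 10$ are
   excluded and the mean F of the survivors is logged.

Harmonization then orients each outcome record onto the exposure's effect
allele. For non-palindromic biallelic SNPs four configurations are
resolvable — identical, swapped (sign flipped), strand-complement
identical, strand-complement swapped (sign flipped) — and anything else
is dropped with a logged reason. A user-supplied exclusion list (one
variant id per line) stands in for confounder-database screening, which
has no reproducible offline contract.

## Estimators

- **Wald ratio** (single SNP): $\hat\beta = r_j$,
  $SE = \sigma_{y,j}/|\hat\gamma_j|$ (first order; with $F \ge 10$
  enforced upstream the second-order term is negligible).
- **IVW**: $\hat\beta = \sum w_j r_j / \sum w_j$, algebraically the
  $1/\sigma_{y}^2$-weighted through-origin regression of outcome on
  exposure betas. The default model is multiplicative random effects:
  the fixed-effect SE $(\sum w_j)^{-1/2}$ inflated by
  $\max(1, \sqrt{Q/(J-1)})$. The inflation is floored at one — it never
  deflates — which is the prevailing, conservative convention; the
  fixed-effect variant is exposed via `model = "fixed"`. At $J = 1$ IVW
  reduces exactly to the Wald ratio.
- **MR-Egger**: rows are first oriented so every exposure beta is
  non-negative (the estimate is invariant to per-SNP sign flips), then
  outcome betas are regressed on exposure betas *with* an intercept,
  weights $1/\sigma_y^2$. Under the InSIDE assumption (instrument
  strength independent of direct effects) the slope is a consistent
  causal estimate and the intercept estimates the average directional
  pleiotropic effect. SEs use the same floored multiplicative
  overdispersion; p-values use $t_{J-2}$, the standard small-sample
  convention for Egger regression.
- **Weighted median**: order the $r_j$, form normalized cumulative
  weights $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum w$, and interpolate $r$
  at $s = 0.5$. Consistent while less than half the instrument *weight*
  is invalid. The SE comes from a seeded parametric bootstrap (default
  1000 replicates) resampling both betas from normals with their SEs;
  the seed is a required argument and results are bit-reproducible.

Odds ratios are $e^{\hat\beta}$ with 95% intervals
$e^{\hat\beta \mp 1.96\,SE}$, kept at full precision internally and
rounded to 3 decimals only in report tables.

## Sensitivity battery and adjudication

- **Cochran's Q** with first-order weights about the fixed-effect IVW
  center, $\chi^2_{J-1}$; $p < 0.05$ flags heterogeneity.
- **Egger intercept test**: re-exports the regression intercept;
  $p < 0.05$ flags directional pleiotropy. Not computable below $J = 3$.
- **MR-PRESSO**: the observed statistic is the weighted residual sum of
  squares about leave-one-out IVW fits,
  $\mathrm{RSS} = \sum_j (\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2
  / \sigma_{y,j}^2$. Its null distribution is built from seeded
  parametric replicates drawing
  $\hat\gamma^*_j \sim N(\hat\gamma_j, \sigma_{x,j})$ and
  $\hat\Gamma^*_j \sim N(\hat\beta_{(-j)}\hat\gamma_j, \sigma_{y,j})$
  and recomputing the statistic. The global p is the fraction of
  simulated RSS at or above the observed; per-SNP outlier p-values
  compare the j-th squared residuals, Bonferroni-gated at $0.05/J$;
  when outliers are flagged the IVW estimate is recomputed without them.
  A distortion test (raw-vs-corrected shift against random same-size
  removals) is reported as informational only. Minimum $J = 4$.
- **Leave-one-out**: J IVW re-fits, flagging exclusions that flip the
  estimate's sign or move its p across 0.05.

The **adjudication rule** mirrors how such screens are read: $J = 1$
supports only a Wald ratio and no sensitivity analysis, so no causal
claim (`wald_only`, classified `not_established`); at $J = 2$ IVW and Q
are available but pleiotropy is `not_assessable`; at $J \ge 3$,
heterogeneity ($Q$ p < 0.05) demotes IVW and promotes the weighted
median to primary — the claim stands only if the weighted median is
itself significant with concordant sign — otherwise IVW remains primary.

Classification uses the Bonferroni threshold
$\alpha/(\text{exposures} \times \text{outcomes})$ — for a
$12 \times 8$ screen, $0.05/96 = 5.21\times10^{-4}$ at 3 significant
figures. The threshold is printed at 3 s.f. but compared at full
precision, avoiding boundary artifacts; `significant` means
$p < \text{threshold}$, `suggestive` means
$\text{threshold} \le p < 0.05$.

## Multivariable MR

`build_mvmr_design()` pools SNPs genome-wide significant for *at least
one* exposure (each SNP once, clumped on its minimum p across exposures —
the standard construction), applies the same MAF/palindrome/F filters,
intersects all exposure tables and the outcome, and aligns every table to
a single orientation. `mvmr_ivw()` is the weighted multiple regression of
outcome betas on the K exposure-beta columns without intercept, weights
$1/\sigma_y^2$; each coefficient is a *direct* effect conditional on the
other exposures. SEs use overdispersion $\max(1, \sqrt{Q_{res}/(J-K)})$,
so at $K = 1$ the result equals univariable IVW exactly. Reported
per-exposure SNP counts are the number of union SNPs genome-wide
significant for that exposure — a counting convention, documented here
because published tables rarely define theirs. Conditional F statistics
and MVMR-Egger are out of scope.

## Two-step mediation

For exposure → mediator → outcome, `run_mediation_stage()` estimates the
total effect $\beta_1$ (exposure → outcome), $\beta_2$ (exposure →
mediator) and $\beta_3$ (mediator → outcome), all as adjudicated primary
estimates of univariable two-sample runs; the mediated effect is
$\beta_2\beta_3$ and the proportion mediated $\beta_2\beta_3/\beta_1$
(reported even when negative or above 100%, flagged, never clipped). The
mediator → outcome step excludes the exposure's selected instruments via
the harmonizer's exclusion list, so the mediator's instrument set is not
downstream of the exposure. $\beta_2$ and $\beta_3$ deliberately come
from univariable runs, not MVMR direct effects, matching the convention
of the published tables the package reproduces. Triplets whose
mediator → outcome link is not established are emitted with a
`not_established` flag rather than silently dropped. No SE for the
mediated effect is attached by default; a delta-method SE
($\sqrt{\beta_3^2 se_2^2 + \beta_2^2 se_3^2}$) is available as a clearly
labelled extension.

Two rounding profiles are exposed. `full_precision` is the analytical
default. `published_rounding` rounds the product to 3 decimals *before*
dividing by $\beta_1$ and reports the percentage at 2 decimals; this is
the convention required to reproduce the bundled published mediation
table digit for digit (the unrounded product gives, e.g., 22.27% where
the published row says 22.49%). One bundled row carries a
mediator-outcome coefficient corrected from 0.195 to 0.196: the printed
value is inconsistent both with the row's own printed product and with
the logarithm of the corresponding published odds ratio, so the
OR-consistent value is carried with `beta3_corrected = TRUE` and the
printed one kept alongside.

## The synthetic generator

`simulate_gwas_pair()` emits exposure and outcome tables under a fully
specified causal model. Design choices, and what they do and do not
emulate:

- **Sampling noise.** For a standardized trait,
  $\sigma_j = 1/\sqrt{2 n p_j (1-p_j)}$ with effect-allele frequency
  $p_j \sim U(0.05, 0.95)$; binary traits use the same normal
  approximation on the log-odds scale with `n` read as an effective
  sample size. Doubling `n` scales every SE by $1/\sqrt2$.
- **Instrument strengths.** True effects are $|N(0, 0.05)|$, floored at
  $(z_{5\times10^{-8}} + 2)\,\sigma_{x,j}$ so each instrument clears
  genome-wide significance with high (~98%) probability; a configuration
  whose floor dwarfs the effect scale fails loudly rather than emitting
  unusable instruments.
- **Orientation.** The generator reports the exposure-increasing allele
  as the effect allele. This is deliberate: with sign-symmetric
  instrument effects a constant pleiotropic shift is indistinguishable
  from balanced pleiotropy once MR-Egger orients its rows, so
  "directional" pleiotropy is only meaningful relative to a fixed
  orientation — the setup standard in the MR simulation literature.
- **Pleiotropy modes.** `none`; `balanced` ($\alpha_j \sim N(0,\sigma)$);
  `directional` ($N(\mu,\sigma)$); `inside_violating`, which couples
  $\alpha_j$ to instrument strength through a Gaussian copula on the
  rank-transformed strengths with correlation `rho` — the violated
  assumption is named in the field but no mechanism is standard, so the
  copula is a documented choice. `prop_invalid` confines pleiotropy to a
  random subset of SNPs (e.g. 40% invalid instruments).
- **Outliers.** `n_outliers` SNPs receive a bump of
  `outlier_scale` × the outcome SE on their true outcome effect, with
  positive sign: directional outliers are what outlier-corrected
  re-estimation is meant to fix, and sign-random bumps would cancel in
  roughly half the replicates, making planted-outlier tests
  uninformative.
- **LD.** Optionally block-diagonal with constant within-block
  $r^2$; blocks are placed far beyond the clumping window. Real LD
  panels are out of scope.
- **Mediation triplets.** Two disjoint instrument sets are emitted in the
  same tables: exposure instruments (mediator effect
  $\beta_2\gamma_j$, outcome effect
  $(\text{direct} + \beta_2\beta_3)\gamma_j$) and mediator-specific
  instruments with no exposure effect. The true total effect is
  $\beta_1 = \text{direct} + \beta_2\beta_3$.

Because the generator draws independent noise for the two samples, it
emulates non-overlapping GWAS; it does not emulate sample overlap,
ancestry structure, winner's-curse selection from a discovery scan, or
real LD — passing tests show correctness of the estimators and pipeline
under the stated model, not robustness to those features of real data.

## Problem sizes, seeds and numerical conventions

All Monte-Carlo components take explicit seeds and restore the caller's
RNG state; nothing uses global random state. The simulation suites use
50-SNP instrument sets (100 for effect-recovery runs) at effective sample
sizes of $5\times10^5$: null calibration over 1000 replicates, recovery
and robustness comparisons over 500, outlier correction over 100 and
end-to-end mediation recovery over 200 — sizes chosen so each suite
estimates its rate to about a percentage point. Emitted p-values are
$2\Phi(-|\hat\beta/\sigma|)$ floored at the smallest positive double so
the $(0,1]$ invariant survives extreme z-scores. Table I/O writes 17
significant digits, so a write/read round trip is exact. Strictness
conventions: significance selection strict (<), MAF exclusion inclusive
(≤), clumping window strict (<).

## Known limitations

- **Weak-instrument attenuation.** First-order IVW on noisy exposure
  betas is attenuated by roughly $1/\bar F$; at the default simulation
  conditions this is a relative bias of ~0.25%, visible (though within
  three Monte-Carlo SEs) in 500-replicate recovery runs.
- **Weighted-median bootstrap SE.** The parametric bootstrap resamples
  sampling noise only; with many invalid instruments the spread induced
  by pleiotropy is not reflected in the SE, so the weighted median can
  be overconfident under a null causal effect. This matches the
  estimator as commonly implemented; it is why adjudication requires
  sign-concordance with IVW rather than treating the weighted median
  p-value as sufficient on its own.
- **Outlier correction is an average improvement, not a guarantee.**
  Removing planted directional outliers improves the estimate in most
  replicates, but in a minority the outlier-free estimate's own sampling
  noise lands it farther from the truth than the partially-cancelled
  raw estimate.
- Reverse-direction MR, Steiger filtering, proxy-SNP search, funnel
  plots/I², mode-based estimators and real-data downloads are out of
  scope.
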
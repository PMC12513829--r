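---
title: "Simulating susceptibility versus progression genetics and index event bias"
author: "progsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating susceptibility versus progression genetics and index event bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsim)
```

## The problem

Genetic studies of disease *progression* — here operationalised as
disease-specific mortality after diagnosis — differ from studies of
disease *susceptibility* in two structural ways. First, they are run
within patients only, so any factor that contributes to becoming a case
acts as a collider: conditioning on case status induces spurious
(typically negative) correlations among otherwise independent causes of
susceptibility, distorting within-case effect estimates of
susceptibility variants on progression ("index event bias"). Second,
their effective sample size is driven by the event count, which is far
smaller than the case-control sample sizes behind modern susceptibility
GWAS.

`progsim` provides a complete, self-contained laboratory for this
problem: a liability-threshold generative model in which susceptibility
and progression share causal variants and a nongenetic risk factor,
fast survival and case-control genome-wide scans, quantification of the
collider bias against the known simulated truth, a slope-hunter-style
summary-statistic correction, and the comparison statistics used when
contrasting the two genetic architectures (direction concordance,
Bonferroni replication counts, polygenic-score transfer under
proportional hazards, fixed-effect meta-analysis with Cochran's Q).

## The generative model

For individual $i$ with genotype dosages $g_{ij}$ at $m$ independent
biallelic variants (allele frequencies $p_j$, Hardy–Weinberg, no LD),
the susceptibility liability is

$$L_{S,i} = \sum_j \beta_{S,j}\,(g_{ij} - 2p_j) + c_S U_i + e_i,$$

with $U_i \sim N(0,1)$ a shared nongenetic risk factor,
$e_i \sim N(0,\,1 - h^2_S - c^2_S)$, and effects rescaled after drawing
so that $\sum_j 2p_j(1-p_j)\beta_{S,j}^2 = h^2_S$ *exactly*. Disease is
the threshold indicator $L_{S,i} > t_S = \Phi^{-1}(1-K)$ for prevalence
$K$. Centring dosages by $2p_j$ keeps allele frequencies from shifting
the threshold — the standard liability-model convention.

Within cases, the progression linear predictor is

$$\eta_i = \sum_j \beta_{P,j}\,(g_{ij} - 2p_j) + c_P U_i,$$

reusing the *same* $U_i$ — this is the sole source of the collider.
The primary progression outcome is time-to-event: survival time after
diagnosis drawn from an exponential with rate
$\lambda_0 e^{\eta_i}$, censored uniformly on $(0, t_{max})$, matching
the proportional-hazards analyses the framework is meant to emulate. A
binary threshold mode ($\eta_i + e_{P,i} > t_P$) is retained for
liability-style checks.

Variants fall into four classes — null, susceptibility-only,
progression-only, and shared (effect correlation $\rho$) — drawn
per-variant with configurable fractions. Age at diagnosis is a
decreasing function of liability
($\text{age} = 65 - 5 L_S + N(0, 5^2)$ years, truncated to [18, 100]),
so that adjusting for onset age matters, mirroring the known genetic
overlap between onset age and susceptibility; non-cases carry a
censoring age drawn around the same location. Sex and birth year are
simulated as pure noise covariates.

### Reference study conditions

The package defaults define one set of study conditions used throughout
the tests and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| n_individuals | 50,000 | yields ≈5,000 cases at K = 0.1 |
| m_variants | 2,000 | desk-scale panel; each variant is its own locus (no LD) |
| prevalence K | 0.10 | a common complex disease |
| h2_S / h2_P | 0.30 / 0.02 | strong susceptibility, weak progression heritability |
| c2_S = c2_P | 0.20 (grid 0–0.4) | "various proportions" of shared nongenetic liability |
| pi_S_only / pi_P_only / pi_shared | 0.05 / 0.05 / 0.025 | sparse causal architecture, ρ = 0.5 in the shared class |
| lambda0 | 0.08 / year | ≈40% case fatality within the 15-year censoring horizon, typical of high-mortality diseases |
| eligibility | ≥ 0.25 y follow-up, ≥ 50 events | boundary-inclusive ("at minimum") |
| QC | INFO > 0.7 (strict), MAC ≥ 20 (inclusive) | simulated INFO is fixed at 1 |

Sample-size choices in tests are the package's own: cohorts of 20,000
individuals for the bias grid and PGS-transfer replicates, 50,000 where
≈5,000 cases are required, 100,000 for one-off variance-decomposition
checks. These sizes keep Monte Carlo error well inside the stated
tolerances.

## The scans

`scanProgression()` and `scanSusceptibility(mode = "age_of_onset")`
implement the architecture of fast score-test survival GWAS tools: one
covariate-only Cox partial-likelihood fit (Breslow ties), then for each
variant the score statistic $U_j = \sum_i g_{ij} r_i$ (martingale
residuals $r$), its risk-set variance reduced by the covariate
information (the efficient score), a one-step estimate
$\hat\beta_j = U_j/V_j$ with $se_j = V_j^{-1/2}$. Breslow tie handling
is used throughout; simulated event times are continuous, so ties are
rare and the convention is immaterial. `exactCoxFit()` — a full Newton
maximisation of the same partial likelihood — is kept as the per-variant
oracle: across random small instances the two routes agree to
$|\Delta z| < 0.2$ with complete sign agreement for $|z| > 1$.
Monomorphic variants produce flagged records (z = 0) rather than being
dropped silently, which keeps the output shape stable;
`variantQC()` removes them along with low-INFO / low-MAC records.

`scanSusceptibility(mode = "case_control")` is a per-variant logistic
score test (null model: disease ~ covariates), the direction-of-effect
path that feeds Z-score meta-analysis when effect sizes are
unavailable. `downsampleMatch()` subsamples a cohort to exact event and
censored counts so the susceptibility scan can be run at the
progression scan's effective sample size.

Simulated cohorts are homogeneous, so principal components are omitted
from all default covariate sets; sex and birth year are retained as in
the emulated designs.

## Index event bias and its correction

With $c_S, c_P > 0$, case-only estimates of susceptibility-only
variants on progression are biased *against* the susceptibility
direction. `biasMetrics()` reports, per causal class, the raw mean
signed bias, the RMSE and MAE, and a **susceptibility-oriented** mean
bias $E[\mathrm{sign}(\beta_{S})(\hat\beta_P - \beta_{P})]$. The
oriented version is the informative one: effect draws are symmetric, so
the raw mean across variants is ~0 by construction even under strong
collider bias, while the oriented mean is zero when $c^2 = 0$ and grows
in magnitude (negative, i.e. opposite to $\beta_S$) along the
$c^2$ grid.

The correction follows the slope-hunter idea on summary statistics.
Among susceptibility-selected pairs, `fitSlopeMixture()` fits by EM a
K-component (default K = 2: susceptibility-only versus shared) mixture
of regressions through the origin, $\beta_P = b_k \beta_S +
\varepsilon_k$ with component variance $\sigma_k^2 + se_P^2$ —
progression measurement error enters additively, the simple and
standard treatment for summary-statistic mixtures. The M-step is a
generalized EM: an exact weighted-least-squares update of $b_k$ given
$\sigma_k^2$, then a one-dimensional maximisation of the expected
complete-data log-likelihood in $\sigma_k^2$; each step increases the
EM objective, so the log-likelihood trace is provably non-decreasing
(asserted in the tests). Ten random restarts guard against local
optima; restart seeds derive deterministically from the caller's seed.

The adjustment slope is read from the component designated
susceptibility-only — by default the one with the **largest mixing
proportion**, on the assumption that susceptibility-only variants
dominate the selected set (the analogue of the original method's
selection assumption); a smallest-residual-variance rule is available
(`designation = "smallest_sigma"`) since the susceptibility-only
cluster is exactly the one with no extra dispersion around its line.
`adjustEffects()` then applies
$\beta_P^{adj} = \beta_P - b\,\beta_S$,
$se^{adj} = \sqrt{se_P^2 + b^2 se_S^2}$ to **all** pairs, not only
selected ones, mirroring summary-statistic practice; the adjusted
standard error can never shrink.

Two open choices were resolved as configuration: the selection
threshold for pairs entering the slope fit (default the genome-wide
5e-8; presets that need a well-populated selected set at desk scale
concentrate h2_S in fewer loci rather than loosening the threshold) and
whether correction is applied to all or only selected pairs (all, as
above).

## Scenarios

`scenarioPreset()` / `runScenario()` wire the stages into four designs:

- **power_comparison** — progression scan among cases versus an
  age-of-onset susceptibility scan on a cohort down-sampled to the same
  event/censored counts. The preset concentrates $h^2_S = 0.3$ in ~10
  loci (pi_S_only = 0.005): the emulated reality is a mature
  susceptibility GWAS with many well-powered loci contrasted against a
  weak progression trait ($h^2_P = 0.02$ over 5% of variants); spreading
  0.3 over 100 loci would make *both* scans powerless at desk scale and
  the contrast vacuous.
- **pgs_transfer** — standardized PGS from the true susceptibility and
  progression effects, evaluated on onset (age scale, whole cohort) and
  on within-case survival; partial overlap (pi_shared = 0.025, ρ = 0.5).
- **ieb_grid** — sweeps $c^2_S = c^2_P \in \{0, 0.1, 0.2, 0.4\}$ and
  reports per-class bias metrics of the progression scan against the
  truth (no susceptibility scan is needed: orientation uses the true
  $\beta_S$).
- **correction_eval** — the full selection → mixture fit → adjustment
  pipeline at $c^2 = 0.4$, with $h^2_S$ concentrated in ~30 loci
  (pi_S_only = 0.015, n = 25,000) so that the 5e-8 selection reliably
  yields the ≥10 pairs the mixture fit requires.

All replicate- and restart-level randomness derives from a single seed
via the documented splitting rule in `childSeed()`; identical spec and
seed reproduce every table byte for byte, and each report embeds a
provenance block (full configuration, seed, package version) sufficient
to regenerate it.

## Numerical conventions and degenerate inputs

- Thresholds follow the quoted wording: significance and INFO are
  strict (`p < 5e-8`, `INFO > 0.7`), eligibility and MAC are inclusive
  (`≥ 0.25` years, `≥ 50` events, `MAC ≥ 20`).
- The two-sided binomial test doubles the smaller tail; against 0.5 it
  coincides with the exact likelihood-based test and agrees with the
  continuity-corrected normal approximation to three decimals from
  n = 500. The default confidence interval is the normal approximation
  (Wilson and exact Clopper–Pearson by flag).
- Pairs with an exactly zero effect on either axis carry no direction
  and are excluded from concordance counts (reported, not silently
  dropped).
- Onset-age stratification splits at the median with ties going to the
  early-onset stratum; a stratum below 50 events is refused and flagged
  rather than fitted.
- Monomorphic dosage vectors, all-censored outcomes, single-class
  outcomes, degenerate (zero-variance) scores, collinear covariates and
  monotone partial likelihoods all raise informative errors instead of
  returning numbers.
- PGS standardisation uses the sample (n − 1) variance; with one
  simulated population, per-ancestry standardisation collapses to
  global standardisation.

## What the simulation does and does not emulate

The generator reproduces the statistical structure that matters for
index event bias and power comparisons: threshold ascertainment, a
shared nongenetic factor, liability-scale effect sharing, event-count
driven information, onset-age/liability coupling. It deliberately omits
linkage disequilibrium (each variant is its own locus, so locus and
variant counts coincide), imputation uncertainty (INFO ≡ 1),
relatedness, population structure (hence no PC covariates), the X
chromosome, and multi-ancestry sampling. Passing tests therefore
demonstrate correctness of the methods under the stated generative
model — not that real-data complications are handled; applying the
correction machinery to real summary statistics via the GWAS-SSF-style
TSV interface is supported but inherits all the usual caveats
(LD-aware selection, winner's curse, heterogeneous phenotype
definitions) that are out of scope here.

## Known limitations

- The one-step score estimate $U/V$ attenuates for large per-variant
  effects (|β| well above 0.3 on the log-hazard scale); the exact fit
  is available where that matters.
- The mixture correction assumes the selected set is dominated by one
  cluster with a linear susceptibility→progression relationship;
  with very few selected pairs (< 10) it refuses to fit rather than
  extrapolate.
- Binary-mode progression reuses the susceptibility threshold for its
  liability cut, a simplification adequate for the qualitative checks
  it serves.
- All cases are treated as diagnosed (complete lifetime ascertainment);
  survivor bias from enrolment timing is not modelled.
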
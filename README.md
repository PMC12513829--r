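# progsim

Do genetic variants that make people susceptible to a disease also
drive how the disease progresses once they have it? Studies that ask
this question compare susceptibility GWAS against within-patient
survival GWAS of disease-specific mortality — and face two structural
obstacles: conditioning on being a case turns every shared cause of
susceptibility into a collider ("index event bias"), and survival GWAS
information is limited by the event count, not the cohort size.

`progsim` is an R package for studying exactly this setting under a
fully known truth. It is aimed at statistical geneticists and
biostatisticians who want to reason about, teach, or stress-test
progression-GWAS designs and bias corrections.

## What it implements

**Generative model.** A liability-threshold cohort simulator: disease
status from $L_S = \sum_j \beta_{S,j}(g_j - 2p_j) + c_S U + e > t_S$
with $t_S = \Phi^{-1}(1-K)$, and within-case survival with hazard
$\lambda_0 \exp\{\sum_j \beta_{P,j}(g_j - 2p_j) + c_P U\}$ — the shared
nongenetic factor $U$ is the collider's source. Variants are null,
susceptibility-only, progression-only or shared; effects are rescaled
so explained variance equals the configured $h^2$ exactly. Cohorts are
`SummarizedExperiment`-based S4 objects carrying dosages, phenotypes
and the generative truth.

**Scans.** Fast efficient-score survival GWAS (martingale-residual
score statistic, risk-set variance with covariate-information
correction, one-step $\hat\beta = U/V$, Breslow ties) for within-case
progression and for age-of-onset susceptibility; a logistic score scan
for case-control direction of effect; an exact partial-likelihood fit
as the per-variant oracle; INFO/MAC quality control; down-sampling to
matched event/censored counts.

**Index event bias.** Per-class bias metrics against the simulated
truth, and a slope-hunter-style correction: an EM-fitted K-component
mixture of regressions through the origin on susceptibility-selected
effect pairs, whose designated component's slope $b$ gives
$\beta_P^{adj} = \beta_P - b\,\beta_S$,
$se^{adj} = \sqrt{se_P^2 + b^2 se_S^2}$.

**Comparison statistics.** Direction concordance with a two-sided
binomial test against 0.5, Bonferroni replication counting, strict
genome-wide significance counting, effect correlations, standardized
polygenic scores with proportional-hazards transfer evaluation
(HR per SD; onset-age-stratified sensitivity analysis), and
METAL-style inverse-variance and sample-size-weighted Z meta-analysis
with Cochran's Q.

## Worked example

```r
library(progsim)

cfg <- simulationConfig(n_individuals = 20000, m_variants = 500,
                        c2_S = 0.4, c2_P = 0.4, seed = 7)
cohort <- applyEligibilityFilters(simulateCohort(cfg))
cohort
#> ProgressionCohort: 19879 individuals x 500 variants
#>   cases: 1890 (prevalence 0.095); progression events: 1191
#>   eligibility: eligible

prog <- variantQC(scanProgression(cohort))
sus  <- scanSusceptibility(cohort, mode = "case_control")
pairs <- buildEffectPairs(sus, prog, selectionP = 1e-5,
                          truth = trueEffectsTable(cohort))

fit <- fitSlopeMixture(pairs, seed = 7)
fit
#> SlopeMixtureFit: 2 components, 19 selected pairs
#>   adjustment slope b = -0.1167 (largest_pi); converged: TRUE after 210 iterations
#>   component slopes: -0.1167 -0.2417 | mixing: 0.615 0.385

adjusted <- adjustEffects(pairs, slope(fit))
biasMetrics(adjusted)[, c("class", "n", "mean_bias_oriented",
                          "mean_bias_oriented_adj", "rmse", "rmse_adj")]
#>    class   n mean_bias_oriented mean_bias_oriented_adj       rmse   rmse_adj
#> 1   null 448         0.00000000             0.00000000 0.05494544 0.05526131
#> 2 S_only  23        -0.04440400            -0.01412561 0.06804794 0.05127419
#> 3 P_only  19         0.00000000             0.00000000 0.03741051 0.03784144
#> 4 shared  10        -0.03764268            -0.01012217 0.06933059 0.04999050
```

Reading the bias table: with 40% of both liabilities carried by the
shared factor, progression estimates of susceptibility-only variants
are biased by −0.044 *against* the susceptibility direction (the
collider at work; the null class is untouched), and the mixture
correction cuts that to −0.014 while shrinking the RMSE from 0.068 to
0.051. The same machinery produces the direction-concordance summary
(here 241/500 = 0.482, binomial p = 0.45 — no more concordance than a
coin flip) and the PGS-transfer contrast:

```r
score <- computePGS(cohort, truePGSWeights(cohort, "susceptibility"))
pgsOnsetAssociation(score, cohort)          # HR 3.07 (2.93-3.23) per SD
pgsProgressionAssociation(score[phenotypes(cohort)$disease],
                          caseCohort(cohort))
#> progression HR 0.81 (0.76-0.87), p = 2.2e-09
```

A susceptibility score that triples the onset hazard per SD comes out
*protective* within cases — the index event bias pattern the package
exists to demonstrate.

Four preset experiment designs (`power_comparison`, `pgs_transfer`,
`ieb_grid`, `correction_eval`) are orchestrated by
`scenarioPreset()` / `runScenario()`, all deterministic under a single
seed.

## Documentation

The methods vignette (`vignettes/progression-genetics.Rmd`) describes
the generative model and its assumptions, all tunable parameters with
defaults and rationale, the numerical conventions, what the simulator
does and does not emulate, and known limitations.
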
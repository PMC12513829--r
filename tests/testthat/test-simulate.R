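test_that("genotype dosages follow the Binomial(2, p) model", {
  # fixed maf: exact binomial pmf as oracle
  cfg <- simulationConfig(n_individuals = 100000, m_variants = 1,
                          maf_low = 0.2, maf_high = 0.2, seed = 5)
  gen <- simulateGenotypes(cfg)
  g <- gen$dosage[1, ]
  expect_equal(gen$maf, 0.2)
  pmf <- stats::dbinom(0:2, 2, 0.2) # (0.64, 0.32, 0.04)
  for (k in 0:2) {
    se <- sqrt(pmf[k + 1] * (1 - pmf[k + 1]) / length(g))
    expect_lt(abs(mean(g == k) - pmf[k + 1]), 4 * se)
  }
  # symmetric maf: mean dosage near 1
  cfg2 <- simulationConfig(n_individuals = 10000, m_variants = 1,
                           maf_low = 0.5, maf_high = 0.5, seed = 1)
  g2 <- simulateGenotypes(cfg2)$dosage[1, ]
  expect_lt(abs(mean(g2) - 1), 4 * sqrt(0.5 / 10000))
  # empty panel
  gen0 <- simulateGenotypes(simulationConfig(n_individuals = 10,
                                             m_variants = 0))
  expect_identical(dim(gen0$dosage), c(0L, 10L))
  expect_length(gen0$maf, 0)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(maf_low = 0), "maf")
  expect_error(simulationConfig(maf_low = 0.3, maf_high = 0.2), "maf")
  expect_error(simulationConfig(h2_S = 0.6, c2_S = 0.5), "h2_S")
  expect_error(simulationConfig(baseline_hazard_lambda0 = 0), "lambda0")
  expect_error(simulationConfig(pi_S_only = 0.6, pi_P_only = 0.5), "fractions")
  # h2 > 0 but nothing causal
  cfg <- smallConfig(pi_S_only = 0, pi_P_only = 0, pi_shared = 0, h2_S = 0.3)
  expect_error(drawEffects(cfg, simulateGenotypes(cfg)$maf), "causal")
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- smallConfig(seed = 42)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(dosages(a), dosages(b))
  expect_identical(phenotypes(a), phenotypes(b))
  expect_identical(trueEffectsTable(a), trueEffectsTable(b))
  c2 <- simulateCohort(smallConfig(seed = 43))
  expect_false(identical(dosages(a), dosages(c2)))
})

test_that("effects rescale to the exact heritability and respect classes", {
  cfg <- smallConfig(m_variants = 500, h2_S = 0.3, h2_P = 0.05)
  maf <- simulateGenotypes(cfg)$maf
  eff <- drawEffects(cfg, maf)
  het <- 2 * maf * (1 - maf)
  expect_equal(sum(het * eff@beta_S^2), 0.3, tolerance = 1e-12)
  expect_equal(sum(het * eff@beta_P^2), 0.05, tolerance = 1e-12)
  expect_true(all(eff@beta_S[eff@variantClass %in% c("null", "P_only")] == 0))
  expect_true(all(eff@beta_P[eff@variantClass %in% c("null", "S_only")] == 0))
  # h2_S = 0 leaves all susceptibility effects at zero, threshold unchanged
  eff0 <- drawEffects(smallConfig(m_variants = 500, h2_S = 0), maf)
  expect_true(all(eff0@beta_S == 0))
  expect_equal(eff0@t_S, qnorm(0.9))
  # no shared class => no variant carries both effects
  effNS <- drawEffects(smallConfig(m_variants = 500, pi_shared = 0), maf)
  expect_false(any(effNS@beta_S != 0 & effNS@beta_P != 0))
})

test_that("disease prevalence and case liability match the threshold model", {
  cfg <- simulationConfig(n_individuals = 50000, m_variants = 200,
                          prevalence_K = 0.1, seed = 7)
  coh <- simulateCohort(cfg)
  cd <- phenotypes(coh)
  expect_lt(abs(mean(cd$disease) - 0.1), 3 * sqrt(0.1 * 0.9 / 50000))
  # mean liability among cases: truncated-normal mean phi(t)/K
  t <- qnorm(0.9)
  muCase <- dnorm(t) / 0.1
  obs <- mean(cd$L_S[cd$disease])
  expect_lt(abs(obs - muCase), 3 * sd(cd$L_S[cd$disease]) /
                                 sqrt(sum(cd$disease)))
  # threshold relation is exact
  expect_identical(cd$disease, cd$L_S > trueEffects(coh)@t_S)
  # prevalence 1: everyone diseased
  cohAll <- simulateCohort(smallConfig(prevalence_K = 1))
  expect_true(all(phenotypes(cohAll)$disease))
})

test_that("progression outcomes follow the exponential survival model", {
  # eta = 0 for everyone: median event time ln 2 / lambda0
  cfg <- simulationConfig(n_individuals = 40000, m_variants = 50,
                          h2_P = 0, c2_P = 0, censor_time_max = 1e6,
                          baseline_hazard_lambda0 = 0.08, seed = 3)
  coh <- simulateCohort(cfg)
  cd <- phenotypes(coh)
  fu <- cd$followup[cd$disease]
  expect_true(all(cd$event[cd$disease] == 1L)) # censoring horizon huge
  med <- median(fu)
  expect_lt(abs(med - log(2) / 0.08), 3 * (log(2) / 0.08) / sqrt(sum(cd$disease)) * 1.5)
  # zero censoring horizon: everyone censored at 0
  coh0 <- simulateCohort(smallConfig(censor_time_max = 0))
  cd0 <- phenotypes(coh0)
  expect_true(all(cd0$event[cd0$disease] == 0L))
  expect_true(all(cd0$followup[cd0$disease] == 0))
  expect_true(all(cd0$followup[cd0$disease] >= 0))
})

test_that("eligibility filters enforce boundaries, truncation and the event floor", {
  cfg <- smallConfig(seed = 11)
  coh <- simulateCohort(cfg)
  cd <- SummarizedExperiment::colData(coh)
  cases <- which(cd$disease)
  expect_gte(length(cases), 60)
  # pin all case follow-ups above the floor, then set five boundary values
  cd$followup[cases] <- 1.0
  cd$followup[cases[1:5]] <- c(0.1, 0.25, 0.3, 1.0, 2.0)
  SummarizedExperiment::colData(coh) <- cd
  filt <- applyEligibilityFilters(coh, minFollowup = 0.25)
  expect_equal(nCases(filt), length(cases) - 1L) # only 0.1 dropped
  expect_true(all(phenotypes(filt)$followup[phenotypes(filt)$disease] >= 0.25))
  # truncation recodes late events as censored at the horizon
  cd2 <- SummarizedExperiment::colData(coh)
  cd2$followup[cases[6]] <- 3.0
  cd2$event[cases[6]] <- 1L
  SummarizedExperiment::colData(coh) <- cd2
  filt2 <- applyEligibilityFilters(coh, minFollowup = 0.25, maxFollowup = 2)
  ph2 <- phenotypes(filt2)
  i <- which(ph2$individual_id ==
             phenotypes(coh)$individual_id[cases[6]])
  expect_equal(ph2$followup[i], 2)
  expect_equal(ph2$event[i], 0L)
  # 49 events => ineligible flag
  cd3 <- SummarizedExperiment::colData(coh)
  ev <- which(cd3$disease & !is.na(cd3$event) & cd3$event == 1L)
  cd3$event[ev[-seq_len(min(49, length(ev)))]] <- 0L
  SummarizedExperiment::colData(coh) <- cd3
  filt3 <- applyEligibilityFilters(coh, minEvents = 50)
  expect_false(isEligible(filt3))
  expect_true(isEligible(applyEligibilityFilters(coh, minEvents = 49)))
  # idempotence
  once <- applyEligibilityFilters(coh, minFollowup = 0.25, maxFollowup = 5)
  twice <- applyEligibilityFilters(once, minFollowup = 0.25, maxFollowup = 5)
  expect_identical(phenotypes(once), phenotypes(twice))
  expect_identical(isEligible(once), isEligible(twice))
})

test_that("liability variance decomposes into genetic, shared and residual parts", {
  cfg <- simulationConfig(n_individuals = 100000, m_variants = 300,
                          h2_S = 0.3, c2_S = 0.2, seed = 21)
  coh <- simulateCohort(cfg)
  cd <- phenotypes(coh)
  eff <- trueEffects(coh)
  gv <- var(cd$G_S)
  uv <- var(eff@c_S * cd$U)
  rv <- var(cd$L_S - cd$G_S - eff@c_S * cd$U)
  mcTol <- function(v) 3 * v * sqrt(2 / length(cd$L_S)) + 0.003
  expect_lt(abs(gv - 0.3), mcTol(0.3))
  expect_lt(abs(uv - 0.2), mcTol(0.2))
  expect_lt(abs(rv - 0.5), mcTol(0.5))
  expect_lt(abs(var(cd$L_S) - 1), 0.02)
})

test_that("case ascertainment induces the collider correlation with U", {
  cfg <- simulationConfig(n_individuals = 100000, m_variants = 300,
                          h2_S = 0.3, c2_S = 0.2, seed = 22)
  coh <- simulateCohort(cfg)
  cd <- phenotypes(coh)
  rAll <- cor(cd$G_S, cd$U)
  rCase <- cor(cd$G_S[cd$disease], cd$U[cd$disease])
  expect_lt(abs(rAll), 3 / sqrt(nrow(cd)))           # independent overall
  expect_lt(rCase, -3 / sqrt(sum(cd$disease)))       # negative among cases
})

test_that("configuration files round-trip through YAML and JSON", {
  cfg <- smallConfig(h2_S = 0.25, c2_S = 0.15, seed = 9)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_individuals = 3000, m_variants = 100,
                        h2_S = 0.25, c2_S = 0.15, seed = 9), yml)
  cfg2 <- readSimulationConfig(yml)
  expect_equal(cfg2@h2_S, 0.25)
  expect_equal(cfg2@c2_S, 0.15)
  expect_identical(phenotypes(simulateCohort(cfg)),
                   phenotypes(simulateCohort(cfg2)))
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(list(h2_S = 0.25), jsn, auto_unbox = TRUE)
  expect_equal(readSimulationConfig(jsn)@h2_S, 0.25)
  yaml::write_yaml(list(not_a_field = 1), yml)
  expect_error(readSimulationConfig(yml), "unknown configuration")
})

test_that("cohort export and import round-trip through TSV", {
  coh <- simulateCohort(smallConfig(n_individuals = 150, m_variants = 20))
  prefix <- tempfile()
  writeCohort(coh, prefix)
  back <- readCohort(prefix)
  expect_identical(unname(back$dosage), unname(t(dosages(coh))))
  expect_equal(back$phenotypes$followup, phenotypes(coh)$followup)
  expect_equal(back$phenotypes$disease, phenotypes(coh)$disease)
})
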
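test_that("PGS arithmetic, standardisation and allele flipping are exact", {
  coh <- simulateCohort(smallConfig(n_individuals = 3, m_variants = 1, h2_S = 0, h2_P = 0))
  a <- SummarizedExperiment::assay(coh, "dosage")
  a[1, ] <- c(0L, 1L, 2L)
  SummarizedExperiment::assay(coh, "dosage") <- a
  rd <- SummarizedExperiment::rowData(coh)
  w <- data.frame(variant_id = rd$variant_id,
                  effect_allele = rd$effect_allele, weight = 0.5)
  s <- computePGS(coh, w)
  expect_equal(attr(s, "raw"), c(0, 0.5, 1))
  expect_equal(as.numeric(s), c(-1, 0, 1)) # n - 1 variance convention
  # flipping to the other allele mirrors the score
  wFlip <- data.frame(variant_id = rd$variant_id,
                      effect_allele = rd$other_allele, weight = 0.5)
  expect_equal(as.numeric(computePGS(coh, wFlip)), c(1, 0, -1))
  expect_equal(attr(computePGS(coh, wFlip), "raw"), c(1, 0.5, 0))
  # zero weights => degenerate
  w0 <- w
  w0$weight <- 0
  expect_error(computePGS(coh, w0), "degenerate")
  # unknown variants are dropped with a message
  w2 <- rbind(w, data.frame(variant_id = "nope", effect_allele = "A",
                            weight = 1))
  expect_message(computePGS(coh, w2), "absent")
})

test_that("true-effect susceptibility PGS tracks the genetic liability", {
  cfg <- simulationConfig(n_individuals = 20000, m_variants = 500,
                          h2_S = 0.3, seed = 14)
  coh <- simulateCohort(cfg)
  s <- computePGS(coh, truePGSWeights(coh, "susceptibility"))
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(var(s), 1, tolerance = 1e-12)
  expect_gt(cor(s, phenotypes(coh)$G_S), 0.95)
})

test_that("PGS-onset association recovers an injected hazard effect", {
  # inject a known log-HR per SD directly into an onset-hazard simulation
  set.seed(55)
  covered <- 0L
  nRep <- 30L
  for (r in seq_len(nRep)) {
    n <- 4000
    score <- rnorm(n)
    tOnset <- rexp(n, rate = 0.02 * exp(0.2 * score))
    cens <- runif(n, 0, 40)
    time <- pmin(tOnset, cens)
    status <- as.integer(tOnset <= cens)
    fit <- progsim:::pgsFit(time, status, score,
                            data.frame(sex = rbinom(n, 1, 0.5)),
                            "onset", "all")
    if (0.2 >= fit$beta - qnorm(0.975) * fit$se &&
        0.2 <= fit$beta + qnorm(0.975) * fit$se) covered <- covered + 1L
  }
  expect_gte(covered, 0.9 * nRep)
})

test_that("progression association guards eligibility and degenerate scores", {
  coh <- applyEligibilityFilters(
    simulateCohort(smallConfig(n_individuals = 8000, seed = 6)))
  cases <- caseCohort(coh)
  s <- computePGS(coh, truePGSWeights(coh, "progression"))[
    phenotypes(coh)$disease]
  res <- pgsProgressionAssociation(s, cases)
  expect_true(res$hr > 0 && res$ci_low < res$hr && res$hr < res$ci_high)
  # constant score refused
  expect_error(pgsProgressionAssociation(rep(0, ncol(cases)), cases),
               "degenerate")
  # 49 events => refusal
  cd <- SummarizedExperiment::colData(cases)
  ev <- which(!is.na(cd$event) & cd$event == 1L)
  cd$event[ev[-seq_len(49)]] <- 0L
  SummarizedExperiment::colData(cases) <- cd
  expect_error(pgsProgressionAssociation(s, cases), "ineligible")
})

test_that("positive control: progression-truth PGS predicts progression", {
  cfg <- simulationConfig(n_individuals = 20000, m_variants = 400,
                          h2_P = 0.2, c2_P = 0.1, seed = 19)
  coh <- applyEligibilityFilters(simulateCohort(cfg))
  s <- computePGS(coh, truePGSWeights(coh, "progression"))[
    phenotypes(coh)$disease]
  res <- pgsProgressionAssociation(s, caseCohort(coh))
  expect_gt(res$hr, 1)
  expect_lt(res$p, 0.05)
})

test_that("onset-age stratification partitions cases and detects heterogeneity", {
  coh <- applyEligibilityFilters(
    simulateCohort(smallConfig(n_individuals = 10000, seed = 23)))
  cases <- caseCohort(coh)
  cd <- phenotypes(cases)
  score <- computePGS(coh, truePGSWeights(coh, "susceptibility"))[
    phenotypes(coh)$disease]
  st <- stratifyByOnsetAge(score, cases)
  # partition: strata nonempty, union = all cases (ties to early)
  early <- cd$age_dx <= st$cutoff
  expect_gt(sum(early), 0)
  expect_gt(sum(!early), 0)
  expect_equal(sum(early) + sum(!early), nrow(cd))
  if (st$eligible_early && st$eligible_late) {
    expect_equal(st$early$n + st$late$n,
                 sum(!is.na(cd$followup)))
  }
  # an effect confined to early-onset cases yields positive delta z
  set.seed(90)
  posCount <- 0L
  for (r in 1:10) {
    n <- 3000
    age <- runif(n, 40, 90)
    sc <- rnorm(n)
    eff <- ifelse(age <= median(age), 0.5, 0)
    tEv <- rexp(n, 0.08 * exp(eff * sc))
    cens <- runif(n, 0, 15)
    df <- data.frame(disease = TRUE, age_dx = age,
                     followup = pmin(tEv, cens),
                     event = as.integer(tEv <= cens),
                     sex = rbinom(n, 1, 0.5),
                     birth_year = round(runif(n, 1940, 1970)))
    zE <- progsim:::pgsFit(df$followup[age <= median(age)],
                           df$event[age <= median(age)],
                           sc[age <= median(age)],
                           df[age <= median(age), c("sex", "birth_year")],
                           "progression", "early")$z
    zL <- progsim:::pgsFit(df$followup[age > median(age)],
                           df$event[age > median(age)],
                           sc[age > median(age)],
                           df[age > median(age), c("sex", "birth_year")],
                           "progression", "late")$z
    if (zE - zL > 0) posCount <- posCount + 1L
  }
  expect_gte(posCount, 9L)
})

test_that("inverse-variance meta-analysis matches closed forms and metafor", {
  m <- ivwMeta(c(1, 3), c(1, 1))
  expect_equal(m$beta_meta, 2)
  expect_equal(m$se_meta, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$Q, 2)
  expect_equal(m$df, 1L)
  expect_equal(m$p_Q, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  # single study passes through; Q = 0 with df = 0
  m1 <- ivwMeta(0.3, 0.1)
  expect_equal(m1$beta_meta, 0.3)
  expect_equal(m1$se_meta, 0.1)
  expect_equal(m1$Q, 0)
  expect_true(is.na(m1$p_Q))
  # identical studies are perfectly homogeneous
  expect_equal(ivwMeta(c(0.2, 0.2), c(0.05, 0.05))$Q, 0)
  # equal se reduces to the simple mean with se / sqrt(K)
  set.seed(2)
  b <- rnorm(5)
  me <- ivwMeta(b, rep(0.3, 5))
  expect_equal(me$beta_meta, mean(b), tolerance = 1e-12)
  expect_equal(me$se_meta, 0.3 / sqrt(5), tolerance = 1e-12)
  expect_error(ivwMeta(c(1, 2), c(0.1, 0)), "standard errors")
  # independent route: metafor fixed-effect model
  if (requireNamespace("metafor", quietly = TRUE)) {
    set.seed(7)
    bb <- rnorm(4)
    ss <- runif(4, 0.05, 0.2)
    rma <- metafor::rma(yi = bb, sei = ss, method = "FE")
    mm <- ivwMeta(bb, ss)
    expect_equal(mm$beta_meta, as.numeric(rma$beta), tolerance = 1e-10)
    expect_equal(mm$se_meta, rma$se, tolerance = 1e-10)
    expect_equal(mm$Q, rma$QE, tolerance = 1e-10)
  }
})

test_that("z-score meta-analysis: passthrough, cancellation, antisymmetry", {
  expect_equal(zMeta(1.7, 250)$z_meta, 1.7)
  mz <- zMeta(c(1, 1), c(100, 100), c(1, -1))
  expect_equal(mz$z_meta, 0)
  expect_equal(mz$p_meta, 1)
  set.seed(3)
  z <- rnorm(4)
  n <- c(100, 200, 300, 400)
  expect_equal(zMeta(z, n, c(-1, -1, -1, -1))$z_meta,
               -zMeta(z, n)$z_meta, tolerance = 1e-12)
  expect_error(zMeta(1, 0), "positive")
})
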
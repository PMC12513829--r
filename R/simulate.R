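#' Construct a simulation configuration
#'
#' Defaults describe the package's reference study conditions: a
#' population cohort of 50,000 individuals typed at 2,000 independent
#' biallelic variants, 10% lifetime prevalence, susceptibility
#' heritability 0.30 and progression heritability 0.02 on the liability
#' scale, a shared nongenetic factor carrying 20% of both liabilities,
#' 5% susceptibility-only and 5% progression-only causal variants plus
#' 2.5% shared causal variants with effect correlation 0.5, an
#' exponential within-case mortality hazard of 0.08/year censored
#' uniformly within 15 years of diagnosis, and an onset-age map of
#' 65 - 5 * liability years with 5-year noise.
#'
#' @param n_individuals,m_variants cohort and variant-panel size.
#' @param maf_low,maf_high allele-frequency window, in (0, 0.5].
#' @param prevalence_K lifetime disease prevalence.
#' @param h2_S,h2_P liability-scale heritabilities.
#' @param c2_S,c2_P shared nongenetic factor variance fractions.
#' @param pi_S_only,pi_P_only,pi_shared causal-class fractions.
#' @param rho_shared effect correlation within the shared class.
#' @param baseline_hazard_lambda0 progression baseline hazard (events/year).
#' @param censor_time_max uniform censoring horizon (years).
#' @param onset_age_mean,onset_age_slope,onset_age_sd onset-age map (years).
#' @param seed integer seed.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(n_individuals = 2000, m_variants = 100)
#' @export
simulationConfig <- function(n_individuals = 50000,
                             m_variants = 2000,
                             maf_low = 0.05, maf_high = 0.5,
                             prevalence_K = 0.1,
                             h2_S = 0.3, h2_P = 0.02,
                             c2_S = 0.2, c2_P = 0.2,
                             pi_S_only = 0.05, pi_P_only = 0.05,
                             pi_shared = 0.025,
                             rho_shared = 0.5,
                             baseline_hazard_lambda0 = 0.08,
                             censor_time_max = 15,
                             onset_age_mean = 65,
                             onset_age_slope = 5,
                             onset_age_sd = 5,
                             seed = 1L) {
  new("SimulationConfig",
      n_individuals = n_individuals, m_variants = m_variants,
      maf_low = maf_low, maf_high = maf_high,
      prevalence_K = prevalence_K,
      h2_S = h2_S, h2_P = h2_P, c2_S = c2_S, c2_P = c2_P,
      pi_S_only = pi_S_only, pi_P_only = pi_P_only, pi_shared = pi_shared,
      rho_shared = rho_shared,
      baseline_hazard_lambda0 = baseline_hazard_lambda0,
      censor_time_max = censor_time_max,
      onset_age_mean = onset_age_mean, onset_age_slope = onset_age_slope,
      onset_age_sd = onset_age_sd,
      seed = seed)
}

#' Read a simulation configuration from YAML or JSON
#'
#' Field names mirror [simulationConfig()] arguments exactly; absent
#' fields keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(simulationConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration fields: ", paste(bad, collapse = ", "))
  do.call(simulationConfig, vals)
}

#' Deterministic child seeds
#'
#' All scenario- and replicate-level randomness is derived from one
#' top-level seed through this splitting rule, keeping every derived seed
#' a valid 32-bit integer.
#' @param seed top-level integer seed.
#' @param index child index (replicate number, restart number, ...).
#' @return an integer seed.
#' @export
childSeed <- function(seed, index) {
  v <- ((as.double(seed) %% 2147483629) * 7919 +
        as.double(index) * 104729) %% 2147483629
  as.integer(v)
}

#' Simulate genotype dosages
#'
#' Draws per-variant allele frequencies uniformly within the configured
#' window and fills a variants-by-individuals dosage matrix with
#' independent Binomial(2, p_j) draws (Hardy-Weinberg, no linkage
#' disequilibrium).
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides `config@seed` when given.
#' @return list with `dosage` (m x n integer matrix) and `maf` (length m).
#' @export
simulateGenotypes <- function(config, seed = config@seed) {
  validObject(config)
  n <- as.integer(config@n_individuals)
  m <- as.integer(config@m_variants)
  set.seed(seed)
  maf <- runif(m, config@maf_low, config@maf_high)
  G <- matrix(rbinom(m * n, 2L, maf), nrow = m, ncol = n)
  rownames(G) <- variantIds(m)
  list(dosage = G, maf = maf)
}

variantIds <- function(m) if (m) sprintf("v%05d", seq_len(m)) else character()

#' Draw per-variant causal effects
#'
#' Assigns each variant to the null, susceptibility-only,
#' progression-only or shared class by independent multinomial draws,
#' samples nonzero effects from a Gaussian (bivariate with correlation
#' `rho_shared` inside the shared class) and rescales each trait's
#' effects so that the explained liability variance
#' \eqn{\sum_j 2 p_j (1-p_j) \beta_j^2} equals the configured
#' heritability exactly. The susceptibility threshold is
#' \eqn{t_S = \Phi^{-1}(1 - K)}.
#'
#' @param config a [SimulationConfig-class].
#' @param maf allele-frequency vector from [simulateGenotypes()].
#' @param seed overrides `config@seed` when given.
#' @return A [TrueEffects-class].
#' @export
drawEffects <- function(config, maf, seed = config@seed) {
  validObject(config)
  m <- length(maf)
  if (m != config@m_variants)
    stop("maf length does not match m_variants")
  set.seed(childSeed(seed, 1L))
  probs <- c(null = 1 - config@pi_S_only - config@pi_P_only - config@pi_shared,
             S_only = config@pi_S_only, P_only = config@pi_P_only,
             shared = config@pi_shared)
  cls <- if (m) sample(names(probs), m, replace = TRUE, prob = probs) else character()
  beta_S <- numeric(m)
  beta_P <- numeric(m)
  isS <- cls %in% c("S_only", "shared")
  isP <- cls %in% c("P_only", "shared")
  beta_S[isS] <- rnorm(sum(isS))
  beta_P[cls == "P_only"] <- rnorm(sum(cls == "P_only"))
  sh <- cls == "shared"
  # correlated draws within the shared class
  beta_P[sh] <- config@rho_shared * beta_S[sh] +
    sqrt(1 - config@rho_shared^2) * rnorm(sum(sh))
  het <- 2 * maf * (1 - maf)
  rescale <- function(beta, h2, trait) {
    if (h2 == 0) return(numeric(length(beta)))
    tot <- sum(het * beta^2)
    if (tot == 0)
      stop(sprintf("h2_%s > 0 requires at least one causal variant for %s",
                   trait, trait))
    beta * sqrt(h2 / tot)
  }
  beta_S <- rescale(beta_S, config@h2_S, "S")
  beta_P <- rescale(beta_P, config@h2_P, "P")
  t <- qnorm(1 - config@prevalence_K)
  new("TrueEffects", maf = maf, beta_S = beta_S, beta_P = beta_P,
      variantClass = cls, t_S = t, t_P = t,
      c_S = sqrt(config@c2_S), c_P = sqrt(config@c2_P))
}

# centered genetic score: colSums over causal rows of (g - 2p) * beta,
# chunked so the integer dosage matrix is never fully coerced to double
geneticScore <- function(dosage, beta, maf, chunk = 250L) {
  idx <- which(beta != 0)
  n <- ncol(dosage)
  out <- numeric(n)
  if (!length(idx) || !n) return(out)
  for (s in split(idx, ceiling(seq_along(idx) / chunk))) {
    out <- out + as.vector(crossprod(dosage[s, , drop = FALSE], beta[s]))
  }
  out - sum(2 * maf[beta != 0] * beta[beta != 0])
}

#' Simulate disease status and age at diagnosis
#'
#' Builds the susceptibility liability
#' \eqn{L_S = \sum_j \beta_{S,j} (g_j - 2p_j) + c_S U + e} with standard
#' normal shared factor U and residual variance \eqn{1 - h^2_S - c^2_S},
#' so that Var(L_S) = 1 in expectation; disease is the threshold
#' indicator \eqn{L_S > t_S}. Age at diagnosis decreases with liability
#' (earlier onset for higher liability) and is truncated to [18, 100];
#' non-cases receive a censoring age.
#'
#' @param dosage m x n dosage matrix.
#' @param effects a [TrueEffects-class].
#' @param config the generating [SimulationConfig-class].
#' @param seed overrides `config@seed` when given.
#' @return list with `U`, `L_S`, `disease`, `age_dx` (NA for non-cases),
#'   `age_end` (censoring age), `sex`, `birth_year`.
#' @export
simulateDiseaseOnset <- function(dosage, effects, config, seed = config@seed) {
  n <- ncol(dosage)
  if (nrow(dosage) != length(effects@maf))
    stop("dosage and effects are dimensionally inconsistent")
  set.seed(childSeed(seed, 2L))
  U <- rnorm(n)
  e <- rnorm(n, 0, sqrt(1 - config@h2_S - config@c2_S))
  gsc <- geneticScore(dosage, effects@beta_S, effects@maf)
  L_S <- gsc + effects@c_S * U + e
  disease <- L_S > effects@t_S
  age_dx <- config@onset_age_mean - config@onset_age_slope * L_S +
    rnorm(n, 0, config@onset_age_sd)
  age_dx <- pmin(pmax(age_dx, 18), 100)
  age_dx[!disease] <- NA_real_
  age_end <- pmin(pmax(config@onset_age_mean + runif(n, -10, 15), 18), 100)
  sex <- rbinom(n, 1L, 0.5)
  birth_year <- round(runif(n, 1940, 1970))
  list(U = U, L_S = L_S, G_S = gsc, disease = disease, age_dx = age_dx,
       age_end = age_end, sex = sex, birth_year = birth_year)
}

#' Simulate within-case progression outcomes
#'
#' Among cases, the progression linear predictor is
#' \eqn{\eta = \sum_j \beta_{P,j} (g_j - 2p_j) + c_P U}, reusing the same
#' shared factor U that entered susceptibility — the source of the
#' collider once analysis conditions on being a case. The default
#' survival mode draws event times from Exponential(rate =
#' \eqn{\lambda_0 e^{\eta}}) with Uniform(0, censor_time_max) censoring;
#' the binary mode thresholds the progression liability
#' \eqn{\eta + e_P} at `t_P` instead.
#'
#' @param dosage m x n dosage matrix (full cohort).
#' @param effects a [TrueEffects-class].
#' @param config the generating [SimulationConfig-class].
#' @param U shared-factor values (length n).
#' @param disease logical case indicator (length n).
#' @param seed overrides `config@seed` when given.
#' @param mode `"survival"` (default) or `"binary"`.
#' @return list with `followup`, `event`, `eta` (all length n, NA for
#'   non-cases).
#' @export
simulateProgression <- function(dosage, effects, config, U, disease,
                                seed = config@seed,
                                mode = c("survival", "binary")) {
  mode <- match.arg(mode)
  if (config@baseline_hazard_lambda0 <= 0)
    stop("baseline_hazard_lambda0 must be > 0")
  n <- ncol(dosage)
  if (!any(disease)) stop("no diseased individuals to simulate progression for")
  set.seed(childSeed(seed, 3L))
  idx <- which(disease)
  gsc <- geneticScore(dosage[, idx, drop = FALSE], effects@beta_P, effects@maf)
  eta <- gsc + effects@c_P * U[idx]
  followup <- rep(NA_real_, n)
  event <- rep(NA_integer_, n)
  if (mode == "survival") {
    tEvent <- rexp(length(idx), rate = config@baseline_hazard_lambda0 * exp(eta))
    tCens <- runif(length(idx), 0, config@censor_time_max)
    followup[idx] <- pmin(tEvent, tCens)
    event[idx] <- as.integer(tEvent <= tCens)
  } else {
    eP <- rnorm(length(idx), 0, sqrt(1 - config@h2_P - config@c2_P))
    event[idx] <- as.integer(eta + eP > effects@t_P)
    followup[idx] <- config@censor_time_max
  }
  etaFull <- rep(NA_real_, n)
  etaFull[idx] <- eta
  list(followup = followup, event = event, eta = etaFull)
}

#' Simulate a complete cohort
#'
#' Runs [simulateGenotypes()], [drawEffects()], [simulateDiseaseOnset()]
#' and [simulateProgression()] under one seed and assembles the result
#' into a [ProgressionCohort-class]. Identical config + seed yields a
#' byte-identical cohort.
#'
#' @param config a [SimulationConfig-class].
#' @param seed overrides `config@seed` when given.
#' @param progressionMode `"survival"` or `"binary"`, see
#'   [simulateProgression()].
#' @return A [ProgressionCohort-class].
#' @examples
#' coh <- simulateCohort(simulationConfig(n_individuals = 3000,
#'                                        m_variants = 150, seed = 7))
#' coh
#' @export
simulateCohort <- function(config, seed = config@seed,
                           progressionMode = c("survival", "binary")) {
  progressionMode <- match.arg(progressionMode)
  validObject(config)
  gen <- simulateGenotypes(config, seed)
  eff <- drawEffects(config, gen$maf, seed)
  ons <- simulateDiseaseOnset(gen$dosage, eff, config, seed)
  prg <- if (any(ons$disease)) {
    simulateProgression(gen$dosage, eff, config, ons$U, ons$disease,
                        seed, mode = progressionMode)
  } else {
    n <- ncol(gen$dosage)
    list(followup = rep(NA_real_, n), event = rep(NA_integer_, n),
         eta = rep(NA_real_, n))
  }
  m <- nrow(gen$dosage)
  set.seed(childSeed(seed, 4L))
  alleles <- matrix(replicate(m, sample(c("A", "C", "G", "T"), 2L)),
                    nrow = 2L)
  rd <- DataFrame(
    variant_id = variantIds(m),
    chromosome = rep(1L, m),
    base_pair_location = seq_len(m),
    effect_allele = if (m) alleles[1L, ] else character(),
    other_allele = if (m) alleles[2L, ] else character(),
    maf = gen$maf,
    beta_S = eff@beta_S,
    beta_P = eff@beta_P,
    class = eff@variantClass
  )
  cd <- DataFrame(
    individual_id = sprintf("i%06d", seq_len(ncol(gen$dosage))),
    U = ons$U, L_S = ons$L_S, L_P = prg$eta, G_S = ons$G_S,
    disease = ons$disease, age_dx = ons$age_dx, age_end = ons$age_end,
    followup = prg$followup, event = prg$event,
    sex = ons$sex, birth_year = ons$birth_year,
    eligible = ons$disease # refined by applyEligibilityFilters()
  )
  se <- SummarizedExperiment(
    assays = SimpleList(dosage = gen$dosage),
    rowData = rd, colData = cd,
    metadata = list(config = config, effects = eff,
                    progressionMode = progressionMode,
                    filters = NULL, cohortEligible = NA)
  )
  colnames(se) <- cd$individual_id
  new("ProgressionCohort", se)
}

#' Apply within-case eligibility filters
#'
#' Removes cases with follow-up below `minFollowup` (boundary kept),
#' truncates follow-up at `maxFollowup` when given — events beyond the
#' truncation point are recoded as censored at it — and flags the cohort
#' ineligible when fewer than `minEvents` progression events remain.
#' Non-cases are untouched. The operation is idempotent.
#'
#' @param cohort a [ProgressionCohort-class].
#' @param minFollowup minimum follow-up after diagnosis, years (inclusive).
#' @param maxFollowup optional truncation of follow-up, years.
#' @param minEvents minimum progression event count (inclusive).
#' @return The filtered cohort; `isEligible()` reports the flag.
#' @export
applyEligibilityFilters <- function(cohort, minFollowup = 0.25,
                                    maxFollowup = NULL, minEvents = 50) {
  cd <- colData(cohort)
  drop <- cd$disease & !is.na(cd$followup) & cd$followup < minFollowup
  out <- cohort[, !drop]
  cd <- colData(out)
  if (!is.null(maxFollowup)) {
    over <- cd$disease & !is.na(cd$followup) & cd$followup > maxFollowup
    cd$event[over] <- 0L
    cd$followup[over] <- maxFollowup
  }
  cd$eligible <- cd$disease
  colData(out) <- cd
  nev <- sum(cd$event[cd$disease], na.rm = TRUE)
  md <- metadata(out)
  md$cohortEligible <- nev >= minEvents
  md$filters <- list(minFollowup = minFollowup, maxFollowup = maxFollowup,
                     minEvents = minEvents, nEventsAfter = nev,
                     nRemoved = sum(drop))
  metadata(out) <- md
  out
}
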
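#' @import methods
#' @importFrom stats qnorm pnorm dnorm rnorm runif rbinom rexp pbinom pchisq
#'   coef vcov glm binomial median sd var cor optimize setNames model.matrix
#'   complete.cases quantile ks.test
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   colData<- rowData<-
NULL

#' Simulation configuration for a susceptibility/progression cohort
#'
#' Holds every generative parameter of the liability-threshold model:
#' cohort and variant panel dimensions, the allele-frequency window,
#' disease prevalence, liability-scale heritabilities of susceptibility
#' (`h2_S`) and progression (`h2_P`), the fractions of liability variance
#' carried by the shared nongenetic factor U (`c2_S`, `c2_P`), the causal
#' architecture (`pi_S_only`, `pi_P_only`, `pi_shared`, `rho_shared`),
#' the exponential baseline hazard of the progression outcome, the
#' administrative censoring horizon, and the onset-age map.
#'
#' @slot n_individuals number of individuals in the population cohort.
#' @slot m_variants number of independent biallelic variants.
#' @slot maf_low,maf_high allele-frequency bounds in (0, 0.5].
#' @slot prevalence_K lifetime disease prevalence in (0, 1].
#' @slot h2_S,h2_P liability-scale heritabilities in [0, 1).
#' @slot c2_S,c2_P shared-factor variance fractions in [0, 1).
#' @slot pi_S_only,pi_P_only,pi_shared causal-class fractions (rest null).
#' @slot rho_shared effect-size correlation within the shared class.
#' @slot baseline_hazard_lambda0 progression baseline hazard, events/year.
#' @slot censor_time_max uniform censoring horizon after diagnosis, years.
#' @slot onset_age_mean,onset_age_slope,onset_age_sd onset-age map:
#'   age at diagnosis = mean - slope * liability + Normal(0, sd), years.
#' @slot seed integer seed; identical config + seed reproduces the cohort.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    n_individuals = "numeric",
    m_variants = "numeric",
    maf_low = "numeric",
    maf_high = "numeric",
    prevalence_K = "numeric",
    h2_S = "numeric",
    h2_P = "numeric",
    c2_S = "numeric",
    c2_P = "numeric",
    pi_S_only = "numeric",
    pi_P_only = "numeric",
    pi_shared = "numeric",
    rho_shared = "numeric",
    baseline_hazard_lambda0 = "numeric",
    censor_time_max = "numeric",
    onset_age_mean = "numeric",
    onset_age_slope = "numeric",
    onset_age_sd = "numeric",
    seed = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  sc1 <- function(x, nm) {
    if (length(slot(object, x)) != 1L || !is.finite(slot(object, x)))
      msg <<- c(msg, sprintf("'%s' must be a single finite number", x))
  }
  for (nm in slotNames(object)) sc1(nm, nm)
  if (length(msg)) return(msg)
  if (object@n_individuals < 0 || object@m_variants < 0)
    msg <- c(msg, "dimensions must be non-negative")
  if (!(object@maf_low > 0 && object@maf_high <= 0.5 &&
        object@maf_low <= object@maf_high))
    msg <- c(msg, "maf bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  if (object@prevalence_K <= 0 || object@prevalence_K > 1)
    msg <- c(msg, "prevalence_K must be in (0, 1]")
  for (h in c("h2_S", "h2_P", "c2_S", "c2_P")) {
    v <- slot(object, h)
    if (v < 0 || v >= 1) msg <- c(msg, sprintf("'%s' must be in [0, 1)", h))
  }
  if (object@h2_S + object@c2_S >= 1)
    msg <- c(msg, "h2_S + c2_S must be < 1 (residual variance must be positive)")
  if (object@h2_P + object@c2_P >= 1)
    msg <- c(msg, "h2_P + c2_P must be < 1 (residual variance must be positive)")
  pis <- c(object@pi_S_only, object@pi_P_only, object@pi_shared)
  if (any(pis < 0) || sum(pis) > 1)
    msg <- c(msg, "causal fractions must be >= 0 and sum to <= 1")
  if (abs(object@rho_shared) > 1)
    msg <- c(msg, "rho_shared must be in [-1, 1]")
  if (object@baseline_hazard_lambda0 <= 0)
    msg <- c(msg, "baseline_hazard_lambda0 must be > 0")
  if (object@censor_time_max < 0)
    msg <- c(msg, "censor_time_max must be >= 0")
  if (object@onset_age_sd < 0)
    msg <- c(msg, "onset_age_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-variant generative truth
#'
#' The realised causal architecture of one simulated cohort: allele
#' frequencies, liability-scale allelic effects on susceptibility and
#' progression (rescaled so the total explained variance equals the
#' configured heritabilities exactly), the causal class of every variant,
#' the liability thresholds and the shared-factor loadings.
#'
#' @slot maf simulated allele frequency per variant.
#' @slot beta_S,beta_P liability-scale allelic effects.
#' @slot variantClass one of "null", "S_only", "P_only", "shared" per variant.
#' @slot t_S,t_P liability thresholds (susceptibility / binary progression).
#' @slot c_S,c_P shared-factor loadings, i.e. sqrt(c2_S), sqrt(c2_P).
#' @exportClass TrueEffects
setClass("TrueEffects",
  representation(
    maf = "numeric",
    beta_S = "numeric",
    beta_P = "numeric",
    variantClass = "character",
    t_S = "numeric",
    t_P = "numeric",
    c_S = "numeric",
    c_P = "numeric"
  )
)

setValidity("TrueEffects", function(object) {
  m <- length(object@maf)
  msg <- character()
  if (length(object@beta_S) != m || length(object@beta_P) != m ||
      length(object@variantClass) != m)
    msg <- c(msg, "maf, beta_S, beta_P and class must have equal length")
  if (!all(object@variantClass %in% c("null", "S_only", "P_only", "shared")))
    msg <- c(msg, "class labels must be null/S_only/P_only/shared")
  if (m) {
    if (any(object@beta_S[object@variantClass %in% c("null", "P_only")] != 0))
      msg <- c(msg, "null and P_only variants must have beta_S = 0")
    if (any(object@beta_P[object@variantClass %in% c("null", "S_only")] != 0))
      msg <- c(msg, "null and S_only variants must have beta_P = 0")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated cohort container
#'
#' A \linkS4class{SummarizedExperiment} whose `"dosage"` assay holds the
#' variants-by-individuals genotype dosage matrix (entries 0/1/2), whose
#' `rowData` mirrors the per-variant truth (allele frequency, causal class,
#' liability effects, placeholder coordinates and alleles), and whose
#' `colData` carries the per-individual phenotypes: the shared factor `U`,
#' the susceptibility liability `L_S`, disease status, age at diagnosis,
#' censoring age, within-case follow-up and progression event indicator,
#' sex, birth year and the eligibility flag maintained by
#' [applyEligibilityFilters()]. The generating [SimulationConfig] and
#' [TrueEffects] live in `metadata()`.
#'
#' @exportClass ProgressionCohort
setClass("ProgressionCohort", contains = "SummarizedExperiment")

setValidity("ProgressionCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  need <- c("U", "L_S", "disease", "age_dx", "age_end", "followup",
            "event", "sex", "birth_year", "eligible")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (!is(metadata(object)$config, "SimulationConfig"))
    msg <- c(msg, "metadata()$config must be a SimulationConfig")
  if (!is(metadata(object)$effects, "TrueEffects"))
    msg <- c(msg, "metadata()$effects must be a TrueEffects")
  if (length(msg)) msg else TRUE
})

#' Fitted covariate-only proportional-hazards null model
#'
#' Caches everything the score-test scan needs: per-individual relative
#' risks under the covariate-only Cox fit (Breslow ties), martingale
#' residuals, the risk-set index sorted by decreasing time, cumulative
#' risk-weight sums at event positions, weighted covariate means per event
#' and the inverse covariate information for the efficient-score variance.
#'
#' @exportClass NullSurvivalModel
setClass("NullSurvivalModel",
  representation(
    time = "numeric",
    status = "integer",
    w = "numeric",          # exp(covariate linear predictor)
    resid = "numeric",      # martingale residuals, original order
    coefficients = "numeric",
    ord = "integer",        # sort order, decreasing time
    ks = "integer",         # risk-set end position of each event (sorted scale)
    cwk = "numeric",        # cumulative sum of w at ks
    Zs = "matrix",          # covariates, sorted order (0 columns if none)
    EZd = "matrix",         # weighted covariate mean per event (D x q)
    IZZinv = "matrix",      # inverse covariate information (q x q)
    n = "integer",
    nEvents = "integer"
  )
)

#' Slope-hunter-style mixture fit on paired effects
#'
#' Result of the EM fit of a K-component mixture of regressions through
#' the origin relating progression to susceptibility effects among
#' susceptibility-selected variants. The designated component's slope is
#' the index-event-bias adjustment factor.
#'
#' @slot slope adjustment slope b taken from the designated component.
#' @slot b per-component slopes.
#' @slot pi mixing proportions (sum to 1).
#' @slot sigma2 per-component residual variances (beyond measurement error).
#' @slot posterior n_selected x K posterior membership matrix.
#' @slot logLik log-likelihood trace of the best start (non-decreasing).
#' @slot converged logical.
#' @slot nIterations iterations used by the best start.
#' @slot designation rule used to pick the susceptibility-only component.
#' @slot variantId variant ids of the selected pairs (posterior rows).
#' @exportClass SlopeMixtureFit
setClass("SlopeMixtureFit",
  representation(
    slope = "numeric",
    b = "numeric",
    pi = "numeric",
    sigma2 = "numeric",
    posterior = "matrix",
    logLik = "numeric",
    converged = "logical",
    nIterations = "integer",
    designation = "character",
    variantId = "character"
  )
)

setValidity("SlopeMixtureFit", function(object) {
  if (abs(sum(object@pi) - 1) > 1e-8) "mixing proportions must sum to 1" else TRUE
})
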
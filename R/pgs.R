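#' Compute a standardised polygenic score
#'
#' Weighted sum of effect-allele dosages across the weight table's
#' variants, standardised to mean 0 and variance 1 (sample variance,
#' n - 1 denominator). Weight variants absent from the cohort are
#' dropped with a reported count; weights whose effect allele matches
#' the cohort's other allele are flipped onto the cohort's effect
#' allele.
#'
#' @param cohort a [ProgressionCohort-class].
#' @param weights data.frame with `variant_id`, `effect_allele`,
#'   `weight`.
#' @return numeric score vector (one value per individual), with the raw
#'   (unstandardised) score as attribute `raw`.
#' @export
computePGS <- function(cohort, weights) {
  if (ncol(cohort) < 2) stop("need at least 2 individuals")
  rd <- rowData(cohort)
  idx <- match(weights$variant_id, rd$variant_id)
  miss <- is.na(idx)
  if (any(miss))
    message(sum(miss), " weight variant(s) absent from the cohort, dropped")
  w <- weights$weight[!miss]
  idx <- idx[!miss]
  if (!length(idx)) stop("no scoring variants present in the cohort")
  flip <- weights$effect_allele[!miss] == rd$other_allele[idx]
  # scoring the other allele: dosage 2 - g, i.e. negate the weight up to
  # a constant that standardisation removes (constant kept in raw score)
  shift <- sum(2 * w[flip])
  w[flip] <- -w[flip]
  G <- assay(cohort, "dosage")
  raw <- numeric(ncol(G))
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / 250L))) {
    raw <- raw + as.vector(crossprod(G[idx[s], , drop = FALSE], w[s]))
  }
  raw <- raw + shift
  sdv <- sd(raw)
  if (!is.finite(sdv) || sdv == 0) stop("degenerate score: zero variance")
  out <- (raw - mean(raw)) / sdv
  attr(out, "raw") <- raw
  out
}

#' Weight table from the simulated truth
#'
#' Convenience constructor of a PGS weight table using the cohort's true
#' liability effects (`"susceptibility"` uses beta_S, `"progression"`
#' beta_P), emulating a score built from an infinitely well-powered
#' GWAS of that trait.
#'
#' @param cohort a [ProgressionCohort-class].
#' @param trait `"susceptibility"` or `"progression"`.
#' @return data.frame with `variant_id`, `effect_allele`, `weight`.
#' @export
truePGSWeights <- function(cohort,
                           trait = c("susceptibility", "progression")) {
  trait <- match.arg(trait)
  rd <- rowData(cohort)
  w <- if (trait == "susceptibility") rd$beta_S else rd$beta_P
  data.frame(variant_id = rd$variant_id,
             effect_allele = rd$effect_allele,
             weight = w, stringsAsFactors = FALSE)[w != 0, , drop = FALSE]
}

pgsFit <- function(time, status, score, covars, outcome, stratum) {
  if (sd(score) == 0) stop("degenerate score: zero variance")
  status <- as.integer(status)
  if (all(status == 1L) || all(status == 0L))
    stop("single-class outcome")
  df <- cbind(data.frame(time = time, status = status, score = score), covars)
  rhs <- setdiff(names(df), c("time", "status"))
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  b <- unname(coef(fit)["score"])
  se <- sqrt(vcov(fit)["score", "score"])
  z <- b / se
  list(outcome = outcome, stratum = stratum,
       beta = unname(b), se = unname(se), hr = exp(unname(b)),
       ci_low = exp(unname(b) - qnorm(0.975) * se),
       ci_high = exp(unname(b) + qnorm(0.975) * se),
       z = unname(z), p = 2 * pnorm(-abs(z)),
       n = length(time), n_events = sum(status))
}

#' PGS association with disease onset
#'
#' Proportional-hazards fit on the age scale across the whole cohort:
#' event is diagnosis at the diagnosis age, non-cases are censored at
#' their end-of-follow-up age; sex and birth year are covariates. The
#' effect is reported as a hazard ratio per standard deviation of the
#' score.
#'
#' @param score standardised score from [computePGS()].
#' @param cohort a [ProgressionCohort-class] with cases and non-cases.
#' @param covariates colData columns used as covariates.
#' @return list: outcome, stratum, beta (log-HR per SD), se, hr, ci_low,
#'   ci_high, z, p, n, n_events.
#' @export
pgsOnsetAssociation <- function(score, cohort,
                                covariates = c("sex", "birth_year")) {
  cd <- colData(cohort)
  time <- ifelse(cd$disease, cd$age_dx, cd$age_end)
  pgsFit(time, as.integer(cd$disease), score,
         as.data.frame(cd[, covariates, drop = FALSE]),
         outcome = "onset", stratum = "all")
}

#' PGS association with within-case progression
#'
#' Proportional-hazards fit of survival after diagnosis among cases,
#' adjusting for age at diagnosis, sex and birth year; refuses cohorts
#' with fewer than `minEvents` progression events.
#'
#' @param score standardised score aligned with `cohort`'s cases.
#' @param cohort a case-level [ProgressionCohort-class] (see
#'   [caseCohort()]), already filtered for eligibility.
#' @param covariates colData columns used as covariates.
#' @param minEvents minimum progression event count.
#' @return list as in [pgsOnsetAssociation()].
#' @export
pgsProgressionAssociation <- function(score, cohort,
                                      covariates = c("sex", "birth_year",
                                                     "age_dx"),
                                      minEvents = 50) {
  cd <- colData(cohort)
  if (!all(cd$disease)) {
    score <- score[cd$disease]
    cohort <- cohort[, cd$disease]
    cd <- colData(cohort)
  }
  ok <- !is.na(cd$followup)
  cd <- cd[ok, ]
  score <- score[ok]
  nev <- sum(cd$event, na.rm = TRUE)
  if (nev < minEvents)
    stop(sprintf("cohort ineligible: %d progression events < required %d",
                 nev, minEvents))
  pgsFit(cd$followup, cd$event, score,
         as.data.frame(cd[, covariates, drop = FALSE]),
         outcome = "progression", stratum = "all")
}

#' Onset-age-stratified PGS progression association
#'
#' Splits cases at the median age of diagnosis (ties to the early-onset
#' stratum), fits the progression association per stratum when it holds
#' at least `minEvents` events, and reports the z-score difference
#' `delta_z = z_early - z_late`.
#'
#' @param score standardised score aligned with the case cohort.
#' @param cohort a case-level, filtered [ProgressionCohort-class].
#' @param covariates colData columns used as covariates.
#' @param minEvents per-stratum minimum event count.
#' @return list with `early`, `late` (association lists or NULL when the
#'   stratum is ineligible), `delta_z`, `cutoff`, `eligible_early`,
#'   `eligible_late`.
#' @export
stratifyByOnsetAge <- function(score, cohort,
                               covariates = c("sex", "birth_year", "age_dx"),
                               minEvents = 50) {
  cd <- colData(cohort)
  if (!all(cd$disease)) stop("stratification expects a case cohort")
  cutoff <- median(cd$age_dx)
  early <- cd$age_dx <= cutoff
  fitStratum <- function(idx, label) {
    nev <- sum(cd$event[idx], na.rm = TRUE)
    if (nev < minEvents) return(NULL)
    res <- pgsFit(cd$followup[idx], cd$event[idx], score[idx],
                  as.data.frame(cd[idx, covariates, drop = FALSE]),
                  outcome = "progression", stratum = label)
    res
  }
  eFit <- fitStratum(which(early), "early_onset")
  lFit <- fitStratum(which(!early), "late_onset")
  list(early = eFit, late = lFit,
       delta_z = if (!is.null(eFit) && !is.null(lFit)) eFit$z - lFit$z
                 else NA_real_,
       cutoff = cutoff,
       eligible_early = !is.null(eFit), eligible_late = !is.null(lFit))
}
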
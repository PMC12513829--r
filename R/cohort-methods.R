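#' Genotype dosages of a cohort
#'
#' @param x a [ProgressionCohort-class].
#' @param transpose return individuals-by-variants instead of the stored
#'   variants-by-individuals orientation.
#' @param ... unused.
#' @return integer dosage matrix.
#' @export
setMethod("dosages", "ProgressionCohort", function(x, transpose = FALSE, ...) {
  d <- assay(x, "dosage")
  if (transpose) t(d) else d
})

#' Generative truth of a simulated cohort
#'
#' `trueEffects()` returns the [TrueEffects-class] stored at simulation
#' time; `trueEffectsTable()` returns it as a per-variant data.frame
#' (variant_id, true_class, beta_S_true, beta_P_true, maf) suitable for
#' joining onto summary statistics.
#'
#' @param x a [ProgressionCohort-class].
#' @return A [TrueEffects-class] or a data.frame.
#' @export
setMethod("trueEffects", "ProgressionCohort", function(x) metadata(x)$effects)

#' @rdname trueEffects
#' @export
setMethod("trueEffectsTable", "ProgressionCohort", function(x) {
  rd <- rowData(x)
  data.frame(variant_id = rd$variant_id,
             true_class = rd$class,
             beta_S_true = rd$beta_S,
             beta_P_true = rd$beta_P,
             maf = rd$maf,
             stringsAsFactors = FALSE)
})

#' Per-individual phenotype table
#'
#' @param x a [ProgressionCohort-class].
#' @return `colData(x)` as a plain data.frame.
#' @export
setMethod("phenotypes", "ProgressionCohort",
          function(x) as.data.frame(colData(x)))

#' Restrict a cohort to diseased individuals
#'
#' @param x a [ProgressionCohort-class].
#' @return the case-only [ProgressionCohort-class].
#' @export
setMethod("caseCohort", "ProgressionCohort",
          function(x) x[, colData(x)$disease])

#' Cohort counts and eligibility
#'
#' `nCases()` counts diseased individuals, `nEvents()` progression events
#' among cases, `isEligible()` reports the flag set by
#' [applyEligibilityFilters()] (NA before filtering).
#'
#' @param x a [ProgressionCohort-class].
#' @return integer count or logical flag.
#' @export
setMethod("nCases", "ProgressionCohort",
          function(x) sum(colData(x)$disease))

#' @rdname cohort-counts
#' @export
setMethod("nEvents", "ProgressionCohort",
          function(x) sum(colData(x)$event[colData(x)$disease], na.rm = TRUE))

#' @rdname cohort-counts
#' @export
setMethod("isEligible", "ProgressionCohort",
          function(x) metadata(x)$cohortEligible)

#' @rdname simConfig
#' @export
setMethod("simConfig", "ProgressionCohort", function(x) metadata(x)$config)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      sprintf("n = %d individuals, m = %d variants",
              as.integer(object@n_individuals),
              as.integer(object@m_variants)), "\n")
  cat(sprintf("  prevalence K = %.3g; h2_S = %.3g, h2_P = %.3g; c2_S = %.3g, c2_P = %.3g\n",
              object@prevalence_K, object@h2_S, object@h2_P,
              object@c2_S, object@c2_P))
  cat(sprintf("  causal fractions: S_only %.3g, P_only %.3g, shared %.3g (rho = %.2f)\n",
              object@pi_S_only, object@pi_P_only, object@pi_shared,
              object@rho_shared))
  cat(sprintf("  hazard lambda0 = %.3g/yr, censoring <= %.3g yr; seed = %d\n",
              object@baseline_hazard_lambda0, object@censor_time_max,
              as.integer(object@seed)))
})

setMethod("show", "TrueEffects", function(object) {
  cat("TrueEffects:", length(object@maf), "variants\n")
  print(table(factor(object@variantClass,
                     levels = c("null", "S_only", "P_only", "shared"))))
  cat(sprintf("  t_S = %.4f; loadings c_S = %.3f, c_P = %.3f\n",
              object@t_S, object@c_S, object@c_P))
})

setMethod("show", "ProgressionCohort", function(object) {
  cd <- colData(object)
  cat("ProgressionCohort:", ncol(object), "individuals x", nrow(object),
      "variants\n")
  cat(sprintf("  cases: %d (prevalence %.3f); progression events: %d\n",
              sum(cd$disease), mean(cd$disease), nEvents(object)))
  elig <- isEligible(object)
  cat("  eligibility:",
      if (is.na(elig)) "unfiltered" else if (elig) "eligible" else "INELIGIBLE",
      "\n")
})

setMethod("show", "NullSurvivalModel", function(object) {
  cat("NullSurvivalModel:", object@n, "individuals,", object@nEvents,
      "events,", ncol(object@Zs), "covariates (Breslow ties)\n")
})

setMethod("show", "SlopeMixtureFit", function(object) {
  cat("SlopeMixtureFit:", length(object@b), "components,",
      nrow(object@posterior), "selected pairs\n")
  cat(sprintf("  adjustment slope b = %.4f (%s); converged: %s after %d iterations\n",
              object@slope, object@designation, object@converged,
              object@nIterations))
  cat("  component slopes:", sprintf("%.4f", object@b),
      "| mixing:", sprintf("%.3f", object@pi), "\n")
})

#' @rdname fitSlopeMixture
#' @export
setMethod("slope", "SlopeMixtureFit", function(x) x@slope)

#' @rdname fitSlopeMixture
#' @export
setMethod("mixingProportions", "SlopeMixtureFit", function(x) x@pi)

#' @rdname fitSlopeMixture
#' @export
setMethod("posteriorMembership", "SlopeMixtureFit", function(x) x@posterior)

#' Export / import a cohort as tab-separated text
#'
#' `writeCohort()` writes `<prefix>_cohort.tsv` (individual_id, disease,
#' age_dx, age_end, followup, event, sex, birth_year, eligible) and
#' `<prefix>_dosage.tsv` (individuals as rows, variant ids as header).
#' `readCohort()` reads the pair back into plain data structures for
#' interoperability; the generative truth is not part of the export.
#'
#' @param cohort a [ProgressionCohort-class].
#' @param prefix output path prefix.
#' @return `writeCohort()` the two file paths, invisibly; `readCohort()` a
#'   list with `phenotypes` (data.frame) and `dosage` (individuals x
#'   variants integer matrix).
#' @export
writeCohort <- function(cohort, prefix) {
  cd <- as.data.frame(colData(cohort))
  keep <- c("individual_id", "disease", "age_dx", "age_end", "followup",
            "event", "sex", "birth_year", "eligible")
  phenoPath <- paste0(prefix, "_cohort.tsv")
  dosPath <- paste0(prefix, "_dosage.tsv")
  write.table(cd[, keep], phenoPath, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  d <- as.data.frame(t(assay(cohort, "dosage")))
  d <- cbind(individual_id = cd$individual_id, d)
  write.table(d, dosPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(phenoPath, dosPath))
}

#' @rdname writeCohort
#' @export
readCohort <- function(prefix) {
  pheno <- read.delim(paste0(prefix, "_cohort.tsv"), na.strings = "")
  d <- read.delim(paste0(prefix, "_dosage.tsv"), check.names = FALSE)
  ids <- d$individual_id
  d <- as.matrix(d[, setdiff(colnames(d), "individual_id"), drop = FALSE])
  storage.mode(d) <- "integer"
  rownames(d) <- ids
  list(phenotypes = pheno, dosage = d)
}
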
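scenarioNames <- c("power_comparison", "pgs_transfer", "ieb_grid",
                   "correction_eval")

#' Preset scenario specifications
#'
#' Returns a fully populated scenario specification. Presets:
#' \describe{
#'   \item{power_comparison}{matched-effective-sample-size contrast of
#'     the susceptibility (age-of-onset) and progression scans;
#'     susceptibility heritability 0.3 concentrated in ~10 loci
#'     (pi_S_only = 0.005) so the simulated susceptibility GWAS has
#'     genome-wide-significant variants to find, progression
#'     heritability 0.02 spread over 5% of variants; filters
#'     min_followup = 0.25, min_events = 50.}
#'   \item{pgs_transfer}{PGS built from the true susceptibility and
#'     progression effects, evaluated on onset and on within-case
#'     progression; partial overlap (pi_shared = 0.025,
#'     rho_shared = 0.5).}
#'   \item{ieb_grid}{sweeps the shared-factor variance fraction
#'     c2_S = c2_P over \{0, 0.1, 0.2, 0.4\} and reports per-class bias
#'     metrics of the progression scan against the simulated truth.}
#'   \item{correction_eval}{slope-hunter-style mixture fit and
#'     correction at c2 = 0.4, with h2_S = 0.3 concentrated in ~30
#'     susceptibility loci (pi_S_only = 0.015, pi_shared = 0.005) so the
#'     susceptibility-significant selection is well populated.}
#' }
#' Each call returns a fresh spec; mutating the result does not affect
#' later calls.
#'
#' @param name one of `"power_comparison"`, `"pgs_transfer"`,
#'   `"ieb_grid"`, `"correction_eval"`.
#' @return list of class `"scenarioSpec"` with elements `scenario`,
#'   `config` ([SimulationConfig-class]), `options` (list), `replicates`,
#'   `seed`.
#' @export
scenarioPreset <- function(name) {
  if (!name %in% scenarioNames)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(scenarioNames, collapse = ", "))
  base <- list(minFollowup = 0.25, maxFollowup = NULL, minEvents = 50,
               gwsThreshold = 5e-8, selectionP = 5e-8)
  spec <- switch(name,
    power_comparison = list(
      config = simulationConfig(h2_S = 0.3, h2_P = 0.02,
                                pi_S_only = 0.005, pi_P_only = 0.05,
                                pi_shared = 0, c2_S = 0.1, c2_P = 0.1),
      options = base,
      replicates = 5L),
    pgs_transfer = list(
      config = simulationConfig(pi_shared = 0.025, rho_shared = 0.5,
                                n_individuals = 20000),
      options = base,
      replicates = 10L),
    ieb_grid = list(
      config = simulationConfig(n_individuals = 20000),
      options = c(base, list(c2_grid = c(0, 0.1, 0.2, 0.4))),
      replicates = 10L),
    correction_eval = list(
      config = simulationConfig(h2_S = 0.3, pi_S_only = 0.015,
                                pi_P_only = 0.02, pi_shared = 0.005,
                                c2_S = 0.4, c2_P = 0.4,
                                n_individuals = 25000),
      options = c(base, list(mixtureK = 2L, nStarts = 10L)),
      replicates = 10L)
  )
  structure(c(list(scenario = name), spec, list(seed = 1L)),
            class = "scenarioSpec")
}

replicatePipeline <- function(config, opts, seed) {
  coh <- simulateCohort(config, seed = seed)
  coh <- applyEligibilityFilters(coh, minFollowup = opts$minFollowup,
                                 maxFollowup = opts$maxFollowup,
                                 minEvents = opts$minEvents)
  coh
}

#' Run a scenario
#'
#' Executes one of the four experimental designs over `spec$replicates`
#' independent cohorts (replicate seeds derive from `spec$seed` via
#' [childSeed()]) and aggregates the results. Replicates whose simulated
#' cohort fails the eligibility filters are reported as flagged skips,
#' never silently dropped. The report embeds a provenance block (full
#' configuration, seed, package version) sufficient to reproduce it.
#'
#' @param spec a scenario specification from [scenarioPreset()]
#'   (optionally modified).
#' @return list of class `"scenarioReport"` with `scenario`,
#'   `provenance`, `replicates` (per-replicate tables), `aggregate`.
#' @export
runScenario <- function(spec) {
  if (!inherits(spec, "scenarioSpec")) stop("spec must be a scenarioSpec")
  if (!spec$scenario %in% scenarioNames)
    stop("unknown scenario '", spec$scenario, "'; valid names: ",
         paste(scenarioNames, collapse = ", "))
  if (spec$replicates < 1) stop("replicate count must be >= 1")
  opts <- spec$options
  runner <- switch(spec$scenario,
                   power_comparison = runPowerComparison,
                   pgs_transfer = runPgsTransfer,
                   ieb_grid = runIebGrid,
                   correction_eval = runCorrectionEval)
  res <- runner(spec)
  prov <- list(scenario = spec$scenario,
               config = configAsList(spec$config),
               options = opts[!vapply(opts, is.null, logical(1))],
               replicates = spec$replicates,
               seed = spec$seed,
               package_version = as.character(packageVersion("progsim")))
  structure(c(list(scenario = spec$scenario, provenance = prov), res),
            class = "scenarioReport")
}

configAsList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}

runPowerComparison <- function(spec) {
  opts <- spec$options
  rows <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    sd <- childSeed(spec$seed, r)
    coh <- replicatePipeline(spec$config, opts, sd)
    if (!isTRUE(isEligible(coh))) {
      rows[[r]] <- data.frame(replicate = r, eligible = FALSE,
                              n_cases = nCases(coh), n_events = nEvents(coh),
                              n_censored = NA, sig_progression = NA,
                              sig_susceptibility = NA)
      next
    }
    prog <- variantQC(scanProgression(coh, minEvents = opts$minEvents))
    nEv <- nEvents(coh)
    nCn <- nCases(coh) - nEv
    sub <- downsampleMatch(coh, nEv, nCn, seed = childSeed(sd, 9L),
                           outcome = "onset")
    sus <- variantQC(scanSusceptibility(sub, mode = "age_of_onset"))
    rows[[r]] <- data.frame(replicate = r, eligible = TRUE,
                            n_cases = nCases(coh), n_events = nEv,
                            n_censored = nCn,
                            sig_progression =
                              countSignificant(prog, opts$gwsThreshold),
                            sig_susceptibility =
                              countSignificant(sus, opts$gwsThreshold))
  }
  tab <- do.call(rbind, rows)
  ok <- tab$eligible
  list(replicates = tab,
       aggregate = data.frame(
         n_replicates = nrow(tab), n_eligible = sum(ok),
         total_sig_susceptibility = sum(tab$sig_susceptibility[ok]),
         total_sig_progression = sum(tab$sig_progression[ok])))
}

runPgsTransfer <- function(spec) {
  opts <- spec$options
  rows <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    sd <- childSeed(spec$seed, r)
    coh <- replicatePipeline(spec$config, opts, sd)
    if (!isTRUE(isEligible(coh))) {
      rows[[r]] <- data.frame(replicate = r, eligible = FALSE)
      next
    }
    wS <- truePGSWeights(coh, "susceptibility")
    wP <- truePGSWeights(coh, "progression")
    sS <- computePGS(coh, wS)
    sP <- computePGS(coh, wP)
    cases <- caseCohort(coh)
    sSc <- sS[colData(coh)$disease]
    sPc <- sP[colData(coh)$disease]
    onsS <- pgsOnsetAssociation(sS, coh)
    prgS <- pgsProgressionAssociation(sSc, cases, minEvents = opts$minEvents)
    prgP <- pgsProgressionAssociation(sPc, cases, minEvents = opts$minEvents)
    rows[[r]] <- data.frame(replicate = r, eligible = TRUE,
                            hr_onset_susPGS = onsS$hr,
                            hr_progression_susPGS = prgS$hr,
                            hr_progression_progPGS = prgP$hr,
                            z_onset_susPGS = onsS$z,
                            z_progression_susPGS = prgS$z,
                            z_progression_progPGS = prgP$z)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$eligible
  list(replicates = tab,
       aggregate = data.frame(
         n_replicates = nrow(tab), n_eligible = sum(ok),
         mean_hr_onset_susPGS = mean(tab$hr_onset_susPGS[ok]),
         mean_hr_progression_susPGS = mean(tab$hr_progression_susPGS[ok]),
         mean_hr_progression_progPGS = mean(tab$hr_progression_progPGS[ok])))
}

runIebGrid <- function(spec) {
  opts <- spec$options
  grid <- opts$c2_grid
  cells <- list()
  for (ci in seq_along(grid)) {
    for (r in seq_len(spec$replicates)) {
      cfg <- spec$config
      cfg@c2_S <- grid[ci]
      cfg@c2_P <- grid[ci]
      sd <- childSeed(spec$seed, ci * 1000L + r)
      coh <- replicatePipeline(cfg, opts, sd)
      if (!isTRUE(isEligible(coh))) {
        cells[[length(cells) + 1L]] <-
          data.frame(c2 = grid[ci], replicate = r, eligible = FALSE)
        next
      }
      prog <- scanProgression(coh, minEvents = opts$minEvents)
      # bias against the truth needs no susceptibility scan: orient by
      # the true susceptibility effects
      truth <- trueEffectsTable(coh)
      pairs <- merge(data.frame(variant_id = prog$variant_id,
                                beta_P = prog$beta,
                                se_P = prog$standard_error,
                                p_P = prog$p_value),
                     truth, by = "variant_id")
      bm <- biasMetrics(pairs, threshold = opts$gwsThreshold)
      cells[[length(cells) + 1L]] <-
        cbind(data.frame(c2 = grid[ci], replicate = r, eligible = TRUE), bm)
    }
  }
  tab <- do.call(rbind, lapply(cells, function(x) {
    miss <- setdiff(c("class", "n", "mean_bias", "mean_bias_oriented",
                      "mae", "rmse", "n_sig_before"), names(x))
    for (mm in miss) x[[mm]] <- NA
    x[, c("c2", "replicate", "eligible", "class", "n", "mean_bias",
          "mean_bias_oriented", "mae", "rmse", "n_sig_before")]
  }))
  sOnly <- tab[tab$eligible & tab$class == "S_only", , drop = FALSE]
  agg <- do.call(rbind, lapply(split(sOnly, sOnly$c2), function(d)
    data.frame(c2 = d$c2[1], n_replicates = nrow(d),
               mean_bias_oriented = mean(d$mean_bias_oriented),
               se_bias_oriented = sd(d$mean_bias_oriented) /
                 sqrt(nrow(d)))))
  rownames(agg) <- NULL
  list(replicates = tab, aggregate = agg)
}

runCorrectionEval <- function(spec) {
  opts <- spec$options
  rows <- vector("list", spec$replicates)
  for (r in seq_len(spec$replicates)) {
    sd <- childSeed(spec$seed, r)
    coh <- replicatePipeline(spec$config, opts, sd)
    if (!isTRUE(isEligible(coh))) {
      rows[[r]] <- data.frame(replicate = r, eligible = FALSE)
      next
    }
    prog <- scanProgression(coh, minEvents = opts$minEvents)
    sus <- scanSusceptibility(coh, mode = "case_control")
    pairs <- buildEffectPairs(sus, prog, selectionP = opts$selectionP,
                              truth = trueEffectsTable(coh))
    fit <- fitSlopeMixture(pairs, K = opts$mixtureK,
                           nStarts = opts$nStarts, seed = childSeed(sd, 8L))
    adj <- adjustEffects(pairs, slope(fit))
    bm <- biasMetrics(adj, threshold = opts$gwsThreshold)
    sOnly <- bm[bm$class == "S_only", ]
    rows[[r]] <- data.frame(replicate = r, eligible = TRUE,
                            slope = slope(fit),
                            n_selected = sum(pairs$selected),
                            bias_oriented_before = sOnly$mean_bias_oriented,
                            bias_oriented_after = sOnly$mean_bias_oriented_adj,
                            mae_before = sOnly$mae,
                            mae_after = sOnly$mae_adj,
                            rmse_before = sOnly$rmse,
                            rmse_after = sOnly$rmse_adj,
                            sig_before = sum(bm$n_sig_before),
                            sig_after = sum(bm$n_sig_after))
  }
  tab <- do.call(rbind, rows)
  ok <- tab$eligible
  list(replicates = tab,
       aggregate = data.frame(
         n_replicates = nrow(tab), n_eligible = sum(ok),
         mean_slope = mean(tab$slope[ok]),
         mean_abs_bias_before = mean(abs(tab$bias_oriented_before[ok])),
         mean_abs_bias_after = mean(abs(tab$bias_oriented_after[ok])),
         mean_mae_before = mean(tab$mae_before[ok]),
         mean_mae_after = mean(tab$mae_after[ok])))
}

#' @export
print.scenarioReport <- function(x, ...) {
  cat("scenarioReport:", x$scenario, "(seed", x$provenance$seed, ",",
      x$provenance$replicates, "replicates)\n")
  print(x$aggregate)
  invisible(x)
}
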
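#' Fit the covariate-only proportional-hazards null model
#'
#' Fits `Surv(time, status) ~ covariates` by Cox partial likelihood with
#' the Breslow ties convention (via \pkg{survival} when covariates are
#' present; the covariate-free model has unit relative risks and
#' Nelson-Aalen cumulative hazard) and caches martingale residuals,
#' sorted risk sets, cumulative risk-weight sums and the inverse
#' covariate information — everything the per-variant efficient score
#' test needs.
#'
#' @param time follow-up times (>= 0).
#' @param status event indicators (0/1).
#' @param covariates optional data.frame or matrix of covariates.
#' @return A [NullSurvivalModel-class].
#' @export
fitNullSurvival <- function(time, status, covariates = NULL) {
  status <- as.integer(status)
  n <- length(time)
  if (length(status) != n) stop("time and status lengths differ")
  if (sum(status) == 0L) stop("no events")
  Z <- if (is.null(covariates) || NCOL(covariates) == 0L) {
    matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    zm <- as.matrix(as.data.frame(covariates))
    storage.mode(zm) <- "double"
    zm
  }
  if (ncol(Z)) {
    qrz <- qr(cbind(1, scale(Z, scale = FALSE)))
    if (qrz$rank < ncol(Z) + 1L) {
      bad <- colnames(Z)[qrz$pivot[seq(qrz$rank + 1L, ncol(Z) + 1L)] - 1L]
      stop("collinear covariates: ", paste(bad, collapse = ", "))
    }
    fit <- survival::coxph(survival::Surv(time, status) ~ Z,
                           ties = "breslow")
    w <- exp(as.vector(Z %*% coef(fit)) -
             sum(fit$means * coef(fit)))
    r <- as.vector(stats::residuals(fit, type = "martingale"))
    cf <- setNames(coef(fit), colnames(Z))
  } else {
    w <- rep(1, n)
    cf <- numeric(0)
    r <- NULL # filled below from the Nelson-Aalen hazard
  }
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  ss <- status[ord]
  ws <- w[ord]
  cw <- cumsum(ws)
  # risk-set end position of each sorted index (last tied position)
  rl <- rle(ts)
  kk <- rep(cumsum(rl$lengths), rl$lengths)
  evPos <- which(ss == 1L)
  ks <- kk[evPos]
  cwk <- cw[ks]
  Zs <- Z[ord, , drop = FALSE]
  q <- ncol(Z)
  D <- length(ks)
  EZd <- matrix(numeric(0), nrow = D, ncol = 0L)
  IZZinv <- matrix(numeric(0), 0L, 0L)
  if (q) {
    EZd <- matrix(0, D, q)
    for (cidx in seq_len(q)) {
      EZd[, cidx] <- cumsum(ws * Zs[, cidx])[ks] / cwk
    }
    IZZ <- matrix(0, q, q)
    for (a in seq_len(q)) {
      for (b in seq_len(a)) {
        Eab <- cumsum(ws * Zs[, a] * Zs[, b])[ks] / cwk
        IZZ[a, b] <- IZZ[b, a] <- sum(Eab - EZd[, a] * EZd[, b])
      }
    }
    IZZinv <- solve(IZZ)
  }
  if (is.null(r)) {
    # martingale residuals from the Nelson-Aalen cumulative hazard
    H <- numeric(n) # cumulative hazard at each sorted position's time
    dH <- numeric(n)
    dH[ks] <- dH[ks] + 1 / cwk # ties accumulate at the shared position
    # hazard experienced by sorted index i: sum over event positions >= i
    H <- rev(cumsum(rev(dH)))
    r <- numeric(n)
    r[ord] <- ss - H[kk] * ws
  }
  new("NullSurvivalModel",
      time = as.numeric(time), status = status, w = w, resid = r,
      coefficients = cf, ord = as.integer(ord), ks = as.integer(ks),
      cwk = cwk, Zs = Zs, EZd = EZd, IZZinv = IZZinv,
      n = n, nEvents = sum(status))
}

#' Baseline cumulative hazard of a null model
#'
#' Breslow estimator (Nelson-Aalen when the model has no covariates),
#' returned as a step function table.
#'
#' @param x a [NullSurvivalModel-class].
#' @param ... unused.
#' @return data.frame with `time` and `cumhaz` at each event time.
#' @export
setMethod("cumulativeHazard", "NullSurvivalModel", function(x, ...) {
  tEv <- x@time[x@ord][x@ks]
  steps <- tapply(1 / x@cwk, tEv, sum)
  tt <- as.numeric(names(steps))
  o <- order(tt)
  data.frame(time = tt[o], cumhaz = cumsum(as.numeric(steps)[o]))
})

# Efficient score test of one dosage vector against a cached null model.
# Returns c(U, V) with V the efficient (covariate-corrected) variance.
scoreStat <- function(g, nm) {
  U <- sum(g * nm@resid)
  gs <- g[nm@ord]
  wg <- nm@w[nm@ord] * gs
  Eg <- cumsum(wg)[nm@ks] / nm@cwk
  V <- sum(cumsum(wg * gs)[nm@ks] / nm@cwk - Eg^2)
  q <- ncol(nm@Zs)
  if (q) {
    vgz <- numeric(q)
    for (cidx in seq_len(q)) {
      vgz[cidx] <- sum(cumsum(wg * nm@Zs[, cidx])[nm@ks] / nm@cwk -
                       Eg * nm@EZd[, cidx])
    }
    V <- V - drop(crossprod(vgz, nm@IZZinv %*% vgz))
  }
  c(U = U, V = V)
}

emptyRecords <- function() {
  data.frame(variant_id = character(), chromosome = integer(),
             base_pair_location = integer(), effect_allele = character(),
             other_allele = character(), effect_allele_frequency = numeric(),
             beta = numeric(), standard_error = numeric(), z = numeric(),
             p_value = numeric(), n = integer(), n_events = integer(),
             info = numeric(), mac = numeric(), flag = character(),
             stringsAsFactors = FALSE)
}

# assemble one AssociationRecord row from a score statistic
recordRow <- function(U, V, g, n, nEvents) {
  mac <- min(sum(g), 2 * n - sum(g))
  eaf <- mean(g) / 2
  if (!is.finite(V) || V <= 0) {
    return(list(eaf = eaf, beta = 0, se = NA_real_, z = 0, p = 1,
                mac = mac, flag = "monomorphic"))
  }
  z <- U / sqrt(V)
  list(eaf = eaf, beta = U / V, se = 1 / sqrt(V), z = z,
       p = 2 * pnorm(-abs(z)), mac = mac, flag = "ok")
}

scanCore <- function(G, nm, rowInfo, nEvents) {
  m <- ncol(G)
  n <- nrow(G)
  out <- emptyRecords()[rep(1L, 0L), ]
  eaf <- beta <- se <- z <- p <- mac <- numeric(m)
  flag <- character(m)
  for (j in seq_len(m)) {
    g <- as.numeric(G[, j])
    rng <- range(g)
    if (rng[1] == rng[2]) {
      rr <- recordRow(0, 0, g, n, nEvents)
    } else {
      uv <- scoreStat(g, nm)
      rr <- recordRow(uv[1], uv[2], g, n, nEvents)
    }
    eaf[j] <- rr$eaf; beta[j] <- rr$beta; se[j] <- rr$se
    z[j] <- rr$z; p[j] <- rr$p; mac[j] <- rr$mac; flag[j] <- rr$flag
  }
  data.frame(variant_id = rowInfo$variant_id,
             chromosome = rowInfo$chromosome,
             base_pair_location = rowInfo$base_pair_location,
             effect_allele = rowInfo$effect_allele,
             other_allele = rowInfo$other_allele,
             effect_allele_frequency = eaf,
             beta = beta, standard_error = se, z = z, p_value = p,
             n = n, n_events = nEvents, info = 1, mac = mac, flag = flag,
             stringsAsFactors = FALSE)
}

rowInfoOf <- function(cohort) {
  as.data.frame(rowData(cohort)[, c("variant_id", "chromosome",
                                    "base_pair_location", "effect_allele",
                                    "other_allele")])
}

#' Within-case progression survival scan
#'
#' Per-variant genome-wide scan of survival after diagnosis among cases,
#' in the style of fast score-test survival GWAS tools: one covariate-only
#' Cox null model (follow-up after diagnosis, progression event), then for
#' each variant the efficient score statistic
#' \eqn{U_j = \sum_i g_{ij} r_i} (martingale residuals r), its risk-set
#' variance corrected for covariate information, the one-step estimate
#' \eqn{\hat\beta_j = U_j / V_j} and Wald-style `se`, `z`, `p`. Default
#' covariates are age at diagnosis, birth year and sex. Monomorphic
#' variants yield flagged records with z = 0.
#'
#' @param cohort a filtered [ProgressionCohort-class] (the case subset is
#'   taken internally).
#' @param covariates colData columns used as covariates.
#' @param minEvents refuse cohorts with fewer progression events.
#' @return data.frame of association records (GWAS-SSF-style columns plus
#'   `flag`).
#' @export
scanProgression <- function(cohort,
                            covariates = c("age_dx", "birth_year", "sex"),
                            minEvents = 50) {
  cc <- caseCohort(cohort)
  cd <- colData(cc)
  keep <- !is.na(cd$followup)
  cc <- cc[, keep]
  cd <- colData(cc)
  nev <- sum(cd$event, na.rm = TRUE)
  if (nev < minEvents)
    stop(sprintf("cohort ineligible: %d progression events < required %d",
                 nev, minEvents))
  Z <- as.data.frame(cd[, covariates, drop = FALSE])
  nm <- fitNullSurvival(cd$followup, cd$event, Z)
  G <- t(assay(cc, "dosage"))
  scanCore(G, nm, rowInfoOf(cc), nm@nEvents)
}

#' Susceptibility scan: age-of-onset survival or case-control
#'
#' `age_of_onset` mode runs the same efficient score machinery on the
#' age scale: event = diagnosis at `age_dx`, non-cases censored at their
#' end-of-follow-up age. `case_control` mode performs a per-variant
#' logistic score test of disease status on dosage (null model
#' `disease ~ covariates`), the direction-of-effect path feeding Z-score
#' meta-analysis.
#'
#' @param cohort a [ProgressionCohort-class] with cases and non-cases.
#' @param mode `"age_of_onset"` or `"case_control"`.
#' @param covariates colData columns used as covariates.
#' @return data.frame of association records.
#' @export
scanSusceptibility <- function(cohort,
                               mode = c("age_of_onset", "case_control"),
                               covariates = c("birth_year", "sex")) {
  mode <- match.arg(mode)
  cd <- colData(cohort)
  y <- as.integer(cd$disease)
  if (all(y == 1L) || all(y == 0L))
    stop("single-class outcome: need both cases and non-cases")
  if (mode == "age_of_onset") {
    time <- ifelse(cd$disease, cd$age_dx, cd$age_end)
    if (var(time) == 0) stop("no variation in onset/censoring ages")
    Z <- as.data.frame(cd[, covariates, drop = FALSE])
    nm <- fitNullSurvival(time, y, Z)
    G <- t(assay(cohort, "dosage"))
    return(scanCore(G, nm, rowInfoOf(cohort), nm@nEvents))
  }
  # logistic score scan
  Zdf <- as.data.frame(cd[, covariates, drop = FALSE])
  dat <- cbind(data.frame(y = y), Zdf)
  fit <- glm(y ~ ., data = dat, family = binomial())
  ph <- fit$fitted.values
  v <- ph * (1 - ph)
  X <- model.matrix(fit)
  XtVX <- crossprod(X * v, X)
  XtVXinv <- solve(XtVX)
  res <- y - ph
  m <- nrow(cohort)
  n <- ncol(cohort)
  eaf <- beta <- se <- zst <- p <- mac <- numeric(m)
  flag <- character(m)
  Gm <- assay(cohort, "dosage")
  chunks <- split(seq_len(m), ceiling(seq_len(m) / 250L))
  for (ch in chunks) {
    Gc <- t(Gm[ch, , drop = FALSE]) # n x |ch| double
    storage.mode(Gc) <- "double"
    Uv <- as.vector(crossprod(Gc, res))
    S2 <- as.vector(crossprod(Gc^2, v))
    A <- crossprod(Gc * v, X) # |ch| x qx
    Vv <- S2 - rowSums((A %*% XtVXinv) * A)
    for (i in seq_along(ch)) {
      j <- ch[i]
      g <- Gc[, i]
      rng <- range(g)
      rr <- if (rng[1] == rng[2]) recordRow(0, 0, g, n, sum(y)) else
        recordRow(Uv[i], Vv[i], g, n, sum(y))
      eaf[j] <- rr$eaf; beta[j] <- rr$beta; se[j] <- rr$se
      zst[j] <- rr$z; p[j] <- rr$p; mac[j] <- rr$mac; flag[j] <- rr$flag
    }
  }
  ri <- rowInfoOf(cohort)
  data.frame(variant_id = ri$variant_id, chromosome = ri$chromosome,
             base_pair_location = ri$base_pair_location,
             effect_allele = ri$effect_allele, other_allele = ri$other_allele,
             effect_allele_frequency = eaf, beta = beta, standard_error = se,
             z = zst, p_value = p, n = n, n_events = sum(y), info = 1,
             mac = mac, flag = flag, stringsAsFactors = FALSE)
}

#' Exact per-variant Cox fit (scan oracle)
#'
#' Full Newton maximisation of the Breslow partial likelihood for
#' genotype plus covariates via \pkg{survival}, with Wald standard error
#' from the observed information. Serves as the independent oracle for
#' the one-step score scan.
#'
#' @param g dosage vector (non-constant).
#' @param time,status survival outcome; at least one event required.
#' @param covariates optional covariate data.frame.
#' @return single-row data.frame with `beta`, `standard_error`, `z`,
#'   `p_value`, `n`, `n_events`.
#' @export
exactCoxFit <- function(g, time, status, covariates = NULL) {
  if (sum(status) == 0) stop("no events")
  if (length(unique(g)) == 1L) stop("constant dosage vector")
  df <- data.frame(time = time, status = as.integer(status), g = as.numeric(g))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  rhs <- setdiff(names(df), c("time", "status"))
  fml <- stats::as.formula(paste("survival::Surv(time, status) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("partial likelihood is monotone: no finite estimate")
      invokeRestart("muffleWarning")
    }
  )
  b <- coef(fit)["g"]
  se <- sqrt(vcov(fit)["g", "g"])
  if (!is.finite(b) || abs(b) > 15)
    stop("partial likelihood is monotone: no finite estimate")
  z <- b / se
  data.frame(beta = unname(b), standard_error = unname(se), z = unname(z),
             p_value = 2 * pnorm(-abs(z)), n = length(g),
             n_events = sum(status))
}

#' Summary-statistic quality control
#'
#' Retains records with imputation INFO strictly above `minInfo` and
#' minor allele count of at least `minMac`; records flagged monomorphic
#' are always dropped. Idempotent and order-independent.
#'
#' @param records association record data.frame.
#' @param minInfo INFO threshold (strict).
#' @param minMac minor-allele-count threshold (inclusive).
#' @return the filtered data.frame.
#' @export
variantQC <- function(records, minInfo = 0.7, minMac = 20) {
  if (!nrow(records)) return(records)
  keep <- records$info > minInfo & records$mac >= minMac
  if ("flag" %in% names(records)) keep <- keep & records$flag != "monomorphic"
  records[keep, , drop = FALSE]
}

#' Down-sample a cohort to matched event/censored counts
#'
#' Uniform subsample without replacement reaching exactly the target
#' event and censored counts, used to run the susceptibility scan at the
#' effective sample size of the progression scan. For `outcome =
#' "onset"` events are diagnosed individuals and censored are non-cases;
#' for `outcome = "progression"` both pools are cases, split by the
#' progression event indicator.
#'
#' @param cohort a [ProgressionCohort-class].
#' @param targetEvents,targetCensored required counts.
#' @param seed integer seed (deterministic selection).
#' @param outcome `"onset"` or `"progression"`.
#' @return the subsampled [ProgressionCohort-class].
#' @export
downsampleMatch <- function(cohort, targetEvents, targetCensored, seed,
                            outcome = c("onset", "progression")) {
  outcome <- match.arg(outcome)
  cd <- colData(cohort)
  if (outcome == "onset") {
    evPool <- which(cd$disease)
    cnPool <- which(!cd$disease)
  } else {
    evPool <- which(cd$disease & !is.na(cd$event) & cd$event == 1L)
    cnPool <- which(cd$disease & !is.na(cd$event) & cd$event == 0L)
  }
  if (targetEvents > length(evPool))
    stop(sprintf("target events %d exceed available %d (shortfall %d)",
                 targetEvents, length(evPool), targetEvents - length(evPool)))
  if (targetCensored > length(cnPool))
    stop(sprintf("target censored %d exceed available %d (shortfall %d)",
                 targetCensored, length(cnPool),
                 targetCensored - length(cnPool)))
  set.seed(seed)
  pick <- sort(c(sample(evPool, targetEvents),
                 sample(cnPool, targetCensored)))
  cohort[, pick]
}
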
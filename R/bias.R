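#' Pair susceptibility and progression summary statistics
#'
#' Inner join of two association-record tables on `variant_id` with
#' allele harmonisation: when the effect/other alleles are swapped
#' between tables the progression beta (and allele frequency) are
#' flipped onto the susceptibility table's effect allele; variants whose
#' allele pairs cannot be reconciled are dropped and counted. Pairs are
#' marked `selected` when the susceptibility p-value is below
#' `selectionP`. When a truth table (from [trueEffectsTable()]) is
#' supplied, `true_class`, `beta_S_true` and `beta_P_true` are attached.
#'
#' @param recordsS,recordsP association records for susceptibility and
#'   progression.
#' @param selectionP selection threshold on the susceptibility p-value.
#' @param truth optional data.frame from [trueEffectsTable()].
#' @return data.frame of effect pairs; attribute `n_dropped` counts
#'   variants lost to allele mismatch.
#' @export
buildEffectPairs <- function(recordsS, recordsP, selectionP = 5e-8,
                             truth = NULL) {
  if (!nrow(recordsS) || !nrow(recordsP))
    stop("empty summary statistics table")
  s <- recordsS[, c("variant_id", "effect_allele", "other_allele",
                    "effect_allele_frequency", "beta", "standard_error",
                    "p_value")]
  names(s) <- c("variant_id", "ea", "oa", "eaf", "beta_S", "se_S", "p_S")
  p <- recordsP[, c("variant_id", "effect_allele", "other_allele",
                    "beta", "standard_error", "p_value")]
  names(p) <- c("variant_id", "ea_P", "oa_P", "beta_P", "se_P", "p_P")
  m <- merge(s, p, by = "variant_id")
  if (!nrow(m)) stop("no shared variants between the two tables")
  same <- m$ea == m$ea_P & m$oa == m$oa_P
  swapped <- m$ea == m$oa_P & m$oa == m$ea_P
  bad <- !(same | swapped)
  nDropped <- sum(bad)
  if (nDropped) message(nDropped, " pair(s) dropped: irreconcilable alleles")
  m <- m[!bad, , drop = FALSE]
  m$beta_P[swapped[!bad]] <- -m$beta_P[swapped[!bad]]
  out <- data.frame(variant_id = m$variant_id,
                    effect_allele = m$ea, other_allele = m$oa,
                    eaf = m$eaf,
                    beta_S = m$beta_S, se_S = m$se_S, p_S = m$p_S,
                    beta_P = m$beta_P, se_P = m$se_P, p_P = m$p_P,
                    selected = m$p_S < selectionP,
                    stringsAsFactors = FALSE)
  if (!is.null(truth)) {
    out <- merge(out, truth[, c("variant_id", "true_class", "beta_S_true",
                                "beta_P_true")],
                 by = "variant_id", sort = FALSE)
  }
  attr(out, "n_dropped") <- nDropped
  out
}

# expected complete-data log-likelihood piece for one component, as a
# function of sigma2 (b fixed); used by the generalized M-step
componentQ <- function(sigma2, resid2, s2, gamma) {
  v <- sigma2 + s2
  -0.5 * sum(gamma * (log(v) + resid2 / v))
}

emSlopeOnce <- function(x, y, s2, K, maxIter, tol, init) {
  b <- init$b
  sigma2 <- init$sigma2
  pi_k <- init$pi
  nOk <- length(x)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  logdens <- matrix(0, nOk, K)
  repeat {
    iter <- iter + 1L
    for (k in seq_len(K)) {
      v <- sigma2[k] + s2
      logdens[, k] <- log(pi_k[k]) - 0.5 * (log(2 * pi * v) +
                                            (y - b[k] * x)^2 / v)
    }
    mx <- apply(logdens, 1L, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- c(ll, sum(lse))
    gamma <- exp(logdens - lse)
    if (iter > 1L && abs(ll[iter] - ll[iter - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= maxIter) break
    # M-step (generalized): exact weighted-LS slope given sigma2, then
    # 1-D maximisation of Q in sigma2 given the new slope
    pi_k <- pmax(colMeans(gamma), 1e-12)
    pi_k <- pi_k / sum(pi_k)
    for (k in seq_len(K)) {
      w <- gamma[, k] / (sigma2[k] + s2)
      sxx <- sum(w * x^2)
      b[k] <- if (sxx > 0) sum(w * x * y) / sxx else 0
      resid2 <- (y - b[k] * x)^2
      if (sum(gamma[, k]) > 1e-10) {
        upper <- max(resid2 + s2, 1e-6)
        opt <- optimize(componentQ, interval = c(0, upper),
                        resid2 = resid2, s2 = s2, gamma = gamma[, k],
                        maximum = TRUE, tol = 1e-10)
        # keep the boundary value when it beats the interior optimum
        if (componentQ(0, resid2, s2, gamma[, k]) >= opt$objective)
          sigma2[k] <- 0 else sigma2[k] <- opt$maximum
      }
    }
  }
  list(b = b, sigma2 = sigma2, pi = pi_k, gamma = gamma, logLik = ll,
       converged = converged, iter = iter)
}

#' Fit a slope-hunter-style mixture to selected effect pairs
#'
#' EM fit, on susceptibility-selected pairs, of a K-component mixture of
#' regressions through the origin: component k models
#' \eqn{\beta_P = b_k \beta_S + \varepsilon_k} with variance
#' \eqn{\sigma_k^2 + se_P^2} (progression measurement error folded in
#' additively). The adjustment slope is read from the component
#' designated susceptibility-only: by default the one with the largest
#' mixing proportion (susceptibility-only variants are assumed to
#' dominate the selected set); `"smallest_sigma"` picks the component
#' with the least extra residual variance instead. Several random
#' restarts are run and the best log-likelihood kept; the log-likelihood
#' trace of the winning start is non-decreasing by construction.
#'
#' @param pairs data.frame from [buildEffectPairs()].
#' @param K number of mixture components.
#' @param maxIter,tol EM stopping rule (absolute log-likelihood change).
#' @param nStarts random restarts.
#' @param seed integer seed; restart seeds derive from it.
#' @param designation `"largest_pi"` or `"smallest_sigma"`.
#' @param useSelected fit on selected pairs only (default) or all pairs.
#' @return A [SlopeMixtureFit-class].
#' @export
fitSlopeMixture <- function(pairs, K = 2, maxIter = 1000, tol = 1e-6,
                            nStarts = 10, seed = 1L,
                            designation = c("largest_pi", "smallest_sigma"),
                            useSelected = TRUE) {
  designation <- match.arg(designation)
  sel <- if (useSelected) pairs[pairs$selected, , drop = FALSE] else pairs
  if (nrow(sel) < 10)
    stop(sprintf("only %d selected pairs; need at least 10", nrow(sel)))
  x <- sel$beta_S
  y <- sel$beta_P
  s2 <- sel$se_P^2
  b0 <- {
    w <- 1 / s2
    sum(w * x * y) / max(sum(w * x^2), .Machine$double.eps)
  }
  v0 <- max(var(y - b0 * x) - mean(s2), 1e-6)
  best <- NULL
  for (s in seq_len(nStarts)) {
    set.seed(childSeed(seed, 100L + s))
    init <- list(
      b = b0 + rnorm(K, 0, max(abs(b0), 0.2)) * (s > 1),
      sigma2 = v0 * exp(runif(K, -1, 1)),
      pi = {p0 <- runif(K, 0.5, 1); p0 / sum(p0)}
    )
    fit <- emSlopeOnce(x, y, s2, K, maxIter, tol, init)
    if (is.null(best) || max(fit$logLik) > max(best$logLik)) best <- fit
  }
  if (!best$converged)
    stop(sprintf(paste0("EM did not converge in %d iterations across %d ",
                        "starts (last log-likelihood change %.3g)"),
                 maxIter, nStarts,
                 abs(diff(utils::tail(best$logLik, 2)))))
  kStar <- switch(designation,
                  largest_pi = which.max(best$pi),
                  smallest_sigma = which.min(best$sigma2))
  new("SlopeMixtureFit",
      slope = best$b[kStar], b = best$b, pi = best$pi,
      sigma2 = best$sigma2, posterior = best$gamma,
      logLik = best$logLik, converged = best$converged,
      nIterations = best$iter, designation = designation,
      variantId = as.character(sel$variant_id))
}

#' Adjust progression effects for index event bias
#'
#' Applies the slope-hunter-style correction to every pair (not only the
#' selected ones): `beta_P_adj = beta_P - b * beta_S`,
#' `se_P_adj = sqrt(se_P^2 + b^2 * se_S^2)`; z and p are recomputed from
#' the adjusted values. The adjusted standard error never falls below
#' the unadjusted one.
#'
#' @param pairs data.frame from [buildEffectPairs()].
#' @param slopeB adjustment slope (finite scalar), e.g. `slope(fit)`.
#' @return `pairs` with columns `beta_P_adj`, `se_P_adj`, `z_adj`,
#'   `p_adj` added.
#' @export
adjustEffects <- function(pairs, slopeB) {
  if (!is.finite(slopeB)) stop("adjustment slope must be finite")
  pairs$beta_P_adj <- pairs$beta_P - slopeB * pairs$beta_S
  pairs$se_P_adj <- sqrt(pairs$se_P^2 + slopeB^2 * pairs$se_S^2)
  pairs$z_adj <- pairs$beta_P_adj / pairs$se_P_adj
  pairs$p_adj <- 2 * pnorm(-abs(pairs$z_adj))
  pairs
}

#' Bias metrics against the simulated truth
#'
#' Per causal class (null, S_only, P_only, shared): mean signed bias
#' \eqn{E[\hat\beta_P - \beta_{P,true}]}, its susceptibility-oriented
#' version \eqn{E[\mathrm{sign}(\beta_{S,true})(\hat\beta_P -
#' \beta_{P,true})]} (the quantity that vanishes without a shared factor
#' and grows with it — with symmetric effect draws the unoriented mean
#' is ~0 by construction), the mean absolute error, the RMSE, and — when
#' adjusted columns are
#' present — the same after correction plus counts of significant
#' variants before/after at `threshold`.
#'
#' @param pairs data.frame from [buildEffectPairs()] carrying truth
#'   columns (simulated data only), optionally after [adjustEffects()].
#' @param threshold significance threshold for the before/after counts.
#' @return data.frame with one row per class present.
#' @export
biasMetrics <- function(pairs, threshold = 5e-8) {
  if (!all(c("true_class", "beta_P_true", "beta_S_true") %in% names(pairs)))
    stop("truth columns absent: bias metrics require a simulated cohort ",
         "(see trueEffectsTable())")
  hasAdj <- "beta_P_adj" %in% names(pairs)
  one <- function(df) {
    err <- df$beta_P - df$beta_P_true
    orient <- sign(df$beta_S_true)
    out <- data.frame(
      n = nrow(df),
      mean_bias = mean(err),
      mean_bias_oriented = mean(orient * err),
      mae = mean(abs(err)),
      rmse = sqrt(mean(err^2)),
      n_sig_before = sum(df$p_P < threshold)
    )
    if (hasAdj) {
      errA <- df$beta_P_adj - df$beta_P_true
      out$mean_bias_adj <- mean(errA)
      out$mean_bias_oriented_adj <- mean(orient * errA)
      out$mae_adj <- mean(abs(errA))
      out$rmse_adj <- sqrt(mean(errA^2))
      out$n_sig_after <- sum(df$p_adj < threshold)
    }
    out
  }
  cls <- intersect(c("null", "S_only", "P_only", "shared"),
                   unique(pairs$true_class))
  res <- do.call(rbind, lapply(cls, function(cl)
    cbind(data.frame(class = cl), one(pairs[pairs$true_class == cl, ]))))
  rownames(res) <- NULL
  res
}
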
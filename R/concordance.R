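#' Direction concordance between susceptibility and progression effects
#'
#' Counts pairs whose effects share a sign, tests the proportion against
#' 0.5 with a two-sided binomial test (doubled smaller tail) and returns
#' a 95% confidence interval (normal approximation by default; Wilson
#' and exact Clopper-Pearson available). Pairs with an exactly zero
#' effect on either axis carry no direction and are excluded from the
#' count (the number excluded is reported). Also counts pairs whose
#' progression p-value clears the Bonferroni threshold
#' `bonferroniAlpha / n_pairs`.
#'
#' @param pairs data.frame from [buildEffectPairs()].
#' @param ciMethod `"normal"`, `"wilson"` or `"exact"`.
#' @param bonferroniAlpha family-wise alpha for the replication count.
#' @return list of class `"concordanceSummary"`: `n_pairs`,
#'   `n_same_direction`, `proportion`, `ci_low`, `ci_high`,
#'   `p_binomial`, `bonferroni_alpha` (the per-test threshold),
#'   `n_replicated`, `n_excluded`.
#' @examples
#' pairs <- data.frame(beta_S = c(1, -2, 3), beta_P = c(2, -1, -1),
#'                     p_P = c(0.01, 0.2, 0.6))
#' directionConcordance(pairs)
#' @export
directionConcordance <- function(pairs,
                                 ciMethod = c("normal", "wilson", "exact"),
                                 bonferroniAlpha = 0.05) {
  ciMethod <- match.arg(ciMethod)
  if (!nrow(pairs)) stop("no pairs to compare")
  zero <- pairs$beta_S == 0 | pairs$beta_P == 0
  nExcluded <- sum(zero)
  if (nExcluded) message(nExcluded, " zero-effect pair(s) excluded")
  df <- pairs[!zero, , drop = FALSE]
  n <- nrow(df)
  if (!n) stop("no pairs with defined effect direction")
  k <- sum(sign(df$beta_S) == sign(df$beta_P))
  prop <- k / n
  p <- binomTwoSided(k, n)
  zc <- qnorm(0.975)
  ci <- switch(ciMethod,
    normal = prop + c(-1, 1) * zc * sqrt(prop * (1 - prop) / n),
    wilson = {
      den <- 1 + zc^2 / n
      ctr <- (prop + zc^2 / (2 * n)) / den
      hw <- zc * sqrt(prop * (1 - prop) / n + zc^2 / (4 * n^2)) / den
      ctr + c(-1, 1) * hw
    },
    exact = as.numeric(stats::binom.test(k, n)$conf.int)
  )
  thr <- bonferroniThreshold(bonferroniAlpha, nrow(pairs))
  nRep <- if ("p_P" %in% names(pairs)) sum(pairs$p_P < thr) else NA_integer_
  structure(list(n_pairs = n, n_same_direction = k, proportion = prop,
                 ci_low = ci[1], ci_high = ci[2], p_binomial = p,
                 bonferroni_alpha = thr, n_replicated = nRep,
                 n_excluded = nExcluded, ci_method = ciMethod),
            class = "concordanceSummary")
}

# two-sided binomial test against 0.5: doubled smaller tail
binomTwoSided <- function(k, n) {
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' @export
print.concordanceSummary <- function(x, ...) {
  cat(sprintf("Direction concordance: %d / %d pairs (%.3f), 95%% CI [%.3f, %.3f] (%s)\n",
              x$n_same_direction, x$n_pairs, x$proportion, x$ci_low,
              x$ci_high, x$ci_method))
  cat(sprintf("  binomial test vs 0.5: p = %.4f\n", x$p_binomial))
  cat(sprintf("  replicated at p < %.3g: %s (of %d); %d zero-effect pair(s) excluded\n",
              x$bonferroni_alpha,
              ifelse(is.na(x$n_replicated), "NA", x$n_replicated),
              x$n_pairs, x$n_excluded))
  invisible(x)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise error rate.
#' @param nTests number of tests (>= 1).
#' @return `alpha / nTests`.
#' @examples
#' bonferroniThreshold(0.05, 804)
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  if (nTests < 1) stop("nTests must be >= 1")
  alpha / nTests
}

#' Count records below a significance threshold
#'
#' Strict inequality, matching the conventional "P < 5e-8" notation.
#'
#' @param records data.frame with a `p_value` column, or a numeric
#'   p-value vector.
#' @param threshold significance threshold.
#' @return integer count.
#' @export
countSignificant <- function(records, threshold = 5e-8) {
  p <- if (is.data.frame(records)) records$p_value else records
  sum(p < threshold, na.rm = TRUE)
}

#' Correlation of effect estimates across two scans
#'
#' Pearson correlation of `beta` (or `z`) across the variants shared by
#' two association-record tables, used for sensitivity-analysis
#' comparisons.
#'
#' @param a,b association record data.frames.
#' @param on `"beta"` or `"z"`.
#' @return the correlation coefficient.
#' @export
effectCorrelation <- function(a, b, on = c("beta", "z")) {
  on <- match.arg(on)
  m <- merge(a[, c("variant_id", on)], b[, c("variant_id", on)],
             by = "variant_id")
  if (nrow(m) < 3) stop("fewer than 3 shared variants")
  x <- m[[paste0(on, ".x")]]
  y <- m[[paste0(on, ".y")]]
  if (var(x) == 0 || var(y) == 0) stop("zero variance in effect estimates")
  cor(x, y)
}
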
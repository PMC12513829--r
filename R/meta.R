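#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' METAL-style combination of per-study estimates: weights
#' \eqn{w_k = 1/se_k^2}, combined effect \eqn{\sum w \beta / \sum w},
#' standard error \eqn{1/\sqrt{\sum w}}, and Cochran's heterogeneity
#' statistic \eqn{Q = \sum w_k (\beta_k - \beta_{meta})^2} against
#' chi-square with K - 1 degrees of freedom.
#'
#' @param beta per-study effect estimates.
#' @param se per-study standard errors (> 0).
#' @return list of class `"metaResult"`: `beta_meta`, `se_meta`, `z`,
#'   `p_meta`, `Q`, `df`, `p_Q`, `n_studies`.
#' @examples
#' ivwMeta(c(1, 3), c(1, 1)) # beta 2, se 1/sqrt(2), Q = 2
#' @export
ivwMeta <- function(beta, se) {
  if (!length(beta)) stop("need at least one study")
  if (length(se) != length(beta)) stop("beta and se lengths differ")
  if (any(!is.finite(se) | se <= 0)) stop("standard errors must be > 0")
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sem <- 1 / sqrt(sum(w))
  z <- bm / sem
  Q <- sum(w * (beta - bm)^2)
  df <- length(beta) - 1L
  structure(list(beta_meta = bm, se_meta = sem, z = z,
                 p_meta = 2 * pnorm(-abs(z)),
                 Q = Q, df = df,
                 p_Q = if (df > 0) pchisq(Q, df, lower.tail = FALSE)
                       else NA_real_,
                 n_studies = length(beta)),
            class = "metaResult")
}

#' Sample-size weighted Z-score meta-analysis
#'
#' For studies without usable effect sizes (direction + Z only):
#' \eqn{z_{meta} = \sum \sqrt{n_k} \, s_k z_k / \sqrt{\sum n_k}} with
#' direction flags \eqn{s_k}, two-sided p from the normal.
#'
#' @param z per-study z-scores.
#' @param n per-study sample sizes (> 0 in total).
#' @param direction optional direction flags (+1/-1), default +1.
#' @return list of class `"metaResult"`: `z_meta`, `p_meta`,
#'   `n_studies`, `n_total`.
#' @examples
#' zMeta(c(1, 1), c(100, 100), c(1, -1)) # cancels to 0
#' @export
zMeta <- function(z, n, direction = NULL) {
  if (!length(z)) stop("need at least one study")
  if (is.null(direction)) direction <- rep(1, length(z))
  if (length(n) != length(z) || length(direction) != length(z))
    stop("z, n and direction lengths differ")
  if (sum(n) <= 0) stop("total sample size must be positive")
  zm <- sum(sqrt(n) * sign(direction) * z) / sqrt(sum(n))
  structure(list(z_meta = zm, p_meta = 2 * pnorm(-abs(zm)),
                 n_studies = length(z), n_total = sum(n)),
            class = "metaResult")
}

#' @export
print.metaResult <- function(x, ...) {
  if (!is.null(x$beta_meta)) {
    cat(sprintf("IVW meta: beta = %.4f (se %.4f), p = %.3g; Q = %.3f (df %d, p = %.3g); %d studies\n",
                x$beta_meta, x$se_meta, x$p_meta, x$Q, x$df,
                ifelse(is.na(x$p_Q), NaN, x$p_Q), x$n_studies))
  } else {
    cat(sprintf("Z meta: z = %.4f, p = %.3g; %d studies, total n = %g\n",
                x$z_meta, x$p_meta, x$n_studies, x$n_total))
  }
  invisible(x)
}
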
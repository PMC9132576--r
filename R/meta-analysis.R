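# Random-effects standardized-mean-difference meta-analysis per cognitive
# domain, with heterogeneity statistics, funnel diagnostics and Bonferroni
# correction across domains.

#' Cohen's d and its sampling variance from group summaries
#'
#' \code{d = (m_t2dm - m_hc) / s_pooled} with the pooled SD
#' \code{sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1+n2-2))}, after direction
#' harmonization (domains scored so that lower values mean better
#' performance are sign-flipped, so negative d always means worse T2DM
#' performance). The variance is
#' \code{(n1+n2)/(n1 n2) + d^2 / (2 (n1+n2))}. No small-sample (Hedges)
#' correction is applied by default.
#'
#' @param mT2dm,sdT2dm,nT2dm T2DM-group mean, SD and size (vectorized).
#' @param mHc,sdHc,nHc control-group mean, SD and size.
#' @param higherBetter TRUE when higher scores mean better performance.
#' @param hedges apply the Hedges small-sample correction factor
#'   \code{1 - 3/(4(n1+n2)-9)} to d (default FALSE).
#' @return data.frame with columns \code{d} and \code{variance}.
#' @examples
#' cohensD(1, 1, 10, 0, 1, 10)
#' @export
cohensD <- function(mT2dm, sdT2dm, nT2dm, mHc, sdHc, nHc,
                    higherBetter = TRUE, hedges = FALSE) {
  if (any(c(sdT2dm, sdHc) <= 0)) stop("SDs must be > 0", call. = FALSE)
  if (any(c(nT2dm, nHc) < 2)) stop("group sizes must be >= 2", call. = FALSE)
  sp <- sqrt(((nT2dm - 1) * sdT2dm^2 + (nHc - 1) * sdHc^2) /
               (nT2dm + nHc - 2))
  if (any(sp == 0)) stop("zero pooled SD", call. = FALSE)
  d <- (mT2dm - mHc) / sp
  d <- ifelse(rep(higherBetter, length.out = length(d)), d, -d)
  if (hedges) d <- d * (1 - 3 / (4 * (nT2dm + nHc) - 9))
  n <- nT2dm + nHc
  data.frame(d = d, variance = n / (nT2dm * nHc) + d^2 / (2 * n))
}

#' Random-effects pooling of study effects
#'
#' Pools per-study standardized mean differences with inverse-variance
#' weights \code{1/(variance + tau2)}. The between-study variance tau^2 is
#' estimated by REML (default) or DerSimonian-Laird; the CI is normal-based.
#' Cochran's Q uses fixed-effect weights and I^2 is recomputed from Q as
#' \code{max(0, (Q - (k-1)) / Q) * 100}.
#'
#' @param d,variance per-study effects and sampling variances (k >= 2).
#' @param method tau^2 estimator, \code{"REML"} or \code{"DL"}.
#' @param domain label carried through to the result.
#' @param mBonferroni family size for the Bonferroni-adjusted p.
#' @return a \linkS4class{MetaResult}.
#' @examples
#' randomEffectsPool(c(0.2, 0.4, 0.6), rep(0.04, 3), method = "DL")
#' @export
randomEffectsPool <- function(d, variance, method = c("REML", "DL"),
                              domain = "", mBonferroni = 1) {
  method <- match.arg(method)
  k <- length(d)
  if (k < 2) stop("at least 2 studies are required", call. = FALSE)
  fit <- metafor::rma(yi = d, vi = variance, method = method)
  q <- fit$QE
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  new("MetaResult", domain = domain, k = as.integer(k),
      dPooled = as.numeric(fit$beta), ciLow = fit$ci.lb, ciHigh = fit$ci.ub,
      tau2 = fit$tau2, q = q, i2 = i2, p = fit$pval,
      pBonferroni = min(1, fit$pval * mBonferroni), method = method)
}

#' Pool per-study summaries across cognitive domains
#'
#' Computes Cohen's d per study row, optionally averages multiple effects
#' contributed by the same study to one domain (effect = mean d, variance =
#' mean variance, a conservative choice for correlated tests), pools each
#' domain with \code{\link{randomEffectsPool}}, and Bonferroni-adjusts the
#' pooled p-values with the number of domains as family size. A domain with
#' a single study is reported with missing pooled statistics and a warning.
#'
#' @param studies data.frame with columns \code{study_id}, \code{domain},
#'   \code{m_t2dm}, \code{sd_t2dm}, \code{n_t2dm}, \code{m_hc},
#'   \code{sd_hc}, \code{n_hc} and optionally \code{higher_better}
#'   (default TRUE).
#' @param method tau^2 estimator passed through.
#' @param averageWithinStudy average multiple effects per (study, domain)
#'   before pooling (default TRUE).
#' @return data.frame, one row per domain, with the
#'   \linkS4class{MetaResult} fields.
#' @export
poolDomains <- function(studies, method = c("REML", "DL"),
                        averageWithinStudy = TRUE) {
  method <- match.arg(method)
  hb <- if ("higher_better" %in% names(studies)) studies$higher_better else TRUE
  eff <- cohensD(studies$m_t2dm, studies$sd_t2dm, studies$n_t2dm,
                 studies$m_hc, studies$sd_hc, studies$n_hc,
                 higherBetter = hb)
  eff$study_id <- studies$study_id
  eff$domain <- studies$domain
  if (averageWithinStudy) {
    eff <- do.call(rbind, lapply(
      split(eff, list(eff$domain, eff$study_id), drop = TRUE),
      function(g) data.frame(d = mean(g$d), variance = mean(g$variance),
                             study_id = g$study_id[1], domain = g$domain[1])))
  }
  domains <- sort(unique(eff$domain))
  m <- length(domains)
  rows <- lapply(domains, function(dom) {
    g <- eff[eff$domain == dom, ]
    if (nrow(g) < 2) {
      warning("domain '", dom, "' has a single study; not pooled")
      return(data.frame(domain = dom, k = nrow(g), d_pooled = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        tau2 = NA_real_, q = NA_real_, i2 = NA_real_,
                        p = NA_real_, p_bonferroni = NA_real_,
                        method = method, stringsAsFactors = FALSE))
    }
    metaTable(randomEffectsPool(g$d, g$variance, method = method,
                                domain = dom, mBonferroni = m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Funnel-plot data: per-study points and the pseudo-95% boundary
#'
#' @param d,variance per-study effects and variances.
#' @param pooled center of the funnel; defaults to the fixed-effect
#'   (inverse-variance) pooled estimate.
#' @return list with \code{points} (d, se per study) and \code{boundary}
#'   (se grid with low/high pseudo-confidence bounds, apex at se = 0 equal
#'   to the pooled estimate).
#' @export
funnelData <- function(d, variance, pooled = NULL) {
  se <- sqrt(variance)
  if (is.null(pooled)) pooled <- sum(d / variance) / sum(1 / variance)
  grid <- seq(0, max(se) * 1.05, length.out = 50)
  list(points = data.frame(d = d, se = se),
       boundary = data.frame(se = grid,
                             low = pooled - 1.959964 * grid,
                             high = pooled + 1.959964 * grid),
       pooled = pooled)
}
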
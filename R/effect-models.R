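# Linear-model effect estimation: factor coefficients with t-based 95% CIs,
# percent-of-control-mean scaling, and multiple-comparison correction.

.as_model_numeric <- function(x, name) {
  if (is.logical(x)) return(as.numeric(x))
  if (is.character(x) || is.factor(x)) {
    lev <- sort(unique(as.character(x[!is.na(x)])))
    if (length(lev) > 2)
      stop("term '", name, "' has more than two levels; recode it",
           call. = FALSE)
    return(as.numeric(factor(as.character(x), levels = lev)) - 1)
  }
  as.numeric(x)
}

#' Estimate one factor's effect on an outcome by OLS
#'
#' Fits an ordinary-least-squares model of the outcome on the factor and any
#' covariates (plus an intercept), and reports the factor coefficient as the
#' maximum-likelihood point estimate with a two-sided t test and a t-based
#' confidence interval at \code{level}. Rows with a missing outcome, factor
#' or covariate are dropped and counted.
#'
#' @param outcome numeric vector, one value per cohort row.
#' @param cohort data.frame holding the factor and covariate columns.
#' @param factor name of the factor of interest; binary factors are coded
#'   0/1, continuous factors are in their native units (e.g. years).
#' @param covariates character vector of additional regressor names.
#' @param level confidence level (default 0.95).
#' @return an \linkS4class{EffectEstimate}.
#' @examples
#' co <- generateCohort(cohortSpec(nSubjects = 200, t2dmPrevalence = 0.5,
#'                                 seed = 5))
#' fitEffect(100 - 0.5 * co$age + rnorm(200), co, "age")
#' @export
fitEffect <- function(outcome, cohort, factor, covariates = character(),
                      level = 0.95) {
  terms <- c(factor, covariates)
  missing_cols <- setdiff(terms, names(cohort))
  if (length(missing_cols))
    stop("model terms not in cohort: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             vapply(terms, function(tm) .as_model_numeric(cohort[[tm]], tm),
                    numeric(nrow(cohort))))
  colnames(X) <- c("(Intercept)", terms)
  y <- as.numeric(outcome)
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1)
    stop("too few complete rows (", n, ") for ", p, " model terms",
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- lm.fit(X, y)
  df <- n - p
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  j <- match(factor, colnames(X))
  beta <- fit$coefficients[j]
  sej <- se[j]
  tstat <- if (sej > 0) beta / sej else sign(beta) * Inf
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  tcrit <- qt(1 - (1 - level) / 2, df)
  new("EffectEstimate", beta = unname(beta), se = unname(sej),
      ciLow = unname(beta - tcrit * sej), ciHigh = unname(beta + tcrit * sej),
      t = unname(tstat), p = unname(pval), n = as.integer(n), df = df,
      nDropped = as.integer(sum(!ok)), factor = factor,
      covariates = covariates, level = level)
}

#' Express an effect as percent of the healthy-control mean
#'
#' @param est an \linkS4class{EffectEstimate}.
#' @param hcMean mean outcome of the (matched) control arm; must be nonzero.
#' @return a \linkS4class{PercentEffect}: the coefficient and its CI bounds
#'   divided by \code{hcMean} and scaled to percent.
#' @examples
#' percentEffect(new("EffectEstimate", beta = -0.5, se = 0.1, ciLow = -0.7,
#'                   ciHigh = -0.3, t = -5, p = 0.001, n = 100L, df = 98,
#'                   nDropped = 0L, factor = "t2dm",
#'                   covariates = character(), level = 0.95), 10)
#' @export
percentEffect <- function(est, hcMean) {
  stopifnot(is(est, "EffectEstimate"))
  if (!is.finite(hcMean) || hcMean == 0)
    stop("control mean is zero; percent effect undefined", call. = FALSE)
  b <- range(100 * c(est@ciLow, est@ciHigh) / hcMean)
  new("PercentEffect", percent = 100 * est@beta / hcMean,
      percentCiLow = b[1], percentCiHigh = b[2], hcMean = hcMean)
}

#' Bonferroni adjustment with an explicit family size
#'
#' @param p vector of p-values.
#' @param m family size (defaults to \code{length(p)}).
#' @return \code{pmin(1, p * m)}.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted values: with p-values ranked increasingly,
#' \code{adj[i] = min over j >= i of min(1, p[j] * m / j)}.
#'
#' @param p vector of p-values.
#' @return adjusted p-values in the input order.
#' @export
bhFdr <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  adj
}

# Multi-response OLS sharing one design matrix: returns per-response beta,
# se, t, p for the requested column, plus n/df. Y is n x q.
.ols_multi <- function(X, Y, j, level) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear terms: ",
         paste(colnames(X)[-seq_len(qrX$rank)], collapse = ", "),
         call. = FALSE)
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  n <- nrow(X); df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  cjj <- chol2inv(qr.R(qrX))[j, j]
  se <- sqrt(sigma2 * cjj)
  beta <- B[j, ]
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  tcrit <- qt(1 - (1 - level) / 2, df)
  list(beta = beta, se = se, t = tstat, p = pval,
       ciLow = beta - tcrit * se, ciHigh = beta + tcrit * se,
       n = n, df = df)
}

#' Per-region effect map from a volume experiment
#'
#' Head-size-normalizes each subject's regional volumes (division by the
#' \code{head_scaling} column when present), fits the factor model per
#' region with a shared design, attaches Bonferroni-adjusted p-values
#' (family size 45) and percent effects relative to the control-arm mean.
#' For a binary 0/1 factor the denominator is the mean over the factor's
#' zero arm; for a continuous factor it is the mean over all modelled rows.
#'
#' @param volumes \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{volume} assay (regions x subjects) whose \code{colData} carries
#'   the cohort, or a regions x subjects matrix plus \code{cohort}.
#' @param factor,covariates model terms (columns of the cohort).
#' @param cohort cohort data.frame (ignored when \code{volumes} is a
#'   SummarizedExperiment).
#' @param level confidence level.
#' @param normalizeHeadSize divide volumes by the \code{head_scaling}
#'   column (default TRUE when the column exists).
#' @return an \linkS4class{EffectMap} with 45 entries.
#' @export
regionalEffectMap <- function(volumes, factor, covariates = character(),
                              cohort = NULL, level = 0.95,
                              normalizeHeadSize = TRUE) {
  if (is(volumes, "SummarizedExperiment")) {
    cohort <- as.data.frame(SummarizedExperiment::colData(volumes))
    V <- SummarizedExperiment::assay(volumes, "volume")
  } else V <- as.matrix(volumes)
  if (is.null(cohort)) stop("a cohort table is required", call. = FALSE)
  if (nrow(V) != 45L)
    stop("expected 45 regions, got ", nrow(V), call. = FALSE)
  if (normalizeHeadSize && "head_scaling" %in% names(cohort))
    V <- sweep(V, 2, cohort$head_scaling, "/")
  terms <- c(factor, covariates)
  Xcols <- vapply(terms, function(tm) .as_model_numeric(cohort[[tm]], tm),
                  numeric(nrow(cohort)))
  X <- cbind(`(Intercept)` = 1, Xcols)
  colnames(X) <- c("(Intercept)", terms)
  Y <- t(V)
  ok <- complete.cases(X) & complete.cases(Y)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok, , drop = FALSE]
  fit <- .ols_multi(X, Y, match(factor, colnames(X)), level)

  fx <- X[, factor]
  hcRows <- if (all(fx %in% c(0, 1))) fx == 0 else rep(TRUE, nrow(X))
  hcMean <- colMeans(Y[hcRows, , drop = FALSE])
  if (any(hcMean == 0))
    stop("control mean is zero for some region", call. = FALSE)
  pl <- 100 * fit$ciLow / hcMean
  ph <- 100 * fit$ciHigh / hcMean
  tab <- data.frame(
    name = rownames(V), beta = fit$beta, se = fit$se,
    ci_low = fit$ciLow, ci_high = fit$ciHigh, t = fit$t, p = fit$p,
    p_adjusted = bonferroni(fit$p, 45),
    percent = 100 * fit$beta / hcMean,
    percent_ci_low = pmin(pl, ph), percent_ci_high = pmax(pl, ph),
    n = fit$n, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  new("EffectMap", table = tab, factor = factor)
}

#' Per-domain cognitive effect map
#'
#' Runs \code{\link{fitEffect}} per domain column and expresses each effect
#' as percent of the control-arm domain mean, with Bonferroni adjustment
#' across the domains.
#'
#' @param scores data.frame from \code{\link{generateCognitiveScores}} (an
#'   \code{id} column plus one column per domain), aligned with
#'   \code{cohort}.
#' @param cohort cohort data.frame.
#' @param factor,covariates,level as in \code{\link{fitEffect}}.
#' @return an \linkS4class{EffectMap} keyed by domain.
#' @export
cognitiveEffectMap <- function(scores, cohort, factor,
                               covariates = character(), level = 0.95) {
  domains <- setdiff(names(scores), "id")
  rows <- lapply(domains, function(d) {
    y <- scores[[d]]
    est <- fitEffect(y, cohort, factor, covariates, level)
    fx <- .as_model_numeric(cohort[[factor]], factor)
    use <- !is.na(y) & !is.na(fx)
    hcMean <- if (all(fx[use] %in% c(0, 1)))
      mean(y[use & fx == 0]) else mean(y[use])
    pe <- percentEffect(est, hcMean)
    data.frame(name = d, beta = est@beta, se = est@se, ci_low = est@ciLow,
               ci_high = est@ciHigh, t = est@t, p = est@p, p_adjusted = NA,
               percent = pe@percent, percent_ci_low = pe@percentCiLow,
               percent_ci_high = pe@percentCiHigh, n = est@n,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- bonferroni(tab$p, length(domains))
  new("EffectMap", table = tab, factor = factor)
}

#' Coarse-grain a unilateral parcellation to bilateral regions
#'
#' Sums left/right volumes per bilateral region according to a
#' user-supplied mapping.
#'
#' @param volumes matrix, unilateral regions x subjects.
#' @param mapping data.frame with columns \code{unilateral} (row names of
#'   \code{volumes}) and \code{bilateral} (target region).
#' @return matrix, bilateral regions x subjects.
#' @export
coarseGrainBilateral <- function(volumes, mapping) {
  if (!all(mapping$unilateral %in% rownames(volumes)))
    stop("mapping refers to unknown unilateral regions", call. = FALSE)
  regions <- unique(mapping$bilateral)
  out <- vapply(regions, function(r) {
    rows <- mapping$unilateral[mapping$bilateral == r]
    colSums(volumes[rows, , drop = FALSE])
  }, numeric(ncol(volumes)))
  t(out)
}
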
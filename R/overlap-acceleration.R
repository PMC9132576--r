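# Overlap of effect topographies and the Fieller acceleration ratio.

#' Pearson overlap between two effect maps
#'
#' Correlates the paired per-region (or per-domain) effect estimates of two
#' factors — the measure of how much the T2DM effect topography resembles
#' the aging topography. The two-sided p-value comes from the t transform
#' with n - 2 degrees of freedom.
#'
#' @param mapA,mapB \linkS4class{EffectMap}s (matched by entry name) or
#'   named numeric vectors.
#' @param field which column of the effect table to correlate (default
#'   \code{"beta"}; \code{"percent"} gives the percent-scaled variant).
#' @return an \linkS4class{OverlapResult}.
#' @export
overlapCorrelation <- function(mapA, mapB, field = "beta") {
  vec <- function(m) {
    if (is(m, "EffectMap")) setNames(m@table[[field]], m@table$name)
    else m
  }
  a <- vec(mapA); b <- vec(mapB)
  shared <- intersect(names(a), names(b))
  a <- a[shared]; b <- b[shared]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("fewer than 3 shared entries", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in an effect vector", call. = FALSE)
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  new("OverlapResult", r = unname(ct$estimate), p = ct$p.value,
      n = as.integer(length(a)))
}

#' Fieller confidence set for a ratio of coefficients
#'
#' For jointly Gaussian estimates (b1, b2) with covariance
#' \code{[[v11, v12], [v12, v22]]}, the level-\code{level} confidence set
#' for rho = b1/b2 is the solution set of the quadratic inequality
#' \deqn{(b_2^2 - t^{*2} v_{22})\rho^2 - 2 (b_1 b_2 - t^{*2} v_{12})\rho +
#'   (b_1^2 - t^{*2} v_{11}) \le 0,}
#' with t* the two-sided critical value of the t distribution on \code{df}
#' degrees of freedom. When the denominator is significantly nonzero
#' (\code{b2^2 > t*^2 v22}) the set is a bounded interval; otherwise it is
#' the whole line, a half line, or the complement of an interval
#' (\code{exclusive}), and \code{bounded} is FALSE.
#'
#' @param b1,b2 numerator and denominator coefficient estimates.
#' @param v11,v22,v12 their variances and covariance.
#' @param df residual degrees of freedom.
#' @param level confidence level (default 0.95).
#' @return a \linkS4class{RatioCI}.
#' @examples
#' fiellerRatioCI(2, 4, 0.01, 0.01, 0, df = 1000)
#' @export
fiellerRatioCI <- function(b1, b2, v11, v22, v12, df, level = 0.95) {
  if (v11 < 0 || v22 < 0) stop("variances must be >= 0", call. = FALSE)
  if (abs(v12) > sqrt(v11 * v22) + 1e-12)
    stop("covariance inconsistent with the variances", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (b2 == 0 && v22 == 0)
    stop("denominator is exactly zero: ratio undefined", call. = FALSE)
  ratio <- b1 / b2
  if (v11 == 0 && v22 == 0 && v12 == 0)
    return(new("RatioCI", ratio = ratio, ciLow = ratio, ciHigh = ratio,
               bounded = TRUE, exclusive = FALSE, level = level, df = df))
  tc <- qt(1 - (1 - level) / 2, df)
  A <- b2^2 - tc^2 * v22
  B <- b1 * b2 - tc^2 * v12
  C <- b1^2 - tc^2 * v11
  disc <- B^2 - A * C
  if (A > 0) {
    s <- sqrt(max(disc, 0))
    return(new("RatioCI", ratio = ratio, ciLow = (B - s) / A,
               ciHigh = (B + s) / A, bounded = TRUE, exclusive = FALSE,
               level = level, df = df))
  }
  if (A == 0) {
    if (B == 0)  # inequality is C <= 0 for all rho (C <= 0 holds here)
      return(new("RatioCI", ratio = ratio, ciLow = -Inf, ciHigh = Inf,
                 bounded = FALSE, exclusive = FALSE, level = level, df = df))
    bound <- C / (2 * B)
    lo <- if (B > 0) bound else -Inf
    hi <- if (B > 0) Inf else bound
    return(new("RatioCI", ratio = ratio, ciLow = lo, ciHigh = hi,
               bounded = FALSE, exclusive = FALSE, level = level, df = df))
  }
  # A < 0: parabola opens downward
  if (disc > 0) {
    roots <- sort(c((B - sqrt(disc)) / A, (B + sqrt(disc)) / A))
    return(new("RatioCI", ratio = ratio, ciLow = roots[1], ciHigh = roots[2],
               bounded = FALSE, exclusive = TRUE, level = level, df = df))
  }
  new("RatioCI", ratio = ratio, ciLow = -Inf, ciHigh = Inf, bounded = FALSE,
      exclusive = FALSE, level = level, df = df)
}

#' Acceleration of brain aging from disease duration
#'
#' Within T2DM subjects, fits one joint OLS model of whole-brain gray
#' matter volume on age and disease duration, and returns the Fieller
#' confidence set for the ratio of the duration slope to the age slope —
#' the acceleration factor (e.g. 0.26 means each year of disease adds 0.26
#' years of typical volumetric aging). Using a single joint fit provides
#' the coefficient covariance the Fieller set requires.
#'
#' @param volumes \link[SummarizedExperiment]{SummarizedExperiment} of
#'   regional volumes (whole-brain volume is the column sum, head-size
#'   normalized), or a numeric vector of whole-brain volumes.
#' @param cohort cohort data.frame with \code{age} and \code{duration}
#'   (ignored when \code{volumes} is a SummarizedExperiment).
#' @param durationColumn which duration column to regress on (default the
#'   derived \code{duration} from averaged onset reports).
#' @param level confidence level.
#' @return a \linkS4class{RatioCI}.
#' @export
accelerationEstimate <- function(volumes, cohort = NULL,
                                 durationColumn = "duration", level = 0.95) {
  if (is(volumes, "SummarizedExperiment")) {
    cohort <- as.data.frame(SummarizedExperiment::colData(volumes))
    V <- SummarizedExperiment::assay(volumes, "volume")
    if ("head_scaling" %in% names(cohort))
      V <- sweep(V, 2, cohort$head_scaling, "/")
    total <- colSums(V)
  } else total <- as.numeric(volumes)
  if (is.null(cohort)) stop("a cohort table is required", call. = FALSE)
  if ("t2dm" %in% names(cohort) && !all(cohort$t2dm)) {
    keep <- which(cohort$t2dm)
    cohort <- cohort[keep, , drop = FALSE]
    total <- total[keep]
  }
  dur <- cohort[[durationColumn]]
  ok <- !is.na(total) & !is.na(cohort$age) & !is.na(dur)
  total <- total[ok]; age <- cohort$age[ok]; dur <- dur[ok]
  if (length(total) < 4)
    stop("too few T2DM subjects with duration", call. = FALSE)
  if (abs(cor(age, dur)) > 0.999)
    stop("duration is collinear with age in this sample (|r| > 0.999); ",
         "the joint model cannot separate the two slopes", call. = FALSE)
  fit <- lm(total ~ age + dur)
  # suppress the "essentially perfect fit" note on noiseless data
  V2 <- suppressWarnings(vcov(fit))
  b <- coef(fit)
  fiellerRatioCI(b[["dur"]], b[["age"]], V2["dur", "dur"],
                 V2["age", "age"], V2["age", "dur"],
                 df = fit$df.residual, level = level)
}
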
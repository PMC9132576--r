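# Eligibility rules and derived variables applied before matching.

#' Label hypertension from measured blood pressure
#'
#' A subject is hypertensive when systolic pressure exceeds 140 mmHg or
#' diastolic pressure exceeds 90 mmHg (both strict inequalities). A missing
#' measurement yields a missing flag, not FALSE, so the subject drops out of
#' matching keys rather than being treated as normotensive.
#'
#' @param sbp,dbp systolic and diastolic blood pressure, mmHg (vectorized).
#' @return logical vector (NA where either measurement is missing).
#' @examples
#' labelHypertension(c(150, 140, 120), c(80, 90, 95))
#' @export
labelHypertension <- function(sbp, dbp) {
  ok <- !is.na(sbp) & !is.na(dbp)
  if (any(sbp[ok] <= 0) || any(dbp[ok] <= 0))
    stop("blood pressure values must be positive", call. = FALSE)
  out <- sbp > 140 | dbp > 90
  out[!ok] <- NA
  out
}

#' Average self-reported onset age over up to three visits
#'
#' Self-reported onset is noisy; averaging the per-visit reports improves
#' accuracy. All available (1-3) reports are used; if every report is
#' missing the result is missing.
#'
#' @param reports numeric vector of one subject's reports, or a matrix with
#'   one row per subject and one column per visit.
#' @return mean onset age (vector if a matrix was given), NA when all
#'   reports are missing.
#' @examples
#' averageOnsetAge(c(45, 47, 49))
#' averageOnsetAge(c(45, NA, 49))
#' @export
averageOnsetAge <- function(reports) {
  if (is.matrix(reports) || is.data.frame(reports)) {
    m <- as.matrix(reports)
    out <- rowMeans(m, na.rm = TRUE)
    out[rowSums(!is.na(m)) == 0] <- NA
    return(out)
  }
  if (all(is.na(reports))) return(NA_real_)
  mean(reports, na.rm = TRUE)
}

#' Compute derived cohort fields
#'
#' Adds/overwrites \code{hypertension} (from blood pressure),
#' \code{onset_age} (mean of the per-visit reports) and \code{duration}
#' (age minus mean onset; NA for non-T2DM subjects).
#'
#' @param cohort cohort data.frame.
#' @return the cohort with derived columns filled in.
#' @export
deriveCohortFields <- function(cohort) {
  cohort$hypertension <- labelHypertension(cohort$sbp, cohort$dbp)
  reps <- intersect(paste0("onset_report_", 1:3), names(cohort))
  if (length(reps)) {
    cohort$onset_age <- averageOnsetAge(cohort[, reps, drop = FALSE])
    cohort$onset_age[!cohort$t2dm] <- NA
    cohort$duration <- cohort$age - cohort$onset_age
  }
  cohort
}

#' Apply the eligibility rules
#'
#' Rules, in order of attribution (a subject counts against the first rule
#' it fails):
#' \enumerate{
#'   \item females who did not report menopause, or who report ongoing
#'     hormone therapy, are excluded (menopausal-transition confound; a
#'     missing menopause report counts as not reported);
#'   \item T2DM subjects with mean self-reported onset age below 40 years
#'     are excluded (minimizes type 1 diabetes contamination; onset exactly
#'     40 is retained, and a T2DM subject with no usable onset report is
#'     excluded because the rule cannot be verified).
#' }
#'
#' @param cohort cohort data.frame with derived fields (see
#'   \code{\link{deriveCohortFields}}).
#' @param onsetMin minimum mean onset age, years.
#' @return the eligible subset; attribute \code{"exclusions"} carries the
#'   named per-rule exclusion counts plus the retained count.
#' @export
applyEligibility <- function(cohort, onsetMin = 40) {
  failMeno <- cohort$sex == "female" &
    (is.na(cohort$menopause) | !cohort$menopause |
       (!is.na(cohort$hormone_therapy) & cohort$hormone_therapy))
  onset <- if ("onset_age" %in% names(cohort)) cohort$onset_age else
    averageOnsetAge(cohort[, intersect(paste0("onset_report_", 1:3),
                                       names(cohort)), drop = FALSE])
  failOnset <- cohort$t2dm & (is.na(onset) | onset < onsetMin)
  failOnset <- failOnset & !failMeno  # first-failure attribution
  keep <- !failMeno & !failOnset
  out <- cohort[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(
    menopause_or_hormone = sum(failMeno),
    onset_before_minimum = sum(failOnset),
    retained = sum(keep))
  out
}
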
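# Synthetic study populations with known ground truth. Every downstream
# stage (filtering, matching, effect maps, acceleration, overlap) is
# exercised against cohorts generated here, so the generative parameters are
# the planted truths that parameter-recovery tests check.

.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' The 45 bilateral gray-matter region labels
#'
#' Region names used throughout the package for the coarse-grained bilateral
#' parcellation of cortical and subcortical gray matter.
#'
#' @return character vector of length 45.
#' @export
regionNames45 <- function() {
  c("frontal_pole", "insular_cortex", "superior_frontal_gyrus",
    "middle_frontal_gyrus", "inferior_frontal_gyrus", "precentral_gyrus",
    "temporal_pole", "superior_temporal_gyrus", "middle_temporal_gyrus",
    "inferior_temporal_gyrus", "postcentral_gyrus",
    "superior_parietal_lobule", "supramarginal_gyrus", "angular_gyrus",
    "lateral_occipital_cortex", "intracalcarine_cortex",
    "frontal_medial_cortex", "supplementary_motor_cortex",
    "subcallosal_cortex", "paracingulate_gyrus", "anterior_cingulate_gyrus",
    "posterior_cingulate_gyrus", "precuneus_cortex", "cuneal_cortex",
    "orbitofrontal_cortex", "parahippocampal_gyrus", "lingual_gyrus",
    "temporal_fusiform_cortex", "occipital_fusiform_gyrus",
    "frontal_operculum_cortex", "central_opercular_cortex",
    "parietal_operculum_cortex", "planum_polare", "heschls_gyrus",
    "planum_temporale", "supracalcarine_cortex", "occipital_pole",
    "thalamus", "caudate", "putamen", "pallidum", "hippocampus", "amygdala",
    "ventral_striatum", "cerebellum")
}

#' Construct an AtrophySpec
#'
#' Defaults describe a plausible aging gray matter: region volumes from
#' about 1,100 mm^3 (ventral striatum) to 110,000 mm^3 (cerebellum), age
#' slopes between -0.2 and -1.0 percent of baseline per year (steepest in
#' the ventral striatum and Heschl's gyrus), a T2DM offset equivalent to
#' \code{t2dmOffsetScale} extra years of aging plus an orthogonal
#' perturbation, a duration slope of \code{acceleration} times the age
#' slope, and residual SD of 3 percent of baseline per region.
#'
#' @param regionNames,baseVolumes,ageSlopes,t2dmOffsetScale,perturbationMagnitude,acceleration,noiseSd,ageRef,seed
#'   see the slots of \linkS4class{AtrophySpec}.
#' @return a validated \linkS4class{AtrophySpec}.
#' @examples
#' sp <- atrophySpec(acceleration = 0.26)
#' @export
atrophySpec <- function(regionNames = regionNames45(), baseVolumes = NULL,
                        ageSlopes = NULL, t2dmOffsetScale = 6,
                        perturbationMagnitude = 4 / 3, acceleration = 0.26,
                        noiseSd = NULL, ageRef = 50, seed = 1L) {
  n <- length(regionNames)
  if (is.null(baseVolumes)) {
    # deterministic spread of plausible bilateral volumes, mm^3
    baseVolumes <- 4000 + 900 * ((seq_len(n) * 11) %% n)
    baseVolumes[regionNames == "cerebellum"] <- 110000
    baseVolumes[regionNames == "thalamus"] <- 16000
    baseVolumes[regionNames == "putamen"] <- 10200
    baseVolumes[regionNames == "caudate"] <- 7300
    baseVolumes[regionNames == "hippocampus"] <- 7800
    baseVolumes[regionNames == "amygdala"] <- 3200
    baseVolumes[regionNames == "pallidum"] <- 3600
    baseVolumes[regionNames == "ventral_striatum"] <- 1100
  }
  if (is.null(ageSlopes)) {
    slopePct <- 0.2 + 0.8 * ((seq_len(n) * 7) %% n) / max(1, n - 1)
    slopePct[regionNames == "ventral_striatum"] <- 1.0
    slopePct[regionNames == "heschls_gyrus"] <- 0.9
    ageSlopes <- -slopePct / 100 * baseVolumes
  }
  if (is.null(noiseSd)) noiseSd <- 0.03 * baseVolumes
  new("AtrophySpec", regionNames = regionNames, baseVolumes = baseVolumes,
      ageSlopes = ageSlopes, t2dmOffsetScale = t2dmOffsetScale,
      perturbationMagnitude = perturbationMagnitude,
      acceleration = acceleration, noiseSd = noiseSd, ageRef = ageRef,
      seed = as.numeric(seed))
}

#' The orthogonal perturbation of the T2DM offset vector
#'
#' The T2DM offset is \code{k * ageSlopes + perturbation}, where the
#' perturbation is a seeded Gaussian draw Gram-Schmidt orthogonalized
#' against both the constant vector and the centered age slopes, then scaled
#' to \code{m * k * ||centered ageSlopes||}. With this construction the
#' population Pearson correlation between the T2DM offset vector and the age
#' slopes is exactly \eqn{1/\sqrt{1+m^2}}.
#'
#' @param spec an \linkS4class{AtrophySpec}.
#' @return numeric perturbation vector (zeros when magnitude is 0).
#' @export
offsetPerturbation <- function(spec) {
  stopifnot(is(spec, "AtrophySpec"))
  m <- spec@perturbationMagnitude
  s <- spec@ageSlopes
  if (m == 0 || spec@t2dmOffsetScale == 0) return(numeric(length(s)))
  sc <- s - mean(s)
  z <- .with_seed(spec@seed + 1337, rnorm(length(s)))
  z <- z - mean(z)
  z <- z - sum(z * sc) / sum(sc * sc) * sc
  z / sqrt(sum(z^2)) * m * abs(spec@t2dmOffsetScale) * sqrt(sum(sc^2))
}

#' Population T2DM offset vector (ground truth)
#'
#' @param spec an \linkS4class{AtrophySpec}.
#' @return named numeric vector: \code{k * ageSlopes + perturbation}.
#' @export
t2dmOffsetTruth <- function(spec) {
  setNames(spec@t2dmOffsetScale * spec@ageSlopes + offsetPerturbation(spec),
           spec@regionNames)
}

#' Generate a synthetic cohort table
#'
#' Produces one row per subject with demographics (integer age, sex,
#' education, blood pressure with the derived hypertension flag, menopause
#' and hormone-therapy status for females, BMI, a head-size scaling factor),
#' T2DM status with a true onset age, three noisy per-visit onset reports
#' (integer-rounded Gaussian reporting error, SD 1 year, truncated at the
#' visit age), the derived mean onset age and duration, and medication
#' flags. Ground-truth columns \code{onset_truth} and \code{duration_truth}
#' are retained for parameter-recovery testing.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return data.frame, one row per subject, deterministic given the spec.
#' @examples
#' co <- generateCohort(cohortSpec(nSubjects = 50, seed = 3))
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- as.integer(spec@nSubjects)
  .with_seed(spec@seed, {
    age <- as.integer(round(runif(n, spec@ageRange[1], spec@ageRange[2])))
    sex <- ifelse(runif(n) < spec@sexRatio, "female", "male")
    education <- ifelse(runif(n) < spec@educationRate, "degree", "no_degree")
    htn <- runif(n) < spec@hypertensionRate
    # blood pressure drawn consistently with the hypertension label
    sbp <- ifelse(htn, runif(n, 141, 180), runif(n, 100, 140))
    dbp <- ifelse(htn, ifelse(runif(n) < 0.5, runif(n, 91, 110),
                              runif(n, 60, 90)),
                  runif(n, 60, 90))
    menopause <- ifelse(sex == "female", runif(n) < spec@menopauseRate, NA)
    hormone <- ifelse(sex == "female",
                      runif(n) < spec@hormoneTherapyRate, NA)
    t2dm <- runif(n) < spec@t2dmPrevalence

    # true duration: gamma-shaped (mean 8.5 y, SD 6 y), capped by the onset
    # floor and the maximum representable duration
    durTruth <- rep(0, n)
    if (any(t2dm)) {
      raw <- rgamma(n, shape = 2, scale = 4.25)
      cap <- pmin(age - spec@onsetMin, spec@durationMax)
      durTruth <- ifelse(t2dm, pmin(raw, pmax(cap, 0)), 0)
    }
    onsetTruth <- ifelse(t2dm, age - durTruth, NA)

    reports <- matrix(NA_real_, n, 3)
    for (v in 1:3) {
      r <- round(onsetTruth + rnorm(n, 0, 1))
      reports[, v] <- pmin(pmax(r, 0), age)
    }
    reports[!t2dm, ] <- NA

    medClass <- rep("none", n)
    if (any(t2dm)) {
      u <- runif(n)
      otherShare <- 0.31 * (1 - spec@metforminRate)
      medClass <- ifelse(!t2dm, "none",
                         ifelse(u < spec@metforminRate, "metformin_only",
                                ifelse(u < spec@metforminRate + otherShare,
                                       "other", "unmedicated")))
    }
    bmi <- round(ifelse(t2dm, rnorm(n, 29.5, 4), rnorm(n, 26.5, 4)), 1)
    headScaling <- pmax(rnorm(n, 1, 0.05), 0.8)

    out <- data.frame(
      id = sprintf("S%06d", seq_len(n)),
      age = age, sex = sex, education = education,
      sbp = round(sbp, 1), dbp = round(dbp, 1),
      menopause = menopause, hormone_therapy = hormone,
      t2dm = t2dm,
      onset_report_1 = reports[, 1], onset_report_2 = reports[, 2],
      onset_report_3 = reports[, 3],
      onset_truth = onsetTruth, duration_truth = durTruth,
      metformin = t2dm & medClass == "metformin_only",
      other_t2dm_medication = t2dm & medClass == "other",
      bmi = pmax(bmi, 15), head_scaling = headScaling,
      stringsAsFactors = FALSE)
    deriveCohortFields(out)
  })
}

#' Generate regional gray-matter volumes for a cohort
#'
#' Implements the linear generative model
#' \deqn{V_{ir} = h_i\,[b_r + s_r (a_i - a_0) + D_i (k s_r + e_r)
#'   + D_i \alpha s_r d_i + \epsilon_{ir}]}
#' with baseline \eqn{b_r}, age slope \eqn{s_r}, T2DM indicator \eqn{D_i},
#' offset scale \eqn{k}, orthogonal perturbation \eqn{e_r}, acceleration
#' \eqn{\alpha}, true duration \eqn{d_i}, head-size factor \eqn{h_i} and
#' heteroscedastic Gaussian noise \eqn{\epsilon_{ir}} with per-region SD.
#'
#' @param cohort data.frame from \code{\link{generateCohort}}.
#' @param spec an \linkS4class{AtrophySpec}.
#' @return \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{volume} (45 regions x subjects), region truths in \code{rowData}
#'   and the cohort in \code{colData}.
#' @export
generateRegionVolumes <- function(cohort, spec) {
  stopifnot(is(spec, "AtrophySpec"))
  validObject(spec)
  nR <- length(spec@regionNames)
  if (nR != 45L) stop("exactly 45 regions are required", call. = FALSE)
  n <- nrow(cohort)
  pert <- offsetPerturbation(spec)
  noiseSd <- rep(spec@noiseSd, length.out = nR)
  dur <- ifelse(cohort$t2dm, cohort$duration_truth, 0)
  dur[is.na(dur)] <- 0
  d <- as.numeric(cohort$t2dm)

  .with_seed(spec@seed, {
    eps <- matrix(rnorm(nR * n, 0, noiseSd), nrow = nR)  # recycles by region
    vol <- spec@baseVolumes +
      outer(spec@ageSlopes, cohort$age - spec@ageRef) +
      outer(spec@t2dmOffsetScale * spec@ageSlopes + pert, d) +
      spec@acceleration * outer(spec@ageSlopes, d * dur) +
      eps
    vol <- sweep(vol, 2, cohort$head_scaling, "*")
    dimnames(vol) <- list(spec@regionNames, cohort$id)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(volume = vol),
      rowData = S4Vectors::DataFrame(
        region = spec@regionNames, base_volume = spec@baseVolumes,
        age_slope = spec@ageSlopes,
        t2dm_offset = spec@t2dmOffsetScale * spec@ageSlopes + pert,
        noise_sd = noiseSd),
      colData = S4Vectors::DataFrame(cohort, row.names = cohort$id))
  })
}

#' Default specification of the five cognitive domains
#'
#' Planted per-domain truths: intercept 100 at age 50, age slopes and T2DM
#' offsets in percent of the intercept, residual SD in score units, and a
#' per-domain missingness rate (sample sizes vary by domain in real
#' cohorts). Higher scores mean better performance in every domain.
#'
#' @return data.frame with columns domain, intercept, age_slope_pct,
#'   t2dm_offset_pct, noise_sd, missing_rate.
#' @export
defaultCognitiveDomains <- function() {
  data.frame(
    domain = c("abstract_reasoning", "executive_function",
               "processing_speed", "reaction_time", "numeric_memory"),
    intercept = 100,
    age_slope_pct = c(-0.7, -1.9, -1.5, -0.8, -0.9),
    t2dm_offset_pct = c(-2.0, -13.1, -6.7, -1.0, -3.7),
    noise_sd = 50,
    missing_rate = 0.1,
    stringsAsFactors = FALSE)
}

#' Generate per-domain cognitive scores
#'
#' Each score is \code{intercept + slope*(age-50) + offset*T2DM + noise},
#' with slope and offset given as percent of the intercept, and a per-domain
#' missingness rate applied completely at random (missing scores are NA,
#' never zero).
#'
#' @param cohort data.frame from \code{\link{generateCohort}}.
#' @param domains data.frame as \code{\link{defaultCognitiveDomains}}.
#' @param seed integer seed.
#' @return data.frame with \code{id} and one column per domain.
#' @export
generateCognitiveScores <- function(cohort, domains = defaultCognitiveDomains(),
                                    seed = 1L) {
  need <- c("domain", "intercept", "age_slope_pct", "t2dm_offset_pct",
            "noise_sd", "missing_rate")
  if (!all(need %in% names(domains)))
    stop("domain spec must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(domains$domain))
    stop("unknown or duplicated domain label", call. = FALSE)
  n <- nrow(cohort)
  .with_seed(seed, {
    out <- data.frame(id = cohort$id, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(domains))) {
      d <- domains[i, ]
      score <- d$intercept +
        d$age_slope_pct / 100 * d$intercept * (cohort$age - 50) +
        d$t2dm_offset_pct / 100 * d$intercept * as.numeric(cohort$t2dm) +
        rnorm(n, 0, d$noise_sd)
      if (d$missing_rate > 0)
        score[runif(n) < d$missing_rate] <- NA
      out[[d$domain]] <- score
    }
    out
  })
}

#' Generate synthetic 4D fMRI time series for a group of subjects
#'
#' Every voxel carries a single band-limited sinusoid (frequency uniform in
#' the spec's band, random phase) of amplitude \code{baseAmplitude}, plus
#' white noise. Voxels inside a cluster definition have their sinusoid
#' amplitude multiplied by that cluster's factor for the subject's group.
#'
#' @param spec an \linkS4class{FmriSpec}.
#' @param groupAssignment character/factor vector, one group label per
#'   subject.
#' @return list of \linkS4class{FmriData}, one per subject; deterministic
#'   given the spec seed.
#' @export
generateFmri <- function(spec, groupAssignment) {
  stopifnot(is(spec, "FmriSpec"))
  validObject(spec)
  g <- as.character(groupAssignment)
  dims <- spec@gridShape
  nv <- prod(dims)
  tt <- (seq_len(spec@nTimepoints) - 1) * spec@tr
  mask <- array(TRUE, dim = dims)

  ampFor <- function(group) {
    a <- rep(spec@baseAmplitude, nv)
    for (cl in spec@clusters) {
      idx <- cl$voxels
      lin <- idx[, 1] + dims[1] * (idx[, 2] - 1) + dims[1] * dims[2] * (idx[, 3] - 1)
      mult <- cl$multipliers[[group]]
      if (is.null(mult)) mult <- 1
      a[lin] <- a[lin] * mult
    }
    a
  }

  .with_seed(spec@seed, {
    lapply(seq_along(g), function(i) {
      freqs <- runif(nv, spec@band[1], spec@band[2])
      phase <- runif(nv, 0, 2 * pi)
      # voxels x time; the phase vector recycles down the voxel dimension
      sig <- ampFor(g[i]) * sin(outer(2 * pi * freqs, tt) + phase)
      if (spec@noiseSd > 0)
        sig <- sig + matrix(rnorm(nv * length(tt), 0, spec@noiseSd), nv)
      new("FmriData", data = array(sig, dim = c(dims, spec@nTimepoints)),
          tr = spec@tr, mask = mask, voxelSize = spec@voxelSize)
    })
  })
}
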
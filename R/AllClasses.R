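#' @import methods
#' @importFrom stats coef complete.cases cor fft lm lm.fit median na.omit
#'   p.adjust pnorm pt qnorm qt quantile rbinom rgamma rnorm runif sd setNames
#'   var vcov cor.test confint rexp
#' @importFrom utils read.csv write.csv head modifyList
NULL

.assert <- function(ok, ...) if (!isTRUE(ok)) stop(..., call. = FALSE)

.is_prop <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

#' Parameters of a synthetic matched-cohort study population
#'
#' A \code{CohortSpec} fixes the demographic and disease structure of a
#' simulated cohort: sample size, age range, T2DM prevalence, the mix of sex,
#' education, hypertension, menopause and medication, and the onset/duration
#' distribution of the diabetic arm. Defaults mirror a population aged 50-80
#' with onset at 40 years or later and disease duration up to 31 years.
#'
#' @slot nSubjects number of subjects to generate.
#' @slot ageRange closed age interval in years.
#' @slot t2dmPrevalence proportion of subjects carrying a T2DM diagnosis.
#' @slot sexRatio proportion female.
#' @slot educationRate proportion holding a college degree.
#' @slot hypertensionRate target proportion labelled hypertensive.
#' @slot menopauseRate proportion of females reporting menopause.
#' @slot hormoneTherapyRate proportion of females on hormone therapy.
#' @slot onsetMin minimum true age of T2DM onset, years.
#' @slot durationMax maximum disease duration, years.
#' @slot metforminRate proportion of T2DM subjects on metformin only.
#' @slot seed integer seed; the generator is deterministic given the spec.
#' @export
setClass("CohortSpec", representation(
  nSubjects = "numeric", ageRange = "numeric", t2dmPrevalence = "numeric",
  sexRatio = "numeric", educationRate = "numeric", hypertensionRate = "numeric",
  menopauseRate = "numeric", hormoneTherapyRate = "numeric",
  onsetMin = "numeric", durationMax = "numeric", metforminRate = "numeric",
  seed = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (!(length(object@nSubjects) == 1L && object@nSubjects >= 1))
    msg <- c(msg, "nSubjects must be a positive integer")
  if (length(object@ageRange) != 2L || diff(object@ageRange) < 0)
    msg <- c(msg, "ageRange must be a nonempty closed interval")
  for (p in c("t2dmPrevalence", "sexRatio", "educationRate",
              "hypertensionRate", "menopauseRate", "hormoneTherapyRate",
              "metforminRate"))
    if (!.is_prop(slot(object, p))) msg <- c(msg, paste(p, "must be in [0,1]"))
  if (object@onsetMin > object@ageRange[2])
    msg <- c(msg, "onsetMin exceeds the oldest generable age")
  if (object@durationMax < 0) msg <- c(msg, "durationMax must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param nSubjects,ageRange,t2dmPrevalence,sexRatio,educationRate,hypertensionRate,menopauseRate,hormoneTherapyRate,onsetMin,durationMax,metforminRate,seed
#'   see the slots of \linkS4class{CohortSpec}.
#' @return a validated \linkS4class{CohortSpec}.
#' @examples
#' cohortSpec(nSubjects = 100, t2dmPrevalence = 0.5, seed = 1)
#' @export
cohortSpec <- function(nSubjects, ageRange = c(50, 80), t2dmPrevalence = 0.05,
                       sexRatio = 0.5, educationRate = 0.35,
                       hypertensionRate = 0.35, menopauseRate = 0.95,
                       hormoneTherapyRate = 0.05, onsetMin = 40,
                       durationMax = 31, metforminRate = 0.5, seed = 1L) {
  new("CohortSpec", nSubjects = nSubjects, ageRange = as.numeric(ageRange),
      t2dmPrevalence = t2dmPrevalence, sexRatio = sexRatio,
      educationRate = educationRate, hypertensionRate = hypertensionRate,
      menopauseRate = menopauseRate, hormoneTherapyRate = hormoneTherapyRate,
      onsetMin = onsetMin, durationMax = durationMax,
      metforminRate = metforminRate, seed = as.numeric(seed))
}

#' Generative model of regional gray-matter aging
#'
#' An \code{AtrophySpec} describes the linear volume trajectories of the 45
#' bilateral gray-matter regions: a baseline volume and a signed yearly age
#' slope per region, a T2DM offset proportional to the age-slope vector
#' (scale \code{t2dmOffsetScale}, optionally perturbed orthogonally so that
#' the population overlap correlation has the closed form
#' \eqn{1/\sqrt{1+m^2}}), a disease-duration slope equal to
#' \code{acceleration} times the age slope, and heteroscedastic Gaussian
#' residual noise.
#'
#' @slot regionNames exactly 45 region labels.
#' @slot baseVolumes mean volume per region at \code{ageRef}, mm^3, positive.
#' @slot ageSlopes volume change per year of age, mm^3 (signed).
#' @slot t2dmOffsetScale scalar k: T2DM offset = k * ageSlopes (+ perturbation).
#' @slot perturbationMagnitude relative magnitude m of the orthogonal
#'   perturbation (0 disables it); the perturbation is Gram-Schmidt
#'   orthogonalized against the centered age slopes and scaled to
#'   m * ||k * centered ageSlopes||.
#' @slot acceleration scalar alpha: duration slope = alpha * age slope.
#' @slot noiseSd per-region residual SD, mm^3 (recycled if scalar).
#' @slot ageRef reference age at which baseVolumes apply, years.
#' @slot seed seed for the perturbation draw.
#' @export
setClass("AtrophySpec", representation(
  regionNames = "character", baseVolumes = "numeric", ageSlopes = "numeric",
  t2dmOffsetScale = "numeric", perturbationMagnitude = "numeric",
  acceleration = "numeric", noiseSd = "numeric", ageRef = "numeric",
  seed = "numeric"))

setValidity("AtrophySpec", function(object) {
  n <- length(object@regionNames)
  msg <- character()
  if (n != 45L) msg <- c(msg, "exactly 45 regions are required")
  if (length(object@baseVolumes) != n || any(object@baseVolumes <= 0))
    msg <- c(msg, "baseVolumes must be positive, one per region")
  if (length(object@ageSlopes) != n)
    msg <- c(msg, "ageSlopes must have one value per region")
  if (!length(object@noiseSd) %in% c(1L, n) || any(object@noiseSd < 0))
    msg <- c(msg, "noiseSd must be nonnegative (scalar or per-region)")
  if (object@perturbationMagnitude < 0)
    msg <- c(msg, "perturbationMagnitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Parameters of a synthetic band-limited fMRI acquisition
#'
#' @slot gridShape three positive integers, the spatial grid.
#' @slot nTimepoints number of volumes in the time series.
#' @slot tr repetition time, seconds.
#' @slot band frequency interval of the oscillatory signal, Hz; must lie
#'   within (0, Nyquist).
#' @slot clusters list of cluster definitions, each a list with a
#'   \code{voxels} integer matrix (n x 3 coordinates) and a named numeric
#'   \code{multipliers} vector of per-group amplitude factors.
#' @slot noiseSd white-noise SD added to every voxel.
#' @slot baseAmplitude amplitude of the common oscillatory component.
#' @slot voxelSize voxel edge lengths, mm.
#' @slot seed integer seed.
#' @export
setClass("FmriSpec", representation(
  gridShape = "integer", nTimepoints = "integer", tr = "numeric",
  band = "numeric", clusters = "list", noiseSd = "numeric",
  baseAmplitude = "numeric", voxelSize = "numeric", seed = "numeric"))

setValidity("FmriSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1))
    msg <- c(msg, "gridShape must be three positive integers")
  if (object@tr <= 0) msg <- c(msg, "tr must be > 0")
  nyq <- 1 / (2 * object@tr)
  if (length(object@band) != 2L || object@band[1] <= 0 ||
      object@band[2] > nyq || diff(object@band) < 0)
    msg <- c(msg, "band must lie within (0, Nyquist]")
  if (object@nTimepoints < 16L) msg <- c(msg, "nTimepoints must be >= 16")
  for (cl in object@clusters) {
    v <- cl$voxels
    if (!is.matrix(v) || ncol(v) != 3L ||
        any(v < 1) || any(t(v) > object@gridShape))
      msg <- c(msg, "cluster voxel sets must be n x 3 coordinates inside the grid")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an FmriSpec
#'
#' @param gridShape,nTimepoints,tr,band,clusters,noiseSd,baseAmplitude,voxelSize,seed
#'   see the slots of \linkS4class{FmriSpec}.
#' @return a validated \linkS4class{FmriSpec}.
#' @export
fmriSpec <- function(gridShape = c(20L, 20L, 20L), nTimepoints = 200L,
                     tr = 1, band = c(0.01, 0.08), clusters = list(),
                     noiseSd = 1, baseAmplitude = 1, voxelSize = c(2, 2, 2),
                     seed = 1L) {
  new("FmriSpec", gridShape = as.integer(gridShape),
      nTimepoints = as.integer(nTimepoints), tr = tr, band = band,
      clusters = clusters, noiseSd = noiseSd, baseAmplitude = baseAmplitude,
      voxelSize = as.numeric(voxelSize), seed = as.numeric(seed))
}

#' Matching specification: exact and binned (coarse) keys
#'
#' @slot exactKeys covariates matched exactly (equal values required).
#' @slot binnedKeys data.frame with columns \code{key}, \code{width},
#'   \code{origin}: covariates matched coarsely on half-open bins
#'   \code{[origin + j*width, origin + (j+1)*width)}.
#' @slot seed seed for optional randomized tie-breaking (pairing is by
#'   sorted id and deterministic unless randomization is requested).
#' @export
setClass("MatchSpec", representation(
  exactKeys = "character", binnedKeys = "data.frame", seed = "numeric"))

setValidity("MatchSpec", function(object) {
  msg <- character()
  bk <- object@binnedKeys
  if (nrow(bk) &&
      !all(c("key", "width", "origin") %in% names(bk)))
    msg <- c(msg, "binnedKeys needs columns key, width, origin")
  if (nrow(bk) && any(bk$width <= 0))
    msg <- c(msg, "bin widths must be > 0")
  if (nrow(bk) && any(bk$key %in% object@exactKeys))
    msg <- c(msg, "exact and binned key lists must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct a MatchSpec
#'
#' @param exactKeys character vector of exact-match covariates.
#' @param binnedKeys data.frame(key, width, origin) of coarse keys, or NULL.
#' @param seed integer seed.
#' @return a validated \linkS4class{MatchSpec}.
#' @examples
#' matchSpec(c("age", "sex", "education", "hypertension"))
#' @export
matchSpec <- function(exactKeys, binnedKeys = NULL, seed = 1L) {
  if (is.null(binnedKeys))
    binnedKeys <- data.frame(key = character(), width = numeric(),
                             origin = numeric())
  new("MatchSpec", exactKeys = exactKeys, binnedKeys = binnedKeys,
      seed = as.numeric(seed))
}

#' One-to-one matched case/control pairs
#'
#' @slot pairs data.frame with columns \code{case}, \code{control},
#'   \code{stratum}.
#' @slot unmatchedCases ids of cases left without a control.
#' @slot droppedMissing named counts of subjects excluded for missing keys.
#' @slot spec the \linkS4class{MatchSpec} used.
#' @export
setClass("MatchedPairs", representation(
  pairs = "data.frame", unmatchedCases = "character",
  droppedMissing = "numeric", spec = "MatchSpec"))

setValidity("MatchedPairs", function(object) {
  ids <- c(object@pairs$case, object@pairs$control)
  if (anyDuplicated(ids)) "an id appears in more than one pair" else TRUE
})

#' A single regression effect estimate
#'
#' Ordinary-least-squares coefficient for one factor, with t-based 95%
#' confidence bounds and the two-sided p-value.
#'
#' @slot beta,se point estimate and standard error, outcome units per factor
#'   unit.
#' @slot ciLow,ciHigh confidence bounds at \code{level}.
#' @slot t,p t statistic and two-sided p-value.
#' @slot n rows used; \code{df} residual degrees of freedom.
#' @slot nDropped rows dropped for missing model variables.
#' @slot factor,covariates model terms.
#' @slot level confidence level.
#' @export
setClass("EffectEstimate", representation(
  beta = "numeric", se = "numeric", ciLow = "numeric", ciHigh = "numeric",
  t = "numeric", p = "numeric", n = "integer", df = "numeric",
  nDropped = "integer", factor = "character", covariates = "character",
  level = "numeric"))

setValidity("EffectEstimate", function(object) {
  msg <- character()
  if (!(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    msg <- c(msg, "beta must lie inside its confidence interval")
  if (object@p < 0 || object@p > 1) msg <- c(msg, "p must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' A factor effect expressed as percent of the healthy-control mean
#'
#' @slot percent,percentCiLow,percentCiHigh effect and CI, percent of
#'   \code{hcMean}.
#' @slot hcMean the control-arm mean outcome used as denominator.
#' @export
setClass("PercentEffect", representation(
  percent = "numeric", percentCiLow = "numeric", percentCiHigh = "numeric",
  hcMean = "numeric"))

#' Per-region (or per-domain) effect map for one factor
#'
#' @slot table data.frame with one row per entry: \code{name}, \code{beta},
#'   \code{se}, \code{ci_low}, \code{ci_high}, \code{t}, \code{p},
#'   \code{p_adjusted}, \code{percent}, \code{percent_ci_low},
#'   \code{percent_ci_high}, \code{n}.
#' @slot factor the modelled factor.
#' @export
setClass("EffectMap", representation(table = "data.frame", factor = "character"))

setValidity("EffectMap", function(object) {
  if (anyDuplicated(object@table$name)) "entry names must be unique" else TRUE
})

#' 4D voxel time series with acquisition metadata
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot tr repetition time, seconds.
#' @slot mask 3D logical/0-1 array matching the spatial grid.
#' @slot voxelSize voxel edge lengths, mm.
#' @export
setClass("FmriData", representation(
  data = "array", tr = "numeric", mask = "array", voxelSize = "numeric"))

setValidity("FmriData", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4L) msg <- c(msg, "data must be a 4D array")
  else {
    if (!identical(dim(object@mask), d[1:3]))
      msg <- c(msg, "mask shape must equal the spatial shape")
    if (d[4] < 16L) msg <- c(msg, "at least 16 timepoints are required")
  }
  if (object@tr <= 0) msg <- c(msg, "tr must be > 0")
  if (length(msg)) msg else TRUE
})

#' Voxelwise amplitude-of-low-frequency-fluctuation map
#'
#' @slot values 3D array; NA outside the mask.
#' @slot normalized TRUE once divided by the in-mask global mean.
#' @slot band analysis frequency band, Hz.
#' @slot mask 3D logical array.
#' @slot voxelSize voxel edge lengths, mm.
#' @export
setClass("ALFFMap", representation(
  values = "array", normalized = "logical", band = "numeric",
  mask = "array", voxelSize = "numeric"))

setValidity("ALFFMap", function(object) {
  if (isTRUE(object@normalized)) {
    m <- mean(object@values[object@mask > 0])
    if (abs(m - 1) > 1e-6)
      return("normalized map must have in-mask mean 1 (tolerance 1e-6)")
  }
  TRUE
})

#' Voxelwise z map from group statistics
#'
#' @slot values 3D array of signed z scores (NA outside mask).
#' @slot mask 3D logical array.
#' @slot df residual degrees of freedom of the underlying t statistics.
#' @export
setClass("ZMap", representation(values = "array", mask = "array", df = "numeric"))

#' FDR/extent-thresholded significant clusters
#'
#' @slot clusters data.frame: \code{id}, \code{size}, \code{peak_x},
#'   \code{peak_y}, \code{peak_z}, \code{peak_value}, \code{sign}.
#' @slot voxels list of n x 3 coordinate matrices, one per cluster.
#' @slot thresholdQ FDR level applied.
#' @slot minSize minimum cluster extent, voxels.
#' @export
setClass("ClusterSet", representation(
  clusters = "data.frame", voxels = "list", thresholdQ = "numeric",
  minSize = "numeric"))

setValidity("ClusterSet", function(object) {
  if (nrow(object@clusters) && any(object@clusters$size < object@minSize))
    "every retained cluster must reach the minimum size" else TRUE
})

#' Pearson overlap between two effect maps
#'
#' @slot r correlation; \code{p} two-sided p from the t transform with
#'   \code{n}-2 df; \code{n} shared entries.
#' @export
setClass("OverlapResult", representation(r = "numeric", p = "numeric", n = "integer"))

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "|r| must be <= 1")
  if (object@n < 3L) msg <- c(msg, "at least 3 paired entries are required")
  if (length(msg)) msg else TRUE
})

#' Fieller confidence set for a ratio of regression coefficients
#'
#' @slot ratio point estimate b1/b2 (duration slope over age slope for the
#'   acceleration factor).
#' @slot ciLow,ciHigh bounds of the confidence set when it is an interval;
#'   \code{-Inf}/\code{Inf} or the excluded interval's bounds otherwise.
#' @slot bounded TRUE when the set is a finite interval containing the ratio.
#' @slot exclusive TRUE when the set is the complement of (ciLow, ciHigh).
#' @slot level confidence level; \code{df} degrees of freedom used.
#' @export
setClass("RatioCI", representation(
  ratio = "numeric", ciLow = "numeric", ciHigh = "numeric",
  bounded = "logical", exclusive = "logical", level = "numeric",
  df = "numeric"))

setValidity("RatioCI", function(object) {
  if (isTRUE(object@bounded) &&
      !(object@ciLow <= object@ratio && object@ratio <= object@ciHigh))
    "a bounded Fieller set must contain the point ratio" else TRUE
})

#' Pooled random-effects meta-analytic result for one domain
#'
#' @slot domain label; \code{k} number of studies.
#' @slot dPooled pooled standardized mean difference.
#' @slot ciLow,ciHigh normal-based 95% bounds.
#' @slot tau2 between-study variance; \code{q} Cochran's Q; \code{i2} I^2 in
#'   percent.
#' @slot p two-sided p; \code{pBonferroni} adjusted across domains.
#' @slot method tau^2 estimator used ("REML" or "DL").
#' @export
setClass("MetaResult", representation(
  domain = "character", k = "integer", dPooled = "numeric", ciLow = "numeric",
  ciHigh = "numeric", tau2 = "numeric", q = "numeric", i2 = "numeric",
  p = "numeric", pBonferroni = "numeric", method = "character"))

setValidity("MetaResult", function(object) {
  msg <- character()
  if (object@i2 < 0 || object@i2 > 100) msg <- c(msg, "I^2 must be in [0,100]")
  if (!(object@ciLow <= object@dPooled && object@dPooled <= object@ciHigh))
    msg <- c(msg, "pooled estimate must lie inside its CI")
  if (object@k < 2L) msg <- c(msg, "at least 2 studies are required")
  if (length(msg)) msg else TRUE
})
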
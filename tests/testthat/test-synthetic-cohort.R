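test_that("cohort generation is deterministic and honors the spec", {
  sp <- cohortSpec(nSubjects = 1000, t2dmPrevalence = 0.3, seed = 7)
  a <- generateCohort(sp)
  b <- generateCohort(sp)
  expect_identical(a, b)
  expect_false(anyDuplicated(a$id) > 0)
  expect_true(all(a$age >= 50 & a$age <= 80))
  # onset truths respect the type-1-diabetes floor
  expect_gte(min(a$onset_truth[a$t2dm]), 40)
  expect_true(all(a$duration_truth[a$t2dm] <= 31 + 1e-12))
  # boundary of the prevalence proportion
  none <- generateCohort(cohortSpec(nSubjects = 200, t2dmPrevalence = 0,
                                    seed = 1))
  expect_identical(sum(none$t2dm), 0L)
  expect_error(cohortSpec(nSubjects = 10, t2dmPrevalence = 1.2),
               "\\[0,1\\]")
  expect_error(cohortSpec(nSubjects = 10, ageRange = c(70, 60)), "ageRange")
})

test_that("noiseless volumes are exactly linear in age with recoverable slopes", {
  co <- generateCohort(cohortSpec(nSubjects = 300, t2dmPrevalence = 0,
                                  seed = 3))
  co$head_scaling <- 1
  sp <- atrophySpec(t2dmOffsetScale = 0, perturbationMagnitude = 0,
                    acceleration = 0, noiseSd = 0, seed = 2)
  se <- generateRegionVolumes(co, sp)
  V <- SummarizedExperiment::assay(se, "volume")
  for (r in c(1, 20, 45)) {
    fit <- lm(V[r, ] ~ co$age)
    expect_equal(unname(coef(fit)[2]), sp@ageSlopes[r], tolerance = 1e-10)
  }
  # equal covariates + zero noise => identical volume rows
  co2 <- co[c(1, 1), ]
  co2$id <- c("X1", "X2")
  se2 <- generateRegionVolumes(co2, sp)
  V2 <- SummarizedExperiment::assay(se2, "volume")
  expect_identical(unname(V2[, 1]), unname(V2[, 2]))
  expect_error(generateRegionVolumes(co, atrophySpec(regionNames = letters)),
               "45")
})

test_that("planted T2DM offset and duration slope are recovered from volumes", {
  co <- generateCohort(cohortSpec(nSubjects = 1500, t2dmPrevalence = 0.5,
                                  seed = 9))
  sp <- atrophySpec(t2dmOffsetScale = 6, perturbationMagnitude = 0,
                    acceleration = 0, noiseSd = 0, seed = 5)
  se <- generateRegionVolumes(co, sp)
  em <- regionalEffectMap(se, "t2dm", covariates = "age")
  truth <- t2dmOffsetTruth(sp)
  expect_equal(effectTable(em)$beta, unname(truth[effectTable(em)$name]),
               tolerance = 1e-6)
})

test_that("the offset perturbation realizes the closed-form overlap estimand", {
  for (m in c(0, 1, 4 / 3)) {
    sp <- atrophySpec(perturbationMagnitude = m, seed = 21)
    pert <- offsetPerturbation(sp)
    s <- sp@ageSlopes
    sc <- s - mean(s)
    if (m == 0) expect_identical(pert, numeric(45))
    else {
      expect_lt(abs(sum(pert * sc)), 1e-6)         # orthogonal to slopes
      expect_lt(abs(sum(pert)), 1e-6)              # centered
      expect_equal(sqrt(sum(pert^2)),
                   m * sp@t2dmOffsetScale * sqrt(sum(sc^2)),
                   tolerance = 1e-10)
    }
    expect_equal(cor(t2dmOffsetTruth(sp), s), 1 / sqrt(1 + m^2),
                 tolerance = 1e-10)
  }
})

test_that("cognitive scores carry planted truths and calibrated missingness", {
  co <- generateCohort(cohortSpec(nSubjects = 4000, t2dmPrevalence = 0.5,
                                  seed = 4))
  flat <- data.frame(domain = "flat", intercept = 7, age_slope_pct = 0,
                     t2dm_offset_pct = 0, noise_sd = 0, missing_rate = 0)
  sc <- generateCognitiveScores(co, flat, seed = 1)
  expect_true(all(sc$flat == 7))
  # missingness within binomial 99% bounds
  miss <- data.frame(domain = "m", intercept = 100, age_slope_pct = 0,
                     t2dm_offset_pct = 0, noise_sd = 1, missing_rate = 0.1)
  sm <- generateCognitiveScores(co, miss, seed = 2)
  n <- nrow(co)
  bounds <- qbinom(c(0.005, 0.995), n, 0.1) / n
  expect_gte(mean(is.na(sm$m)), bounds[1])
  expect_lte(mean(is.na(sm$m)), bounds[2])
  expect_error(generateCognitiveScores(co, flat[, -1]), "columns")
})

test_that("planted executive-function deficit is recovered as a percent effect", {
  co <- generateCohort(cohortSpec(nSubjects = 6000, t2dmPrevalence = 0.5,
                                  seed = 8))
  dom <- data.frame(domain = "executive_function", intercept = 100,
                    age_slope_pct = 0, t2dm_offset_pct = -13.1,
                    noise_sd = 10, missing_rate = 0)
  sc <- generateCognitiveScores(co, dom, seed = 3)
  em <- cognitiveEffectMap(sc, co, "t2dm")
  expect_equal(effectTable(em)$percent, -13.1, tolerance = 0.05)
})

test_that("fMRI generator is deterministic, band-limited and amplitude-linear", {
  cl <- list(list(voxels = as.matrix(expand.grid(2:4, 2:4, 2:4)),
                  multipliers = c(case = 2, control = 1)))
  sp <- fmriSpec(gridShape = c(8, 8, 8), nTimepoints = 100, noiseSd = 0,
                 clusters = cl, seed = 6)
  f1 <- generateFmri(sp, c("case", "control"))
  f2 <- generateFmri(sp, c("case", "control"))
  expect_identical(f1[[1]]@data, f2[[1]]@data)
  # same seed, same draws, multiplier 2 vs 1: amplitude exactly doubled
  caseRun <- generateFmri(sp, "case")[[1]]
  ctrlRun <- generateFmri(sp, "control")[[1]]
  aCase <- bandpassAmplitude(caseRun@data[3, 3, 3, ], sp@tr, sp@band)
  aCtrl <- bandpassAmplitude(ctrlRun@data[3, 3, 3, ], sp@tr, sp@band)
  expect_equal(aCase / aCtrl, 2, tolerance = 1e-10)
  # out-of-grid cluster rejected
  bad <- list(list(voxels = matrix(c(9, 1, 1), 1), multipliers = c(a = 1)))
  expect_error(fmriSpec(gridShape = c(8, 8, 8), clusters = bad), "grid")
})
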
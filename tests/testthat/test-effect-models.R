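test_that("noiseless fits recover coefficients with degenerate uncertainty", {
  co <- data.frame(id = 1:50, age = seq(50, 80, length.out = 50))
  est <- fitEffect(2 * co$age, co, "age")
  expect_equal(est@beta, 2, tolerance = 1e-10)
  expect_lt(est@ciHigh - est@ciLow, 1e-8)
  expect_lt(est@p, 1e-12)
})

test_that("degenerate designs raise informative errors", {
  co <- data.frame(id = 1:30, grp = rep(1, 30), age = rnorm(30, 60))
  expect_error(fitEffect(rnorm(30), co, "grp"), "collinear")
  expect_error(fitEffect(rnorm(30), co, "height"), "not in cohort")
  expect_error(fitEffect(rnorm(3), co[1:3, ], "age"), "too few")
})

test_that("binary-factor fits agree with the pooled two-sample t test", {
  set.seed(11)
  for (i in 1:5) {
    g <- rep(c(0, 1), times = c(40, 35))
    y <- 10 + 2 * g + rnorm(75)
    co <- data.frame(id = seq_along(g), grp = g)
    est <- fitEffect(y, co, "grp")
    tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
    expect_equal(est@beta, unname(diff(tapply(y, g, mean))), tolerance = 1e-10)
    expect_equal(est@t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(est@p, tt$p.value, tolerance = 1e-10)
    expect_equal(c(est@ciLow, est@ciHigh), as.numeric(tt$conf.int),
                 tolerance = 1e-10)
  }
})

test_that("planted group offsets are recovered at scale", {
  set.seed(2)
  g <- rbinom(5000, 1, 0.5)
  y <- 100 - 5 * g + rnorm(5000, 0, 3)
  est <- fitEffect(y, data.frame(grp = g), "grp")
  expect_equal(est@beta, -5, tolerance = 0.3)
  pe <- percentEffect(est, mean(y[g == 0]))
  expect_equal(pe@percent, -5, tolerance = 0.3)
})

test_that("percent effects scale the coefficient and CI by the control mean", {
  est <- new("EffectEstimate", beta = -0.5, se = 0.1, ciLow = -0.7,
             ciHigh = -0.3, t = -5, p = 1e-4, n = 100L, df = 98,
             nDropped = 0L, factor = "t2dm", covariates = character(),
             level = 0.95)
  pe <- percentEffect(est, 10)
  expect_equal(pe@percent, -5)
  expect_equal(c(pe@percentCiLow, pe@percentCiHigh), c(-7, -3))
  # scale invariance: outcome and mean in other units
  est2 <- est
  for (s in c("beta", "se", "ciLow", "ciHigh")) slot(est2, s) <- slot(est, s) * 3
  expect_equal(percentEffect(est2, 30)@percent, pe@percent)
  expect_error(percentEffect(est, 0), "zero")
})

test_that("Bonferroni uses the explicit family size and caps at one", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 5), 1)
  expect_equal(bonferroni(c(0.2, 0.04), 1), c(0.2, 0.04))
})

test_that("BH step-up matches the hand formula and p.adjust", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhFdr(0.3), 0.3)
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(2:60, 1))^sample(1:3, 1)
    expect_equal(bhFdr(p), bhByHand(p))
    expect_equal(bhFdr(p), p.adjust(p, "BH"))
    expect_true(all(bhFdr(p) >= p))
    expect_true(all(bonferroni(p) >= bhFdr(p)))
  }
})

test_that("regional effect maps recover planted offsets and are scale invariant", {
  co <- generateCohort(cohortSpec(nSubjects = 800, t2dmPrevalence = 0.5,
                                  seed = 14))
  sp <- atrophySpec(t2dmOffsetScale = 6, perturbationMagnitude = 0.5,
                    acceleration = 0, noiseSd = 0, seed = 3)
  se <- generateRegionVolumes(co, sp)
  em <- regionalEffectMap(se, "t2dm", covariates = "age")
  tab <- effectTable(em)
  truth <- t2dmOffsetTruth(sp)
  expect_gt(cor(tab$beta, unname(truth[tab$name])), 0.99)
  expect_identical(nrow(tab), 45L)
  # doubling all volumes leaves the percent map unchanged
  V <- SummarizedExperiment::assay(se, "volume")
  em2 <- regionalEffectMap(2 * V, "t2dm", covariates = "age",
                           cohort = as.data.frame(SummarizedExperiment::colData(se)))
  expect_equal(effectTable(em2)$percent, tab$percent, tolerance = 1e-6)
  # multi-response fit agrees with per-region fitEffect
  cohort <- as.data.frame(SummarizedExperiment::colData(se))
  Vn <- sweep(V, 2, cohort$head_scaling, "/")
  for (r in c(3, 44)) {
    single <- fitEffect(Vn[r, ], cohort, "t2dm", "age")
    expect_equal(tab$beta[tab$name == rownames(V)[r]], single@beta,
                 tolerance = 1e-10)
    expect_equal(tab$se[tab$name == rownames(V)[r]], single@se,
                 tolerance = 1e-10)
  }
})

test_that("null regional maps keep Bonferroni-significant fractions at bay", {
  sig <- 0
  total <- 0
  for (i in 1:12) {
    co <- generateCohort(cohortSpec(nSubjects = 250, t2dmPrevalence = 0.5,
                                    seed = 100 + i))
    sp <- atrophySpec(t2dmOffsetScale = 0, perturbationMagnitude = 0,
                      acceleration = 0, seed = i)
    se <- generateRegionVolumes(co, sp)
    tab <- effectTable(regionalEffectMap(se, "t2dm", covariates = "age"))
    sig <- sig + sum(tab$p_adjusted < 0.05)
    total <- total + nrow(tab)
  }
  expect_lte(sig / total, 0.05)
})

test_that("bilateral coarse-graining sums left and right volumes", {
  V <- matrix(1:8, 4, 2,
              dimnames = list(c("L_a", "R_a", "L_b", "R_b"), c("s1", "s2")))
  mapng <- data.frame(unilateral = c("L_a", "R_a", "L_b", "R_b"),
                      bilateral = c("a", "a", "b", "b"))
  out <- coarseGrainBilateral(V, mapng)
  expect_equal(out["a", ], c(s1 = 3, s2 = 11))
  expect_equal(out["b", ], c(s1 = 7, s2 = 15))
  expect_error(coarseGrainBilateral(V, data.frame(unilateral = "x",
                                                  bilateral = "a")),
               "unknown")
})
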
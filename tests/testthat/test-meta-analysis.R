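test_that("Cohen's d and its variance follow the pooled-SD formulas", {
  e <- cohensD(1, 1, 10, 0, 1, 10)
  expect_equal(e$d, 1)
  expect_equal(cohensD(5, 2, 30, 5, 3, 40)$d, 0)
  # hand-computed: pooled SD = sqrt(10), d = -2/sqrt(10), var formula
  e2 <- cohensD(10, 2, 20, 12, 4, 20)
  expect_equal(e2$d, -2 / sqrt(10), tolerance = 1e-12)
  expect_equal(e2$d, -0.6325, tolerance = 1e-4)
  expect_equal(e2$variance, 40 / 400 + e2$d^2 / 80, tolerance = 1e-12)
  expect_equal(e2$variance, 0.1050, tolerance = 1e-4)
  # direction harmonization: lower-is-better domains are sign flipped
  e3 <- cohensD(10, 2, 20, 12, 4, 20, higherBetter = FALSE)
  expect_equal(e3$d, -e2$d)
  expect_error(cohensD(1, 0, 10, 0, 1, 10), "SDs")
  expect_error(cohensD(1, 1, 1, 0, 1, 10), ">= 2")
})

test_that("DerSimonian-Laird pooling reproduces hand-computed toy values", {
  mr <- randomEffectsPool(c(0.2, 0.4, 0.6), rep(0.04, 3), method = "DL")
  expect_equal(mr@dPooled, 0.4, tolerance = 1e-12)
  expect_equal(mr@q, 2.0, tolerance = 1e-12)
  expect_equal(mr@i2, 0)
  expect_equal(mr@tau2, 0, tolerance = 1e-12)
  # homogeneous studies: pooled equals the common effect with no heterogeneity
  hom <- randomEffectsPool(rep(0.3, 4), rep(0.05, 4), method = "DL")
  expect_equal(hom@dPooled, 0.3, tolerance = 1e-12)
  expect_equal(hom@q, 0, tolerance = 1e-12)
  expect_equal(hom@i2, 0)
  expect_error(randomEffectsPool(0.3, 0.05), "at least 2")
})

test_that("with tau2 = 0 random-effects pooling equals inverse-variance fixed effect", {
  d <- c(0.35, 0.3, 0.32, 0.28)
  v <- c(0.02, 0.05, 0.03, 0.04)
  mr <- randomEffectsPool(d, v, method = "DL")
  if (mr@tau2 == 0)
    expect_equal(mr@dPooled, sum(d / v) / sum(1 / v), tolerance = 1e-10)
  # pooled estimate lies within the range of the inputs (positive weights)
  for (m in c("REML", "DL")) {
    mr2 <- randomEffectsPool(c(-0.6, -0.2, 0.1), c(0.02, 0.08, 0.05),
                             method = m)
    expect_gte(mr2@dPooled, -0.6)
    expect_lte(mr2@dPooled, 0.1)
    # I2 recomputation matches the (Q - df)/Q formula exactly
    expect_equal(mr2@i2, max(0, (mr2@q - 2) / mr2@q) * 100, tolerance = 1e-12)
  }
})

test_that("random-effects CIs cover the true effect at near-nominal rates", {
  set.seed(41)
  hits <- 0
  reps <- 150
  for (i in seq_len(reps)) {
    k <- 30
    v <- runif(k, 0.02, 0.1)
    d <- rnorm(k, -0.4, sqrt(0.02 + v))
    mr <- randomEffectsPool(d, v, method = "DL")
    hits <- hits + (mr@ciLow <= -0.4 && -0.4 <= mr@ciHigh)
  }
  expect_gt(hits / reps, 0.88)
  expect_lte(hits / reps, 1)
})

mkStudies <- function(domains, kPer, dTrue, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(domains), function(j) {
    n <- sample(30:100, kPer, replace = TRUE)
    data.frame(study_id = sprintf("%s_s%02d", domains[j], seq_len(kPer)),
               domain = domains[j],
               m_t2dm = dTrue[j] + rnorm(kPer, 0, 0.05), sd_t2dm = 1,
               n_t2dm = n, m_hc = 0, sd_hc = 1, n_hc = n,
               stringsAsFactors = FALSE)
  }))
}

test_that("domain pooling is independent across domains and Bonferroni adjusted", {
  st <- mkStudies(c("exec", "speed"), 6, c(-0.5, -0.2), seed = 31)
  res <- poolDomains(st, method = "DL")
  one <- randomEffectsPool(
    cohensD(st$m_t2dm[st$domain == "exec"], 1, st$n_t2dm[st$domain == "exec"],
            0, 1, st$n_hc[st$domain == "exec"])$d,
    cohensD(st$m_t2dm[st$domain == "exec"], 1, st$n_t2dm[st$domain == "exec"],
            0, 1, st$n_hc[st$domain == "exec"])$variance,
    method = "DL", domain = "exec")
  expect_equal(res$d_pooled[res$domain == "exec"], one@dPooled,
               tolerance = 1e-10)
  expect_equal(res$p_bonferroni, pmin(1, res$p * 2), tolerance = 1e-12)
  # planted ordering of domain severities is recovered
  st3 <- mkStudies(c("a", "b", "c"), 8, c(-0.6, -0.3, -0.05), seed = 32)
  res3 <- poolDomains(st3, method = "DL")
  expect_identical(res3$domain[order(res3$d_pooled)], c("a", "b", "c"))
})

test_that("single-study domains are reported unpooled with a warning", {
  st <- mkStudies(c("exec", "lonely"), 3, c(-0.4, -0.4), seed = 33)
  st <- st[st$domain == "exec" | st$study_id == "lonely_s01", ]
  expect_warning(res <- poolDomains(st, method = "DL"), "single study")
  expect_true(is.na(res$d_pooled[res$domain == "lonely"]))
  expect_identical(res$k[res$domain == "lonely"], 1L)
})

test_that("within-study effects can be averaged before pooling", {
  st <- mkStudies("exec", 4, -0.4, seed = 35)
  dup <- rbind(st, st)  # every study contributes the same effect twice
  r1 <- poolDomains(st, method = "DL", averageWithinStudy = TRUE)
  r2 <- poolDomains(dup, method = "DL", averageWithinStudy = TRUE)
  expect_equal(r1$d_pooled, r2$d_pooled, tolerance = 1e-10)
  expect_identical(r2$k, 4L)
})

test_that("funnel data centers the pseudo-confidence cone on the pooled effect", {
  d <- c(0.2, 0.3, 0.4)
  v <- c(0.04, 0.02, 0.03)
  fd <- funnelData(d, v)
  expect_equal(fd$points$se, sqrt(v))
  expect_equal(fd$pooled, sum(d / v) / sum(1 / v), tolerance = 1e-12)
  expect_equal(fd$boundary$low[1], fd$pooled, tolerance = 1e-9)
  expect_equal(fd$boundary$high[1], fd$pooled, tolerance = 1e-9)
  one <- funnelData(0.5, 0.04)
  expect_equal(one$pooled, 0.5)
})

test_that("symmetric simulated studies show no funnel asymmetry on average", {
  set.seed(55)
  slopes <- replicate(40, {
    k <- 20
    v <- runif(k, 0.01, 0.2)
    d <- rnorm(k, 0.3, sqrt(v))
    coef(lm(d ~ sqrt(v)))[2]
  })
  expect_lt(abs(mean(slopes)), 0.15)
})
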
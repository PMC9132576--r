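symCos <- function(f, n, tr = 1) {
  t <- (0:(n - 1)) * tr
  cos(2 * pi * f * (t - (n - 1) * tr / 2))  # orthogonal to constant + trend
}

test_that("bandpass amplitude follows the documented spectral convention", {
  expect_equal(bandpassAmplitude(rep(5, 128), 1), 0, tolerance = 1e-12)
  x <- symCos(0.05, 500)
  a1 <- bandpassAmplitude(x, 1)
  a2 <- bandpassAmplitude(2 * x, 1)
  expect_equal(a2 / a1, 2, tolerance = 1e-12)
  # single exact-bin sinusoid: mean over the in-band bins of A/sqrt(2)
  nbins <- sum((1:250) / 500 >= 0.01 & (1:250) / 500 <= 0.08)
  expect_equal(a1, (1 / sqrt(2)) / nbins, tolerance = 1e-10)
  # invariance to constant offset and linear trend
  t <- 0:499
  expect_equal(bandpassAmplitude(x + 7 - 0.2 * t, 1), a1, tolerance = 1e-10)
  expect_error(bandpassAmplitude(x, 1, band = c(0.01, 0.6)), "Nyquist")
  expect_error(bandpassAmplitude(x[1:8], 1), ">= 16")
})

test_that("out-of-band oscillations are rejected to numerical precision", {
  a_in <- bandpassAmplitude(symCos(0.05, 500), 1)
  a_out <- bandpassAmplitude(symCos(0.2, 500), 1)
  expect_lt(a_out / a_in, 1e-8)
})

test_that("normalized ALFF maps have unit in-mask mean and scale invariance", {
  sp <- fmriSpec(gridShape = c(6, 6, 6), nTimepoints = 64, noiseSd = 0.3,
                 seed = 2)
  fm <- generateFmri(sp, "a")[[1]]
  m <- computeAlffMap(fm)
  expect_equal(mean(mapValues(m)[fm@mask]), 1, tolerance = 1e-9)
  fm2 <- fm
  fm2@data <- fm@data * 2
  m2 <- computeAlffMap(fm2)
  expect_equal(mapValues(m2), mapValues(m), tolerance = 1e-12)
  # spatially uniform signal: every in-mask value is 1
  fm3 <- fm
  fm3@data <- array(rep(sin(2 * pi * 0.05 * (0:63)), each = 216),
                    dim = c(6, 6, 6, 64))
  expect_equal(unname(mapValues(computeAlffMap(fm3))[fm3@mask]), rep(1, 216),
               tolerance = 1e-9)
  fm4 <- fm
  fm4@mask <- array(FALSE, c(6, 6, 6))
  expect_error(computeAlffMap(fm4), "mask")
})

test_that("planted amplitude clusters raise normalized ALFF above one", {
  cl <- list(list(voxels = as.matrix(expand.grid(2:3, 2:3, 2:3)),
                  multipliers = c(case = 2)))
  sp <- fmriSpec(gridShape = c(8, 8, 8), nTimepoints = 100, noiseSd = 0,
                 clusters = cl, seed = 3)
  fm <- generateFmri(sp, "case")[[1]]
  m <- mapValues(computeAlffMap(fm))
  expect_true(all(m[2:3, 2:3, 2:3] > 1))
  expect_true(mean(m[6:8, 6:8, 6:8]) < 1)
})

test_that("Gaussian smoothing preserves uniform fields and matches the kernel", {
  u <- array(3, c(9, 9, 9))
  expect_identical(smoothGaussian(u, 0), u)
  s <- smoothGaussian(u, 6, c(2, 2, 2))
  expect_equal(s, u, tolerance = 1e-12)
  # delta input (far from edges) reproduces the closed-form separable kernel
  d <- array(0, c(21, 21, 21)); d[11, 11, 11] <- 1
  fwhm <- 5; vox <- 2
  s <- smoothGaussian(d, fwhm, rep(vox, 3))
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
  r <- max(1, ceiling(3.5 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2)); w <- w / sum(w)
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0), c(1, 1, 1))) {
    expect_equal(s[11 + off[1], 11 + off[2], 11 + off[3]],
                 w[r + 1 + off[1]] * w[r + 1 + off[2]] * w[r + 1 + off[3]],
                 tolerance = 1e-12)
  }
  expect_equal(sum(s), 1, tolerance = 1e-12)  # mass preservation
  expect_error(smoothGaussian(u, -1), "fwhm")
})

test_that("smoothing a normalized map keeps the unit-mean invariant", {
  sp <- fmriSpec(gridShape = c(8, 8, 8), nTimepoints = 64, noiseSd = 0.5,
                 seed = 9)
  m <- computeAlffMap(generateFmri(sp, "a")[[1]])
  sm <- smoothAlffMap(m, 5)
  expect_equal(mean(mapValues(sm)[sm@mask]), 1, tolerance = 1e-9)
})

test_that("voxelwise group statistics are calibrated under the null", {
  set.seed(31)
  dims <- c(10, 10, 10)
  mask <- array(TRUE, dims)
  mkmap <- function() new("ALFFMap",
                          values = array(rnorm(prod(dims), 1, 0.1), dims),
                          normalized = FALSE, band = c(0.01, 0.08),
                          mask = mask, voxelSize = c(2, 2, 2))
  maps <- replicate(40, mkmap(), simplify = FALSE)
  z <- voxelwiseGroupStats(maps, rep(c(0, 1), 20))
  frac <- mean(abs(mapValues(z)) > qnorm(0.975))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
  expect_error(voxelwiseGroupStats(list(maps[[1]], maps[[1]]), c(0, 1)),
               "length|>= 3")
})

test_that("cluster thresholding applies FDR, connectivity and minimum extent", {
  dims <- c(12, 12, 12)
  vals <- array(0, dims)
  # 20-voxel blob (face-connected) and a separate 5-voxel blob
  blob20 <- as.matrix(expand.grid(2:6, 2:5, 2))[1:20, ]
  blob5 <- cbind(10, 10, 8:12)
  vals[blob20] <- 10
  vals[blob5] <- 10
  z <- new("ZMap", values = vals, mask = array(TRUE, dims), df = 50)
  cs <- thresholdClusters(z, q = 0.05, minSize = 12)
  expect_identical(nrow(clusterTable(cs)), 1L)
  expect_identical(clusterTable(cs)$size, 20L)
  expect_identical(clusterTable(cs)$sign, 1L)
  # degenerate thresholds: every in-mask voxel ends up in a cluster
  all_in <- thresholdClusters(z, q = 1, minSize = 1)
  expect_equal(sum(clusterTable(all_in)$size), prod(dims))
  expect_error(thresholdClusters(z, q = 0), "q must")
})

test_that("clusters grow monotonically with the FDR level", {
  set.seed(8)
  dims <- c(10, 10, 10)
  vals <- array(rnorm(prod(dims)), dims)
  vals[2:4, 2:4, 2:4] <- vals[2:4, 2:4, 2:4] + 4
  z <- new("ZMap", values = vals, mask = array(TRUE, dims), df = 40)
  vox <- function(q) {
    cs <- thresholdClusters(z, q, minSize = 1)
    if (!length(cs@voxels)) return(character())
    apply(do.call(rbind, cs@voxels), 1, paste, collapse = ",")
  }
  v1 <- vox(0.01); v2 <- vox(0.1)
  expect_true(all(v1 %in% v2))
})

test_that("region aggregation averages in-region non-missing voxels", {
  m <- array(1, c(4, 4, 2))
  labels <- array(0L, c(4, 4, 2))
  labels[1:2, , ] <- 1L
  labels[3:4, , ] <- 2L
  m[labels == 2] <- 2
  out <- aggregateRegions(m, labels, c("one", "two"))
  expect_equal(out$value, c(1, 2))
  expect_identical(out$name, c("one", "two"))
  # uniform map: every region equals the constant
  expect_equal(aggregateRegions(array(7, dim(labels)), labels)$value,
               c(7, 7))
  # empty region warns and yields NA
  labels2 <- labels
  labels2[labels2 == 2L] <- 3L
  m2 <- m
  m2[labels2 == 3L] <- NA
  expect_warning(out2 <- aggregateRegions(m2, labels2), "empty")
  expect_true(is.na(out2$value[2]))
})
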
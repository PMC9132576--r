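# Amplitude of low-frequency fluctuation: per-voxel spectral amplitude in a
# low-frequency band, global-mean normalization, Gaussian smoothing,
# voxelwise group statistics, and FDR + cluster-extent thresholding.

.check_band <- function(band, tr) {
  nyq <- 1 / (2 * tr)
  if (length(band) != 2L || band[1] <= 0 || band[2] > nyq + 1e-12 ||
      band[1] > band[2])
    stop("frequency band must lie within (0, Nyquist = ", signif(nyq, 4),
         " Hz]", call. = FALSE)
}

# residuals after removing intercept + linear trend, columnwise
.detrend <- function(Y) {
  n <- nrow(Y)
  X <- cbind(1, seq_len(n))
  Y - X %*% qr.coef(qr(X), Y)
}

#' Spectral amplitude of a time series within a frequency band
#'
#' The series is linearly detrended, discrete-Fourier-transformed, and the
#' amplitude is the mean over the in-band frequency bins (inclusive at both
#' edges, bins from the unpadded DFT at k/(N*tr) Hz) of
#' \code{sqrt(2) * |X(f)| / N}. Under this convention a pure sinusoid of
#' amplitude A at an exact bin frequency yields \code{A / sqrt(2)}, its root
#' mean square, and the result is invariant to adding any constant or linear
#' trend.
#'
#' @param x numeric time series, length >= 16.
#' @param tr sampling interval, seconds.
#' @param band frequency interval, Hz, within (0, Nyquist].
#' @return nonnegative scalar amplitude.
#' @examples
#' t <- seq(0, 511)
#' bandpassAmplitude(sin(2 * pi * 0.05 * t), tr = 1, band = c(0.01, 0.08))
#' @export
bandpassAmplitude <- function(x, tr, band = c(0.01, 0.08)) {
  n <- length(x)
  if (n < 16) stop("series length must be >= 16", call. = FALSE)
  .check_band(band, tr)
  r <- .detrend(matrix(x, ncol = 1))
  X <- fft(r[, 1])
  k <- seq_len(floor(n / 2))          # positive frequencies
  f <- k / (n * tr)
  sel <- k[f >= band[1] & f <= band[2]]
  if (!length(sel)) return(0)
  mean(sqrt(2) * Mod(X[sel + 1]) / n)
}

#' Voxelwise ALFF map, normalized to the subject's global mean
#'
#' Computes \code{\link{bandpassAmplitude}} for every in-mask voxel and
#' divides by the mean over the mask, so the normalized map has in-mask
#' mean exactly 1 and is invariant to global rescaling of the raw signal.
#'
#' @param vol an \linkS4class{FmriData}.
#' @param band frequency interval, Hz.
#' @param normalize divide by the in-mask global mean (default TRUE).
#' @return an \linkS4class{ALFFMap} (NA outside the mask).
#' @export
computeAlffMap <- function(vol, band = c(0.01, 0.08), normalize = TRUE) {
  stopifnot(is(vol, "FmriData"))
  .check_band(band, vol@tr)
  dims <- dim(vol@data)
  inMask <- which(vol@mask > 0)
  if (!length(inMask)) stop("empty mask", call. = FALSE)
  n <- dims[4]
  Y <- t(matrix(vol@data, prod(dims[1:3]), n)[inMask, , drop = FALSE])
  R <- .detrend(Y)
  Fc <- mvfft(R)
  k <- seq_len(floor(n / 2))
  f <- k / (n * vol@tr)
  sel <- k[f >= band[1] & f <= band[2]]
  amp <- if (length(sel))
    colMeans(sqrt(2) * Mod(Fc[sel + 1, , drop = FALSE]) / n)
  else rep(0, length(inMask))
  if (normalize) {
    g <- mean(amp)
    if (g == 0) stop("zero global mean amplitude", call. = FALSE)
    amp <- amp / g
  }
  vals <- array(NA_real_, dims[1:3])
  vals[inMask] <- amp
  new("ALFFMap", values = vals, normalized = normalize, band = band,
      mask = vol@mask, voxelSize = vol@voxelSize)
}

# 1D Gaussian kernel in voxel units; sum normalized to 1
.gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma_vox))
  w <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  w / sum(w)
}

.convolve_axis <- function(vol, w, axis) {
  if (length(w) == 1L) return(vol)
  r <- (length(w) - 1L) / 2L
  d <- dim(vol)
  out <- array(0, d)
  for (off in (-r):r) {
    wt <- w[off + r + 1L]
    src <- seq_len(d[axis]) + off
    ok <- src >= 1L & src <= d[axis]
    idx_dst <- idx_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_dst[[axis]] <- which(ok)
    idx_src[[axis]] <- src[ok]
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      wt * vol[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

#' Separable 3D Gaussian smoothing
#'
#' Per-axis Gaussian kernel with \code{sigma = fwhm / (2 sqrt(2 ln 2))}
#' converted to voxel units; the kernel sums to one, so a uniform field is
#' preserved. NA voxels are excluded and the result renormalized by the
#' smoothed support indicator (NAs stay NA), which also keeps a uniform
#' field exactly unchanged at the edges.
#'
#' @param volume 3D numeric array (may contain NA).
#' @param fwhm full width at half maximum, mm (0 = identity).
#' @param voxelSize voxel edge lengths, mm per axis.
#' @return smoothed 3D array.
#' @export
smoothGaussian <- function(volume, fwhm, voxelSize = c(2, 2, 2)) {
  if (fwhm < 0) stop("fwhm must be >= 0", call. = FALSE)
  if (fwhm == 0) return(volume)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  nas <- is.na(volume)
  v <- volume; v[nas] <- 0
  supp <- array(1, dim(volume)); supp[nas] <- 0
  for (a in 1:3) {
    w <- .gauss_kernel(sigma / voxelSize[a])
    v <- .convolve_axis(v, w, a)
    supp <- .convolve_axis(supp, w, a)
  }
  out <- v / supp
  out[nas] <- NA
  out
}

#' Smooth the values of an ALFF map
#'
#' @param map an \linkS4class{ALFFMap}.
#' @param fwhm full width at half maximum, mm.
#' @return the map with smoothed values (renormalized to in-mask mean 1 if
#'   it was normalized, so the normalization invariant is preserved).
#' @export
smoothAlffMap <- function(map, fwhm) {
  stopifnot(is(map, "ALFFMap"))
  v <- smoothGaussian(map@values, fwhm, map@voxelSize)
  if (map@normalized) {
    g <- mean(v[map@mask > 0])
    v <- v / g
  }
  new("ALFFMap", values = v, normalized = map@normalized, band = map@band,
      mask = map@mask, voxelSize = map@voxelSize)
}

#' Voxelwise group statistics on a collection of ALFF maps
#'
#' Per voxel, fits OLS of the (normalized) amplitude on the factor (plus
#' covariates) with a shared design matrix, and converts the factor t
#' statistic to a signed z score by two-sided tail matching, making maps
#' comparable across differing degrees of freedom. Voxels missing in any
#' subject are excluded (NA in the z map).
#'
#' @param maps list of \linkS4class{ALFFMap} with identical shapes/masks.
#' @param factor numeric/logical vector, one value per map (e.g. 0/1 group).
#' @param covariates optional numeric matrix/data.frame of additional
#'   regressors (one row per map).
#' @return a \linkS4class{ZMap}.
#' @export
voxelwiseGroupStats <- function(maps, factor, covariates = NULL) {
  stopifnot(length(maps) >= 3, length(factor) == length(maps))
  dims <- dim(maps[[1]]@values)
  for (m in maps)
    if (!identical(dim(m@values), dims))
      stop("maps have mismatched shapes", call. = FALSE)
  Y <- t(vapply(maps, function(m) as.vector(m@values), numeric(prod(dims))))
  X <- cbind(`(Intercept)` = 1, factor = .as_model_numeric(factor, "factor"))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  voxOk <- colSums(is.na(Y)) == 0
  fit <- .ols_multi(X, Y[, voxOk, drop = FALSE], 2L, 0.95)
  # t -> z via matched two-sided tail probabilities, sign preserved
  lt <- pt(abs(fit$t), fit$df, lower.tail = FALSE, log.p = TRUE)
  z <- sign(fit$t) * qnorm(lt, lower.tail = FALSE, log.p = TRUE)
  vals <- array(NA_real_, dims)
  vals[voxOk] <- z
  mask <- array(FALSE, dims)
  mask[voxOk & maps[[1]]@mask > 0] <- TRUE
  vals[!mask] <- NA
  new("ZMap", values = vals, mask = mask, df = fit$df)
}

# 6-connectivity (face-adjacent) connected components over a logical array;
# returns an integer label array (0 = background)
.label_components6 <- function(sig) {
  d <- dim(sig)
  lab <- array(0L, d)
  idx <- which(sig)
  if (!length(idx)) return(lab)
  nxt <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  coord <- arrayInd(idx, d)
  inSig <- array(FALSE, d); inSig[idx] <- TRUE
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ci <- arrayInd(v, d)[1, ]
      for (a in 1:3) for (s in c(-1L, 1L)) {
        cj <- ci; cj[a] <- cj[a] + s
        if (cj[a] < 1L || cj[a] > d[a]) next
        w <- v + s * strides[a]
        if (inSig[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

#' FDR + cluster-extent thresholding of a z map
#'
#' Two-sided voxel p-values are Benjamini-Hochberg adjusted across in-mask
#' voxels; suprathreshold voxels (adjusted p <= q) are grouped by face
#' (6-neighbour) connectivity, clusters smaller than \code{minSize} voxels
#' are discarded, and each retained cluster is signed by the direction of
#' its absolute-peak z.
#'
#' @param z a \linkS4class{ZMap}.
#' @param q FDR level in (0, 1].
#' @param minSize minimum cluster extent in voxels (default 12).
#' @return a \linkS4class{ClusterSet}.
#' @export
thresholdClusters <- function(z, q = 0.05, minSize = 12) {
  stopifnot(is(z, "ZMap"))
  if (!(q > 0 && q <= 1)) stop("q must be in (0, 1]", call. = FALSE)
  dims <- dim(z@values)
  inMask <- which(z@mask > 0)
  p <- 2 * pnorm(-abs(z@values[inMask]))
  padj <- bhFdr(p)
  sig <- array(FALSE, dims)
  sig[inMask[padj <= q]] <- TRUE
  lab <- .label_components6(sig)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  rows <- list(); voxLists <- list()
  cid <- 0L
  for (i in ids) {
    vox <- which(lab == i)
    if (length(vox) < minSize) next
    cid <- cid + 1L
    zv <- z@values[vox]
    pk <- vox[which.max(abs(zv))]
    pc <- arrayInd(pk, dims)[1, ]
    rows[[cid]] <- data.frame(
      id = cid, size = length(vox), peak_x = pc[1], peak_y = pc[2],
      peak_z = pc[3], peak_value = zv[which.max(abs(zv))],
      sign = ifelse(zv[which.max(abs(zv))] >= 0, 1L, -1L))
    voxLists[[cid]] <- arrayInd(vox, dims)
  }
  clusters <- if (cid) do.call(rbind, rows) else
    data.frame(id = integer(), size = integer(), peak_x = integer(),
               peak_y = integer(), peak_z = integer(),
               peak_value = numeric(), sign = integer())
  new("ClusterSet", clusters = clusters, voxels = voxLists,
      thresholdQ = q, minSize = minSize)
}

#' Aggregate a voxel map to labelled regions
#'
#' Per region (positive label value), the mean of in-region, non-missing
#' voxels; an empty region yields NA with a warning.
#'
#' @param map 3D numeric array (e.g. smoothed ALFF or a z map).
#' @param regionLabels integer 3D array of the same shape; 0 = background.
#' @param regionNames optional names for label values 1..K.
#' @return data.frame with columns \code{name} and \code{value}.
#' @export
aggregateRegions <- function(map, regionLabels, regionNames = NULL) {
  stopifnot(identical(dim(map), dim(regionLabels)))
  labs <- sort(setdiff(unique(as.vector(regionLabels)), 0))
  vals <- vapply(labs, function(l) {
    v <- map[regionLabels == l]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (anyNA(vals)) warning("empty region(s): ",
                           paste(labs[is.na(vals)], collapse = ", "))
  nm <- if (!is.null(regionNames)) regionNames[labs] else as.character(labs)
  data.frame(name = nm, value = vals, stringsAsFactors = FALSE)
}
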
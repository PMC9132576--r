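#' @describeIn EffectEstimate compact display
#' @param object an object of the documented class
#' @export
setMethod("show", "EffectEstimate", function(object) {
  cat(sprintf("EffectEstimate [%s]: beta = %.4g (SE %.3g), %g%% CI [%.4g, %.4g], t = %.3g, p = %.3g, n = %d\n",
              object@factor, object@beta, object@se, 100 * object@level,
              object@ciLow, object@ciHigh, object@t, object@p, object@n))
  if (length(object@covariates))
    cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
})

#' @describeIn EffectMap compact display
#' @param object an object of the documented class
#' @export
setMethod("show", "EffectMap", function(object) {
  cat(sprintf("EffectMap [%s] with %d entries\n", object@factor,
              nrow(object@table)))
  print(head(object@table, 5))
  if (nrow(object@table) > 5) cat("  ...\n")
})

#' @describeIn MatchedPairs compact display
#' @param object an object of the documented class
#' @export
setMethod("show", "MatchedPairs", function(object) {
  cat(sprintf("MatchedPairs: %d pairs, %d unmatched cases\n",
              nrow(object@pairs), length(object@unmatchedCases)))
})

#' @describeIn RatioCI compact display
#' @param object an object of the documented class
#' @export
setMethod("show", "RatioCI", function(object) {
  set <- if (object@bounded)
    sprintf("[%.4g, %.4g]", object@ciLow, object@ciHigh)
  else if (object@exclusive)
    sprintf("(-Inf, %.4g] U [%.4g, Inf)", object@ciLow, object@ciHigh)
  else "(-Inf, Inf)"
  cat(sprintf("RatioCI: ratio = %.4g, %g%% Fieller set %s (df = %g)\n",
              object@ratio, 100 * object@level, set, object@df))
})

#' @describeIn OverlapResult compact display
#' @param object an object of the documented class
#' @export
setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("OverlapResult: r = %.3f, p = %.3g, n = %d\n",
              object@r, object@p, object@n))
})

#' @describeIn ClusterSet compact display
#' @param object an object of the documented class
#' @export
setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters (q = %g, min size = %g voxels)\n",
              nrow(object@clusters), object@thresholdQ, object@minSize))
  if (nrow(object@clusters)) print(object@clusters)
})

#' @describeIn MetaResult compact display
#' @param object an object of the documented class
#' @export
setMethod("show", "MetaResult", function(object) {
  cat(sprintf("MetaResult [%s]: d = %.3f [%.3f, %.3f], k = %d, tau2 = %.4g, Q = %.3g, I2 = %.1f%%, p = %.3g (Bonferroni %.3g)\n",
              object@domain, object@dPooled, object@ciLow, object@ciHigh,
              object@k, object@tau2, object@q, object@i2, object@p,
              object@pBonferroni))
})

#' @describeIn ALFFMap compact display
#' @param object an object of the documented class
#' @export
setMethod("show", "ALFFMap", function(object) {
  cat(sprintf("ALFFMap %s, band %.3g-%.3g Hz, %s, %d in-mask voxels\n",
              paste(dim(object@values), collapse = "x"),
              object@band[1], object@band[2],
              if (object@normalized) "normalized" else "raw",
              sum(object@mask > 0)))
})

# ---- accessors -------------------------------------------------------------

#' Extract the per-entry table of an EffectMap
#' @param x an \linkS4class{EffectMap}
#' @return the underlying data.frame (one row per region or domain)
#' @export
effectTable <- function(x) {
  stopifnot(is(x, "EffectMap"))
  x@table
}

#' Matched pairs as a data.frame
#' @param x a \linkS4class{MatchedPairs}
#' @return data.frame with columns case, control, stratum
#' @export
pairsTable <- function(x) {
  stopifnot(is(x, "MatchedPairs"))
  x@pairs
}

#' Retained-cluster table of a ClusterSet
#' @param x a \linkS4class{ClusterSet}
#' @return data.frame of cluster id, size, peak coordinate, peak value, sign
#' @export
clusterTable <- function(x) {
  stopifnot(is(x, "ClusterSet"))
  x@clusters
}

#' Voxel values of an ALFFMap or ZMap
#' @param x an \linkS4class{ALFFMap} or \linkS4class{ZMap}
#' @return the 3D array of values (NA outside the mask)
#' @export
mapValues <- function(x) {
  stopifnot(is(x, "ALFFMap") || is(x, "ZMap"))
  x@values
}

#' MetaResult fields as a one-row data.frame
#' @param x a \linkS4class{MetaResult}
#' @return one-row data.frame of the pooled statistics
#' @export
metaTable <- function(x) {
  stopifnot(is(x, "MetaResult"))
  data.frame(domain = x@domain, k = x@k, d_pooled = x@dPooled,
             ci_low = x@ciLow, ci_high = x@ciHigh, tau2 = x@tau2,
             q = x@q, i2 = x@i2, p = x@p, p_bonferroni = x@pBonferroni,
             method = x@method, stringsAsFactors = FALSE)
}
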
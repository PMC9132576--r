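# Readers and writers: delimited text for tables, NIfTI-1 for volumes.

#' Read / write a cohort table
#'
#' Comma-separated with a header row, one row per subject; missing values
#' are the NA sentinel (never zero).
#'
#' @param path file path.
#' @return \code{readCohortTable}: the cohort data.frame.
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname readCohortTable
#' @param cohort cohort data.frame to write.
#' @export
writeCohortTable <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a regions-x-subjects volume matrix
#'
#' @param volumes \link[SummarizedExperiment]{SummarizedExperiment} or
#'   matrix with region row names.
#' @param path file path.
#' @export
writeVolumeTable <- function(volumes, path) {
  V <- if (is(volumes, "SummarizedExperiment"))
    SummarizedExperiment::assay(volumes, "volume") else as.matrix(volumes)
  df <- data.frame(region = rownames(V), V, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVolumeTable
#' @return \code{readVolumeTable}: matrix, regions x subjects.
#' @export
readVolumeTable <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df[[1]]
  V
}

#' Write / read an effect map as delimited text
#'
#' Columns: name, beta, se, ci_low, ci_high, t, p, p_adjusted, percent,
#' percent_ci_low, percent_ci_high, n.
#'
#' @param map an \linkS4class{EffectMap}.
#' @param path file path.
#' @export
writeEffectMap <- function(map, path) {
  stopifnot(is(map, "EffectMap"))
  tab <- map@table
  tab$factor <- map@factor
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEffectMap
#' @return \code{readEffectMap}: the \linkS4class{EffectMap}.
#' @export
readEffectMap <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  fac <- if ("factor" %in% names(tab)) tab$factor[1] else ""
  tab$factor <- NULL
  new("EffectMap", table = tab, factor = fac)
}

#' Write a cluster set as delimited text
#'
#' One row per retained cluster: id, size, peak coordinate, peak value,
#' sign.
#'
#' @param clusters a \linkS4class{ClusterSet}.
#' @param path file path.
#' @export
writeClusterSet <- function(clusters, path) {
  stopifnot(is(clusters, "ClusterSet"))
  write.csv(clusterTable(clusters), path, row.names = FALSE)
  invisible(path)
}

#' Write / read 4D fMRI data as NIfTI-1
#'
#' The repetition time is stored in the fourth pixdim entry of the header.
#'
#' @param fmri an \linkS4class{FmriData}.
#' @param path file path (.nii or .nii.gz).
#' @export
writeFmriNifti <- function(fmri, path) {
  stopifnot(is(fmri, "FmriData"))
  img <- RNifti::asNifti(fmri@data)
  RNifti::pixdim(img) <- c(fmri@voxelSize, fmri@tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeFmriNifti
#' @param maskPath optional NIfTI mask to attach (defaults to all-ones).
#' @return \code{readFmriNifti}: the \linkS4class{FmriData}.
#' @export
readFmriNifti <- function(path, maskPath = NULL) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- array(as.numeric(img), dim = dim(img))
  mask <- if (!is.null(maskPath)) {
    m <- RNifti::readNifti(maskPath)
    array(as.numeric(m) > 0, dim = dim(m))
  } else array(TRUE, dim = dim(arr)[1:3])
  new("FmriData", data = arr, tr = pd[4], mask = mask,
      voxelSize = pd[1:3])
}

#' Write a 3D map (ALFF, z, mask or labels) as NIfTI-1
#'
#' @param values 3D array or \linkS4class{ALFFMap}/\linkS4class{ZMap}.
#' @param path file path.
#' @param voxelSize voxel edge lengths, mm.
#' @export
writeMapNifti <- function(values, path, voxelSize = c(2, 2, 2)) {
  if (is(values, "ALFFMap") || is(values, "ZMap")) values <- mapValues(values)
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- voxelSize
  RNifti::writeNifti(img, path)
  invisible(path)
}
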
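# Pipeline configuration, stage runner and run-directory manifest. Stages
# never mutate their inputs: every output is a new file in the run
# directory, and the manifest records the config hash, seed and package
# version needed to re-run any stage bit-identically.

#' Read a pipeline configuration
#'
#' A single YAML file with per-stage sections (\code{simulate},
#' \code{match}, \code{effects}, \code{accelerate}, \code{overlap},
#' \code{meta}) and a top-level \code{seed}. \code{overrides} (a named
#' list, e.g. from command-line flags) replace file values.
#'
#' @param path YAML file path.
#' @param overrides named list merged over the file contents.
#' @return the configuration list.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("missing input: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  modifyList(cfg, overrides)
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config), tf)
  unname(tools::md5sum(tf))
}

.manifest_add <- function(runDir, stage, inputs, outputs, config, seed) {
  mf <- file.path(runDir, "manifest.yaml")
  man <- if (file.exists(mf)) yaml::read_yaml(mf) else list()
  man[[stage]] <- list(
    inputs = as.list(inputs), outputs = as.list(outputs),
    seed = seed, config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("T2DMAging")))
  writeLines(yaml::as.yaml(man), mf)
}

.log_line <- function(runDir, ...) {
  cat(paste0(..., "\n"), file = file.path(runDir, "run.log"), append = TRUE)
}

.stage_simulate <- function(config, runDir) {
  sc <- config$simulate
  seed <- if (!is.null(sc$seed)) sc$seed else config$seed
  spec <- cohortSpec(
    nSubjects = sc$n_subjects,
    ageRange = if (!is.null(sc$age_range)) unlist(sc$age_range) else c(50, 80),
    t2dmPrevalence = if (!is.null(sc$t2dm_prevalence)) sc$t2dm_prevalence else 0.05,
    seed = seed)
  at <- do.call(atrophySpec, c(
    list(seed = seed + 1),
    sc$atrophy[intersect(names(sc$atrophy),
                         c("t2dmOffsetScale", "perturbationMagnitude",
                           "acceleration", "ageRef"))]))
  cohort <- generateCohort(spec)
  vols <- generateRegionVolumes(cohort, at)
  scores <- generateCognitiveScores(cohort, seed = seed + 2)
  writeCohortTable(cohort, file.path(runDir, "cohort.csv"))
  writeVolumeTable(vols, file.path(runDir, "volumes.csv"))
  writeCohortTable(scores, file.path(runDir, "scores.csv"))
  .log_line(runDir, "simulate: n=", nrow(cohort), " t2dm=", sum(cohort$t2dm))
  c("cohort.csv", "volumes.csv", "scores.csv")
}

.stage_filter <- function(config, runDir) {
  cohort <- readCohortTable(file.path(runDir, "cohort.csv"))
  cohort <- deriveCohortFields(cohort)
  out <- applyEligibility(cohort)
  ex <- attr(out, "exclusions")
  writeCohortTable(out, file.path(runDir, "cohort_eligible.csv"))
  writeLines(paste(names(ex), ex, sep = ": "),
             file.path(runDir, "exclusions.txt"))
  .log_line(runDir, "filter: ", paste(names(ex), ex, sep = "=",
                                      collapse = ", "))
  c("cohort_eligible.csv", "exclusions.txt")
}

.stage_match <- function(config, runDir) {
  cohort <- readCohortTable(file.path(runDir, "cohort_eligible.csv"))
  mc <- config$match
  exact <- if (!is.null(mc$exact_keys)) unlist(mc$exact_keys) else
    c("age", "sex", "education", "hypertension")
  binned <- NULL
  if (!is.null(mc$binned_keys))
    binned <- do.call(rbind, lapply(mc$binned_keys, as.data.frame))
  spec <- matchSpec(exact, binned, seed = config$seed)
  mp <- matchCohort(cohort[cohort$t2dm, ], cohort[!cohort$t2dm, ], spec)
  write.csv(pairsTable(mp), file.path(runDir, "pairs.csv"),
            row.names = FALSE)
  write.csv(balanceReport(mp, cohort[cohort$t2dm, ], cohort[!cohort$t2dm, ]),
            file.path(runDir, "balance.csv"), row.names = FALSE)
  .log_line(runDir, "match: pairs=", nrow(pairsTable(mp)),
            " unmatched_cases=", length(mp@unmatchedCases))
  c("pairs.csv", "balance.csv")
}

.stage_effects <- function(config, runDir) {
  cohort <- readCohortTable(file.path(runDir, "cohort_eligible.csv"))
  V <- readVolumeTable(file.path(runDir, "volumes.csv"))
  pairs <- read.csv(file.path(runDir, "pairs.csv"),
                    stringsAsFactors = FALSE)
  ids <- c(pairs$case, pairs$control)
  mcoh <- cohort[match(ids, cohort$id), , drop = FALSE]
  covariates <- if (!is.null(config$effects$covariates))
    unlist(config$effects$covariates) else character()
  t2dmMap <- regionalEffectMap(V[, ids, drop = FALSE], "t2dm",
                               covariates, cohort = mcoh)
  hc <- cohort[!cohort$t2dm, , drop = FALSE]
  ageMap <- regionalEffectMap(V[, hc$id, drop = FALSE], "age",
                              covariates, cohort = hc)
  writeEffectMap(t2dmMap, file.path(runDir, "effects_t2dm.csv"))
  writeEffectMap(ageMap, file.path(runDir, "effects_age.csv"))
  .log_line(runDir, "effects: n_matched=", length(ids), " n_hc=", nrow(hc))
  c("effects_t2dm.csv", "effects_age.csv")
}

.stage_overlap <- function(config, runDir) {
  a <- readEffectMap(file.path(runDir, "effects_t2dm.csv"))
  b <- readEffectMap(file.path(runDir, "effects_age.csv"))
  ov <- overlapCorrelation(a, b)
  write.csv(data.frame(r = ov@r, p = ov@p, n = ov@n),
            file.path(runDir, "overlap.csv"), row.names = FALSE)
  .log_line(runDir, "overlap: r=", signif(ov@r, 4))
  "overlap.csv"
}

.stage_accelerate <- function(config, runDir) {
  cohort <- readCohortTable(file.path(runDir, "cohort_eligible.csv"))
  V <- readVolumeTable(file.path(runDir, "volumes.csv"))
  t2 <- cohort[cohort$t2dm, , drop = FALSE]
  Vt <- V[, t2$id, drop = FALSE]
  total <- colSums(sweep(Vt, 2, t2$head_scaling, "/"))
  rc <- accelerationEstimate(total, t2)
  write.csv(data.frame(ratio = rc@ratio, ci_low = rc@ciLow,
                       ci_high = rc@ciHigh, bounded = rc@bounded,
                       level = rc@level, df = rc@df, n = nrow(t2),
                       model = "total_volume ~ age + duration"),
            file.path(runDir, "acceleration.csv"), row.names = FALSE)
  .log_line(runDir, "accelerate: ratio=", signif(rc@ratio, 4))
  "acceleration.csv"
}

.stage_meta <- function(config, runDir) {
  studies <- readCohortTable(config$meta$studies)
  res <- poolDomains(studies,
                     method = if (!is.null(config$meta$method))
                       config$meta$method else "REML")
  write.csv(res, file.path(runDir, "meta_results.csv"), row.names = FALSE)
  .log_line(runDir, "meta: domains=", nrow(res))
  "meta_results.csv"
}

.stage_report <- function(config, runDir) {
  arts <- setdiff(list.files(runDir), c("run.log", "manifest.yaml"))
  if (!length(arts))
    stop("run directory is empty: nothing to report", call. = FALSE)
  lines <- c("pipeline run summary", paste("artifact:", arts))
  for (f in c("overlap.csv", "acceleration.csv")) {
    p <- file.path(runDir, f)
    if (file.exists(p))
      lines <- c(lines, paste0(f, ": ",
                               paste(readLines(p), collapse = " | ")))
  }
  writeLines(lines, file.path(runDir, "report.txt"))
  "report.txt"
}

#' Run one pipeline stage
#'
#' Stage outputs are written to \code{runDir}; the manifest records inputs,
#' outputs, the config hash, the seed and the package version.
#'
#' @param name one of \code{"simulate"}, \code{"filter"}, \code{"match"},
#'   \code{"effects"}, \code{"overlap"}, \code{"accelerate"},
#'   \code{"meta"}, \code{"report"}.
#' @param config configuration list (see \code{\link{readPipelineConfig}}).
#' @param runDir run directory (created if absent).
#' @return invisibly, the output file names.
#' @export
runStage <- function(name, config, runDir) {
  stages <- list(simulate = .stage_simulate, filter = .stage_filter,
                 match = .stage_match, effects = .stage_effects,
                 overlap = .stage_overlap, accelerate = .stage_accelerate,
                 meta = .stage_meta, report = .stage_report)
  if (!name %in% names(stages))
    stop("unknown stage: ", name, call. = FALSE)
  if (is.null(config$seed)) stop("config must carry a seed", call. = FALSE)
  dir.create(runDir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list.files(runDir)
  out <- stages[[name]](config, runDir)
  .manifest_add(runDir, name, inputs, out, config, config$seed)
  invisible(out)
}

#' Run a sequence of pipeline stages
#'
#' @param config configuration list.
#' @param runDir run directory.
#' @param stages stage names, executed in order.
#' @return invisibly, the run directory.
#' @export
runPipeline <- function(config, runDir,
                        stages = c("simulate", "filter", "match", "effects",
                                   "overlap", "accelerate", "report")) {
  for (s in stages) runStage(s, config, runDir)
  invisible(runDir)
}
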
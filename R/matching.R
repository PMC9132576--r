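# Exact (and optionally coarse/binned) 1:1 case-control matching.
#
# Subjects are grouped into strata defined by the exact key values crossed
# with half-open bins [origin + j*w, origin + (j+1)*w) of the binned keys;
# within a stratum cases and controls are paired in sorted-id order, giving
# min(#cases, #controls) pairs per stratum. Because compatibility is an
# equivalence relation (shared stratum), this greedy pairing attains the
# maximum bipartite matching size.

.stratum_key <- function(tab, spec) {
  missing_any <- rep(FALSE, nrow(tab))
  parts <- list()
  for (k in spec@exactKeys) {
    if (!k %in% names(tab)) stop("unknown matching key: ", k, call. = FALSE)
    v <- tab[[k]]
    if (k == "age") v <- as.integer(round(v))  # integer-year exact matching
    missing_any <- missing_any | is.na(v)
    parts[[k]] <- as.character(v)
  }
  if (nrow(spec@binnedKeys)) for (i in seq_len(nrow(spec@binnedKeys))) {
    k <- spec@binnedKeys$key[i]
    if (!k %in% names(tab)) stop("unknown matching key: ", k, call. = FALSE)
    v <- tab[[k]]
    missing_any <- missing_any | is.na(v)
    bin <- floor((v - spec@binnedKeys$origin[i]) / spec@binnedKeys$width[i])
    parts[[paste0(k, "_bin")]] <- as.character(bin)
  }
  key <- do.call(paste, c(parts, sep = "|"))
  key[missing_any] <- NA
  key
}

#' Exact/coarse 1:1 matching of cases to controls
#'
#' @param cases,controls cohort data.frames (e.g. the T2DM and HC arms, or
#'   the metformin-only and unmedicated arms).
#' @param spec a \linkS4class{MatchSpec}.
#' @return a \linkS4class{MatchedPairs}; subjects with a missing key value
#'   are excluded and counted in \code{droppedMissing}.
#' @examples
#' co <- generateCohort(cohortSpec(nSubjects = 400, t2dmPrevalence = 0.3,
#'                                 seed = 2))
#' mp <- matchCohort(co[co$t2dm, ], co[!co$t2dm, ],
#'                   matchSpec(c("age", "sex", "education", "hypertension")))
#' @export
matchCohort <- function(cases, controls, spec) {
  stopifnot(is(spec, "MatchSpec"))
  validObject(spec)
  kc <- .stratum_key(cases, spec)
  kh <- .stratum_key(controls, spec)
  dropped <- c(cases = sum(is.na(kc)), controls = sum(is.na(kh)))
  okc <- !is.na(kc); okh <- !is.na(kh)
  caseIds <- cases$id[okc]; kc <- kc[okc]
  ctrlIds <- controls$id[okh]; kh <- kh[okh]

  # deterministic sorted-id order within stratum
  oc <- order(kc, caseIds); caseIds <- caseIds[oc]; kc <- kc[oc]
  oh <- order(kh, ctrlIds); ctrlIds <- ctrlIds[oh]; kh <- kh[oh]

  pairs <- list(); unmatched <- character()
  for (s in unique(kc)) {
    ci <- caseIds[kc == s]
    hi <- ctrlIds[kh == s]
    np <- min(length(ci), length(hi))
    if (np > 0)
      pairs[[s]] <- data.frame(case = ci[seq_len(np)],
                               control = hi[seq_len(np)],
                               stratum = s, stringsAsFactors = FALSE)
    if (length(ci) > np)
      unmatched <- c(unmatched, ci[(np + 1L):length(ci)])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(case = character(), control = character(),
               stratum = character(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("MatchedPairs", pairs = pairs, unmatchedCases = sort(unmatched),
      droppedMissing = dropped, spec = spec)
}

#' Matched sample as a single cohort table
#'
#' @param pairs a \linkS4class{MatchedPairs}.
#' @param cases,controls the tables given to \code{\link{matchCohort}}.
#' @return row-bound cohort of matched cases then matched controls.
#' @export
matchedCohort <- function(pairs, cases, controls) {
  p <- pairsTable(pairs)
  rbind(cases[match(p$case, cases$id), , drop = FALSE],
        controls[match(p$control, controls$id), , drop = FALSE])
}

#' Covariate balance of the two matched arms
#'
#' For every matching key, tabulates the per-arm distribution (exact keys
#' must come out identical by construction; binned keys agree at bin
#' resolution).
#'
#' @param pairs a \linkS4class{MatchedPairs}.
#' @param cases,controls the tables given to \code{\link{matchCohort}}.
#' @return data.frame: key, value, n_case, n_control.
#' @export
balanceReport <- function(pairs, cases, controls) {
  p <- pairsTable(pairs)
  spec <- pairs@spec
  keys <- c(spec@exactKeys,
            if (nrow(spec@binnedKeys)) spec@binnedKeys$key)
  if (!nrow(p))
    return(data.frame(key = character(), value = character(),
                      n_case = integer(), n_control = integer()))
  ca <- cases[match(p$case, cases$id), , drop = FALSE]
  co <- controls[match(p$control, controls$id), , drop = FALSE]
  out <- lapply(keys, function(k) {
    vals <- sort(unique(c(as.character(ca[[k]]), as.character(co[[k]]))))
    data.frame(key = k, value = vals,
               n_case = as.integer(table(factor(as.character(ca[[k]]),
                                                levels = vals))),
               n_control = as.integer(table(factor(as.character(co[[k]]),
                                                   levels = vals))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select the medication-contrast arms within a T2DM cohort
#'
#' "Metformin only" means the metformin flag is set and no other T2DM
#' medication is taken; "unmedicated" means neither flag is set.
#'
#' @param cohort a T2DM cohort data.frame.
#' @return list with elements \code{metformin_only} and \code{unmedicated}.
#' @export
medicationArms <- function(cohort) {
  stopifnot(all(cohort$t2dm))
  list(metformin_only = cohort[cohort$metformin &
                                 !cohort$other_t2dm_medication, , drop = FALSE],
       unmedicated = cohort[!cohort$metformin &
                              !cohort$other_t2dm_medication, , drop = FALSE])
}
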
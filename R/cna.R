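#' Threshold calls of per-sample copy-number alterations
#'
#' Calls each gene in each sample as `gain`, `loss` or `neutral` from its
#' tumor-vs-normal log2 ratio: `gain` iff the ratio is at least
#' `gainThr`, `loss` iff it is at most `lossThr`, otherwise `neutral`.
#' A gene can never be both gained and lost in the same sample.
#'
#' @param logratio numeric vector or genes x samples matrix of
#'   copy-number log2 ratios.
#' @param gainThr,lossThr call thresholds in log2-ratio units;
#'   `gainThr` must be positive and `lossThr` negative.
#' @return character vector/matrix of calls, same shape and dimnames as
#'   the input.
#' @examples
#' callAlterations(c(1.0, -1.0, 0.1))
#' @export
callAlterations <- function(logratio, gainThr = 0.3, lossThr = -0.3) {
  if (!(gainThr > 0) || !(lossThr < 0))
    stop("thresholds must satisfy lossThr < 0 < gainThr")
  if (anyNA(logratio)) stop("log ratios must not contain missing values")
  calls <- ifelse(logratio >= gainThr, "gain",
                  ifelse(logratio <= lossThr, "loss", "neutral"))
  if (is.matrix(logratio)) dimnames(calls) <- dimnames(logratio)
  else names(calls) <- names(logratio)
  calls
}

#' Recurrently altered genes within one cohort
#'
#' A gene belongs to the cohort's gain set iff the fraction of samples in
#' which it is called `gain` is at least `minFreq`; the loss set is
#' analogous.
#'
#' @param calls character genes x samples matrix of
#'   gain/loss/neutral calls (see [callAlterations()]).
#' @param minFreq required fraction of samples, in (0, 1].
#' @return list with character vectors `gain` and `loss` (gene ids) and a
#'   data.frame `freq` (`gene_id`, `gain_freq`, `loss_freq`).
#' @export
recurrentGenes <- function(calls, minFreq = 0.25) {
  if (!is.matrix(calls) || nrow(calls) == 0 || ncol(calls) == 0)
    stop("a non-empty gene x sample call matrix is required")
  if (!(minFreq > 0) || minFreq > 1) stop("minFreq must be in (0, 1]")
  gf <- rowMeans(calls == "gain")
  lf <- rowMeans(calls == "loss")
  ids <- if (is.null(rownames(calls))) sprintf("g%d", seq_len(nrow(calls)))
         else rownames(calls)
  list(gain = ids[gf >= minFreq],
       loss = ids[lf >= minFreq],
       freq = data.frame(gene_id = ids, gain_freq = gf, loss_freq = lf,
                         row.names = NULL, stringsAsFactors = FALSE))
}

#' Cross-cohort recurrent alteration sets
#'
#' A gene is considered amplified (deleted) only when its gain (loss) is
#' supported by at least `minDatasets` of the input cohorts, i.e. the
#' alteration is verified on multiple independent datasets.
#'
#' @param perCohortSets list of per-cohort results, each a list with
#'   character vectors `gain` and `loss` (as from [recurrentGenes()]).
#' @param minDatasets minimum number of supporting cohorts (default 2).
#' @return list with character vectors `amplified` and `deleted`.
#' @examples
#' crossCohortAltered(list(list(gain = "A", loss = character(0)),
#'                         list(gain = c("A", "B"), loss = "C"),
#'                         list(gain = "B", loss = "C")))
#' @export
crossCohortAltered <- function(perCohortSets, minDatasets = 2L) {
  if (length(perCohortSets) == 0) stop("at least one cohort is required")
  if (minDatasets < 1 || minDatasets > length(perCohortSets))
    stop("minDatasets must be between 1 and the number of cohorts")
  countIn <- function(field) {
    tab <- table(unlist(lapply(perCohortSets, `[[`, field)))
    sort(names(tab)[tab >= minDatasets])
  }
  list(amplified = countIn("gain"), deleted = countIn("loss"))
}

#' Recurrent alteration sets from CNA cohorts
#'
#' Convenience wrapper running the whole copy-number arm: per-sample
#' threshold calls, per-cohort recurrence, and cross-cohort support. When
#' a `task` is given, recurrence is assessed over that task's case-stage
#' samples (the advanced group in which progression-associated
#' alterations recur); otherwise over all samples of each cohort.
#'
#' @param cohorts list of [CNACohort] objects.
#' @param task optional [progressionTask()].
#' @inheritParams callAlterations
#' @inheritParams recurrentGenes
#' @inheritParams crossCohortAltered
#' @return list with `amplified`, `deleted` (cross-cohort sets) and
#'   `perCohort` (per-cohort gain/loss sets and frequencies).
#' @export
cnaAlteredSets <- function(cohorts, task = NULL, gainThr = 0.3,
                           lossThr = -0.3, minFreq = 0.25,
                           minDatasets = 2L) {
  stopifnot(length(cohorts) >= 1,
            all(vapply(cohorts, is, logical(1), "CNACohort")))
  perCohort <- lapply(cohorts, function(co) {
    keep <- if (is.null(task)) rep(TRUE, ncol(co))
            else stages(co) == task@case
    if (!any(keep))
      stop(sprintf("cohort %s has no samples for the requested stage",
                   cohortName(co)))
    calls <- callAlterations(assay(co, "logratio")[, keep, drop = FALSE],
                             gainThr = gainThr, lossThr = lossThr)
    recurrentGenes(calls, minFreq = minFreq)
  })
  names(perCohort) <- vapply(cohorts, cohortName, character(1))
  out <- crossCohortAltered(perCohort, minDatasets = minDatasets)
  out$perCohort <- perCohort
  out
}
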
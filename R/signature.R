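#' Combine differential expression and copy-number alteration calls
#'
#' Builds the per-task combined signature: genes both up-regulated and
#' recurrently amplified (`upAmplified = up
#' \eqn{\cap} amplified`) and genes both down-regulated and recurrently
#' deleted (`downDeleted = down \eqn{\cap} deleted`). A gene falling in
#' both intersections (possible only with pathological inputs) is removed
#' from both, with a message.
#'
#' @param up,down character vectors of up-/down-regulated gene ids
#'   (cross-cohort differential expression, see [intersectCohortSets()]).
#' @param amplified,deleted character vectors of recurrently
#'   amplified/deleted gene ids (see [crossCohortAltered()]).
#' @param task the [progressionTask()] the sets were derived for.
#' @return A [CombinedSignature-class] object. Empty intersections are
#'   permitted and flagged with a message.
#' @examples
#' combineSignature(up = c("A", "B", "C"), down = "X",
#'                  amplified = c("B", "C", "D"), deleted = "Y",
#'                  task = progressionTask("II", "III"))
#' @export
combineSignature <- function(up, down, amplified, deleted, task) {
  stopifnot(is(task, "ProgressionTask"))
  upAmp <- sort(intersect(up, amplified))
  downDel <- sort(intersect(down, deleted))
  both <- intersect(upAmp, downDel)
  if (length(both)) {
    message(sprintf(
      "removing %d gene(s) present in both signature directions: %s",
      length(both), paste(both, collapse = ", ")))
    upAmp <- setdiff(upAmp, both)
    downDel <- setdiff(downDel, both)
  }
  if (length(upAmp) == 0 && length(downDel) == 0)
    message(sprintf("task %s: combined signature is empty", taskLabel(task)))
  new("CombinedSignature", task = task, upAmplified = upAmp,
      downDeleted = downDel)
}

#' Per-task signature from the raw cohorts
#'
#' Runs the full selection pipeline for one progression task:
#' rank-product differential expression in each expression cohort
#' ([rankProductDE()] + [selectDE()]), intersection across cohorts,
#' recurrent copy-number sets across CNA cohorts ([cnaAlteredSets()]),
#' and the final combination ([combineSignature()]).
#'
#' @param exprCohorts list (>= 2) of [ExpressionCohort] objects used for
#'   differential expression.
#' @param cnaCohorts list of [CNACohort] objects.
#' @param task a [progressionTask()].
#' @param alpha significance cutoff for [selectDE()].
#' @param deMethod selection scale, `"pval"` or `"pfp"` (see
#'   [selectDE()]).
#' @inheritParams estimatePfp
#' @inheritParams cnaAlteredSets
#' @return list with the `signature` ([CombinedSignature-class]), the
#'   cross-cohort `de` sets, the `cna` sets and the per-cohort `deResults`.
#' @export
buildSignature <- function(exprCohorts, cnaCohorts, task, alpha = 0.01,
                           deMethod = c("pval", "pfp"), nPerm = 100L,
                           seed = 1L, gainThr = 0.3, lossThr = -0.3,
                           minFreq = 0.25, minDatasets = 2L) {
  deMethod <- match.arg(deMethod)
  deResults <- lapply(exprCohorts, rankProductDE, task = task,
                      alpha = alpha, nPerm = nPerm, seed = seed)
  de <- intersectCohortSets(lapply(deResults, selectDE, alpha = alpha,
                                   method = deMethod))
  cna <- cnaAlteredSets(cnaCohorts, task = task, gainThr = gainThr,
                        lossThr = lossThr, minFreq = minFreq,
                        minDatasets = minDatasets)
  sig <- combineSignature(up = de$up, down = de$down,
                          amplified = cna$amplified,
                          deleted = cna$deleted, task = task)
  list(signature = sig, de = de, cna = cna[c("amplified", "deleted")],
       deResults = deResults)
}
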
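#' Observed success/failure counts for a criterion
#'
#' Splits a criterion's (dataset, task) AUC cells at a cutoff: `S0`
#' counts cells with AUC strictly above the cutoff (successes), `F0` the
#' remainder. Cells that failed upstream (missing AUC) are dropped with a
#' warning.
#'
#' @param results a result table from [runExperiment()].
#' @param criterion criterion name to select rows by.
#' @param cutoff AUC success threshold (conventionally 0.60 or 0.80).
#' @return named integer vector `c(S0 = ..., F0 = ...)`.
#' @examples
#' tab <- data.frame(criterion = "COMBDE", auc = c(0.63, 0.51, 0.55))
#' successFailureCounts(tab, "COMBDE", 0.6)   # S0 = 1, F0 = 2
#' @export
successFailureCounts <- function(results, criterion, cutoff = 0.6) {
  auc <- results$auc[results$criterion == criterion]
  if (length(auc) == 0)
    stop(sprintf("no result cells for criterion '%s'", criterion))
  if (anyNA(auc)) {
    warning(sprintf("dropping %d failed cell(s) for criterion '%s'",
                    sum(is.na(auc)), criterion))
    auc <- auc[!is.na(auc)]
    if (length(auc) == 0)
      stop(sprintf("no successful cells for criterion '%s'", criterion))
  }
  c(S0 = sum(auc > cutoff), F0 = sum(auc <= cutoff))
}

#' Chi-squared goodness of fit of a success/failure profile
#'
#' Compares observed success/failure counts against the expected split
#' under a fixed success probability (default 75% success / 25% failure):
#' `Se = p * n`, `Fe = (1 - p) * n`, chi2 = (S0 - Se)^2 / Se +
#' (F0 - Fe)^2 / Fe on 1 degree of freedom, plus the absolute residuals
#' (|Se - S0|, |Fe - F0|). The test is delegated to
#' [stats::chisq.test()] (no continuity correction is applied to a
#' goodness-of-fit test).
#'
#' @param counts numeric vector `c(S0, F0)` of observed successes and
#'   failures (as from [successFailureCounts()]).
#' @param pSuccess expected success probability (default 0.75).
#' @return list of class `"gofTest"`: `S0`, `F0`, `Se`, `Fe`,
#'   `statistic` (chi2), `df`, `p.value`, `residuals`
#'   (`c(success = |Se - S0|, failure = |Fe - F0|)`), `pSuccess`.
#' @examples
#' gofTest(c(6, 3))   # chi2 = 1/3, residuals (0.75, 0.75)
#' @export
gofTest <- function(counts, pSuccess = 0.75) {
  stopifnot(length(counts) == 2, all(counts >= 0))
  if (pSuccess <= 0 || pSuccess >= 1) stop("pSuccess must be in (0, 1)")
  n <- sum(counts)
  if (n < 1) stop("at least one observed cell is required")
  S0 <- counts[[1]]
  F0 <- counts[[2]]
  Se <- pSuccess * n
  Fe <- (1 - pSuccess) * n
  ct <- suppressWarnings(
    stats::chisq.test(c(S0, F0), p = c(pSuccess, 1 - pSuccess)))
  out <- list(S0 = S0, F0 = F0, Se = Se, Fe = Fe,
              statistic = unname(ct$statistic), df = 1L,
              p.value = unname(ct$p.value),
              residuals = c(success = abs(Se - S0), failure = abs(Fe - F0)),
              pSuccess = pSuccess)
  class(out) <- "gofTest"
  out
}

#' @export
print.gofTest <- function(x, ...) {
  cat("Chi-squared goodness of fit of the success/failure profile\n")
  cat(sprintf("  observed: S0 = %g, F0 = %g; expected (p = %g): Se = %g, Fe = %g\n",
              x$S0, x$F0, x$pSuccess, x$Se, x$Fe))
  cat(sprintf("  chi2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  cat(sprintf("  residuals: |Se - S0| = %g, |Fe - F0| = %g\n",
              x$residuals["success"], x$residuals["failure"]))
  invisible(x)
}

#' Pairwise criterion comparison of success/failure profiles
#'
#' The evaluation applied to each criterion pair: at each AUC cutoff, the
#' success/failure counts of both criteria are tested one at a time
#' against the 75/25 expectation ([gofTest()]) and reported jointly with
#' both residual pairs.
#'
#' @param results a result table from [runExperiment()].
#' @param criterionA,criterionB the two criteria to compare (e.g.
#'   `"COMB"` and `"NCOMB"`).
#' @param cutoffs AUC success cutoffs (default 0.60 and 0.80).
#' @inheritParams gofTest
#' @return data.frame with one row per (cutoff, criterion): `comparison`,
#'   `cutoff`, `criterion`, `S0`, `F0`, `chi2`, `p.value`,
#'   `res_success`, `res_failure`.
#' @export
compareCriteria <- function(results, criterionA, criterionB,
                            cutoffs = c(0.6, 0.8), pSuccess = 0.75) {
  comparison <- paste0(criterionA, "-", criterionB)
  rows <- lapply(cutoffs, function(cut) {
    do.call(rbind, lapply(c(criterionA, criterionB), function(cr) {
      g <- gofTest(successFailureCounts(results, cr, cut), pSuccess)
      data.frame(comparison = comparison, cutoff = cut, criterion = cr,
                 S0 = g$S0, F0 = g$F0, chi2 = g$statistic,
                 p.value = g$p.value,
                 res_success = unname(g$residuals["success"]),
                 res_failure = unname(g$residuals["failure"]),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Mean AUC and standard error per criterion
#'
#' Aggregates the result table over all (dataset, task) cells of each
#' criterion: the mean AUC and the standard error of the mean
#' (sd / sqrt(n)). With fewer than two cells the SEM is undefined and
#' reported as `NA`.
#'
#' @param results a result table from [runExperiment()].
#' @return data.frame with columns `criterion`, `n`, `mean_auc`, `sem`.
#' @export
summarizeByCriterion <- function(results) {
  ok <- !is.na(results$auc)
  sp <- split(results$auc[ok], results$criterion[ok])
  out <- data.frame(
    criterion = names(sp),
    n = vapply(sp, length, integer(1)),
    mean_auc = vapply(sp, mean, numeric(1)),
    sem = vapply(sp, function(v)
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v)),
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$criterion), , drop = FALSE]
}
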
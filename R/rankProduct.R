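## Two-sample rank product (Breitling-style): for every one of the
## K = n_control * n_case pairwise case-vs-control comparisons, genes are
## ranked by fold change in the requested direction (rank 1 = strongest);
## RP is the geometric mean of a gene's K ranks. Significance is
## estimated by permuting class labels.

.checkTwoClass <- function(expr, labels) {
  if (anyNA(expr))
    stop("expression matrix must not contain missing values")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must contain exactly two classes (control first level, case second)")
  if (any(table(labels) < 2))
    stop("at least two samples per class are required")
  if (length(labels) != ncol(expr))
    stop("labels must be parallel to the matrix columns")
  labels
}

## fold-change matrix over all pairwise case-vs-control comparisons,
## genes x K, K = n0 * n1
.pairwiseFC <- function(expr, ctrlIdx, caseIdx) {
  expr[, rep(caseIdx, each = length(ctrlIdx)), drop = FALSE] -
    expr[, rep(ctrlIdx, times = length(caseIdx)), drop = FALSE]
}

## per-comparison ranks for both directions; average ranks on ties.
## rank(-x) with average ties equals n + 1 - rank(x), so both directions
## come from one ranking pass (done in compiled code: this is the hot
## loop of the permutation analysis).
.rpBoth <- function(expr, ctrlIdx, caseIdx) {
  fc <- .pairwiseFC(expr, ctrlIdx, caseIdx)
  lm <- .rpLogRankMeans(fc)
  list(up = exp(lm$up), down = exp(lm$down))
}

#' Rank product of a two-class expression matrix
#'
#' Computes, per gene, the geometric mean of its fold-change ranks over
#' all pairwise case-vs-control sample comparisons. Ranks are ascending
#' in the requested direction (rank 1 = largest case-minus-control fold
#' change for `direction = "up"`), so smaller rank products indicate
#' stronger, more consistent regulation; the attainable minimum is 1.
#' Ties receive average ranks.
#'
#' @param expr numeric genes x samples matrix of log2 expression values,
#'   no missing values.
#' @param labels two-class factor (or coercible) parallel to the columns;
#'   the first level is the control class, the second the case class.
#' @param direction `"up"` or `"down"`: rank by case-over-control
#'   up-regulation or down-regulation.
#' @return Named numeric vector of rank products (>= 1), one per gene.
#' @examples
#' m <- matrix(c(5, 5, 8, 8,  7, 7, 7, 7), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
#' rankProduct(m, c("ctrl", "ctrl", "case", "case"), "up")
#' @seealso [estimatePfp()] for permutation significance,
#'   [rankProductDE()] for the full per-cohort analysis.
#' @export
rankProduct <- function(expr, labels, direction = c("up", "down")) {
  direction <- match.arg(direction)
  expr <- as.matrix(expr)
  labels <- .checkTwoClass(expr, labels)
  ctrlIdx <- which(labels == levels(labels)[1])
  caseIdx <- which(labels == levels(labels)[2])
  rp <- .rpBoth(expr, ctrlIdx, caseIdx)[[direction]]
  names(rp) <- rownames(expr)
  rp
}

## all control-index subsets (exhaustive label reassignments) if the
## space is small, otherwise NULL
.exhaustiveAssignments <- function(n, n0, limit = 10000) {
  if (choose(n, n0) > limit) return(NULL)
  utils::combn(n, n0, simplify = FALSE)
}

#' Permutation significance for rank products
#'
#' Estimates, for each gene and direction, the percentage of false
#' predictions (pfp) and a pooled permutation p-value by recomputing the
#' rank product under label permutations. For gene g with observed rank
#' product RP_g, let c_g be the average number of genes per permutation
#' whose permuted rank product is <= RP_g. Then `pfp = c_g / r_g`, with
#' r_g the position of g in the observed RP ranking (made monotone
#' non-decreasing along the ranking), and `pval = c_g / n_genes`, the
#' pooled estimate of how often a null gene scores at least as well.
#' When the label-assignment space has at most `exhaustiveLimit`
#' configurations it is enumerated exhaustively; otherwise `nPerm` random
#' permutations are drawn (reproducibly from `seed`).
#'
#' @inheritParams rankProduct
#' @param nPerm number of random label permutations (>= 1) used when the
#'   space is too large to enumerate.
#' @param seed integer seed for the random permutations.
#' @param exhaustiveLimit enumerate exhaustively whenever the number of
#'   distinct label assignments is at most this.
#' @return A data.frame with one row per gene: `gene_id`, `rp_up`,
#'   `pfp_up`, `pval_up`, `rp_down`, `pfp_down`, `pval_down`, plus an
#'   attribute `exhaustive` (logical) and `nPermUsed`.
#' @export
estimatePfp <- function(expr, labels, nPerm = 100L, seed = 1L,
                        exhaustiveLimit = 10000) {
  expr <- as.matrix(expr)
  labels <- .checkTwoClass(expr, labels)
  if (nPerm < 1) stop("nPerm must be at least 1")
  G <- nrow(expr)
  n <- ncol(expr)
  ctrlIdx <- which(labels == levels(labels)[1])
  caseIdx <- which(labels == levels(labels)[2])
  n0 <- length(ctrlIdx)

  obs <- .rpBoth(expr, ctrlIdx, caseIdx)

  assignments <- .exhaustiveAssignments(n, n0, exhaustiveLimit)
  exhaustive <- !is.null(assignments)
  if (!exhaustive) {
    set.seed(as.integer(seed))
    assignments <- replicate(nPerm, sample.int(n, n0), simplify = FALSE)
  }
  nUsed <- length(assignments)

  ## rank products are compared after rounding to 10 decimals so that
  ## ties between algebraically equal values (computed along different
  ## floating-point paths) are counted consistently
  obsUp <- round(obs$up, 10)
  obsDown <- round(obs$down, 10)
  countUp <- countDown <- numeric(G)
  for (a in assignments) {
    star <- .rpBoth(expr, a, setdiff(seq_len(n), a))
    countUp <- countUp + findInterval(obsUp, sort(round(star$up, 10)))
    countDown <- countDown +
      findInterval(obsDown, sort(round(star$down, 10)))
  }
  cUp <- countUp / nUsed
  cDown <- countDown / nUsed

  pfpOf <- function(rp, cc) {
    r <- rank(rp, ties.method = "max")
    raw <- cc / r
    ord <- order(rp)
    out <- raw
    out[ord] <- cummax(raw[ord])      # monotone along the RP ranking
    pmax(out, 0)
  }
  res <- data.frame(
    gene_id = if (is.null(rownames(expr))) sprintf("g%d", seq_len(G))
              else rownames(expr),
    rp_up = obs$up, pfp_up = pfpOf(obsUp, cUp), pval_up = cUp / G,
    rp_down = obs$down, pfp_down = pfpOf(obsDown, cDown),
    pval_down = cDown / G,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "exhaustive") <- exhaustive
  attr(res, "nPermUsed") <- nUsed
  res
}

#' Per-cohort rank-product differential expression
#'
#' Runs [rankProduct()] and [estimatePfp()] on the two stage groups of a
#' progression task within one expression cohort and packages the result
#' for selection and cross-cohort intersection.
#'
#' @param cohort an [ExpressionCohort].
#' @param task a [progressionTask()]; samples of the control and case
#'   stages are used, control as the reference class.
#' @param alpha significance cutoff stored with the result (see
#'   [selectDE()]).
#' @inheritParams estimatePfp
#' @return A `DEResult` object; see [selectDE()].
#' @aliases DEResult-class
#' @export
rankProductDE <- function(cohort, task, alpha = 0.01, nPerm = 100L,
                          seed = 1L, exhaustiveLimit = 10000) {
  stopifnot(is(cohort, "ExpressionCohort"), is(task, "ProgressionTask"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  keep <- stages(cohort) %in% c(task@control, task@case)
  if (!any(stages(cohort) == task@control) ||
      !any(stages(cohort) == task@case))
    stop(sprintf("cohort %s lacks samples for task %s",
                 cohortName(cohort), taskLabel(task)))
  expr <- assay(cohort, "exprs")[, keep, drop = FALSE]
  labels <- factor(stages(cohort)[keep],
                   levels = c(task@control, task@case))
  tab <- estimatePfp(expr, labels, nPerm = nPerm, seed = seed,
                     exhaustiveLimit = exhaustiveLimit)
  new("DEResult", table = tab, alpha = alpha, task = task,
      cohort = cohortName(cohort),
      exhaustive = attr(tab, "exhaustive"),
      nPerm = as.integer(attr(tab, "nPermUsed")))
}

setClass("DEResult",
         representation(table = "data.frame", alpha = "numeric",
                        task = "ProgressionTask", cohort = "character",
                        exhaustive = "logical", nPerm = "integer"))

setMethod("show", "DEResult", function(object) {
  sel <- selectDE(object)
  cat(sprintf("DEResult: cohort %s, task %s (%d genes)\n",
              object@cohort, taskLabel(object@task), nrow(object@table)))
  cat(sprintf("  significance: %s, %d label assignment(s), alpha = %g\n",
              if (object@exhaustive) "exhaustive" else "permutation",
              object@nPerm, object@alpha))
  cat(sprintf("  selected: %d up-regulated, %d down-regulated\n",
              length(sel$up), length(sel$down)))
})

#' Select up/down-regulated genes from a DE result
#'
#' Applies the significance cutoff `alpha` to a [rankProductDE()] result
#' and returns the selected gene sets. By default the cutoff is applied
#' to the pooled permutation p-value, the calibrated quantity (a fraction
#' `alpha` of null genes passes it on average); `method = "pfp"` applies
#' it to the estimated percentage of false predictions instead, which is
#' far more conservative under the null.
#'
#' @param de a `DEResult`.
#' @param alpha cutoff in (0, 1]; defaults to the value stored in `de`.
#' @param method `"pval"` (default) or `"pfp"`.
#' @return list with character vectors `up` and `down`.
#' @export
selectDE <- function(de, alpha = de@alpha, method = c("pval", "pfp")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  tab <- de@table
  up <- tab[[paste0(method, "_up")]]
  down <- tab[[paste0(method, "_down")]]
  list(up = tab$gene_id[up < alpha], down = tab$gene_id[down < alpha])
}

#' Intersect differential-expression calls across cohorts
#'
#' A gene is retained only if it is called in the same direction in every
#' cohort: the up-sets are intersected with up-sets and down-sets with
#' down-sets, following the rule that differential expression must be
#' supported by all input datasets.
#'
#' @param sets list (length >= 2) of per-cohort selections, each a list
#'   with character vectors `up` and `down` (as from [selectDE()]).
#' @return list with character vectors `up` and `down`.
#' @examples
#' intersectCohortSets(list(list(up = c("A", "B"), down = "X"),
#'                          list(up = c("B", "C"), down = c("X", "Y"))))
#' @export
intersectCohortSets <- function(sets) {
  if (length(sets) == 0) stop("at least one cohort selection is required")
  if (length(sets) < 2)
    stop("cross-cohort intersection needs selections from at least two cohorts")
  list(up = Reduce(intersect, lapply(sets, `[[`, "up")),
       down = Reduce(intersect, lapply(sets, `[[`, "down")))
}
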
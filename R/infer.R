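#' Evaluation criteria
#'
#' The six representation criteria compared by the pipeline, one per
#' factor level: `NCOMB` uses the standard (SA) datatype, i.e. expression
#' of the differentially expressed genes; `COMB` the combined (COMB)
#' datatype, i.e. expression of the signature genes (DE and copy-number
#' altered); and `COMBDE`, `COMBDM`, `COMBDK`, `COMBDT` the relational
#' (RA) datatype, i.e. patients-to-prototypes dissimilarities over the
#' signature genes under the Euclidean, Manhattan, Kullback-Leibler and
#' Kendall-tau dissimilarity respectively.
#'
#' @return data.frame with columns `criterion`, `datatype`
#'   (`SA`/`COMB`/`RA`) and `metric` (RA rows only).
#' @export
progressionCriteria <- function() {
  data.frame(
    criterion = c("NCOMB", "COMB", "COMBDE", "COMBDM", "COMBDK", "COMBDT"),
    datatype = c("SA", "COMB", "RA", "RA", "RA", "RA"),
    metric = c(NA, NA, "euclidean", "manhattan", "kl", "kendall_tau"),
    stringsAsFactors = FALSE)
}

.criterionInfo <- function(name) {
  tab <- progressionCriteria()
  i <- match(name, tab$criterion)
  if (is.na(i)) stop(sprintf("unknown criterion '%s'", name))
  tab[i, ]
}

## rank-based AUC (equals the trapezoidal ROC area with average-tie
## handling): probability that a random case scores above a random
## control, counting ties as 1/2
.aucScore <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

## seed-reproducible stratified fold assignment: each class's samples
## are shuffled and dealt round-robin over the folds
.stratifiedFolds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

## decision scores oriented so that larger means "case" (label 1),
## regardless of the sign convention libsvm picked for this fit
.decisionScores <- function(model, newx) {
  dv <- attr(stats::predict(model, newx, decision.values = TRUE),
             "decision.values")
  positiveFirst <- startsWith(colnames(dv)[1], "1")
  if (positiveFirst) dv[, 1] else -dv[, 1]
}

#' Grid-optimized cross-validated SVM AUC
#'
#' Reproduces the optimization protocol of the inference workflow: for
#' every cost value of the linear grid, a linear-kernel SVM is assessed
#' by k-fold stratified cross-validation (AUC computed from
#' decision-function scores within each test fold, then averaged over
#' folds), and the maximum AUC over the grid is reported together with
#' the achieving cost. With the default [svmGrid()] this evaluates
#' exactly 1101 models. Note the reported value is the grid-maximal CV
#' AUC - deliberately the original (optimistically biased) protocol, not
#' a nested-CV estimate.
#'
#' Features are standardized within each training fold (means/sds from
#' the training samples only) before fitting.
#'
#' @param x numeric samples x features matrix.
#' @param y 0/1 labels (0 = control, 1 = case), parallel to the rows.
#' @param grid an [svmGrid()].
#' @param k number of cross-validation folds (default 10); reduced to
#'   the smallest class size when that is smaller.
#' @param seed integer seed fixing the fold assignment.
#' @return list: `auc` (best cross-validated AUC), `bestC`, `aucByC`
#'   (named vector over the grid), `nModels`, `k`.
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(60), 30, 2)
#' y <- rep(c(0, 1), each = 15)
#' evaluateAUC(x, y, grid = svmGrid(1, 10, 4L), k = 5)
#' @export
evaluateAUC <- function(x, y, grid = svmGrid(), k = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("both classes must be present")
  stopifnot(length(y) == nrow(x), all(y %in% c(0L, 1L)))
  k <- max(2L, min(as.integer(k), min(table(y))))
  folds <- .stratifiedFolds(y, k, seed)
  yf <- factor(y, levels = c(0L, 1L))

  ## precompute per-fold standardized splits once; reused for every C
  splits <- lapply(seq_len(k), function(f) {
    tr <- folds != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv < 1e-8] <- 1
    list(xtr = scale(x[tr, , drop = FALSE], mu, sdv),
         xte = scale(x[!tr, , drop = FALSE], mu, sdv),
         ytr = yf[tr], yte = y[!tr])
  })

  aucByC <- vapply(grid@cValues, function(C) {
    fold <- vapply(splits, function(s) {
      model <- e1071::svm(s$xtr, s$ytr, kernel = "linear", cost = C,
                          scale = FALSE, type = "C-classification")
      .aucScore(.decisionScores(model, s$xte), s$yte)
    }, numeric(1))
    mean(fold, na.rm = TRUE)
  }, numeric(1))
  names(aucByC) <- sprintf("C=%g", grid@cValues)

  best <- which.max(aucByC)
  list(auc = unname(aucByC[best]), bestC = grid@cValues[best],
       aucByC = aucByC, nModels = length(aucByC), k = k)
}

#' Feature extraction per criterion
#'
#' Builds the feature matrix and 0/1 labels for one (cohort, criterion,
#' task) cell: `SA` uses the expression of the cross-cohort
#' differentially expressed genes, `COMB` the expression of the combined
#' signature genes, and `RA` the rows of the patients-to-prototypes
#' dissimilarity matrix over the signature genes. Prototypes are the
#' cohort's samples of the prototype stage; for tasks whose control group
#' is the prototype stage, control patients keep their rows (including
#' the structural zero at their own prototype column).
#'
#' @param cohort an [ExpressionCohort] providing the evaluation patients.
#' @param criterion criterion name, see [progressionCriteria()].
#' @param task a [progressionTask()].
#' @param deSets list with `up` and `down` gene id vectors (cross-cohort
#'   DE selection; required for `NCOMB`).
#' @param signature a [CombinedSignature-class] (required for all other
#'   criteria).
#' @param prototypeStage stage of the prototype group (default `"II"`).
#' @return list: `x` (samples x features matrix), `y` (0/1 labels),
#'   `features` (gene ids or prototype ids).
#' @export
extractFeatures <- function(cohort, criterion, task, deSets = NULL,
                            signature = NULL, prototypeStage = "II") {
  stopifnot(is(cohort, "ExpressionCohort"), is(task, "ProgressionTask"))
  info <- .criterionInfo(criterion)
  keep <- stages(cohort) %in% c(task@control, task@case)
  if (sum(stages(cohort) == task@control) == 0 ||
      sum(stages(cohort) == task@case) == 0)
    stop(sprintf("cohort %s lacks samples for task %s",
                 cohortName(cohort), taskLabel(task)))
  y <- as.integer(stages(cohort)[keep] == task@case)

  if (info$datatype == "SA") {
    genes <- union(deSets$up, deSets$down)
    if (length(genes) == 0)
      stop("differential-expression selection produced an empty gene set")
    x <- t(assay(cohort, "exprs")[genes, keep, drop = FALSE])
    feats <- genes
  } else {
    if (is.null(signature) || length(signatureGenes(signature)) == 0)
      stop("the combined signature is empty; nothing to represent")
    genes <- signatureGenes(signature)
    sub <- assay(cohort, "exprs")[genes, keep, drop = FALSE]
    if (info$datatype == "COMB") {
      x <- t(sub)
      feats <- genes
    } else {
      protos <- selectPrototypes(cohort, stage = prototypeStage,
                                 signature = genes)
      D <- dissimilarityMatrix(sub, protos, metric = info$metric)
      x <- D@.Data
      feats <- colnames(x)
    }
  }
  list(x = x, y = y, features = feats)
}

#' Full factorial AUC experiment
#'
#' Evaluates every (criterion, dataset, task) cell: features are
#' extracted per [extractFeatures()] and scored with the grid-optimized
#' cross-validated SVM of [evaluateAUC()]. Cell failures (e.g. an empty
#' signature) are recorded in the `error` column and the run continues.
#'
#' @param datasets named list of [ExpressionCohort] objects (the
#'   validation datasets).
#' @param deSetsByTask named list (by [taskLabel()]) of cross-cohort DE
#'   selections, each a list with `up`/`down`.
#' @param signaturesByTask named list (by [taskLabel()]) of
#'   [CombinedSignature-class] objects.
#' @param tasks list of [progressionTask()]s (default the three
#'   stage-pair tasks).
#' @param criteria criterion names (default all six).
#' @inheritParams evaluateAUC
#' @inheritParams extractFeatures
#' @return data.frame (the result table): one row per cell with columns
#'   `criterion`, `dataset`, `task`, `auc`, `best_C`, `n_models`,
#'   `error`.
#' @export
runExperiment <- function(datasets, deSetsByTask, signaturesByTask,
                          tasks = defaultTasks(),
                          criteria = progressionCriteria()$criterion,
                          grid = svmGrid(), k = 10L, seed = 1L,
                          prototypeStage = "II") {
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, cohortName, character(1))
  cells <- expand.grid(criterion = criteria, dataset = names(datasets),
                       task = vapply(tasks, taskLabel, character(1)),
                       stringsAsFactors = FALSE)
  taskByLabel <- stats::setNames(tasks, vapply(tasks, taskLabel,
                                               character(1)))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    out <- data.frame(cell, auc = NA_real_, best_C = NA_real_,
                      n_models = NA_integer_, error = NA_character_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      feats <- extractFeatures(datasets[[cell$dataset]], cell$criterion,
                               taskByLabel[[cell$task]],
                               deSets = deSetsByTask[[cell$task]],
                               signature = signaturesByTask[[cell$task]],
                               prototypeStage = prototypeStage)
      evaluateAUC(feats$x, feats$y, grid = grid, k = k, seed = seed)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
      warning(sprintf("cell (%s, %s, %s) failed: %s", cell$criterion,
                      cell$dataset, cell$task, out$error), call. = FALSE)
    } else {
      out$auc <- res$auc
      out$best_C <- res$bestC
      out$n_models <- res$nModels
    }
    out
  })
  do.call(rbind, rows)
}

#' End-to-end study: from cohorts to the result table
#'
#' Runs the complete pipeline on a set of cohorts: per-task signatures
#' via [buildSignature()] (differential expression on `deCohorts`,
#' recurrence over the CNA cohorts), then the full factorial AUC
#' experiment of [runExperiment()] on the validation datasets.
#'
#' @param exprCohorts named list of [ExpressionCohort]s; all serve as
#'   validation datasets.
#' @param cnaCohorts list of [CNACohort]s.
#' @param deCohorts indices/names of the expression cohorts used for
#'   differential expression (default: all of them).
#' @param evalCohorts indices/names of the expression cohorts used as
#'   validation datasets (default: all of them).
#' @inheritParams buildSignature
#' @inheritParams runExperiment
#' @return list: `results` (the result table), `signatures`, `deSets`
#'   (both by task label).
#' @export
runStudy <- function(exprCohorts, cnaCohorts,
                     deCohorts = seq_along(exprCohorts),
                     evalCohorts = seq_along(exprCohorts),
                     tasks = defaultTasks(),
                     criteria = progressionCriteria()$criterion,
                     alpha = 0.01, deMethod = c("pval", "pfp"),
                     nPerm = 100L, gainThr = 0.3, lossThr = -0.3,
                     minFreq = 0.25, minDatasets = 2L,
                     grid = svmGrid(), k = 10L, seed = 1L,
                     prototypeStage = "II") {
  deMethod <- match.arg(deMethod)
  labels <- vapply(tasks, taskLabel, character(1))
  sigs <- lapply(tasks, function(task)
    buildSignature(exprCohorts[deCohorts], cnaCohorts, task,
                   alpha = alpha, deMethod = deMethod, nPerm = nPerm,
                   seed = seed, gainThr = gainThr, lossThr = lossThr,
                   minFreq = minFreq, minDatasets = minDatasets))
  names(sigs) <- labels
  deSets <- lapply(sigs, `[[`, "de")
  signatures <- lapply(sigs, `[[`, "signature")
  results <- runExperiment(exprCohorts[evalCohorts], deSets, signatures,
                           tasks = tasks, criteria = criteria,
                           grid = grid, k = k, seed = seed,
                           prototypeStage = prototypeStage)
  list(results = results, signatures = signatures, deSets = deSets)
}
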
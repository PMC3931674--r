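#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.STAGES <- c("II", "III", "IV")

.validStageCohort <- function(object, assayName) {
  msg <- NULL
  if (!assayName %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, sprintf("assay '%s' is required", assayName))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique gene identifiers (rownames) are required")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "unique sample identifiers (colnames) are required")
  if (!"stage" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain a 'stage' column")
  } else if (!all(as.character(object$stage) %in% .STAGES)) {
    msg <- c(msg, sprintf("stage labels must be one of %s",
                          paste(.STAGES, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
}

#' Cohort containers for staged tumor profiles
#'
#' `ExpressionCohort` holds a genes x samples matrix of log2 expression
#' summaries; `CNACohort` holds a genes x samples matrix of tumor-vs-normal
#' copy-number log2 ratios. Both extend
#' [SummarizedExperiment::SummarizedExperiment] and require a `stage`
#' column (II, III or IV) in their `colData` plus unique gene and sample
#' identifiers.
#'
#' @param exprs,logratio numeric genes x samples matrix with rownames
#'   (gene ids) and colnames (sample ids).
#' @param stage character vector of per-sample stages (II/III/IV),
#'   parallel to the matrix columns.
#' @param name single string naming the cohort.
#'
#' @return An `ExpressionCohort` or `CNACohort` object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ec <- ExpressionCohort(m, stage = c("II", "II", "III", "III", "IV"))
#' stages(ec)
#' @aliases CNACohort ExpressionCohort-class CNACohort-class
#' @export
ExpressionCohort <- function(exprs, stage, name = "cohort") {
  se <- SummarizedExperiment(
    assays = list(exprs = as.matrix(exprs)),
    colData = DataFrame(stage = as.character(stage),
                        cohort = name,
                        row.names = colnames(exprs)))
  new("ExpressionCohort", se)
}

setClass("ExpressionCohort", contains = "SummarizedExperiment")
setValidity("ExpressionCohort", function(object)
  .validStageCohort(object, "exprs"))

setClass("CNACohort", contains = "SummarizedExperiment")
setValidity("CNACohort", function(object)
  .validStageCohort(object, "logratio"))

#' @rdname ExpressionCohort
#' @export
CNACohort <- function(logratio, stage, name = "cohort") {
  se <- SummarizedExperiment(
    assays = list(logratio = as.matrix(logratio)),
    colData = DataFrame(stage = as.character(stage),
                        cohort = name,
                        row.names = colnames(logratio)))
  new("CNACohort", se)
}

#' Control-vs-case stage comparison
#'
#' A progression inference task: classify patients of the `control`
#' (lower) stage against patients of the `case` (higher) stage; controls
#' are labeled 0 and cases 1. The three default tasks are II-vs-III,
#' II-vs-IV and III-vs-IV.
#'
#' @param control,case stage labels among II, III, IV; `control` must
#'   strictly precede `case` in the II < III < IV ordering.
#' @return A `ProgressionTask` object.
#' @examples
#' progressionTask("II", "III")
#' defaultTasks()
#' @aliases ProgressionTask-class
#' @export
progressionTask <- function(control, case) {
  new("ProgressionTask", control = control, case = case)
}

setClass("ProgressionTask",
         representation(control = "character", case = "character"))

setValidity("ProgressionTask", function(object) {
  msg <- NULL
  if (!object@control %in% .STAGES || !object@case %in% .STAGES)
    msg <- c(msg, "stages must be II, III or IV")
  else if (match(object@control, .STAGES) >= match(object@case, .STAGES))
    msg <- c(msg, "control stage must strictly precede the case stage")
  if (is.null(msg)) TRUE else msg
})

#' @rdname progressionTask
#' @export
defaultTasks <- function() {
  list(progressionTask("II", "III"),
       progressionTask("II", "IV"),
       progressionTask("III", "IV"))
}

#' @rdname progressionTask
#' @param task a `ProgressionTask`.
#' @export
taskLabel <- function(task) paste0(task@control, "vs", task@case)

#' Combined expression/copy-number gene signature
#'
#' The per-task signature: genes up-regulated with recurrent copy-number
#' gain (`upAmplified`) and genes down-regulated with recurrent loss
#' (`downDeleted`). Constructed by [combineSignature()].
#'
#' @aliases CombinedSignature-class signatureGenes
#' @export signatureGenes
setClass("CombinedSignature",
         representation(task = "ProgressionTask",
                        upAmplified = "character",
                        downDeleted = "character"))

setValidity("CombinedSignature", function(object) {
  if (length(intersect(object@upAmplified, object@downDeleted)) > 0)
    "upAmplified and downDeleted must be disjoint"
  else TRUE
})

#' All genes of a signature (up-amplified then down-deleted)
#' @param signature a `CombinedSignature`.
#' @rdname CombinedSignature-class
signatureGenes <- function(signature)
  c(signature@upAmplified, signature@downDeleted)

#' Prototype patient set
#'
#' The reference patient group (lowest available stage) whose
#' signature-gene expression profiles anchor the dissimilarity
#' representation. `profiles` is a genes x n matrix, one column per
#' prototype patient, in stable cohort order.
#'
#' @aliases PrototypeSet-class
#' @export
setClass("PrototypeSet",
         representation(profiles = "matrix", stage = "character"))

setValidity("PrototypeSet", function(object) {
  msg <- NULL
  if (ncol(object@profiles) < 1)
    msg <- c(msg, "at least one prototype patient is required")
  if (is.null(colnames(object@profiles)))
    msg <- c(msg, "prototype patient ids (colnames) are required")
  if (is.null(msg)) TRUE else msg
})

#' Patients-to-prototypes dissimilarity matrix
#'
#' An N x n nonnegative matrix: rows index evaluation patients, columns
#' index prototype patients, entry (i, j) is the dissimilarity between
#' patient i and prototype j over the signature genes under `metric`.
#'
#' @aliases DissimilarityMatrix-class
#' @export
setClass("DissimilarityMatrix", contains = "matrix",
         representation(metric = "character"))

setValidity("DissimilarityMatrix", function(object) {
  if (any(!is.finite(object@.Data)) || any(object@.Data < 0))
    "dissimilarities must be finite and nonnegative"
  else TRUE
})

#' Linear C grid for SVM optimization
#'
#' The cost grid over which cross-validated AUC is maximized: an evenly
#' spaced sequence of `cSteps + 1` values from `cMin` to `cMax`. The
#' printed protocol starts the grid at a non-positive value; grid points
#' at or below zero are clamped to `floorC` (SVM cost must be positive)
#' but retain their place so the advertised model count is preserved.
#'
#' @param cMin,cMax grid end points.
#' @param cSteps number of steps; the grid has `cSteps + 1` points.
#' @param floorC positive replacement for non-positive grid values.
#' @return An `SVMGrid` object; `nModels()` gives the number of grid
#'   points (models evaluated per optimization).
#' @examples
#' g <- svmGrid()
#' nModels(g)   # 1101
#' @aliases SVMGrid-class nModels
#' @export svmGrid
#' @export nModels
svmGrid <- function(cMin = -10, cMax = 10000, cSteps = 1100L,
                    floorC = 1e-3) {
  stopifnot(cMax > cMin, cSteps >= 1, floorC > 0)
  cValues <- seq(cMin, cMax, length.out = cSteps + 1)
  cValues[cValues <= 0] <- floorC
  new("SVMGrid", cValues = cValues, cMin = cMin, cMax = cMax,
      cSteps = as.integer(cSteps))
}

setClass("SVMGrid",
         representation(cValues = "numeric", cMin = "numeric",
                        cMax = "numeric", cSteps = "integer"))

setValidity("SVMGrid", function(object) {
  msg <- NULL
  if (length(object@cValues) != object@cSteps + 1L)
    msg <- c(msg, "grid point count must equal cSteps + 1")
  if (any(object@cValues <= 0))
    msg <- c(msg, "all cost values must be positive after clamping")
  if (is.null(msg)) TRUE else msg
})

#' @rdname svmGrid
#' @param grid an `SVMGrid`.
nModels <- function(grid) length(grid@cValues)

## ---- show methods ----------------------------------------------------

setMethod("show", "ProgressionTask", function(object) {
  cat(sprintf("ProgressionTask: stage %s (control, 0) vs stage %s (case, 1)\n",
              object@control, object@case))
})

setMethod("show", "CombinedSignature", function(object) {
  cat(sprintf("CombinedSignature for task %s\n", taskLabel(object@task)))
  cat(sprintf("  up-regulated & amplified: %d gene(s)\n",
              length(object@upAmplified)))
  cat(sprintf("  down-regulated & deleted: %d gene(s)\n",
              length(object@downDeleted)))
})

setMethod("show", "PrototypeSet", function(object) {
  cat(sprintf("PrototypeSet: %d stage-%s patient(s) over %d signature gene(s)\n",
              ncol(object@profiles), object@stage, nrow(object@profiles)))
})

setMethod("show", "SVMGrid", function(object) {
  cat(sprintf("SVMGrid: %d linear-kernel cost values in [%g, %g]\n",
              nModels(object), min(object@cValues), max(object@cValues)))
})

setMethod("show", "DissimilarityMatrix", function(object) {
  cat(sprintf("DissimilarityMatrix (%s): %d patient(s) x %d prototype(s)\n",
              object@metric, nrow(object), ncol(object)))
  if (nrow(object) > 0)
    print(utils::head(object@.Data, 4))
})

## ---- accessors -------------------------------------------------------

#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' Per-sample stage labels of a cohort
#' @param x an `ExpressionCohort` or `CNACohort`.
#' @return character vector of stages, one per sample.
#' @rdname ExpressionCohort
#' @aliases stages
#' @exportMethod stages
setMethod("stages", "SummarizedExperiment",
          function(x) as.character(x$stage))

#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))

#' @rdname ExpressionCohort
#' @aliases cohortName
#' @exportMethod cohortName
setMethod("cohortName", "SummarizedExperiment",
          function(x) unique(as.character(x$cohort)))
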
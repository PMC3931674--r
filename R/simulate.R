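#' Configuration of the synthetic multi-cohort study
#'
#' Defines the generative conditions for a synthetic colorectal-cancer
#' progression study: several expression cohorts and several copy-number
#' cohorts sharing one gene universe, with a planted subset of genes that
#' are concurrently differentially expressed and copy-number altered
#' (`nUpAmplified` gained/up-regulated, `nDownDeleted` lost/down-regulated),
#' plus expression-only (`nDeOnly`), copy-number-only (`nCnaOnly`) and
#' null genes.
#'
#' Expression is simulated directly at the log2 summary level: per-gene
#' baselines are uniform on [4, 12] log2 units, cohorts receive per-gene
#' additive batch offsets (`batchSd`), and samples receive i.i.d. noise
#' (`noiseSd`). Copy-number alterations are penetrance-controlled: each
#' case-stage (III/IV) sample carries a planted alteration with
#' probability `cnaPenetrance`, and for the coupled (up-amplified /
#' down-deleted) genes the expression shift is applied only in carrier
#' samples, modeling gene dosage. Shifts grow linearly with stage:
#' `deEffect` log2 units per stage step above II. Copy-number log2 ratios
#' are centered at 0 (neutral) or at +/- `cnaEffect` (carrier), with
#' noise `cnaNoiseSd` (array log ratios are much less dispersed than
#' expression values, hence the separate field).
#'
#' @param nExpressionCohorts,nCnaCohorts number of cohorts of each kind.
#' @param nGenes size of the gene universe.
#' @param samplesPerStage named count vector (`II`, `III`, `IV`) applied
#'   to every cohort.
#' @param nUpAmplified,nDownDeleted,nDeOnly,nCnaOnly planted class sizes;
#'   the remainder of the universe is null.
#' @param deEffect expression shift per stage step, log2 units.
#' @param cnaEffect gain/loss magnitude, log2-ratio units.
#' @param cnaPenetrance fraction of case-stage samples carrying a planted
#'   alteration, in (0, 1].
#' @param noiseSd,cnaNoiseSd,batchSd noise standard deviations (log2
#'   units): per-sample expression noise, per-sample log-ratio noise, and
#'   per-cohort per-gene expression batch offsets.
#' @param seed integer seed making the whole study reproducible.
#' @return A validated `SimulationConfig` object.
#' @examples
#' cfg <- simulationConfig(nGenes = 100, samplesPerStage = c(II = 5, III = 5, IV = 5))
#' study <- simulateStudy(cfg)
#' names(study)
#' @aliases SimulationConfig-class
#' @export
simulationConfig <- function(nExpressionCohorts = 2L,
                             nCnaCohorts = 3L,
                             nGenes = 500L,
                             samplesPerStage = c(II = 30L, III = 30L, IV = 30L),
                             nUpAmplified = 50L,
                             nDownDeleted = 50L,
                             nDeOnly = 50L,
                             nCnaOnly = 50L,
                             deEffect = 1.0,
                             cnaEffect = 0.8,
                             cnaPenetrance = 0.8,
                             noiseSd = 0.5,
                             cnaNoiseSd = 0.2,
                             batchSd = 0.3,
                             seed = 1L) {
  sps <- as.numeric(samplesPerStage[.STAGES])
  names(sps) <- .STAGES
  new("SimulationConfig",
      nExpressionCohorts = as.integer(nExpressionCohorts),
      nCnaCohorts = as.integer(nCnaCohorts),
      nGenes = as.integer(nGenes),
      samplesPerStage = sps,
      nUpAmplified = as.integer(nUpAmplified),
      nDownDeleted = as.integer(nDownDeleted),
      nDeOnly = as.integer(nDeOnly),
      nCnaOnly = as.integer(nCnaOnly),
      deEffect = deEffect, cnaEffect = cnaEffect,
      cnaPenetrance = cnaPenetrance,
      noiseSd = noiseSd, cnaNoiseSd = cnaNoiseSd, batchSd = batchSd,
      seed = as.integer(seed))
}

setClass("SimulationConfig",
         representation(nExpressionCohorts = "integer",
                        nCnaCohorts = "integer",
                        nGenes = "integer",
                        samplesPerStage = "numeric",
                        nUpAmplified = "integer",
                        nDownDeleted = "integer",
                        nDeOnly = "integer",
                        nCnaOnly = "integer",
                        deEffect = "numeric",
                        cnaEffect = "numeric",
                        cnaPenetrance = "numeric",
                        noiseSd = "numeric",
                        cnaNoiseSd = "numeric",
                        batchSd = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  counts <- c(nExpressionCohorts = object@nExpressionCohorts,
              nCnaCohorts = object@nCnaCohorts,
              nGenes = object@nGenes,
              nUpAmplified = object@nUpAmplified,
              nDownDeleted = object@nDownDeleted,
              nDeOnly = object@nDeOnly,
              nCnaOnly = object@nCnaOnly)
  bad <- names(counts)[is.na(counts) | counts < 0]
  if (length(bad))
    msg <- c(msg, sprintf("field '%s' must be a nonnegative count", bad))
  if (anyNA(object@samplesPerStage) || any(object@samplesPerStage < 0))
    msg <- c(msg, "field 'samplesPerStage' must give nonnegative counts for II, III, IV")
  planted <- object@nUpAmplified + object@nDownDeleted +
    object@nDeOnly + object@nCnaOnly
  if (!is.na(planted) && !is.na(object@nGenes) && planted > object@nGenes)
    msg <- c(msg, "field 'nGenes' must be at least the sum of the planted class sizes")
  if (is.na(object@noiseSd) || object@noiseSd <= 0)
    msg <- c(msg, "field 'noiseSd' must be > 0")
  if (is.na(object@cnaNoiseSd) || object@cnaNoiseSd <= 0)
    msg <- c(msg, "field 'cnaNoiseSd' must be > 0")
  if (is.na(object@batchSd) || object@batchSd < 0)
    msg <- c(msg, "field 'batchSd' must be >= 0")
  if (is.na(object@cnaPenetrance) || object@cnaPenetrance <= 0 ||
      object@cnaPenetrance > 1)
    msg <- c(msg, "field 'cnaPenetrance' must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  cohorts: %d expression, %d copy-number; %d genes\n",
              object@nExpressionCohorts, object@nCnaCohorts, object@nGenes))
  cat(sprintf("  samples/stage: II=%g III=%g IV=%g\n",
              object@samplesPerStage["II"], object@samplesPerStage["III"],
              object@samplesPerStage["IV"]))
  cat(sprintf("  planted: %d up-amplified, %d down-deleted, %d DE-only, %d CNA-only\n",
              object@nUpAmplified, object@nDownDeleted, object@nDeOnly,
              object@nCnaOnly))
  cat(sprintf("  effects: de=%g cna=%g penetrance=%g; noise=%g/%g batch=%g; seed=%d\n",
              object@deEffect, object@cnaEffect, object@cnaPenetrance,
              object@noiseSd, object@cnaNoiseSd, object@batchSd, object@seed))
})

## stage index above the baseline stage II: II -> 0, III -> 1, IV -> 2
.stageIndex <- function(stage) match(stage, .STAGES) - 1L

.geneClasses <- function(config) {
  cls <- rep("null", config@nGenes)
  dir <- rep(NA_character_, config@nGenes)
  i <- 0L
  take <- function(n) seq_len(n) + i
  if (config@nUpAmplified > 0) {
    cls[take(config@nUpAmplified)] <- "up_amplified"
    dir[take(config@nUpAmplified)] <- "up"
    i <- i + config@nUpAmplified
  }
  if (config@nDownDeleted > 0) {
    cls[take(config@nDownDeleted)] <- "down_deleted"
    dir[take(config@nDownDeleted)] <- "down"
    i <- i + config@nDownDeleted
  }
  if (config@nDeOnly > 0) {
    idx <- take(config@nDeOnly)
    cls[idx] <- "de_only"
    dir[idx] <- rep(c("up", "down"), length.out = config@nDeOnly)
    i <- i + config@nDeOnly
  }
  if (config@nCnaOnly > 0) {
    idx <- take(config@nCnaOnly)
    cls[idx] <- "cna_only"
    dir[idx] <- rep(c("up", "down"), length.out = config@nCnaOnly)
    i <- i + config@nCnaOnly
  }
  data.frame(gene_id = sprintf("g%04d", seq_len(config@nGenes)),
             class = cls, direction = dir, stringsAsFactors = FALSE)
}

## per-sample carrier matrix for CNA-bearing genes: carriers only among
## stage III/IV samples, with probability cnaPenetrance
.carrierMatrix <- function(cnaGenes, stage, penetrance) {
  n <- length(stage)
  carrier <- matrix(FALSE, length(cnaGenes), n)
  case <- .stageIndex(stage) > 0L
  if (any(case))
    carrier[, case] <- matrix(
      stats::runif(length(cnaGenes) * sum(case)) < penetrance,
      length(cnaGenes), sum(case))
  carrier
}

#' Generate a synthetic multi-cohort progression study
#'
#' Draws the study defined by a [simulationConfig()]: a list of
#' [ExpressionCohort] objects, a list of [CNACohort] objects and a ground
#' truth table assigning each gene to one of the classes `up_amplified`,
#' `down_deleted`, `de_only`, `cna_only`, `null` (with its planted
#' direction). The whole draw is deterministic given `config@seed`.
#'
#' @param config a `SimulationConfig`.
#' @return A list with elements `expression` (list of `ExpressionCohort`),
#'   `cna` (list of `CNACohort`) and `truth` (data.frame with columns
#'   `gene_id`, `class`, `direction`).
#' @seealso [writeStudy()] to export the study as TSV files.
#' @export
simulateStudy <- function(config) {
  validObject(config)
  set.seed(config@seed)
  truth <- .geneClasses(config)
  G <- config@nGenes
  genes <- truth$gene_id
  stage <- rep(.STAGES, times = config@samplesPerStage)
  nS <- length(stage)
  baseline <- stats::runif(G, 4, 12)
  sgn <- ifelse(is.na(truth$direction) | truth$direction == "up", 1, -1)

  deGene <- truth$class == "de_only"      # unconditional stage shift
  coupledGene <- truth$class %in% c("up_amplified", "down_deleted")
  cnaGene <- coupledGene | truth$class == "cna_only"

  expression <- vector("list", config@nExpressionCohorts)
  for (c in seq_len(config@nExpressionCohorts)) {
    nm <- sprintf("EXPR%d", c)
    batch <- stats::rnorm(G, 0, config@batchSd)
    stepMat <- matrix(.stageIndex(stage), G, nS, byrow = TRUE)
    shift <- matrix(0, G, nS)
    if (any(deGene))
      shift[deGene, ] <- (sgn[deGene] * config@deEffect) *
        stepMat[deGene, , drop = FALSE]
    if (any(coupledGene)) {
      carrier <- .carrierMatrix(which(coupledGene), stage,
                                config@cnaPenetrance)
      shift[coupledGene, ] <- (sgn[coupledGene] * config@deEffect) *
        stepMat[coupledGene, , drop = FALSE] * carrier
    }
    m <- baseline + batch + shift +
      matrix(stats::rnorm(G * nS, 0, config@noiseSd), G, nS)
    dimnames(m) <- list(genes, sprintf("%s_s%03d", nm, seq_len(nS)))
    expression[[c]] <- ExpressionCohort(m, stage = stage, name = nm)
  }
  names(expression) <- vapply(expression, cohortName, character(1))

  cna <- vector("list", config@nCnaCohorts)
  for (c in seq_len(config@nCnaCohorts)) {
    nm <- sprintf("CNA%d", c)
    m <- matrix(stats::rnorm(G * nS, 0, config@cnaNoiseSd), G, nS)
    if (any(cnaGene)) {
      carrier <- .carrierMatrix(which(cnaGene), stage, config@cnaPenetrance)
      m[cnaGene, ] <- m[cnaGene, , drop = FALSE] +
        (sgn[cnaGene] * config@cnaEffect) * carrier
    }
    dimnames(m) <- list(genes, sprintf("%s_s%03d", nm, seq_len(nS)))
    cna[[c]] <- CNACohort(m, stage = stage, name = nm)
  }
  names(cna) <- vapply(cna, cohortName, character(1))

  list(expression = expression, cna = cna, truth = truth)
}
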
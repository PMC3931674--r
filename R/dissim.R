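.METRICS <- c("euclidean", "manhattan", "kendall_tau", "kl")

## symmetrized (Jeffreys) Kullback-Leibler divergence between two log2
## expression vectors: back-transform to the linear scale, add a small
## pseudocount, normalize to the probability simplex
.klDistance <- function(x, y, pseudocount = 1e-6) {
  p <- 2^x + pseudocount
  q <- 2^y + pseudocount
  p <- p / sum(p)
  q <- q / sum(q)
  0.5 * (sum(p * log(p / q)) + sum(q * log(q / p)))
}

#' Dissimilarity between two expression profiles
#'
#' The four dissimilarities of the patient representation:
#' * `euclidean` - the L2 distance;
#' * `manhattan` - the L1 distance;
#' * `kendall_tau` - `(1 - tau_b) / 2` in `[0, 1]`, where `tau_b` is the
#'   tie-corrected Kendall rank correlation (undefined, hence an error,
#'   on constant vectors);
#' * `kl` - the symmetrized (Jeffreys) Kullback-Leibler divergence of the
#'   two profiles after back-transforming log2 values to the linear
#'   scale, adding a pseudocount of 1e-6 and normalizing each profile to
#'   the probability simplex.
#'
#' All four are symmetric, nonnegative, and zero on identical vectors.
#'
#' @param x,y numeric vectors of equal length (length >= 2 for
#'   `kendall_tau`), log2 expression over the same genes in the same
#'   order.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"kendall_tau"`,
#'   `"kl"`.
#' @return A single nonnegative number.
#' @examples
#' pairwiseDistance(c(0, 0), c(3, 4), "euclidean")   # 5
#' pairwiseDistance(c(1, 2), c(4, 6), "manhattan")   # 7
#' pairwiseDistance(1:3, 3:1, "kendall_tau")         # 1
#' @export
pairwiseDistance <- function(x, y, metric = .METRICS) {
  metric <- match.arg(metric)
  if (length(x) != length(y))
    stop("profiles must have the same length")
  if (anyNA(x) || anyNA(y)) stop("profiles must not contain missing values")
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    manhattan = sum(abs(x - y)),
    kendall_tau = {
      if (length(x) < 2)
        stop("kendall_tau needs vectors of length >= 2")
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("kendall_tau is undefined for constant profiles")
      (1 - stats::cor(x, y, method = "kendall")) / 2
    },
    kl = .klDistance(x, y))
}

#' Select the prototype patient group
#'
#' Extracts the prototype set: all samples of the requested (lowest
#' available) stage, restricted to the signature genes, in stable cohort
#' order. These patients anchor the dissimilarity representation: every
#' patient is later described by its vector of distances to them.
#'
#' @param cohort an [ExpressionCohort].
#' @param stage prototype stage (default `"II"`, the lowest stage of the
#'   progression tasks).
#' @param signature a [CombinedSignature-class] or a character vector of
#'   gene ids.
#' @return A [PrototypeSet-class].
#' @export
selectPrototypes <- function(cohort, stage = "II", signature) {
  stopifnot(is(cohort, "ExpressionCohort"))
  genes <- if (is(signature, "CombinedSignature")) signatureGenes(signature)
           else as.character(signature)
  if (length(genes) == 0) stop("the signature gene set is empty")
  missing <- setdiff(genes, rownames(cohort))
  if (length(missing))
    stop(sprintf("cohort lacks %d signature gene(s): %s",
                 length(missing), paste(utils::head(missing, 5),
                                        collapse = ", ")))
  sel <- stages(cohort) == stage
  if (!any(sel))
    stop(sprintf("cohort %s has no stage-%s samples to use as prototypes",
                 cohortName(cohort), stage))
  new("PrototypeSet",
      profiles = assay(cohort, "exprs")[genes, sel, drop = FALSE],
      stage = stage)
}

#' Patients-to-prototypes dissimilarity matrix
#'
#' Maps every patient x to its dissimilarity vector phi(x, P) =
#' (D(x, y1), ..., D(x, yn)) against the n prototype patients, producing
#' the N x n matrix whose rows are the relational (RA) features.
#'
#' @param patients numeric genes x patients matrix over the signature
#'   genes, with the same gene order (rownames) as the prototypes.
#' @param prototypes a [PrototypeSet-class].
#' @param metric dissimilarity name, see [pairwiseDistance()].
#' @return A [DissimilarityMatrix-class] (patients in rows, prototypes in
#'   columns).
#' @examples
#' m <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(c("gA", "gB"), c("p1", "p2")))
#' ps <- new("PrototypeSet", profiles = m, stage = "II")
#' dissimilarityMatrix(m, ps, "euclidean")
#' @export
dissimilarityMatrix <- function(patients, prototypes,
                                metric = .METRICS) {
  metric <- match.arg(metric)
  stopifnot(is(prototypes, "PrototypeSet"))
  patients <- as.matrix(patients)
  P <- prototypes@profiles
  if (is.null(rownames(patients)) || !identical(rownames(patients),
                                                rownames(P)))
    stop("patients and prototypes must share an identical gene ordering")
  D <- matrix(0, ncol(patients), ncol(P),
              dimnames = list(colnames(patients), colnames(P)))
  for (j in seq_len(ncol(P)))
    for (i in seq_len(ncol(patients)))
      D[i, j] <- pairwiseDistance(patients[, i], P[, j], metric)
  new("DissimilarityMatrix", D, metric = metric)
}
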
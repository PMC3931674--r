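## Plain-TSV dialect shared by all modules: one matrix file per cohort
## (rows = genes, first column gene_id, remaining columns = samples), a
## sample annotation table (sample_id, stage, cohort) and a gene
## annotation table (gene_id, class, direction).

.writeMatrixTSV <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a synthetic study as TSV files
#'
#' `writeStudy()` exports a [simulateStudy()] result to a directory:
#' `expr_<name>.tsv` and `cna_<name>.tsv` matrices, `samples.tsv`
#' (sample_id, stage, cohort) and `genes.tsv` (gene_id, class,
#' direction). `readStudy()` reads the same dialect back into cohort
#' objects.
#'
#' @param study list with `expression`, `cna`, `truth` (see
#'   [simulateStudy()]).
#' @param dir directory to write to / read from (created if needed).
#' @return `writeStudy()` returns `dir` invisibly; `readStudy()` returns
#'   a study list of the same shape.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- list()
  for (co in study$expression) {
    .writeMatrixTSV(assay(co, "exprs"),
                    file.path(dir, sprintf("expr_%s.tsv", cohortName(co))))
    ann[[length(ann) + 1L]] <- data.frame(
      sample_id = colnames(co), stage = stages(co),
      cohort = cohortName(co), stringsAsFactors = FALSE)
  }
  for (co in study$cna) {
    .writeMatrixTSV(assay(co, "logratio"),
                    file.path(dir, sprintf("cna_%s.tsv", cohortName(co))))
    ann[[length(ann) + 1L]] <- data.frame(
      sample_id = colnames(co), stage = stages(co),
      cohort = cohortName(co), stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, ann), file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeStudy
#' @export
readStudy <- function(dir) {
  ann <- utils::read.delim(file.path(dir, "samples.tsv"),
                           stringsAsFactors = FALSE)
  truth <- utils::read.delim(file.path(dir, "genes.tsv"),
                             stringsAsFactors = FALSE)
  readKind <- function(prefix, ctor) {
    files <- sort(list.files(dir, sprintf("^%s_.*\\.tsv$", prefix),
                             full.names = TRUE))
    out <- lapply(files, function(f) {
      nm <- sub(sprintf("^%s_(.*)\\.tsv$", prefix), "\\1", basename(f))
      m <- .readMatrixTSV(f)
      st <- ann$stage[match(colnames(m), ann$sample_id)]
      ctor(m, stage = st, name = nm)
    })
    names(out) <- vapply(out, cohortName, character(1))
    out
  }
  list(expression = readKind("expr", ExpressionCohort),
       cna = readKind("cna", CNACohort),
       truth = truth)
}

#' Write analysis artifacts as TSV
#'
#' `writeDEResult()` exports a [rankProductDE()] table (gene_id, rank
#' products, pfp, p-values plus selection flags at the stored alpha);
#' `writeSignature()` exports a [CombinedSignature-class] as (gene_id,
#' direction) rows; `writeResultTable()` exports a [runExperiment()]
#' result table; `writeDissimilarityMatrix()` exports a
#' [DissimilarityMatrix-class] with prototype ids as column headers.
#'
#' @param de a `DEResult`.
#' @param signature a `CombinedSignature`.
#' @param results a result table data.frame.
#' @param D a `DissimilarityMatrix`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeDEResult <- function(de, path) {
  sel <- selectDE(de)
  tab <- de@table
  tab$selected_up <- tab$gene_id %in% sel$up
  tab$selected_down <- tab$gene_id %in% sel$down
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDEResult
#' @export
writeSignature <- function(signature, path) {
  tab <- data.frame(
    gene_id = signatureGenes(signature),
    direction = rep(c("up_amplified", "down_deleted"),
                    c(length(signature@upAmplified),
                      length(signature@downDeleted))),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDEResult
#' @export
writeResultTable <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDEResult
#' @export
readResultTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname writeDEResult
#' @export
writeDissimilarityMatrix <- function(D, path) {
  df <- data.frame(patient_id = rownames(D), D@.Data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
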
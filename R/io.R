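#' Read and write expression matrices as TSV
#'
#' The TSV dialect is tab-separated with a header row, UTF-8, '.' decimal:
#' feature ids in the first column, one column per sample.
#'
#' @param path file path.
#' @return `readExpressionTsv()`: features x samples numeric matrix.
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname readExpressionTsv
#' @param matrix features x samples matrix with dimnames.
#' @param idColumn name for the feature-id column.
#' @export
writeExpressionTsv <- function(matrix, path, idColumn = "feature_id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read a sample metadata TSV
#'
#' @param path file path; must contain a sample_id column.
#' @return data.frame with sample_id as rownames.
#' @export
readMetadataTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("metadata needs a sample_id column")
  rownames(df) <- df$sample_id
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated, name and description
#' followed by member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Export a synthetic cohort to a directory
#'
#' Writes expression.tsv (log2, features x samples), metadata.tsv,
#' fractions_true.tsv, mri.tsv, and truth.json (planted effects and latent
#' severity).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
writeCohortTsv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeExpressionTsv(exprMatrix(cohort), file.path(dir, "expression.tsv"))
  utils::write.table(sampleInfo(cohort), file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  fr <- data.frame(sample_id = rownames(trueFractions(cohort)),
                   trueFractions(cohort), check.names = FALSE)
  utils::write.table(fr, file.path(dir, "fractions_true.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mri <- data.frame(subject_id = rownames(mriFeatures(cohort)),
                    mriFeatures(cohort), check.names = FALSE)
  utils::write.table(mri, file.path(dir, "mri.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(de_genes = trueDeGenes(cohort),
         latent_severity = as.list(latentSeverity(cohort))),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
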
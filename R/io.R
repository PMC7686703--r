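# Plain-text (TSV) input/output for every pipeline artifact. All writers are
# deterministic: the same object always produces byte-identical files.

#' Read and write pipeline tables as TSV
#'
#' Matrices (beta values, detection p-values, abundance) are written probes
#' or samples as rows with a single header line; missing values as NA;
#' numbers at full precision so write/read round trips are lossless.
#'
#' @param m numeric matrix with dimnames.
#' @param file path.
#' @return \code{readMatrixTSV} returns a numeric matrix;
#'   writers return the path invisibly.
#' @export
writeMatrixTSV <- function(m, file) {
  ch <- matrix(sprintf("%.17g", m), nrow(m), ncol(m),
               dimnames = dimnames(m))
  ch[is.na(m)] <- "NA"
  df <- data.frame(id = rownames(m), ch, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @describeIn writeMatrixTSV read a matrix written by
#'   \code{writeMatrixTSV} (first column = row ids).
#' @export
readMatrixTSV <- function(file) {
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' @describeIn writeMatrixTSV read a one-probe-id-per-line exclusion list
#'   (blank lines and '#' comments ignored).
#' @export
readProbeList <- function(file) {
  x <- trimws(readLines(file))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' @describeIn writeMatrixTSV write a data.frame as TSV (no quoting, no row
#'   names) — used for sample sheets, rankings, labels and reports.
#' @param df a data.frame.
#' @export
writeTableTSV <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a cohort's primary artifacts to a directory
#'
#' Writes \code{beta.tsv}, \code{detection_p.tsv} (when present),
#' \code{sample_sheet.tsv}, and for synthetic cohorts additionally
#' \code{abundance.tsv}, \code{true_fractions.tsv} and \code{truth.tsv}
#' (the planted probes and effects).
#'
#' @param cohort a \linkS4class{MethylCohort} or
#'   \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  p <- function(f) file.path(dir, f)
  writeMatrixTSV(betaValues(cohort), p("beta.tsv"))
  files <- p("beta.tsv")
  if (!is.null(detectionP(cohort))) {
    writeMatrixTSV(detectionP(cohort), p("detection_p.tsv"))
    files <- c(files, p("detection_p.tsv"))
  }
  sheet <- as.data.frame(SummarizedExperiment::colData(cohort))
  writeTableTSV(cbind(sample = rownames(sheet), sheet), p("sample_sheet.tsv"))
  files <- c(files, p("sample_sheet.tsv"))
  if (is(cohort, "SyntheticCohort")) {
    writeMatrixTSV(abundanceTable(cohort), p("abundance.tsv"))
    writeMatrixTSV(cellFractions(trueFractions(cohort)),
                   p("true_fractions.tsv"))
    tr <- cohortTruth(cohort)
    truthDf <- rbind(
      data.frame(set = rep("epithelial_dmc", nrow(tr$epithelialDMCs)),
                 probe = tr$epithelialDMCs$probe,
                 effect = tr$epithelialDMCs$effect),
      data.frame(set = rep("immune_dmc", nrow(tr$immuneDMCs)),
                 probe = tr$immuneDMCs$probe,
                 effect = tr$immuneDMCs$effect),
      data.frame(set = rep("age_probe", nrow(tr$ageProbes)),
                 probe = tr$ageProbes$probe,
                 effect = tr$ageProbes$slope))
    writeTableTSV(truthDf, p("truth.tsv"))
    files <- c(files, p("abundance.tsv"), p("true_fractions.tsv"),
               p("truth.tsv"))
  }
  invisible(files)
}
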
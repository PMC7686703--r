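# Constructors, accessors and show() methods for the core classes.

#' Construct a MethylCohort
#'
#' @param beta numeric matrix of beta values, probes as rows, samples as
#'   columns, values in [0, 1] (NA allowed for masked entries).
#' @param detectionP optional congruent matrix of detection p-values.
#' @param sampleData optional data.frame (or DataFrame) of per-sample
#'   covariates; rownames must match sample ids when given.
#' @return a \linkS4class{MethylCohort}.
#' @examples
#' b <- matrix(runif(20), 4, 5,
#'   dimnames = list(paste0("cg", 1:4), paste0("s", 1:5)))
#' MethylCohort(b)
#' @export
MethylCohort <- function(beta, detectionP = NULL, sampleData = NULL) {
  beta <- as.matrix(beta)
  assays <- list(beta = beta)
  if (!is.null(detectionP)) {
    detectionP <- as.matrix(detectionP)
    if (!identical(dim(detectionP), dim(beta)))
      stop("detectionP must have the same dimensions as beta")
    dimnames(detectionP) <- dimnames(beta)
    assays$detectionP <- detectionP
  }
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(beta))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = sampleData)
  new("MethylCohort", se)
}

#' @describeIn MethylCohort the beta-value matrix (probes x samples).
#' @param x a MethylCohort.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @describeIn MethylCohort the detection p-value matrix, or NULL.
#' @export
detectionP <- function(x) {
  if ("detectionP" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "detectionP") else NULL
}

#' @describeIn MethylCohort per-sample community-type labels ("L"/"O"), or
#'   NULL when absent from colData.
#' @export
communityLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("label" %in% colnames(cd)) as.character(cd$label) else NULL
}

setMethod("show", "MethylCohort", function(object) {
  cat("MethylCohort:", nrow(object), "probes x", ncol(object), "samples\n")
  b <- betaValues(object)
  cat(sprintf("  missing entries: %d (%.3f%%)\n", sum(is.na(b)),
              100 * mean(is.na(b))))
  lab <- communityLabels(object)
  if (!is.null(lab)) {
    tl <- table(lab)
    cat("  labels:", paste(names(tl), tl, sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})

#' Construct a CellTypeReference
#'
#' @param profiles numeric matrix of mean beta values, probes x cell types.
#' @param compartments character vector of compartment tags
#'   ("epithelial", "fibroblast", "immune"), one per cell type, named by
#'   cell type (unnamed vectors are matched positionally).
#' @return a \linkS4class{CellTypeReference}.
#' @export
CellTypeReference <- function(profiles, compartments) {
  profiles <- as.matrix(profiles)
  if (is.null(names(compartments)))
    names(compartments) <- colnames(profiles)
  new("CellTypeReference", profiles = profiles,
      compartments = compartments[colnames(profiles)])
}

#' @describeIn CellTypeReference matrix of reference profiles
#'   (probes x cell types).
#' @param x a CellTypeReference.
#' @export
referenceProfiles <- function(x) x@profiles

#' @describeIn CellTypeReference named compartment tag per cell type.
#' @export
compartmentTags <- function(x) x@compartments

setMethod("show", "CellTypeReference", function(object) {
  cat("CellTypeReference:", nrow(object@profiles), "probes x",
      ncol(object@profiles), "cell types\n")
  cat("  compartments:",
      paste(names(object@compartments), object@compartments,
            sep = ":", collapse = ", "), "\n")
  invisible(NULL)
})

#' Construct CellProportions
#'
#' @param fractions numeric matrix, samples x cell types, rows on the simplex.
#' @param compartments compartment tag per cell type (named, or matched
#'   positionally to the columns).
#' @return a \linkS4class{CellProportions}.
#' @export
CellProportions <- function(fractions, compartments) {
  fractions <- as.matrix(fractions)
  if (is.null(names(compartments)))
    names(compartments) <- colnames(fractions)
  new("CellProportions", fractions = fractions,
      compartments = compartments[colnames(fractions)])
}

#' @describeIn CellProportions the samples x cell-types fraction matrix.
#' @param x a CellProportions.
#' @export
cellFractions <- function(x) x@fractions

#' @describeIn CellProportions the immune-cell proportion IC per sample:
#'   the summed fraction over immune-compartment cell types.
#' @export
icFraction <- function(x) {
  imm <- names(x@compartments)[x@compartments == "immune"]
  rowSums(x@fractions[, imm, drop = FALSE])
}

#' @describeIn CellProportions summed fraction per compartment
#'   (samples x compartments matrix).
#' @export
compartmentFractions <- function(x) {
  comps <- sort(unique(x@compartments))
  out <- vapply(comps, function(cc) {
    rowSums(x@fractions[, names(x@compartments)[x@compartments == cc],
                        drop = FALSE])
  }, numeric(nrow(x@fractions)))
  out <- matrix(out, nrow = nrow(x@fractions),
                dimnames = list(rownames(x@fractions), comps))
  out
}

setMethod("show", "CellProportions", function(object) {
  cat("CellProportions:", nrow(object@fractions), "samples x",
      ncol(object@fractions), "cell types\n")
  cat(sprintf("  IC: median %.3f, range [%.3f, %.3f]\n",
              median(icFraction(object)), min(icFraction(object)),
              max(icFraction(object))))
  invisible(NULL)
})

#' @describeIn TrainedSignature data.frame of terms (type, probe, weight);
#'   by default restricted to nonzero weights.
#' @param x a TrainedSignature.
#' @param nonzero keep only nonzero-weight terms?
#' @export
signatureTerms <- function(x, nonzero = TRUE) {
  tt <- x@terms
  if (nonzero) tt <- tt[tt$weight != 0, , drop = FALSE]
  rownames(tt) <- NULL
  tt
}

#' @describeIn TrainedSignature number of nonzero-weight terms.
#' @export
nNonzero <- function(x) sum(x@terms$weight != 0)

setMethod("show", "TrainedSignature", function(object) {
  cat(sprintf("TrainedSignature (%s): %d/%d nonzero terms\n",
              if (object@nonlinear) "nonlinear" else "linear",
              nNonzero(object), nrow(object@terms)))
  cat(sprintf("  pool = %d probes, alpha = %.2f, lambda = %.4g\n",
              as.integer(object@poolSize), object@alpha, object@lambda))
  nint <- sum(object@terms$type == "interaction" & object@terms$weight != 0)
  if (object@nonlinear)
    cat("  nonzero interaction terms:", nint, "\n")
  invisible(NULL)
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f, %s; %d pos / %d neg)\n",
              object@auc, object@ciLow, object@ciHigh, object@method,
              object@nPos, object@nNeg))
  invisible(NULL)
})

#' @describeIn firthLogistic coefficient table of a FirthFit: term,
#'   estimate (log-odds), or, ciLow, ciHigh, p.
#' @param x a FirthFit.
#' @export
firthCoefficients <- function(x) x@coefficients

setMethod("show", "FirthFit", function(object) {
  cat("Firth bias-reduced logistic fit",
      sprintf("(penalized logLik %.3f, %d iterations)\n",
              object@logLik, object@iter))
  print(format(object@coefficients, digits = 4))
  invisible(NULL)
})

#' @describeIn SyntheticCohort the generator's ground truth list.
#' @param x a SyntheticCohort.
#' @export
cohortTruth <- function(x) x@truth

#' @describeIn SyntheticCohort the taxon relative-abundance matrix
#'   (samples x taxa).
#' @export
abundanceTable <- function(x) x@abundance

#' @describeIn SyntheticCohort the true mixing fractions as
#'   \linkS4class{CellProportions}.
#' @export
trueFractions <- function(x) x@trueFractions

setMethod("show", "SyntheticCohort", function(object) {
  callNextMethod()
  cat("  planted:", nrow(object@truth$epithelialDMCs), "epithelial DMCs,",
      nrow(object@truth$immuneDMCs), "immune DMCs,",
      nrow(object@truth$ageProbes), "age probes\n")
  invisible(NULL)
})
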
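#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats binomial fisher.test glm.fit lm median p.adjust pchisq
#'   pnorm predict pt qchisq qnorm quantile rbeta rgamma rnorm runif sd
#'   setNames uniroot var
#' @importFrom utils combn read.delim write.table head
NULL

#' MethylCohort: beta-value methylome with sample annotation
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a
#' probes-by-samples matrix of methylation beta values (assay \code{"beta"}),
#' optionally a congruent matrix of detection p-values (assay
#' \code{"detectionP"}), and per-sample covariates (community-type label,
#' age, estimated cell fractions) in \code{colData}.
#'
#' Validity requires a \code{"beta"} assay whose non-missing values lie in
#' \eqn{[0,1]}, unique probe and sample identifiers, and, when present, a
#' \code{"detectionP"} assay with values in \eqn{[0,1]}.
#'
#' @seealso [MethylCohort()] the constructor; [betaValues()], [detectionP()],
#'   [communityLabels()] accessors.
#' @export
setClass("MethylCohort", contains = "SummarizedExperiment")

setValidity("MethylCohort", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if ("detectionP" %in% SummarizedExperiment::assayNames(object)) {
    dp <- SummarizedExperiment::assay(object, "detectionP")
    if (any(dp < 0 | dp > 1, na.rm = TRUE))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' CellTypeReference: per-cell-type mean methylation profiles
#'
#' Reference beta profiles used both by the synthetic-cohort generator (as
#' ground-truth cell-type methylomes) and by [deconvolveCellFractions()].
#' Each cell type carries a compartment tag (\code{"epithelial"},
#' \code{"fibroblast"} or \code{"immune"}); the immune-compartment fractions
#' sum to the immune-cell proportion IC used throughout the pipeline.
#'
#' @slot profiles numeric matrix, probes x cell types, values in [0, 1].
#' @slot compartments named character vector, one tag per cell type.
#' @export
setClass("CellTypeReference",
  representation(profiles = "matrix", compartments = "character"))

setValidity("CellTypeReference", function(object) {
  msg <- character()
  p <- object@profiles
  if (ncol(p) < 2) msg <- c(msg, "at least 2 cell types are required")
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msg <- c(msg, "reference beta values must lie in [0, 1]")
  if (is.null(colnames(p)) || is.null(rownames(p)))
    msg <- c(msg, "profiles must carry probe rownames and cell-type colnames")
  if (!identical(sort(names(object@compartments)), sort(colnames(p))))
    msg <- c(msg, "compartments must be named by the cell types")
  bad <- setdiff(unique(object@compartments),
                 c("epithelial", "fibroblast", "immune"))
  if (length(bad))
    msg <- c(msg, paste0("unknown compartment tag(s): ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' CellProportions: per-sample cell-type fractions
#'
#' Simplex-constrained cell-type fractions per sample, as recovered by
#' [deconvolveCellFractions()] or planted by [generateCohort()]. The summed
#' immune-compartment fraction is the immune-cell proportion (IC) that enters
#' the adjusted ranking models and the nonlinear index terms.
#'
#' @slot fractions numeric matrix, samples x cell types, rows summing to 1.
#' @slot compartments named character vector, compartment tag per cell type.
#' @export
setClass("CellProportions",
  representation(fractions = "matrix", compartments = "character"))

setValidity("CellProportions", function(object) {
  f <- object@fractions
  msg <- character()
  if (any(f < -1e-9 | f > 1 + 1e-9))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (any(abs(rowSums(f) - 1) > 1e-6))
    msg <- c(msg, "fractions must sum to 1 per sample")
  if (!identical(sort(names(object@compartments)), sort(colnames(f))))
    msg <- c(msg, "compartments must be named by the cell types")
  if (length(msg)) msg else TRUE
})

#' TrainedSignature: a fitted methylation index
#'
#' The product of [cvScan()] (or of loading an exported signature file): a
#' sparse linear model over CpG beta values and, in nonlinear mode, beta x IC
#' interaction terms. Applying it with [computeIndex()] yields the WID-LO
#' index, a linear predictor on the log-odds scale whose higher values favour
#' O-type (non-Lactobacilli-dominated) communities.
#'
#' @slot terms data.frame with columns \code{type} ("linear" or
#'   "interaction"), \code{probe}, \code{weight}.
#' @slot intercept numeric scalar.
#' @slot alpha elastic-net mixing parameter in [0, 1].
#' @slot lambda penalty strength (>= 0).
#' @slot poolSize number of unique probes in the candidate pool.
#' @slot nonlinear logical, whether interaction terms were candidates.
#' @slot cvProfile data.frame of mean cross-validated AUC per
#'   (pool, alpha, lambda).
#' @export
setClass("TrainedSignature",
  representation(terms = "data.frame", intercept = "numeric",
                 alpha = "numeric", lambda = "numeric",
                 poolSize = "numeric", nonlinear = "logical",
                 cvProfile = "data.frame"))

setValidity("TrainedSignature", function(object) {
  msg <- character()
  if (!all(c("type", "probe", "weight") %in% colnames(object@terms)))
    msg <- c(msg, "terms needs columns type, probe, weight")
  if (length(object@alpha) != 1 || object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be a scalar in [0, 1]")
  if (length(object@lambda) != 1 || object@lambda < 0)
    msg <- c(msg, "lambda must be a non-negative scalar")
  bad <- setdiff(unique(object@terms$type), c("linear", "interaction"))
  if (length(bad))
    msg <- c(msg, paste0("unknown term type(s): ", paste(bad, collapse = ", ")))
  if (any(object@terms$type == "interaction") && !object@nonlinear)
    msg <- c(msg, "interaction terms present in a linear signature")
  if (anyDuplicated(object@terms[c("type", "probe")]))
    msg <- c(msg, "duplicate terms")
  if (length(msg)) msg else TRUE
})

#' RocResult: AUC with a confidence interval
#'
#' @slot auc area under the ROC curve, in [0, 1].
#' @slot ciLow,ciHigh 95 percent confidence bounds.
#' @slot method "delong" or "stratified_bootstrap".
#' @slot nPos,nNeg class sizes.
#' @export
setClass("RocResult",
  representation(auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 method = "character", nPos = "integer", nNeg = "integer"))

setValidity("RocResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0, 1]")
  if (!(object@ciLow <= object@auc && object@auc <= object@ciHigh))
    msg <- c(msg, "confidence interval must bracket the AUC")
  if (!object@method %in% c("delong", "stratified_bootstrap"))
    msg <- c(msg, "method must be 'delong' or 'stratified_bootstrap'")
  if (length(msg)) msg else TRUE
})

#' FirthFit: bias-reduced logistic regression fit
#'
#' Coefficients of a logistic model maximizing the Jeffreys-penalized
#' likelihood (Firth's correction), with profile-penalized-likelihood
#' confidence intervals and penalized-likelihood-ratio p-values. Estimates
#' stay finite under complete separation and zero table cells.
#'
#' @slot coefficients data.frame: term, estimate (log-odds), or, ciLow,
#'   ciHigh, p.
#' @slot logLik maximized penalized log-likelihood.
#' @slot iter Newton iterations used.
#' @slot converged logical.
#' @export
setClass("FirthFit",
  representation(coefficients = "data.frame", logLik = "numeric",
                 iter = "integer", converged = "logical"))

#' SyntheticCohort: a generated cohort with known ground truth
#'
#' Extends \linkS4class{MethylCohort} with the generator's ground truth: the
#' true cell fractions used for mixing, the planted differential probes and
#' their effect sizes, and a taxon relative-abundance table consistent with
#' the per-sample community-type labels.
#'
#' @slot truth list with elements \code{epithelialDMCs}, \code{immuneDMCs},
#'   \code{ageProbes} (data.frames of probe/effect), and scalar generator
#'   settings.
#' @slot abundance numeric matrix, samples x taxa, rows summing to 1.
#' @slot trueFractions \linkS4class{CellProportions} used for mixing.
#' @export
setClass("SyntheticCohort", contains = "MethylCohort",
  representation(truth = "list", abundance = "matrix",
                 trueFractions = "CellProportions"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!identical(rownames(object@abundance), colnames(object)))
    msg <- c(msg, "abundance rows must match sample ids")
  if (any(abs(rowSums(object@abundance) - 1) > 1e-6))
    msg <- c(msg, "abundance rows must sum to 1")
  lab <- object$label
  relab <- assignCommunityType(object@abundance)$label
  if (!identical(as.character(lab), relab))
    msg <- c(msg, "stored labels disagree with abundance-derived labels")
  if (length(msg)) msg else TRUE
})
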
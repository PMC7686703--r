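# Beta-level quality control and reference-based cell-fraction estimation.

#' Remove excluded probes (non-CpG, SNP-related, chrY, trimodal)
#'
#' Drops every probe in the union of the supplied exclusion lists. Lists may
#' overlap; a probe is removed once. Identifiers absent from the matrix are
#' ignored and counted as zero removals.
#'
#' @param cohort a \linkS4class{MethylCohort}.
#' @param lists named list of character vectors of probe ids, e.g.
#'   \code{list(non_cpg = ..., snp_related = ..., chr_y = ..., trimodal = ...)}.
#' @return list with \code{cohort} (the filtered object) and \code{removed},
#'   a named integer vector of per-list removal counts (ids actually present)
#'   plus \code{total} — the size of the union removed.
#' @export
applyExclusionLists <- function(cohort, lists) {
  stopifnot(is(cohort, "MethylCohort"))
  if (length(lists) == 0 || !is.list(lists))
    lists <- list()
  present <- rownames(cohort)
  perList <- vapply(lists, function(ids) sum(ids %in% present), integer(1))
  union <- unique(unlist(lists, use.names = FALSE))
  drop <- intersect(present, union)
  out <- cohort[setdiff(present, drop), ]
  list(cohort = out, removed = c(perList, total = length(drop)))
}

#' Mask failed measurements and filter failing samples and probes
#'
#' Entries with detection p-value above \code{pThresh} are set missing.
#' Samples with strictly more than \code{sampleFailThresh} of probes failed
#' are then removed; finally probes with strictly more than
#' \code{probeFailThresh} failure rate, recomputed over the surviving
#' samples, are removed. The order (mask, then samples, then probes) is fixed
#' and deterministic.
#'
#' @param cohort a \linkS4class{MethylCohort} carrying a detectionP assay.
#' @param pThresh failure threshold on the detection p-value (default 0.01).
#' @param sampleFailThresh maximum tolerated fraction of failed probes per
#'   sample (default 0.10).
#' @param probeFailThresh maximum tolerated per-probe failure rate across
#'   surviving samples (default 0.10).
#' @return list with \code{cohort} (masked and filtered; failed entries NA)
#'   and \code{report}: removed sample ids, removed probe ids, and the count
#'   of masked entries remaining in the output.
#' @export
maskAndFilter <- function(cohort, pThresh = 0.01,
                          sampleFailThresh = 0.10, probeFailThresh = 0.10) {
  stopifnot(is(cohort, "MethylCohort"))
  dp <- detectionP(cohort)
  if (is.null(dp)) stop("cohort carries no detectionP assay")
  b <- betaValues(cohort)
  failed <- dp > pThresh
  b[failed] <- NA_real_

  sampleFail <- colMeans(failed)
  badSamples <- colnames(b)[sampleFail > sampleFailThresh]
  keepS <- setdiff(colnames(b), badSamples)
  if (length(keepS) == 0) stop("all samples removed by the failure filter")
  b <- b[, keepS, drop = FALSE]
  failed <- failed[, keepS, drop = FALSE]

  probeFail <- rowMeans(failed)
  badProbes <- rownames(b)[probeFail > probeFailThresh]
  keepP <- setdiff(rownames(b), badProbes)
  b <- b[keepP, , drop = FALSE]

  cd <- SummarizedExperiment::colData(cohort)[keepS, , drop = FALSE]
  out <- MethylCohort(b, sampleData = cd)
  list(cohort = out,
       report = list(removedSamples = badSamples,
                     removedProbes = badProbes,
                     nMasked = sum(is.na(b)),
                     sampleFailFraction = sampleFail,
                     probeFailFraction = probeFail))
}

# Squared Euclidean distances from probe `target` (a row) to all rows of b,
# over columns where both are observed. Rows sharing no observed column get
# Inf. Used by imputeKNN.
probeDistances <- function(b, obs, target) {
  d <- sweep(b, 2, b[target, ], "-")
  d[!obs] <- NA
  d[, !obs[target, ]] <- NA
  shared <- rowSums(!is.na(d))
  out <- rowSums(d * d, na.rm = TRUE)
  out[shared == 0] <- Inf
  out
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' Fills each missing entry (probe j, sample i) with the mean, over the k
#' probes nearest to j, of their values in sample i. Nearness is Euclidean
#' distance between probe rows computed over the samples where both probes
#' are observed; neighbours missing at sample i are skipped in favour of the
#' next nearest. Ties in distance are broken by probe order. Non-missing
#' entries are never altered.
#'
#' @param x a \linkS4class{MethylCohort} or a numeric matrix with NA entries.
#' @param k number of neighbours (default 10).
#' @return object of the same kind as \code{x}, complete.
#' @export
imputeKNN <- function(x, k = 10) {
  isCohort <- is(x, "MethylCohort")
  b <- if (isCohort) betaValues(x) else as.matrix(x)
  obs <- !is.na(b)
  if (any(rowSums(obs) == 0)) {
    bad <- rownames(b)[rowSums(obs) == 0]
    stop("probe(s) entirely missing: ", paste(bad, collapse = ", "))
  }
  if (mean(!obs) >= 0.5) stop("more than half of the matrix is missing")
  todo <- which(rowSums(!obs) > 0)
  for (j in todo) {
    d <- probeDistances(b, obs, j)
    d[j] <- Inf
    ord <- order(d, seq_along(d))
    miss <- which(!obs[j, ])
    for (i in miss) {
      cand <- ord[obs[ord, i] & is.finite(d[ord])]
      if (length(cand) == 0)
        stop("no observed neighbour for probe ", rownames(b)[j],
             " at sample ", colnames(b)[i])
      nb <- cand[seq_len(min(k, length(cand)))]
      b[j, i] <- mean(b[nb, i])
    }
  }
  if (!isCohort) return(b)
  dp <- detectionP(x)
  MethylCohort(b, detectionP = dp,
               sampleData = SummarizedExperiment::colData(x))
}

#' Estimate cell-type fractions by robust regression on reference profiles
#'
#' For each sample, regresses its beta values over the reference probes on
#' the per-cell-type reference profiles using iteratively reweighted least
#' squares with Huber weights (tuning constant 1.345, no intercept), then
#' truncates negative coefficients to zero and renormalizes to the simplex.
#' Reference probes missing in a sample are dropped pairwise for that
#' sample's fit. The immune-cell proportion IC is the summed fraction over
#' immune-compartment cell types.
#'
#' @param x a \linkS4class{MethylCohort} or beta matrix (probes x samples).
#' @param ref a \linkS4class{CellTypeReference}.
#' @param minOverlap minimum probes shared between \code{x} and the
#'   reference (default 50).
#' @return a \linkS4class{CellProportions} (samples x cell types).
#' @examples
#' ref <- generateReferenceProfiles(500, seed = 1)
#' co <- generateCohort(cohortConfig(nSamples = 5, nProbes = 500, seed = 1),
#'                      ref)
#' deconvolveCellFractions(co, ref)
#' @export
deconvolveCellFractions <- function(x, ref, minOverlap = 50) {
  stopifnot(is(ref, "CellTypeReference"))
  b <- if (is(x, "MethylCohort")) betaValues(x) else as.matrix(x)
  mu <- referenceProfiles(ref)
  shared <- intersect(rownames(b), rownames(mu))
  if (length(shared) < minOverlap)
    stop("only ", length(shared), " probes overlap the reference (need >= ",
         minOverlap, ")")
  X <- mu[shared, , drop = FALSE]
  if (qr(X)$rank < ncol(X))
    stop("reference profiles are collinear; fractions are not identifiable")
  B <- b[shared, , drop = FALSE]
  fit1 <- function(y) {
    ok <- !is.na(y)
    if (sum(ok) < minOverlap)
      stop("fewer than ", minOverlap, " observed reference probes in a sample")
    Xs <- X[ok, , drop = FALSE]
    rownames(Xs) <- NULL
    co <- tryCatch(
      MASS::rlm(Xs, unname(y[ok]), psi = MASS::psi.huber,
                k = 1.345, maxit = 100)$coefficients,
      error = function(e) stop("robust fit failed: ", conditionMessage(e)))
    co[co < 0] <- 0
    if (sum(co) == 0) stop("degenerate fit: all coefficients non-positive")
    co / sum(co)
  }
  f <- t(apply(B, 2, fit1))
  dimnames(f) <- list(colnames(B), colnames(X))
  CellProportions(f, compartmentTags(ref))
}
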
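# Evaluation statistics: stratified splitting, ROC/AUC with confidence
# intervals, trend regressions, annotation enrichment and subgroup analyses.

#' Stratified train/validation split
#'
#' Partitions samples into a training and a validation set, stratifying by
#' age bin, immune-cell-proportion bin and community-type label so the two
#' sets match on the covariates that drive methylation heterogeneity.
#' Within each (age bin x IC bin x label) stratum, samples are shuffled
#' under the seed and the training share is rounded to the closest integer
#' count to \code{trainFraction}. Singleton strata go to training.
#'
#' @param samples data.frame with columns \code{age}, \code{ic},
#'   \code{label}, and sample ids as rownames (or a column \code{id}).
#' @param trainFraction target training share (default 2/3).
#' @param ageBins breakpoints for age strata; default decade bins.
#' @param icBins breakpoints for IC strata; default the observed quartiles.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample} and \code{set}
#'   ("training"/"validation").
#' @export
stratifiedSplit <- function(samples, trainFraction = 2 / 3,
                            ageBins = NULL, icBins = NULL, seed = NULL) {
  stopifnot(all(c("age", "ic", "label") %in% colnames(samples)))
  ids <- if ("id" %in% colnames(samples)) as.character(samples$id)
         else rownames(samples)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(samples)))
  if (is.null(ageBins))
    ageBins <- seq(10 * floor(min(samples$age) / 10),
                   10 * ceiling(max(samples$age) / 10), by = 10)
  if (is.null(icBins))
    icBins <- unique(quantile(samples$ic, c(0, 0.25, 0.5, 0.75, 1)))
  binOrConstant <- function(x, breaks) {
    if (length(unique(breaks)) < 2) return(factor(rep("all", length(x))))
    cut(x, unique(breaks), include.lowest = TRUE)
  }
  ageB <- binOrConstant(samples$age, ageBins)
  icB <- binOrConstant(samples$ic, icBins)
  stratum <- interaction(ageB, icB, samples$label, drop = TRUE)
  set <- rep("training", nrow(samples))
  withSeed(seed, {
    for (s in levels(stratum)) {
      idx <- which(stratum == s)
      n <- length(idx)
      if (n <= 1) next                      # singleton -> training
      nTrain <- max(1L, min(n - 0L, round(n * trainFraction)))
      shuffled <- sample(idx)
      set[shuffled[seq_len(n - nTrain) + nTrain]] <- "validation"
    }
  })
  data.frame(sample = ids, set = set, stringsAsFactors = FALSE)
}

asBinary <- function(labels) {
  if (is.numeric(labels) || is.logical(labels)) {
    y <- as.integer(labels)
    if (!all(y %in% 0:1)) stop("numeric labels must be 0/1")
    return(y)
  }
  if (!all(labels %in% c("L", "O"))) stop("labels must be 'L'/'O' or 0/1")
  as.integer(labels == "O")
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The fraction of (positive, negative) score pairs where the positive
#' scores higher, ties counted one half.
#'
#' @param scores numeric scores (e.g. index values); higher favours the
#'   positive (O) class.
#' @param labels "L"/"O" labels or 0/1 outcomes (1 = O = positive).
#' @return scalar AUC in [0, 1].
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
rocAuc <- function(scores, labels) {
  y <- asBinary(labels)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

delongVariance <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  placePos <- vapply(pos, function(s)
    mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  placeNeg <- vapply(neg, function(s)
    mean((s < pos) + 0.5 * (s == pos)), numeric(1))
  var(placePos) / length(pos) + var(placeNeg) / length(neg)
}

#' AUC with a 95\% confidence interval
#'
#' \code{"delong"} uses the closed-form variance of the placement values
#' with a normal-theory interval, truncated to [0, 1];
#' \code{"stratified_bootstrap"} resamples within each class and takes the
#' 2.5/97.5 percentiles.
#'
#' @inheritParams rocAuc
#' @param method "delong" (default) or "stratified_bootstrap".
#' @param nBoot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param level confidence level (default 0.95).
#' @return a \linkS4class{RocResult}.
#' @export
aucCI <- function(scores, labels, method = c("delong",
                                             "stratified_bootstrap"),
                  nBoot = 2000, seed = NULL, level = 0.95) {
  method <- match.arg(method)
  y <- asBinary(labels)
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos < 5 || nNeg < 5)
    stop("need at least 5 samples per class")
  auc <- rocAuc(scores, y)
  if (method == "delong") {
    se <- sqrt(delongVariance(scores, y))
    z <- qnorm(1 - (1 - level) / 2)
    lo <- max(0, auc - z * se); hi <- min(1, auc + z * se)
  } else {
    posIdx <- which(y == 1); negIdx <- which(y == 0)
    boots <- withSeed(seed, vapply(seq_len(nBoot), function(i) {
      idx <- c(sample(posIdx, nPos, replace = TRUE),
               sample(negIdx, nNeg, replace = TRUE))
      rocAuc(scores[idx], y[idx])
    }, numeric(1)))
    qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                   names = FALSE)
    lo <- min(qs[1], auc); hi <- max(qs[2], auc)
  }
  new("RocResult", auc = auc, ciLow = lo, ciHigh = hi, method = method,
      nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' AUC per named sample subgroup
#'
#' Computes [rocAuc()] and [aucCI()] within each mask. Standard subgroup
#' masks (age below/at-or-above 50 years; IC below/at-or-above 0.5, i.e.
#' high versus low epithelial proportion) are available via
#' [subgroupMasks()]. Single-class subgroups are reported as NA with a
#' warning.
#'
#' @inheritParams aucCI
#' @param masks named list of logical vectors selecting samples.
#' @return data.frame: subgroup, n, nPos, nNeg, auc, ciLow, ciHigh.
#' @export
subgroupAuc <- function(scores, labels, masks,
                        method = c("delong", "stratified_bootstrap"),
                        nBoot = 2000, seed = NULL) {
  method <- match.arg(method)
  y <- asBinary(labels)
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (length(unique(y[m])) < 2) {
      warning("subgroup '", nm, "' contains a single class; reported as NA")
      return(data.frame(subgroup = nm, n = sum(m), nPos = sum(y[m] == 1),
                        nNeg = sum(y[m] == 0), auc = NA_real_,
                        ciLow = NA_real_, ciHigh = NA_real_))
    }
    ci <- aucCI(scores[m], y[m], method = method, nBoot = nBoot,
                seed = seed)
    data.frame(subgroup = nm, n = sum(m), nPos = ci@nPos, nNeg = ci@nNeg,
               auc = ci@auc, ciLow = ci@ciLow, ciHigh = ci@ciHigh)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn subgroupAuc the preset subgroup masks: age < 50 / >= 50
#'   years and IC < 0.5 / >= 0.5.
#' @param age,ic per-sample age (years) and immune-cell proportion.
#' @export
subgroupMasks <- function(age, ic) {
  list(age_lt50 = age < 50, age_ge50 = age >= 50,
       ic_lt0.5 = ic < 0.5, ic_ge0.5 = ic >= 0.5)
}

#' Ordinary least-squares trend of an index on a single covariate
#'
#' Fits \code{index ~ covariate} within an optional sample subset (e.g. the
#' L-type or O-type group) and reports intercept, slope and the two-sided
#' slope p-value.
#'
#' @param index numeric index values.
#' @param covariate numeric covariate (age in years, or IC).
#' @param group optional logical/index subset defining the group.
#' @param covariateName,groupLabel labels carried into the output.
#' @return one-row data.frame: intercept, slope, slopeP, covariate, group.
#' @export
linearTrend <- function(index, covariate, group = NULL,
                        covariateName = deparse(substitute(covariate)),
                        groupLabel = "all") {
  if (!is.null(group)) {
    index <- index[group]; covariate <- covariate[group]
  }
  if (length(index) < 3) stop("need at least 3 samples")
  if (sd(covariate) == 0) stop("covariate is constant")
  fit <- lm(index ~ covariate)
  sm <- summary(fit)$coefficients
  data.frame(intercept = sm[1, 1], slope = sm[2, 1], slopeP = sm[2, 4],
             covariate = covariateName, group = groupLabel,
             stringsAsFactors = FALSE)
}

#' CpG annotation enrichment of a selected probe set
#'
#' For each annotation category (CpG-island relation: island, shore, shelf,
#' open sea; or gene region), builds the 2x2 table of membership in the
#' selected set versus the remaining background and applies a two-sided
#' Fisher exact test. The reported odds ratio is the sample odds ratio
#' (ad/bc); p-values are BH-adjusted across categories. Unannotated probes
#' fall into category "unknown".
#'
#' @param selected character vector of selected probe ids; must be a subset
#'   of \code{background}.
#' @param background character vector of all candidate probe ids.
#' @param annotation data.frame with columns \code{probe} and
#'   \code{category}.
#' @return data.frame: category, counts of the 2x2 table, oddsRatio, p, q.
#' @export
annotationEnrichment <- function(selected, background, annotation) {
  extra <- setdiff(selected, background)
  if (length(extra))
    stop("selected probes outside the background: ",
         paste(head(extra, 5), collapse = ", "))
  stopifnot(all(c("probe", "category") %in% colnames(annotation)))
  cat <- annotation$category[match(background, annotation$probe)]
  cat[is.na(cat)] <- "unknown"
  inSel <- background %in% selected
  rows <- lapply(sort(unique(cat)), function(cc) {
    inCat <- cat == cc
    a <- sum(inSel & inCat); b <- sum(inSel & !inCat)
    c2 <- sum(!inSel & inCat); d <- sum(!inSel & !inCat)
    if (a + c2 == 0 || a + b == 0) {
      or <- NA_real_; p <- NA_real_
    } else {
      or <- (a * d) / (b * c2)
      p <- fisher.test(matrix(c(a, b, c2, d), 2))$p.value
    }
    data.frame(category = cc, selectedIn = a, selectedOut = b,
               backgroundIn = c2, backgroundOut = d,
               oddsRatio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- fdrAdjust(out$p[ok])
  rownames(out) <- NULL
  out
}
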
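# Elastic-net signature training: design construction, penalized paths,
# the pool-size x alpha cross-validated scan, scoring and serialization.

#' Build the classifier design matrix from a probe pool
#'
#' Columns are the beta values of the pooled probes, in pool order; in
#' nonlinear mode a second block of beta x IC interaction columns for the
#' same probes follows (second-order terms: the product of the methylation
#' value and the immune-cell proportion).
#'
#' @param x a \linkS4class{MethylCohort} or beta matrix (probes x samples).
#' @param pool ordered character vector of probe ids.
#' @param ic immune-cell proportion per sample; required when
#'   \code{nonlinear = TRUE}.
#' @param nonlinear add the interaction block?
#' @return list with \code{X} (samples x features) and \code{terms}, the
#'   data.frame of term descriptors (type, probe) in column order.
#' @export
buildDesignMatrix <- function(x, pool, ic = NULL, nonlinear = FALSE) {
  b <- if (is(x, "MethylCohort")) betaValues(x) else as.matrix(x)
  missing <- setdiff(pool, rownames(b))
  if (length(missing))
    stop("probes absent from beta: ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  X <- t(b[pool, , drop = FALSE])
  colnames(X) <- pool
  terms <- data.frame(type = "linear", probe = pool,
                      stringsAsFactors = FALSE)
  if (nonlinear) {
    if (is.null(ic)) stop("ic is required for the nonlinear design")
    stopifnot(length(ic) == nrow(X))
    XI <- X * ic
    colnames(XI) <- paste0(pool, ":IC")
    X <- cbind(X, XI)
    terms <- rbind(terms, data.frame(type = "interaction", probe = pool,
                                     stringsAsFactors = FALSE))
  }
  list(X = X, terms = terms)
}

#' Fit an elastic-net regularization path for logistic regression
#'
#' Minimizes the penalized negative log-likelihood with penalty
#' \eqn{\lambda[(1-\alpha)\frac{1}{2}\|w\|_2^2 + \alpha\|w\|_1]} along a
#' lambda path warm-started from the largest lambda. Features are
#' standardized internally for penalization; coefficients are reported on
#' the original scale. Constant columns are dropped (weight 0) with a
#' warning.
#'
#' @param X numeric feature matrix, samples x features.
#' @param y binary outcome (1 = O-type).
#' @param alpha elastic-net mixing parameter in [0, 1] (1 = lasso,
#'   0 = ridge).
#' @param lambda optional decreasing penalty sequence; by default the
#'   solver's own data-derived path.
#' @param nlambda path length when \code{lambda} is NULL.
#' @return the fitted \code{glmnet} path object.
#' @export
fitPenalizedLogistic <- function(X, y, alpha, lambda = NULL, nlambda = 100) {
  if (nrow(X) < 10) stop("need at least 10 samples")
  if (length(unique(y)) != 2) stop("outcome must have two classes")
  const <- apply(X, 2, function(col) max(col) - min(col) == 0)
  if (any(const))
    warning(sum(const), " constant feature column(s); their weight is 0")
  glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                 lambda = lambda, nlambda = nlambda, standardize = TRUE)
}

stratifiedFolds <- function(y, k, seed = NULL, maxAttempts = 10) {
  withSeed(seed, {
    for (att in seq_len(maxAttempts)) {
      fold <- integer(length(y))
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(y[fold != f])) == 2, logical(1)))
      if (ok) return(fold)
    }
    stop("could not draw folds with both classes in every training part")
  })
}

#' Cross-validated scan over feature-pool sizes and elastic-net mixing
#'
#' Scans the aggregated (or single-method) probe ranking from the top down:
#' for each candidate pool size, takes the top-ranked probes as the feature
#' pool, and for each alpha on the grid runs stratified k-fold
#' cross-validation of the full regularization path, measuring mean
#' validation AUC per lambda. The (pool, alpha, lambda) triple with the best
#' mean CV AUC is selected (ties resolved toward the sparser model: larger
#' lambda, then smaller pool, then smaller alpha) and refitted on all
#' supplied samples.
#'
#' @param x a \linkS4class{MethylCohort} or beta matrix of the training set.
#' @param labels "L"/"O" labels (colData default for cohorts).
#' @param ic immune-cell proportion per sample (needed for the nonlinear
#'   design; may be NULL for the linear index).
#' @param ranking a ranking or aggregated-ranking data.frame with columns
#'   \code{probe} and \code{rank}.
#' @param poolGrid ascending integer vector of candidate pool sizes
#'   (clipped to the number of ranked probes).
#' @param alphaGrid elastic-net mixing values; default the 11-point grid
#'   0, 0.1, ..., 1.
#' @param folds number of CV folds (default 10, label-stratified).
#' @param nonlinear include beta x IC second-order terms?
#' @param nlambda path length per fit.
#' @param seed integer seed controlling fold assignment.
#' @return a \linkS4class{TrainedSignature}.
#' @export
cvScan <- function(x, labels = NULL, ic = NULL, ranking,
                   poolGrid = c(1000, 2000, 5000, 10000, 20000, 50000),
                   alphaGrid = seq(0, 1, by = 0.1), folds = 10,
                   nonlinear = FALSE, nlambda = 100, seed = NULL) {
  b <- if (is(x, "MethylCohort")) betaValues(x) else as.matrix(x)
  if (is.null(labels) && is(x, "MethylCohort")) labels <- communityLabels(x)
  y <- as.integer(labels == "O")
  if (folds < 3) stop("need at least 3 folds")
  if (is.unsorted(poolGrid)) stop("poolGrid must be ascending")
  ranked <- ranking$probe[order(ranking$rank)]
  poolGrid <- unique(pmin(poolGrid, length(ranked)))
  fold <- stratifiedFolds(y, folds, seed = subSeed(seed, 1))

  profile <- list()
  best <- list(auc = -Inf)
  for (ps in poolGrid) {
    pool <- ranked[seq_len(ps)]
    dm <- buildDesignMatrix(b, pool, ic = ic, nonlinear = nonlinear)
    X <- dm$X
    for (a in alphaGrid) {
      full <- suppressWarnings(
        fitPenalizedLogistic(X, y, alpha = a, nlambda = nlambda))
      lam <- full$lambda
      aucMat <- matrix(NA_real_, folds, length(lam))
      for (f in seq_len(folds)) {
        tr <- fold != f
        fitF <- suppressWarnings(
          fitPenalizedLogistic(X[tr, , drop = FALSE], y[tr],
                               alpha = a, lambda = lam))
        if (length(unique(y[!tr])) < 2) next
        pred <- predict(fitF, X[!tr, , drop = FALSE], type = "link")
        aucMat[f, seq_len(ncol(pred))] <-
          apply(pred, 2, function(s) rocAuc(s, y[!tr]))
      }
      cvm <- colMeans(aucMat, na.rm = TRUE)
      profile[[length(profile) + 1]] <-
        data.frame(pool = ps, alpha = a, lambda = lam, cvAUC = cvm)
      jb <- which.max(cvm + 1e-12 * rank(lam))  # prefer larger lambda on ties
      if (cvm[jb] > best$auc + 1e-12) {
        best <- list(auc = cvm[jb], pool = ps, alpha = a,
                     lambda = lam[jb], X = X, terms = dm$terms,
                     lambdaSeq = lam)
      }
    }
  }
  finalFit <- suppressWarnings(
    fitPenalizedLogistic(best$X, y, alpha = best$alpha,
                         lambda = best$lambdaSeq))
  co <- as.numeric(predict(finalFit, type = "coefficients",
                           s = best$lambda, exact = FALSE))
  terms <- best$terms
  terms$weight <- co[-1]
  new("TrainedSignature", terms = terms, intercept = co[1],
      alpha = best$alpha, lambda = best$lambda,
      poolSize = as.numeric(best$pool), nonlinear = nonlinear,
      cvProfile = do.call(rbind, profile))
}

#' Compute the methylation index for a set of samples
#'
#' Applies a \linkS4class{TrainedSignature}: the index is the linear
#' predictor intercept + sum over terms of weight x feature, where a linear
#' term's feature is the probe's beta value and an interaction term's
#' feature is beta x IC. The value is on the log-odds scale; higher values
#' favour the O community type.
#'
#' @param sig a \linkS4class{TrainedSignature}.
#' @param x a \linkS4class{MethylCohort} or beta matrix.
#' @param ic immune-cell proportion per sample; required if the signature
#'   carries nonzero interaction terms.
#' @return named numeric vector of index values, one per sample.
#' @export
computeIndex <- function(sig, x, ic = NULL) {
  stopifnot(is(sig, "TrainedSignature"))
  b <- if (is(x, "MethylCohort")) betaValues(x) else as.matrix(x)
  tt <- signatureTerms(sig, nonzero = TRUE)
  missing <- setdiff(unique(tt$probe), rownames(b))
  if (length(missing))
    stop("required probe(s) missing from beta: ",
         paste(head(missing, 5), collapse = ", "))
  out <- rep(sig@intercept, ncol(b))
  names(out) <- colnames(b)
  lin <- tt[tt$type == "linear", , drop = FALSE]
  if (nrow(lin))
    out <- out + drop(crossprod(b[lin$probe, , drop = FALSE], lin$weight))
  int <- tt[tt$type == "interaction", , drop = FALSE]
  if (nrow(int)) {
    if (is.null(ic)) stop("ic is required: signature has interaction terms")
    stopifnot(length(ic) == ncol(b))
    out <- out + drop(crossprod(b[int$probe, , drop = FALSE],
                                int$weight)) * ic
  }
  out
}

#' @describeIn computeIndex write a signature to a TSV file: '#'-prefixed
#'   header metadata (alpha, lambda, pool size, mode, term hash) followed by
#'   the term table (type, probe, weight). Zero-weight terms are omitted.
#' @param file path to write to / read from.
#' @export
exportSignature <- function(sig, file) {
  stopifnot(is(sig, "TrainedSignature"))
  tt <- signatureTerms(sig, nonzero = TRUE)
  hdr <- c(sprintf("# alpha\t%.17g", sig@alpha),
           sprintf("# lambda\t%.17g", sig@lambda),
           sprintf("# pool\t%d", as.integer(sig@poolSize)),
           sprintf("# nonlinear\t%s", tolower(sig@nonlinear)),
           sprintf("# intercept\t%.17g", sig@intercept),
           sprintf("# n_terms\t%d", nrow(tt)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("type\tprobe\tweight", con)
  if (nrow(tt))
    writeLines(sprintf("%s\t%s\t%.17g", tt$type, tt$probe, tt$weight), con)
  invisible(file)
}

#' @describeIn computeIndex read a signature file written by
#'   \code{exportSignature}; the round trip preserves index values to
#'   numerical precision.
#' @export
loadSignature <- function(file) {
  lines <- readLines(file)
  isMeta <- startsWith(lines, "# ")
  meta <- lines[isMeta]
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "\t", fixed = TRUE))
  vals <- setNames(kv[, 2], kv[, 1])
  need <- c("alpha", "lambda", "pool", "nonlinear", "intercept")
  if (!all(need %in% names(vals)))
    stop("malformed signature file: missing header field(s) ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  body <- lines[!isMeta]
  if (length(body) == 0 || body[1] != "type\tprobe\tweight")
    stop("malformed signature file at line ", sum(isMeta) + 1,
         ": expected column header 'type\tprobe\tweight'")
  terms <- if (length(body) > 1) {
    parts <- strsplit(body[-1], "\t", fixed = TRUE)
    badLen <- which(lengths(parts) != 3)
    if (length(badLen))
      stop("malformed signature file at line ",
           sum(isMeta) + 1 + badLen[1], ": expected 3 fields")
    df <- data.frame(type = vapply(parts, `[`, "", 1),
                     probe = vapply(parts, `[`, "", 2),
                     weight = as.numeric(vapply(parts, `[`, "", 3)),
                     stringsAsFactors = FALSE)
    badType <- which(!df$type %in% c("linear", "interaction"))
    if (length(badType))
      stop("malformed signature file at line ",
           sum(isMeta) + 1 + badType[1], ": unknown term type '",
           df$type[badType[1]], "'")
    if (anyNA(df$weight))
      stop("malformed signature file: non-numeric weight")
    df
  } else data.frame(type = character(), probe = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  new("TrainedSignature", terms = terms,
      intercept = as.numeric(vals["intercept"]),
      alpha = as.numeric(vals["alpha"]),
      lambda = as.numeric(vals["lambda"]),
      poolSize = as.numeric(vals["pool"]),
      nonlinear = identical(unname(vals["nonlinear"]), "true"),
      cvProfile = data.frame())
}
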
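# Firth bias-reduced logistic regression with profile-penalized-likelihood
# confidence intervals and penalized-likelihood-ratio tests.

logistLik <- function(eta, y) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# Penalized log-likelihood l(b) + 0.5 log det(X'WX) and its ingredients.
# Returns NULL when the information matrix is (numerically) singular.
firthPieces <- function(X, y, b) {
  eta <- drop(X %*% b)
  pr <- 1 / (1 + exp(-eta))
  w <- pr * (1 - pr)
  I <- crossprod(X, X * w)
  ch <- tryCatch(chol(I), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Iinv <- chol2inv(ch)
  h <- w * rowSums((X %*% Iinv) * X)
  list(pll = logistLik(eta, y) + sum(log(diag(ch))),
       score = drop(crossprod(X, y - pr + h * (0.5 - pr))),
       I = I, Iinv = Iinv)
}

# Maximize the Jeffreys-penalized likelihood by modified-score Newton
# iteration with step-halving; `fixedIdx`/`fixedVal` hold coefficients at
# given values (used for profile likelihoods and PLRT null fits).
firthCore <- function(X, y, fixedIdx = integer(), fixedVal = numeric(),
                      start = NULL, maxit = 100, tol = 1e-8,
                      maxstep = 5, gradTol = 1e-4) {
  p <- ncol(X)
  b <- if (is.null(start)) rep(0, p) else start
  b[fixedIdx] <- fixedVal
  free <- setdiff(seq_len(p), fixedIdx)
  pc <- firthPieces(X, y, b)
  if (is.null(pc) && !is.null(start)) {
    # retry from the origin: fitted probabilities 0.5, information regular
    b <- rep(0, p)
    b[fixedIdx] <- fixedVal
    pc <- firthPieces(X, y, b)
  }
  if (is.null(pc)) stop("information matrix singular at the start values")
  iter <- 0L
  converged <- FALSE
  while (iter < maxit) {
    iter <- iter + 1L
    if (length(free) == 0) { converged <- TRUE; break }
    g <- pc$score[free]
    if (max(abs(g)) < 1e-6 && iter > 1) { converged <- TRUE; break }
    step <- tryCatch(solve(pc$I[free, free, drop = FALSE], g),
                     error = function(e) g / max(diag(pc$I)[free]))
    sl <- sqrt(sum(step^2))
    if (sl > maxstep) step <- step * maxstep / sl
    ok <- FALSE
    for (half in 0:20) {
      bNew <- b
      bNew[free] <- b[free] + step / 2^half
      pcNew <- firthPieces(X, y, bNew)
      if (!is.null(pcNew) && is.finite(pcNew$pll) &&
          pcNew$pll >= pc$pll - 1e-12) {
        ok <- TRUE; break
      }
    }
    if (!ok) { converged <- max(abs(g)) < gradTol; break }
    moved <- max(abs(bNew - b))
    b <- bNew; pc <- pcNew
    if (moved < tol) { converged <- TRUE; break }
  }
  if (!converged && length(free) &&
      max(abs(pc$score[free])) > max(gradTol, 1e-3))
    stop("Firth fit did not converge; last gradient norm ",
         format(max(abs(pc$score[free])), digits = 4))
  list(coef = b, pll = pc$pll, Iinv = pc$Iinv, iter = iter,
       converged = TRUE)
}

# Profile penalized log-likelihood with coefficient j fixed at v. The
# one-dimensional constrained maximizations far from the optimum can stall
# in flat, ill-conditioned regions; a looser gradient tolerance is accepted
# there because a residual gradient g mis-states the profile value by only
# ~ g^2 / (2 I), negligible against the chi-square cut-off. Regions where
# the Fisher information degenerates (fitted probabilities collapse to 0/1)
# have penalized likelihood -Inf and are reported as such.
firthProfile <- function(X, y, j, v, start) {
  tryCatch(firthCore(X, y, fixedIdx = j, fixedVal = v, start = start,
                     gradTol = 0.05)[c("pll", "coef")],
           error = function(e) list(pll = -Inf, coef = start))
}

#' Firth bias-reduced logistic regression
#'
#' Maximizes the Jeffreys-penalized log-likelihood
#' \eqn{\ell(\beta) + \frac{1}{2}\log\det I(\beta)} by modified-score Newton
#' iterations with step-halving. Estimates remain finite under complete
#' separation and zero cells in contingency tables, where ordinary maximum
#' likelihood diverges. Confidence intervals come from the profile penalized
#' likelihood (chi-square cut-off at the requested level, located by
#' root-finding to 1e-6); p-values are penalized likelihood-ratio tests of
#' each coefficient against zero.
#'
#' @param y binary outcome (0/1, logical, or "L"/"O" with O = 1).
#' @param X covariate matrix or data.frame (an intercept is added).
#' @param level confidence level (default 0.95).
#' @param maxit maximum Newton iterations.
#' @return a \linkS4class{FirthFit}.
#' @examples
#' y <- rep(c(0, 1), each = 20)
#' x <- y + rnorm(40)          # informative covariate
#' firthLogistic(y, cbind(x = x))
#' @export
firthLogistic <- function(y, X, level = 0.95, maxit = 100) {
  y <- asBinary(y)
  if (length(unique(y)) < 2) stop("outcome is constant")
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  # scale covariate columns to unit spread for numerical conditioning; a
  # pure scaling is an exact reparametrization (b_orig = b_scaled / s), so
  # estimates, profile CIs and p-values map back exactly
  sds <- apply(X, 2, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  Xd <- cbind("(Intercept)" = 1, sweep(X, 2, sds, "/"))
  scl <- c(1, sds)
  stopifnot(nrow(Xd) == length(y))
  fit <- firthCore(Xd, y, maxit = maxit)
  est <- fit$coef
  se <- sqrt(diag(fit$Iinv))
  cut <- qchisq(level, 1)
  bound <- function(j, dir) {
    # outermost v with 2*(pllMax - profile(v)) <= cut, searched outward
    # with warm starts from the previous profile solution
    warm <- est
    f <- function(v) {
      pr <- firthProfile(Xd, y, j, v, warm)
      if (!identical(warm, est)) {     # guard against a stalled warm start
        pr2 <- firthProfile(Xd, y, j, v, est)
        if (pr2$pll > pr$pll) pr <- pr2
      }
      if (is.finite(pr$pll)) warm <<- pr$coef
      val <- 2 * (fit$pll - pr$pll) - cut
      if (!is.finite(val)) val <- 1e10
      val
    }
    step <- max(se[j], 0.5)
    lo <- est[j]; hi <- est[j] + dir * step
    for (k in 1:40) {
      if (f(hi) >= 0) break
      lo <- hi
      hi <- hi + dir * step * 2^k
      if (k == 40) return(dir * Inf)
    }
    if (f(lo) >= 0) lo <- est[j]   # guard: the estimate is always inside
    uniroot(f, sort(c(lo, hi)), tol = 1e-6)$root
  }
  plrtP <- function(j) {
    null <- firthCore(Xd, y, fixedIdx = j, fixedVal = 0, start = est,
                      gradTol = 0.05)
    pchisq(2 * (fit$pll - null$pll), df = 1, lower.tail = FALSE)
  }
  idx <- seq_along(est)
  lo <- vapply(idx, bound, numeric(1), dir = -1)
  hi <- vapply(idx, bound, numeric(1), dir = 1)
  pv <- vapply(idx, plrtP, numeric(1))
  coefs <- data.frame(term = colnames(Xd), estimate = unname(est / scl),
                      or = exp(unname(est / scl)), ciLow = exp(lo / scl),
                      ciHigh = exp(hi / scl), p = pv,
                      stringsAsFactors = FALSE)
  new("FirthFit", coefficients = coefs, logLik = fit$pll,
      iter = fit$iter, converged = fit$converged)
}

#' Firth association models of an index with community type
#'
#' Fits a set of bias-reduced logistic models of the community-type outcome
#' (O = 1) on the index, unadjusted and adjusted for covariate subsets
#' (by default: age; IC; age + IC). Samples with a missing value in any
#' covariate used by a model are dropped for that model only.
#'
#' @param index numeric index values (per unit of the linear predictor).
#' @param covariates data.frame with a \code{label} column ("L"/"O") and
#'   the adjustment covariates.
#' @param adjustments named list of covariate-name subsets; each entry
#'   yields one model containing the index plus those covariates.
#' @return data.frame with one row per (model, term): estimate, OR,
#'   profile-penalized CI and PLRT p.
#' @export
associationScan <- function(index, covariates,
                            adjustments = list(
                              unadjusted = character(0),
                              age = "age", ic = "ic",
                              age_ic = c("age", "ic"))) {
  stopifnot("label" %in% colnames(covariates),
            nrow(covariates) == length(index))
  rows <- lapply(names(adjustments), function(nm) {
    covs <- adjustments[[nm]]
    absent <- setdiff(covs, colnames(covariates))
    if (length(absent))
      stop("covariate(s) absent from the sample sheet: ",
           paste(absent, collapse = ", "))
    Xm <- cbind(index = index)
    if (length(covs))
      Xm <- cbind(Xm, as.matrix(covariates[, covs, drop = FALSE]))
    keep <- stats::complete.cases(Xm) & !is.na(covariates$label)
    fit <- firthLogistic(covariates$label[keep], Xm[keep, , drop = FALSE])
    cf <- firthCoefficients(fit)
    cf <- cf[cf$term != "(Intercept)", , drop = FALSE]
    cbind(model = nm, n = sum(keep), cf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
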
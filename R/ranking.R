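# Per-CpG ranking statistics and geometric-mean rank aggregation.
#
# All five methods return a data.frame with one row per probe and columns
# probe, statistic, p, q (adjusted logistic only), direction ("hyper_in_O" /
# "hypo_in_O"), flagged, rank (1 = strongest), and carry the method name in
# attr(, "method"). Class encoding throughout: O = 1, L = 0, so positive
# effects are hyper-methylated in O-type samples.

rankingInputs <- function(x, labels) {
  b <- if (is(x, "MethylCohort")) betaValues(x) else as.matrix(x)
  if (is.null(labels) && is(x, "MethylCohort")) labels <- communityLabels(x)
  if (is.null(labels)) stop("labels are required")
  if (length(labels) != ncol(b))
    stop("labels length must match the number of samples")
  if (!all(labels %in% c("L", "O"))) stop("labels must be 'L' or 'O'")
  if (anyNA(b)) stop("beta matrix contains missing values; impute first")
  list(b = b, y = as.integer(labels == "O"))
}

rankTies <- function(keys, stat, probe) {
  order(keys, -abs(stat), probe)
}

finishRanking <- function(df, method, orderKeys) {
  ord <- rankTies(orderKeys, df$statistic, df$probe)
  df$rank <- integer(nrow(df))
  df$rank[ord] <- seq_len(nrow(df))
  df <- df[order(df$rank), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "method") <- method
  df
}

#' Rank CpGs by logistic regression adjusted for age and immune fraction
#'
#' Fits, per probe j, the model \code{logit P(O) ~ beta_j + age + IC} and
#' ranks probes by the two-sided Wald p-value of the beta coefficient.
#' Adjustment for age and IC is essential: both are strong correlates of
#' community type, and unadjusted differences are dominated by cell-type
#' composition. Probes whose fit does not converge (or whose coefficient is
#' inestimable, e.g. constant probes) are flagged, assigned statistic 0 and
#' p = 1, and sink to the bottom of the ranking rather than aborting a
#' genome-scale scan.
#'
#' @param x a \linkS4class{MethylCohort} or beta matrix (probes x samples).
#' @param labels "L"/"O" per sample (taken from \code{colData} when \code{x}
#'   is a cohort).
#' @param age numeric vector of ages, years.
#' @param ic immune-cell proportion per sample (e.g. \code{icFraction()} of
#'   a deconvolution result).
#' @param statistic \code{"wald"} (default) ranks by the Wald z of the beta
#'   coefficient; \code{"lrt"} ranks by the signed square root of the
#'   likelihood-ratio chi-square against the age + IC null model. The LRT
#'   variant does not suffer the Wald statistic's collapse
#'   (Hauck-Donner effect) on probes with near-complete separation.
#' @return ranking data.frame with a BH-adjusted \code{q} column.
#' @export
rankAdjustedLogistic <- function(x, labels = NULL, age, ic,
                                 statistic = c("wald", "lrt")) {
  statistic <- match.arg(statistic)
  inp <- rankingInputs(x, labels)
  b <- inp$b; y <- inp$y
  stopifnot(length(age) == ncol(b), length(ic) == ncol(b))
  if (min(table(y)) < 10)
    stop("need at least 10 samples per class")
  p <- nrow(b)
  stat <- numeric(p); pv <- rep(1, p); flag <- logical(p)
  dev0 <- if (statistic == "lrt")
    suppressWarnings(glm.fit(cbind(1, age, ic), y,
                             family = binomial()))$deviance else NA_real_
  for (j in seq_len(p)) {
    X <- cbind(1, b[j, ], age, ic)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = binomial())),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged && fit$qr$rank == ncol(X)
    if (!ok) { flag[j] <- TRUE; next }
    co <- fit$coefficients[2]
    if (!is.finite(co)) { flag[j] <- TRUE; next }
    if (statistic == "lrt") {
      lr <- max(dev0 - fit$deviance, 0)
      stat[j] <- sign(co) * sqrt(lr)
      pv[j] <- pchisq(lr, df = 1, lower.tail = FALSE)
      next
    }
    R <- fit$qr$qr[seq_len(ncol(X)), , drop = FALSE]
    R[lower.tri(R)] <- 0
    cov <- tryCatch(chol2inv(R), error = function(e) NULL)
    if (is.null(cov) || any(!is.finite(diag(cov)))) {
      flag[j] <- TRUE; next
    }
    piv <- fit$qr$pivot
    se <- sqrt(diag(cov))[order(piv)][2]
    if (!is.finite(se) || se == 0) {
      flag[j] <- TRUE; next
    }
    stat[j] <- co / se
    pv[j] <- 2 * pnorm(-abs(stat[j]))
  }
  df <- data.frame(probe = rownames(b), statistic = stat, p = pv,
                   q = fdrAdjust(pv),
                   direction = ifelse(stat >= 0, "hyper_in_O", "hypo_in_O"),
                   flagged = flag, stringsAsFactors = FALSE)
  finishRanking(df, "adjusted_logistic", df$p)
}

rowVarsBy <- function(b, sel) {
  m <- rowMeans(b[, sel, drop = FALSE])
  v <- rowSums((b[, sel, drop = FALSE] - m)^2) / (sum(sel) - 1)
  list(mean = m, var = v, n = sum(sel))
}

#' Rank CpGs by Welch's unequal-variance two-sample t-test
#'
#' @inheritParams rankAdjustedLogistic
#' @return ranking data.frame.
#' @export
rankWelch <- function(x, labels = NULL) {
  inp <- rankingInputs(x, labels)
  b <- inp$b; y <- inp$y
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  gO <- rowVarsBy(b, y == 1); gL <- rowVarsBy(b, y == 0)
  seSq <- gO$var / gO$n + gL$var / gL$n
  t <- (gO$mean - gL$mean) / sqrt(seSq)
  df <- seSq^2 / ((gO$var / gO$n)^2 / (gO$n - 1) +
                  (gL$var / gL$n)^2 / (gL$n - 1))
  pv <- 2 * pt(-abs(t), df)
  flag <- !is.finite(t)              # both groups constant (or zero se)
  t[flag] <- 0; pv[flag] <- 1
  out <- data.frame(probe = rownames(b), statistic = t, p = pv,
                    direction = ifelse(gO$mean >= gL$mean,
                                       "hyper_in_O", "hypo_in_O"),
                    flagged = flag, stringsAsFactors = FALSE)
  finishRanking(out, "welch", out$p)
}

#' Rank CpGs by Bartlett's test of equal variances between community types
#'
#' Captures differential variability rather than differential means. The
#' direction reports which community type is more variable
#' (\code{"hyper_in_O"} when the O group has the larger variance).
#'
#' @inheritParams rankAdjustedLogistic
#' @return ranking data.frame.
#' @export
rankBartlett <- function(x, labels = NULL) {
  inp <- rankingInputs(x, labels)
  b <- inp$b; y <- inp$y
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  gO <- rowVarsBy(b, y == 1); gL <- rowVarsBy(b, y == 0)
  nO <- gO$n; nL <- gL$n; N <- nO + nL; k <- 2
  sp <- ((nO - 1) * gO$var + (nL - 1) * gL$var) / (N - k)
  C <- 1 + (1 / (nO - 1) + 1 / (nL - 1) - 1 / (N - k)) / (3 * (k - 1))
  stat <- ((N - k) * log(sp) -
           (nO - 1) * log(gO$var) - (nL - 1) * log(gL$var)) / C
  flag <- gO$var == 0 | gL$var == 0 | !is.finite(stat)
  stat[flag] <- 0
  pv <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  pv[flag] <- 1
  out <- data.frame(probe = rownames(b), statistic = stat, p = pv,
                    direction = ifelse(gO$var >= gL$var,
                                       "hyper_in_O", "hypo_in_O"),
                    flagged = flag, stringsAsFactors = FALSE)
  finishRanking(out, "bartlett", out$p)
}

#' Rank CpGs by the delta-beta intercept-extrapolation statistic
#'
#' Per probe, fits \code{beta ~ IC} by ordinary least squares separately in
#' the O and the L group; delta-beta is the difference between the two
#' y-intercepts at IC = 0 (intercept_O - intercept_L) — an extrapolated
#' pure-epithelial group difference that isolates signal originating from
#' the epithelial compartment. Probes are ranked by descending |delta-beta|;
#' no p-value is attached.
#'
#' @inheritParams rankAdjustedLogistic
#' @param ic immune-cell proportion per sample.
#' @return ranking data.frame (column \code{p} is NA).
#' @export
rankDeltaBeta <- function(x, labels = NULL, ic) {
  inp <- rankingInputs(x, labels)
  b <- inp$b; y <- inp$y
  stopifnot(length(ic) == ncol(b))
  groupIntercepts <- function(sel, name) {
    if (sum(sel) < 3)
      stop("group ", name, " has fewer than 3 samples")
    if (sd(ic[sel]) == 0)
      stop("IC is constant within group ", name,
           "; the IC = 0 intercept is unidentifiable")
    D <- cbind(1, ic[sel])
    co <- qr.coef(qr(D), t(b[, sel, drop = FALSE]))
    co[1, ]
  }
  dB <- groupIntercepts(y == 1, "O") - groupIntercepts(y == 0, "L")
  out <- data.frame(probe = rownames(b), statistic = unname(dB),
                    p = NA_real_,
                    direction = ifelse(dB >= 0, "hyper_in_O", "hypo_in_O"),
                    flagged = !is.finite(dB), stringsAsFactors = FALSE)
  finishRanking(out, "delta_beta", -abs(out$statistic))
}

#' Rank CpGs by a cell-type interaction (CellDMC-style) model
#'
#' Per probe, fits the no-intercept linear model
#' \code{beta ~ sum_k f_k + sum_k f_k x label} over the compartments
#' (epithelial, fibroblast, immune), so each compartment contributes its own
#' baseline and its own community-type interaction. The summary p-value is
#' the smallest per-compartment interaction p, Bonferroni-scaled by the
#' number of compartments; the direction is the sign of the winning
#' interaction coefficient.
#'
#' @inheritParams rankAdjustedLogistic
#' @param fractions a \linkS4class{CellProportions} for the same samples.
#' @return ranking data.frame; per-compartment interaction p-values are
#'   attached as \code{attr(, "compartmentP")}.
#' @export
rankCellDMC <- function(x, labels = NULL, fractions) {
  inp <- rankingInputs(x, labels)
  b <- inp$b; y <- inp$y
  stopifnot(is(fractions, "CellProportions"))
  F <- compartmentFractions(fractions)
  if (nrow(F) != ncol(b))
    stop("fractions must cover every sample")
  if (ncol(F) < 2) stop("need at least 2 compartments")
  C <- ncol(F)
  D <- cbind(F, F * y)
  colnames(D) <- c(colnames(F), paste0(colnames(F), ":O"))
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("collinear compartment-fraction design")
  co <- qr.coef(qrD, t(b))                      # 2C x probes
  res <- t(b) - D %*% co
  dfres <- nrow(D) - ncol(D)
  sigma2 <- colSums(res^2) / dfres
  XtXinv <- chol2inv(qr.R(qrD))[order(qrD$pivot), order(qrD$pivot)]
  intIdx <- C + seq_len(C)
  se <- sqrt(outer(diag(XtXinv)[intIdx], sigma2))  # C x probes
  tt <- co[intIdx, , drop = FALSE] / se
  pc <- 2 * pt(-abs(tt), dfres)
  win <- apply(pc, 2, which.min)
  pmin1 <- pc[cbind(win, seq_len(ncol(pc)))]
  psum <- pmin(pmin1 * C, 1)
  winCoef <- co[intIdx, , drop = FALSE][cbind(win, seq_len(ncol(pc)))]
  flag <- !is.finite(psum)
  psum[flag] <- 1; winCoef[flag] <- 0
  out <- data.frame(probe = rownames(b),
                    statistic = tt[cbind(win, seq_len(ncol(pc)))],
                    p = psum,
                    direction = ifelse(winCoef >= 0, "hyper_in_O",
                                       "hypo_in_O"),
                    compartment = colnames(F)[win],
                    flagged = flag, stringsAsFactors = FALSE)
  out <- finishRanking(out, "celldmc", out$p)
  cp <- t(pc); colnames(cp) <- colnames(F); rownames(cp) <- rownames(b)
  attr(out, "compartmentP") <- cp
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of BH step-up adjusted q-values.
#' @export
fdrAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Aggregate ranking methods by the geometric mean of ranks
#'
#' Combines per-method ranks into gm_rank(j) = (prod_m rank_m(j))^(1/M) and
#' orders probes by ascending geometric mean. The geometric mean rewards
#' consistency across complementary statistics (mean shifts, variability,
#' adjusted association, epithelial extrapolation, compartment
#' interactions). Ties are broken by the adjusted-logistic rank when that
#' method is present (otherwise by the first method supplied), then by probe
#' id; the result does not depend on the order in which methods are
#' supplied.
#'
#' @param rankings list of ranking data.frames (from the rank* functions)
#'   over a common probe set, typically all five methods.
#' @return data.frame with per-method rank columns, \code{gmRank} and the
#'   final \code{rank}.
#' @export
aggregateRanks <- function(rankings) {
  if (length(rankings) < 2) stop("supply at least two rankings")
  methods <- vapply(rankings, function(r) {
    m <- attr(r, "method")
    if (is.null(m)) stop("ranking without a method attribute")
    m
  }, character(1))
  if (anyDuplicated(methods)) stop("duplicate ranking methods")
  names(rankings) <- methods
  probes <- sort(rankings[[1]]$probe)
  for (m in methods) {
    diff <- c(setdiff(rankings[[m]]$probe, probes),
              setdiff(probes, rankings[[m]]$probe))
    if (length(diff))
      stop("probe sets differ across methods: ",
           paste(head(diff, 5), collapse = ", "),
           if (length(diff) > 5) " ...")
  }
  rk <- vapply(rankings, function(r) as.numeric(r$rank[match(probes, r$probe)]),
               numeric(length(probes)))
  gm <- exp(rowMeans(log(rk)))
  tieMethod <- if ("adjusted_logistic" %in% methods) "adjusted_logistic"
               else methods[1]
  tie <- rk[, tieMethod]
  ord <- order(gm, tie, probes)
  out <- data.frame(probe = probes, rk, gmRank = gm,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
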
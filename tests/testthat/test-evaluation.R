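test_that("stratified splitting honours the 2/3 share per stratum and the seed", {
  sheet <- data.frame(age = rep(44, 300), ic = rep(0.2, 300),
                      label = rep("L", 300))
  rownames(sheet) <- paste0("s", 1:300)
  sp <- stratifiedSplit(sheet, seed = 1)
  expect_equal(sum(sp$set == "training"), 200)
  expect_equal(sum(sp$set == "validation"), 100)

  two <- data.frame(age = c(30, 31), ic = c(0.1, 0.1), label = c("O", "O"))
  rownames(two) <- c("a", "b")
  sp2 <- stratifiedSplit(two, seed = 2)
  expect_setequal(sp2$set, c("training", "validation"))

  one <- data.frame(age = 50, ic = 0.5, label = "L")
  rownames(one) <- "solo"
  expect_equal(stratifiedSplit(one, seed = 3)$set, "training")

  sp3 <- stratifiedSplit(sheet, seed = 1)
  expect_identical(sp, sp3)
})

test_that("stratified splitting preserves per-stratum label prevalence", {
  set.seed(11)
  sheet <- data.frame(age = runif(240, 20, 79), ic = runif(240),
                      label = sample(c("L", "O"), 240, replace = TRUE))
  rownames(sheet) <- paste0("s", 1:240)
  sp <- stratifiedSplit(sheet, seed = 4)
  ageB <- cut(sheet$age, seq(20, 80, 10), include.lowest = TRUE)
  icB <- cut(sheet$ic, quantile(sheet$ic, 0:4 / 4), include.lowest = TRUE)
  strata <- interaction(ageB, icB, sheet$label, drop = TRUE)
  for (s in levels(strata)) {
    idx <- strata == s
    n <- sum(idx)
    nTrain <- sum(sp$set[idx] == "training")
    expect_lte(abs(nTrain - round(n * 2 / 3)), 1)
  }
})

test_that("AUC matches hand enumeration and is monotone-invariant", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(21)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5)
  expect_equal(rocAuc(s, y), rocAuc(exp(3 * s), y), tolerance = 1e-12)
  expect_error(rocAuc(s, rep(1, 50)), "both classes")
})

test_that("DeLong intervals match pROC and agree with the stratified bootstrap", {
  skip_if_not_installed("pROC")
  set.seed(22)
  n <- 200
  y <- rep(c(0, 1), each = n)
  s <- c(rnorm(n), rnorm(n, 1))
  mine <- aucCI(s, y, method = "delong")
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s), method = "delong"))
  expect_equal(mine@auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(mine@ciLow, as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(mine@ciHigh, as.numeric(ref[3]), tolerance = 1e-6)

  boot <- aucCI(s, y, method = "stratified_bootstrap", seed = 23)
  expect_lt(abs(boot@ciLow - mine@ciLow), 0.03)
  expect_lt(abs(boot@ciHigh - mine@ciHigh), 0.03)
  boot2 <- aucCI(s, y, method = "stratified_bootstrap", seed = 23)
  expect_identical(c(boot@ciLow, boot@ciHigh), c(boot2@ciLow, boot2@ciHigh))

  sep <- aucCI(c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15),
               rep(c(0, 1), each = 5), method = "delong")
  expect_equal(sep@auc, 1)
  expect_equal(sep@ciHigh, 1)
})

test_that("confidence intervals tighten with sample size", {
  set.seed(24)
  widths <- vapply(c(50, 200, 800), function(n) {
    y <- rep(c(0, 1), each = n)
    s <- c(rnorm(n), rnorm(n, 1))
    ci <- aucCI(s, y, method = "delong")
    ci@ciHigh - ci@ciLow
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("Firth fit on a symmetric table gives OR 1 and p 1", {
  y <- rep(c(1, 0, 1, 0), c(10, 10, 10, 10))
  g <- rep(c(0, 0, 1, 1), c(10, 10, 10, 10))
  fit <- firthLogistic(y, cbind(group = g))
  co <- firthCoefficients(fit)
  row <- co[co$term == "group", ]
  expect_equal(row$or, 1, tolerance = 1e-8)
  expect_equal(row$p, 1, tolerance = 1e-8)
  expect_lt(row$ciLow, 1)
  expect_gt(row$ciHigh, 1)
})

test_that("Firth estimates on a zero-cell table match a brute-force grid maximizer", {
  # group A: 10 events / 0 non-events; group B: 5 / 5
  y <- c(rep(1, 10), rep(1, 5), rep(0, 5))
  g <- c(rep(1, 10), rep(0, 10))
  X <- cbind(1, g)
  penll <- function(b0, b1) {
    eta <- X %*% c(b0, b1)
    pr <- 1 / (1 + exp(-eta))
    I <- crossprod(X, X * as.numeric(pr * (1 - pr)))
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus
  }
  grid <- expand.grid(b0 = seq(-3, 3, 0.1), b1 = seq(-1, 6, 0.1))
  vals <- mapply(penll, grid$b0, grid$b1)
  bestCoarse <- grid[which.max(vals), ]
  fine <- expand.grid(b0 = seq(bestCoarse$b0 - 0.2, bestCoarse$b0 + 0.2,
                               0.0005),
                      b1 = seq(bestCoarse$b1 - 0.2, bestCoarse$b1 + 0.2,
                               0.0005))
  valsF <- mapply(penll, fine$b0, fine$b1)
  best <- fine[which.max(valsF), ]
  fit <- firthLogistic(y, cbind(group = g))
  co <- firthCoefficients(fit)
  expect_lt(abs(co$estimate[co$term == "(Intercept)"] - best$b0), 1e-3)
  expect_lt(abs(co$estimate[co$term == "group"] - best$b1), 1e-3)
  expect_true(all(is.finite(co$estimate)))
})

test_that("Firth fitting stays finite under complete separation", {
  x <- c(-5:-1, 1:5) + 10
  y <- as.integer(x > 10)
  fit <- firthLogistic(y, cbind(x = x))
  co <- firthCoefficients(fit)
  expect_true(all(is.finite(co$estimate)))
  expect_true(all(is.finite(co$ciLow) & is.finite(co$ciHigh)))
  # the unpenalized MLE diverges on this fixture
  mle <- suppressWarnings(glm(y ~ x, family = binomial()))
  expect_gt(abs(coef(mle)[2]), 10 * abs(co$estimate[co$term == "x"]))
})

test_that("Firth estimates approach the MLE as n grows", {
  set.seed(25)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.8 * x))
  fit <- firthLogistic(y, cbind(x = x))
  mle <- glm(y ~ x, family = binomial())$coefficients
  expect_lt(abs(firthCoefficients(fit)$estimate[2] - mle[2]), 0.01)
})

test_that("association scans report calibrated and signal-bearing index effects", {
  set.seed(26)
  n <- 150
  sheet <- data.frame(label = sample(c("L", "O"), n, replace = TRUE),
                      age = runif(n, 20, 70), ic = runif(n))
  # null index: CI for the index OR should usually cover 1
  nullIdx <- rnorm(n)
  scanN <- associationScan(nullIdx, sheet,
                           adjustments = list(unadjusted = character(0)))
  idxRow <- scanN[scanN$term == "index", ]
  expect_true(idxRow$ciLow < 1 && idxRow$ciHigh > 1)

  # strong index: effect survives age + IC adjustment
  strong <- ifelse(sheet$label == "O", 1.5, -1.5) + rnorm(n, 0, 0.8)
  scanS <- associationScan(strong, sheet)
  sRows <- scanS[scanS$term == "index", ]
  expect_equal(nrow(sRows), 4)
  expect_true(all(sRows$or > 1))
  expect_true(all(sRows$p < 0.01))
  expect_error(associationScan(strong, sheet,
                               adjustments = list(bad = "bmi")), "bmi")
})

test_that("missing covariate values are dropped per model only", {
  set.seed(27)
  n <- 120
  sheet <- data.frame(label = rep(c("L", "O"), n / 2),
                      age = runif(n, 20, 70), ic = runif(n))
  sheet$age[1:10] <- NA
  idx <- ifelse(sheet$label == "O", 1, -1) + rnorm(n, 0, 1)
  scan <- associationScan(idx, sheet,
                          adjustments = list(unadjusted = character(0),
                                             age = "age"))
  expect_equal(unique(scan$n[scan$model == "unadjusted"]), n)
  expect_equal(unique(scan$n[scan$model == "age"]), n - 10)
})

test_that("linear trends recover exact relationships and OLS duplication behaviour", {
  age <- seq(20, 60, length.out = 30)
  tr <- suppressWarnings(linearTrend(2 * age, age, covariateName = "age"))
  expect_equal(tr$slope, 2, tolerance = 1e-10)
  expect_equal(tr$intercept, 0, tolerance = 1e-8)
  expect_lt(tr$slopeP, 1e-20)

  set.seed(28)
  idx <- rnorm(40); ic <- runif(40)
  t1 <- linearTrend(idx, ic, covariateName = "ic")
  t2 <- linearTrend(rep(idx, 2), rep(ic, 2), covariateName = "ic")
  expect_equal(t2$slope, t1$slope, tolerance = 1e-12)
  expect_lt(t2$slopeP, t1$slopeP)
  expect_error(linearTrend(idx, rep(0.5, 40)), "constant")
})

test_that("trend slope p-values are calibrated under the null", {
  set.seed(29)
  ps <- vapply(1:50, function(i)
    linearTrend(rnorm(40), runif(40))$slopeP, numeric(1))
  expect_lt(ksUniform(ps), 0.2)
})

test_that("annotation enrichment matches the hypergeometric oracle", {
  bg <- sprintf("cg%04d", 1:1020)
  ann <- data.frame(probe = bg,
                    category = c(rep("open_sea", 10), rep("island", 10),
                                 rep("open_sea", 100), rep("island", 900)))
  sel <- bg[1:20]           # 10 open_sea + 10 island
  res <- annotationEnrichment(sel, bg, ann)
  os <- res[res$category == "open_sea", ]
  expect_equal(os$oddsRatio, (10 / 10) / (100 / 900), tolerance = 1e-12)
  # two-sided Fisher p from the hypergeometric distribution directly
  dens <- dhyper(0:20, 110, 910, 20)
  pOracle <- sum(dens[dens <= dhyper(10, 110, 910, 20) * (1 + 1e-7)])
  expect_equal(os$p, pOracle, tolerance = 1e-10)
  expect_lt(os$p, 0.001)

  # selected == background: every odds ratio is driven by zero "out" cells
  resAll <- annotationEnrichment(bg, bg, ann)
  expect_true(all(is.na(resAll$oddsRatio) | is.nan(resAll$oddsRatio) |
                  resAll$p == 1))
  expect_error(annotationEnrichment(c(bg[1], "cgZZZ"), bg, ann), "cgZZZ")

  # unannotated probes fall into "unknown"
  res2 <- annotationEnrichment(sel, bg, ann[1:500, ])
  expect_true("unknown" %in% res2$category)
})

test_that("subgroup AUCs use the preset masks and handle single-class groups", {
  set.seed(30)
  n <- 120
  age <- runif(n, 20, 80)
  ic <- runif(n)
  y <- rbinom(n, 1, 0.5)
  s <- y + rnorm(n, 0, 0.8)
  masks <- subgroupMasks(age, ic)
  res <- subgroupAuc(s, y, masks)
  expect_equal(res$subgroup, names(masks))
  glob <- subgroupAuc(s, y, list(all = rep(TRUE, n)))
  expect_equal(glob$auc, rocAuc(s, y))
  expect_warning(
    bad <- subgroupAuc(s, y, list(onlyPos = y == 1)), "single class")
  expect_true(is.na(bad$auc))
})
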
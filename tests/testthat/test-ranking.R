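test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdrAdjust(0.2), 0.2)
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  expect_error(fdrAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("Welch ranking matches the closed form and the reference implementation", {
  # exact sample moments: means 0.3 / 0.5, sd 0.1, n = 50 per group
  mk <- function(m, s, n) m + s * scale(seq_len(n))[, 1] /
    sd(scale(seq_len(n))[, 1]) * 1
  gL <- as.numeric(scale(rnorm(50))) * 0.1 + 0.3
  gO <- as.numeric(scale(rnorm(50))) * 0.1 + 0.5
  b <- rbind(cg1 = c(gL, gO))
  colnames(b) <- paste0("s", 1:100)
  labels <- rep(c("L", "O"), each = 50)
  r <- rankWelch(b, labels)
  expect_lt(r$p, 1e-10)
  expect_equal(r$direction, "hyper_in_O")
  expect_equal(r$statistic, unname(t.test(gO, gL)$statistic),
               tolerance = 1e-10)

  set.seed(101)
  b2 <- toyBeta(runif(100 * 40), 100, 40)
  labels2 <- rep(c("L", "O"), 20)
  r2 <- rankWelch(b2, labels2)
  for (j in sample(100, 10)) {
    ref <- t.test(b2[j, labels2 == "O"], b2[j, labels2 == "L"])
    row <- r2[r2$probe == rownames(b2)[j], ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$p, ref$p.value, tolerance = 1e-10)
  }
  # identical groups: statistic 0, p 1
  b3 <- rbind(cg1 = rep(0.4, 20))
  colnames(b3) <- paste0("s", 1:20)
  r3 <- rankWelch(b3, rep(c("L", "O"), 10))
  expect_true(r3$flagged)
  expect_equal(r3$p, 1)
  expect_equal(r3$statistic, 0)
})

test_that("Bartlett ranking matches the reference implementation and flags degenerate probes", {
  set.seed(102)
  b <- toyBeta(runif(200 * 60), 200, 60)
  labels <- rep(c("L", "O"), 30)
  r <- rankBartlett(b, labels)
  for (j in sample(200, 10)) {
    ref <- bartlett.test(list(b[j, labels == "O"], b[j, labels == "L"]))
    row <- r[r$probe == rownames(b)[j], ]
    expect_equal(row$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(row$p, ref$p.value, tolerance = 1e-10)
  }
  # strongly unequal variances are detected
  x <- c(as.numeric(scale(rnorm(100))) * 0.1 + 0.5,
         as.numeric(scale(rnorm(100))) * 0.2 + 0.5)
  b2 <- rbind(cg1 = x); colnames(b2) <- paste0("s", 1:200)
  r2 <- rankBartlett(b2, rep(c("L", "O"), each = 100))
  expect_lt(r2$p, 1e-6)
  expect_equal(r2$direction, "hyper_in_O")
  # both groups constant
  b3 <- rbind(cg1 = rep(0.2, 20)); colnames(b3) <- paste0("s", 1:20)
  r3 <- rankBartlett(b3, rep(c("L", "O"), 10))
  expect_true(r3$flagged)
  expect_equal(r3$p, 1)
})

test_that("delta-beta equals the difference of IC=0 intercepts", {
  # lines through two points: L (0,0.2)-(1,0.4); O (0,0.5)-(1,0.7)
  b <- rbind(cg1 = c(0.2, 0.4, 0.5, 0.7, 0.3, 0.6, 0.35, 0.65))
  colnames(b) <- paste0("s", 1:8)
  ic <- c(0, 1, 0, 1, 0.5, 0.5, 0.75, 0.75)
  labels <- c("L", "L", "O", "O", "L", "O", "L", "O")
  # extra points lie on the same two lines so the fit stays exact
  r <- rankDeltaBeta(b, labels, ic = ic)
  expect_equal(r$statistic, 0.3, tolerance = 1e-12)
  expect_equal(r$direction, "hyper_in_O")
  expect_true(is.na(r$p))

  # identical groups give delta-beta 0
  b2 <- rbind(cg1 = rep(c(0.2, 0.4, 0.6), 4))
  colnames(b2) <- paste0("s", 1:12)
  ic2 <- rep(c(0, 0.5, 1), 4)
  lab2 <- rep(c("L", "O"), each = 6)
  expect_equal(rankDeltaBeta(b2, lab2, ic = ic2)$statistic, 0,
               tolerance = 1e-12)
  expect_error(rankDeltaBeta(b2, lab2, ic = rep(0.3, 12)), "constant")
})

test_that("delta-beta isolates epithelial signal: immune-only effects score near zero", {
  co <- epiImmuneCohort(n = 250, nProbes = 1200, planted = 50,
                        where = "immune", seed = 5)
  ic <- trueIC(co)
  labels <- communityLabels(co)
  planted <- cohortTruth(co)$immuneDMCs$probe
  rDB <- rankDeltaBeta(co, ic = ic)
  expect_lt(median(abs(rDB$statistic[rDB$probe %in% planted])), 0.02)
  rW <- rankWelch(co)
  welchRanks <- rW$rank[rW$probe %in% planted]
  expect_gt(mean(welchRanks <= 150), 0.8)   # Welch sees the raw mean shift
})

test_that("delta-beta recovers planted epithelial effects at the IC=0 extrapolation", {
  co <- epiImmuneCohort(n = 300, nProbes = 1200, planted = 60,
                        where = "epithelial", seed = 6)
  tr <- cohortTruth(co)$epithelialDMCs
  rDB <- rankDeltaBeta(co, ic = trueIC(co))
  got <- rDB$statistic[match(tr$probe, rDB$probe)]
  expect_lt(abs(mean(got - tr$effect)), 0.05)
})

test_that("adjusted logistic ranking finds planted effects and flags degenerate probes", {
  ref <- generateReferenceProfiles(1000, seed = 7)
  cfg <- cohortConfig(
    nSamples = 300, nProbes = 1000, noiseSD = 0.05,
    plantedEpithelial = list(n = 30, delta = 0.2, signMix = 0.5), seed = 8)
  co <- generateCohort(cfg, ref)
  ic <- trueIC(co)
  r <- rankAdjustedLogistic(co, age = co$age, ic = ic)
  planted <- cohortTruth(co)$epithelialDMCs$probe
  expect_gt(mean(r$rank[r$probe %in% planted] <= 100), 0.9)
  expect_true(all(sort(r$rank) == seq_len(nrow(r))))
  expect_true(all(r$q >= r$p - 1e-12))

  # the Wald and likelihood-ratio variants agree away from separation
  rl <- rankAdjustedLogistic(co, age = co$age, ic = ic, statistic = "lrt")
  expect_gte(length(intersect(r$probe[r$rank <= 50],
                              rl$probe[rl$rank <= 50])), 45)

  # constant probe: inestimable coefficient -> flagged, p = 1
  b <- betaValues(co)[1:5, ]
  b[3, ] <- 0.5
  r2 <- rankAdjustedLogistic(b, communityLabels(co), age = co$age, ic = ic)
  row <- r2[r2$probe == rownames(b)[3], ]
  expect_true(row$flagged)
  expect_equal(row$p, 1)
  expect_equal(row$statistic, 0)
  expect_equal(row$rank, 5L)        # flagged probes sink to the bottom
})

test_that("adjusted logistic p-values are calibrated on null cohorts", {
  # pooled over replicate null cohorts: single-cohort empirical CDFs wobble
  # with the shared cell-fraction structure, the pooled CDF must not
  ps <- unlist(lapply(1:3, function(s) {
    ref <- generateReferenceProfiles(2000, seed = 80 + s)
    co <- generateCohort(cohortConfig(nSamples = 300, nProbes = 2000,
                                      seed = 90 + s), ref)
    r <- rankAdjustedLogistic(co, age = co$age, ic = trueIC(co))
    expect_lte(mean(r$q < 0.05), 0.07)
    r$p
  }))
  expect_lt(ksUniform(ps), 0.03)
})

test_that("CellDMC-style interaction test localizes effects to the right compartment", {
  sc <- standardCohort(n = 300, nProbes = 1000, planted = 40, seed = 10)
  co <- sc$cohort
  fr <- trueFractions(co)
  r <- rankCellDMC(co, fractions = fr)
  planted <- cohortTruth(co)$epithelialDMCs$probe
  cp <- attr(r, "compartmentP")
  expect_gt(mean(cp[planted, "epithelial"] < 1e-4), 0.9)
  expect_gt(mean(cp[planted, "immune"] > 0.05), 0.85)
  expect_gt(mean(r$compartment[r$probe %in% planted] == "epithelial"), 0.9)

  # permuting labels destroys the enrichment of planted probes at the top
  set.seed(11)
  rPerm <- rankCellDMC(co, sample(communityLabels(co)), fractions = fr)
  topPerm <- rPerm$probe[rPerm$rank <= 50]
  expect_lt(sum(planted %in% topPerm), 10)

  # calibration under the null (no planted effect)
  ref0 <- generateReferenceProfiles(2000, seed = 12)
  co0 <- generateCohort(cohortConfig(nSamples = 250, nProbes = 2000,
                                     seed = 13), ref0)
  r0 <- rankCellDMC(co0, fractions = trueFractions(co0))
  # the Bonferroni-scaled min-p is valid (never anti-conservative) but not
  # uniform: its ECDF must stay at or below the uniform CDF, and the
  # rejection rate at 0.05 must be controlled
  s0 <- sort(r0$p)
  dPlus <- max(seq_along(s0) / length(s0) - s0)
  expect_lt(dPlus, 0.03)
  expect_lte(mean(r0$p < 0.05), 0.06)
})

test_that("geometric-mean aggregation follows the stated tie rules and is order-invariant", {
  mkRank <- function(probes, ranks, method) {
    df <- data.frame(probe = probes, statistic = 0, p = NA,
                     direction = "hyper_in_O", flagged = FALSE,
                     rank = ranks, stringsAsFactors = FALSE)
    attr(df, "method") <- method
    df
  }
  probes <- c("cgA", "cgB", "cgC", "cgD")
  r1 <- mkRank(probes, c(1, 4, 2, 3), "welch")
  r2 <- mkRank(probes, c(4, 1, 2, 3), "bartlett")
  ag <- aggregateRanks(list(r1, r2))
  expect_equal(ag$gmRank[ag$probe == "cgA"], 2)
  expect_equal(ag$gmRank[ag$probe == "cgB"], 2)
  # tie broken by the first method's rank: cgA (welch rank 1) wins
  expect_lt(ag$rank[ag$probe == "cgA"], ag$rank[ag$probe == "cgB"])

  # five identical rankings reproduce the input order
  rs <- lapply(c("adjusted_logistic", "welch", "bartlett", "delta_beta",
                 "celldmc"), function(m) mkRank(probes, 1:4, m))
  ag5 <- aggregateRanks(rs)
  expect_equal(ag5$probe[order(ag5$rank)], probes)
  expect_equal(ag5$gmRank, as.numeric(1:4))

  # supply order does not matter when adjusted_logistic anchors ties
  rs2 <- rs; rs2[[2]]$rank <- c(2, 1, 3, 4)
  agA <- aggregateRanks(rs2)
  agB <- aggregateRanks(rev(rs2))
  expect_equal(agA[order(agA$probe), ], agB[order(agB$probe),
               colnames(agA)], ignore_attr = TRUE)

  # probe-set mismatch is reported
  r3 <- mkRank(c("cgA", "cgB", "cgC", "cgZ"), 1:4, "celldmc")
  expect_error(aggregateRanks(list(r1, r3)), "cgZ|cgD")

  # relabeling probes commutes with aggregation
  relab <- setNames(paste0("new", seq_along(probes)), probes)
  rsR <- lapply(rs2, function(r) { r$probe <- unname(relab[r$probe]); r })
  agR <- aggregateRanks(rsR)
  agO <- aggregateRanks(rs2)
  expect_equal(agR$rank[match(unname(relab[agO$probe]), agR$probe)],
               agO$rank)
})

test_that("aggregated ranking concentrates planted probes at the top", {
  sc <- standardCohort(n = 300, nProbes = 1000, planted = 30, seed = 14)
  co <- sc$cohort
  fr <- trueFractions(co)
  ic <- icFraction(fr)
  rs <- list(rankAdjustedLogistic(co, age = co$age, ic = ic),
             rankWelch(co), rankBartlett(co),
             rankDeltaBeta(co, ic = ic),
             rankCellDMC(co, fractions = fr))
  ag <- aggregateRanks(rs)
  planted <- cohortTruth(co)$epithelialDMCs$probe
  expect_gt(mean(planted %in% ag$probe[ag$rank <= 60]), 0.9)
})
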
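# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A small named beta matrix with probes cg0000001..c gN and samples s1..sM.
toyBeta <- function(values, nProbes, nSamples) {
  matrix(values, nProbes, nSamples,
         dimnames = list(sprintf("cg%07d", seq_len(nProbes)),
                         paste0("s", seq_len(nSamples))))
}

# A two-compartment (epithelial + immune) reference, cohort and
# deconvolution for delta-beta / CellDMC experiments, with planted effects
# in a chosen compartment.
epiImmuneCohort <- function(n = 300, nProbes = 1500, planted = 60,
                            delta = 0.15, where = c("epithelial", "immune"),
                            noiseSD = 0.02, seed = 1) {
  where <- match.arg(where)
  ref <- generateReferenceProfiles(
    nProbes, cellTypes = c(epithelial = "epithelial", immune = "immune"),
    seed = seed)
  pe <- list(n = 0, delta = delta, signMix = 0.5)
  pi <- list(n = 0, delta = delta, signMix = 0.5)
  if (where == "epithelial") pe$n <- planted else pi$n <- planted
  cfg <- cohortConfig(nSamples = n, nProbes = nProbes,
                      dirichlet = c(epithelial = 5, immune = 2.5),
                      plantedEpithelial = pe, plantedImmune = pi,
                      noiseSD = noiseSD, seed = seed + 1)
  generateCohort(cfg, ref)
}

# Standard three-cell-type cohort with an epithelial planted signal.
standardCohort <- function(n = 300, nProbes = 5000, planted = 100,
                           delta = 0.15, noiseSD = 0.02, seed = 1) {
  ref <- generateReferenceProfiles(nProbes, seed = seed)
  cfg <- cohortConfig(
    nSamples = n, nProbes = nProbes,
    plantedEpithelial = list(n = planted, delta = delta, signMix = 0.5),
    noiseSD = noiseSD, seed = seed + 1)
  list(ref = ref, cohort = generateCohort(cfg, ref))
}

trueIC <- function(cohort) icFraction(trueFractions(cohort))

# Independent brute-force kNN imputation oracle implementing the documented
# rule with plain double loops.
naiveKNNImpute <- function(b, k) {
  out <- b
  for (j in seq_len(nrow(b))) {
    miss <- which(is.na(b[j, ]))
    if (!length(miss)) next
    d <- rep(Inf, nrow(b))
    for (q in seq_len(nrow(b))) {
      if (q == j) next
      shared <- which(!is.na(b[j, ]) & !is.na(b[q, ]))
      if (!length(shared)) next
      d[q] <- sum((b[j, shared] - b[q, shared])^2)
    }
    ord <- order(d, seq_along(d))
    for (i in miss) {
      cand <- ord[!is.na(b[ord, i]) & is.finite(d[ord])]
      out[j, i] <- mean(b[cand[seq_len(min(k, length(cand)))], i])
    }
  }
  out
}

ksUniform <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(abs(s - (seq_len(n) - 0.5) / n)) + 0.5 / n
}
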
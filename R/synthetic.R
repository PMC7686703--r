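# Synthetic cohort generation: reference methylomes, cell-type mixtures with
# planted community-type effects, and matching microbiome abundance tables.

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Generate per-cell-type reference methylomes
#'
#' Draws mean beta profiles for a set of cell types with a shared bimodal
#' baseline (most CpGs are similar across cell types, as in real methylomes)
#' plus, for every pair of cell types, a disjoint block of
#' \code{minDiscriminating} probes with an absolute mean difference of at
#' least 0.5 — the identifiability condition reference-based deconvolution
#' relies on.
#'
#' @param nProbes number of probes (>= 100).
#' @param cellTypes named character vector: names are cell-type labels,
#'   values their compartment tag ("epithelial", "fibroblast" or "immune").
#' @param minDiscriminating minimum count of strongly discriminating probes
#'   per cell-type pair (default 50).
#' @param seed integer seed; identical seeds give identical profiles.
#' @return a \linkS4class{CellTypeReference}.
#' @examples
#' generateReferenceProfiles(500, seed = 1)
#' @export
generateReferenceProfiles <- function(nProbes,
                                      cellTypes = c(epithelial = "epithelial",
                                                    fibroblast = "fibroblast",
                                                    immune = "immune"),
                                      minDiscriminating = 50,
                                      seed = NULL) {
  if (length(cellTypes) < 2)
    stop("at least 2 cell types are required")
  if (nProbes < 100) stop("nProbes must be at least 100")
  types <- names(cellTypes)
  if (is.null(types)) stop("cellTypes must be a named vector (name = type, ",
                           "value = compartment tag)")
  pairs <- utils::combn(length(cellTypes), 2)
  need <- ncol(pairs) * minDiscriminating
  if (need > nProbes)
    stop("nProbes too small for ", minDiscriminating,
         " discriminating probes per cell-type pair (need >= ", need, ")")
  withSeed(seed, {
    base <- rbeta(nProbes, 0.35, 0.35)      # bimodal, array-like
    mu <- vapply(seq_along(types), function(k) {
      pmin(pmax(base + rnorm(nProbes, 0, 0.03), 0), 1)
    }, numeric(nProbes))
    colnames(mu) <- types
    rownames(mu) <- sprintf("cg%07d", seq_len(nProbes))
    slots <- matrix(sample.int(nProbes, need), nrow = minDiscriminating)
    for (p in seq_len(ncol(pairs))) {
      idx <- slots[, p]
      hi <- runif(length(idx), 0.78, 0.97)
      lo <- runif(length(idx), 0.03, 0.22)
      mu[idx, pairs[1, p]] <- hi
      mu[idx, pairs[2, p]] <- lo
    }
    CellTypeReference(mu, cellTypes)
  })
}

#' Configure a synthetic cohort
#'
#' Collects the generative settings of [generateCohort()] and checks their
#' consistency. Defaults emulate a cervical-smear case-control cohort:
#' roughly balanced community types, adult age range, epithelial-dominated
#' cell mixtures with a minority immune fraction, array-scale beta noise and
#' a rare probe-failure rate.
#'
#' @param nSamples,nProbes cohort dimensions.
#' @param prevalenceL probability of the L (Lactobacilli-dominated) label,
#'   in (0, 1).
#' @param ageMean,ageSD,ageMin,ageMax truncated-normal age model, in years.
#' @param dirichlet named Dirichlet concentration per cell type, or a list
#'   with elements \code{L} and \code{O} for label-dependent mixtures
#'   (default identical across labels: IC is not itself informative).
#' @param plantedEpithelial,plantedImmune lists \code{(n, delta, signMix)}:
#'   number of planted differential CpGs, effect size on the beta scale
#'   applied to that compartment's mean in O-labelled samples, and the
#'   fraction of probes shifted upward (hyper-methylated in O).
#' @param ageProbes list \code{(n, slope)}: probes whose signal drifts by
#'   \code{slope} beta units per year of age (centred at \code{ageMean}).
#' @param noiseSD standard deviation of measurement noise on the beta scale.
#' @param noiseModel \code{"gaussian"} (additive, truncated to [0,1]) or
#'   \code{"beta"} (beta-distributed around the clean signal with matched
#'   standard deviation).
#' @param probeFailureRate per-entry probability of a failed measurement
#'   (detection p-value above 0.01).
#' @return a list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nSamples = 300, nProbes = 5000,
                         prevalenceL = 0.52,
                         ageMean = 40, ageSD = 12, ageMin = 18, ageMax = 80,
                         dirichlet = c(epithelial = 10, fibroblast = 1.5,
                                       immune = 3.5),
                         plantedEpithelial = list(n = 0, delta = 0.15,
                                                  signMix = 0.5),
                         plantedImmune = list(n = 0, delta = 0.15,
                                              signMix = 0.5),
                         ageProbes = list(n = 0, slope = 0.002),
                         noiseSD = 0.02, noiseModel = c("gaussian", "beta"),
                         probeFailureRate = 1e-5,
                         seed = NULL) {
  noiseModel <- match.arg(noiseModel)
  if (prevalenceL <= 0 || prevalenceL >= 1)
    stop("prevalenceL must lie in (0, 1)")
  if (noiseSD < 0) stop("noiseSD must be non-negative")
  if (probeFailureRate < 0 || probeFailureRate > 1)
    stop("probeFailureRate must lie in [0, 1]")
  nPlanted <- plantedEpithelial$n + plantedImmune$n + ageProbes$n
  if (nPlanted > nProbes)
    stop("planted probe sets exceed nProbes")
  structure(list(nSamples = nSamples, nProbes = nProbes,
                 prevalenceL = prevalenceL,
                 ageMean = ageMean, ageSD = ageSD,
                 ageMin = ageMin, ageMax = ageMax,
                 dirichlet = dirichlet,
                 plantedEpithelial = plantedEpithelial,
                 plantedImmune = plantedImmune,
                 ageProbes = ageProbes,
                 noiseSD = noiseSD, noiseModel = noiseModel,
                 probeFailureRate = probeFailureRate,
                 seed = seed),
            class = "CohortConfig")
}

truncNorm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Pick planted probe ids whose shifted compartment means stay inside [0,1],
# so the planted effect is realized exactly (no clipping).
pickPlanted <- function(mu, typeCols, delta, n, signMix, exclude) {
  if (n == 0)
    return(data.frame(probe = character(), effect = numeric()))
  sgn <- rep(c(1, -1), times = c(round(n * signMix), n - round(n * signMix)))
  sub <- mu[, typeCols, drop = FALSE]
  okUp <- rownames(mu)[apply(sub + delta <= 1, 1, all)]
  okDown <- rownames(mu)[apply(sub - delta >= 0, 1, all)]
  okUp <- setdiff(okUp, exclude); okDown <- setdiff(okDown, exclude)
  nUp <- sum(sgn > 0); nDown <- sum(sgn < 0)
  if (length(okUp) < nUp || length(okDown) < nDown)
    stop("not enough probes admit a planted effect of size ", delta)
  up <- sample(okUp, nUp)
  down <- sample(setdiff(okDown, up), nDown)
  data.frame(probe = c(up, down),
             effect = delta * c(rep(1, nUp), rep(-1, nDown)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic methylome + microbiome cohort with known truth
#'
#' Per sample, draws a community-type label, an age and cell-type fractions,
#' then mixes the reference profiles: clean signal
#' \eqn{\beta_{ij} = \sum_k f_{ik}\,\mu_{kj}}. Planted epithelial
#' (respectively immune) differential CpGs shift only the epithelial
#' (immune) compartment means in O-labelled samples, so their observable
#' effect scales with that compartment's fraction — the structure the
#' delta-beta extrapolation and the cell-type interaction test are designed
#' to detect. Age-effect probes drift linearly with age. Observed values add
#' measurement noise (truncated to [0,1]); detection p-values are below 0.01
#' except for randomly failed entries. A taxon abundance table consistent
#' with the labels is attached.
#'
#' @param config a [cohortConfig()].
#' @param refs a \linkS4class{CellTypeReference} with \code{config$nProbes}
#'   probes.
#' @return a \linkS4class{SyntheticCohort}.
#' @examples
#' refs <- generateReferenceProfiles(500, seed = 1)
#' generateCohort(cohortConfig(nSamples = 20, nProbes = 500, seed = 1), refs)
#' @export
generateCohort <- function(config, refs) {
  stopifnot(inherits(config, "CohortConfig"),
            is(refs, "CellTypeReference"))
  mu <- referenceProfiles(refs)
  if (nrow(mu) != config$nProbes)
    stop("reference has ", nrow(mu), " probes but config expects ",
         config$nProbes)
  comp <- compartmentTags(refs)
  withSeed(config$seed, {
    n <- config$nSamples
    ids <- sprintf("S%04d", seq_len(n))
    label <- ifelse(runif(n) < config$prevalenceL, "L", "O")
    age <- truncNorm(n, config$ageMean, config$ageSD,
                     config$ageMin, config$ageMax)
    conc <- config$dirichlet
    if (is.list(conc)) {
      f <- matrix(NA_real_, n, length(conc$L),
                  dimnames = list(ids, names(conc$L)))
      f[label == "L", ] <- rdirichlet(sum(label == "L"), conc$L)
      f[label == "O", ] <- rdirichlet(sum(label == "O"), conc$O)
    } else {
      f <- rdirichlet(n, conc)
      rownames(f) <- ids
    }
    if (!setequal(colnames(f), colnames(mu)))
      stop("dirichlet concentration names must match reference cell types")
    f <- f[, colnames(mu), drop = FALSE]

    epiTypes <- names(comp)[comp == "epithelial"]
    immTypes <- names(comp)[comp == "immune"]
    epiDMC <- pickPlanted(mu, epiTypes, config$plantedEpithelial$delta,
                          config$plantedEpithelial$n,
                          config$plantedEpithelial$signMix, character())
    immDMC <- pickPlanted(mu, immTypes, config$plantedImmune$delta,
                          config$plantedImmune$n,
                          config$plantedImmune$signMix, epiDMC$probe)
    freeProbes <- setdiff(rownames(mu), c(epiDMC$probe, immDMC$probe))
    nAge <- config$ageProbes$n
    agePr <- data.frame(probe = if (nAge) sample(freeProbes, nAge)
                        else character(),
                        slope = rep(config$ageProbes$slope, nAge),
                        stringsAsFactors = FALSE)

    # clean mixed signal, probes x samples
    signal <- mu %*% t(f)
    isO <- label == "O"
    if (nrow(epiDMC) && any(isO)) {
      fEpi <- rowSums(f[, epiTypes, drop = FALSE])
      signal[epiDMC$probe, isO] <- signal[epiDMC$probe, isO] +
        outer(epiDMC$effect, fEpi[isO])
    }
    if (nrow(immDMC) && any(isO)) {
      fImm <- rowSums(f[, immTypes, drop = FALSE])
      signal[immDMC$probe, isO] <- signal[immDMC$probe, isO] +
        outer(immDMC$effect, fImm[isO])
    }
    if (nrow(agePr))
      signal[agePr$probe, ] <- signal[agePr$probe, ] +
        outer(agePr$slope, age - config$ageMean)
    signal <- pmin(pmax(signal, 0), 1)

    if (config$noiseSD == 0) {
      beta <- signal
    } else if (config$noiseModel == "gaussian") {
      beta <- pmin(pmax(signal +
        rnorm(length(signal), 0, config$noiseSD), 0), 1)
    } else {
      m <- pmin(pmax(signal, 1e-4), 1 - 1e-4)
      nu <- pmax(m * (1 - m) / config$noiseSD^2 - 1, 1)
      beta <- matrix(rbeta(length(m), m * nu, (1 - m) * nu),
                     nrow(m), ncol(m), dimnames = dimnames(m))
    }
    dimnames(beta) <- list(rownames(mu), ids)

    detp <- matrix(runif(length(beta), 0, 0.01), nrow(beta), ncol(beta),
                   dimnames = dimnames(beta))
    fail <- runif(length(beta)) < config$probeFailureRate
    detp[fail] <- runif(sum(fail), 0.01, 1)

    abundance <- generateAbundanceTable(label, seed = NULL)
    rownames(abundance) <- ids

    sheet <- S4Vectors::DataFrame(
      id = ids, label = label, age = age, tissue = "cervical_smear",
      row.names = ids)
    truth <- list(epithelialDMCs = epiDMC, immuneDMCs = immDMC,
                  ageProbes = agePr, config = config)
    new("SyntheticCohort",
        MethylCohort(beta, detectionP = detp, sampleData = sheet),
        truth = truth, abundance = abundance,
        trueFractions = CellProportions(f, comp))
  })
}

#' Generate a taxon relative-abundance table consistent with L/O labels
#'
#' For each sample, draws the summed relative abundance of the four
#' designated Lactobacillus species above 0.5 for L-labelled samples and
#' below 0.5 for O-labelled samples, then splits it among the Lactobacilli
#' and the remainder among the other taxa with Dirichlet draws. Re-typing
#' the table with [assignCommunityType()] recovers the input labels exactly.
#'
#' @param labels character vector of "L"/"O" labels.
#' @param species taxon names; must contain the four designated Lactobacilli.
#' @param seed integer seed.
#' @return relative-abundance matrix (samples x species), rows summing to 1.
#' @export
generateAbundanceTable <- function(labels,
                                   species = c(designatedLactobacilli(),
                                               "Gardnerella vaginalis",
                                               "Atopobium vaginae",
                                               "Prevotella bivia",
                                               "Sneathia amnii",
                                               "Streptococcus anginosus"),
                                   seed = NULL) {
  if (!all(labels %in% c("L", "O")))
    stop("labels must be 'L' or 'O'")
  want <- canonicalTaxon(designatedLactobacilli())
  hit <- canonicalTaxon(species) %in% want
  if (sum(hit) < 4)
    stop("species must include the four designated Lactobacillus species")
  withSeed(seed, {
    n <- length(labels)
    lactoTot <- ifelse(labels == "L", runif(n, 0.55, 0.98),
                       runif(n, 0.02, 0.45))
    nl <- sum(hit); no <- sum(!hit)
    lacto <- rdirichlet(n, rep(1.2, nl)) * lactoTot
    other <- rdirichlet(n, rep(0.8, no)) * (1 - lactoTot)
    out <- matrix(NA_real_, n, length(species),
                  dimnames = list(names(labels), species))
    out[, hit] <- lacto
    out[, !hit] <- other
    out
  })
}
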
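## Synthetic vegetation-plot generator with known ground truth.
##
## Emulates the statistical structure the downstream analyses assume:
## mixed parasite/autotroph species pools, multi-layer covers, near-duplicate
## plot pairs, environmental covariates on smooth spatial gradients that
## drive functional-type occupancy, and species EIVE values correlated with
## plot environment through a latent community gradient.

envPredictorNames <- function() {
  c("bio2", "bio4", "bio10", "bio12", "bio15", "bio18", "pet_penman", "tri")
}

#' Configuration for the synthetic vegetation-plot generator
#'
#' Defaults define the generator's study conditions: 2000 plots on a
#' 1000 x 1000 km planar frame, a pool of 200 species in which parasite
#' shares follow the euphytoid > obligate root > vine > mistletoe ordering
#' of the European flora (enriched so each type has members at desk scale),
#' climate-driven occupancy for euphytoid hemiparasites (cold, humid) and
#' obligate root parasites / vines (warm), and a modest negative shift of
#' the community soil-nitrogen/moisture/temperature/light indicator means
#' in occupied plots for euphytoids (nutrient-poor conditions), positive
#' for the warm-climate types.
#'
#' @param nPlots number of base plots (> 0); near-duplicate clones are
#'   generated in addition.
#' @param nSpecies species-pool size (> 0).
#' @param typeProportions fractions of the species pool per parasitic type
#'   (sum <= 1; the remainder are autotrophs).
#' @param prevalence target fraction of plots occupied by each type.
#' @param effectSpec per-type named coefficient vectors on standardised
#'   environmental predictors, e.g. `list(euphytoid = c(bio10 = -1.5))`.
#' @param eiveShift per-type target difference in community-mean EIVE
#'   (N/M/T/L) between occupied and unoccupied plots.
#' @param dupPairFraction fraction of plots cloned as near-duplicates
#'   (< 1 km apart, Bray-Curtis < 0.2).
#' @param nLayersMax maximum number of vegetation layers per record.
#' @param spatiallyIid if TRUE, environmental covariates are white noise
#'   instead of smooth spatial fields (no spatial autocorrelation).
#' @param missingEive probability that a species x indicator value is
#'   missing.
#' @param aggregateFraction fraction of extra aggregate taxa added to the
#'   pool (with member taxa carrying the EIVE data).
#' @param extentKm side length of the square planar frame.
#' @param richnessTarget expected autotroph richness per plot.
#' @param seed RNG seed; identical configurations and seeds give
#'   byte-identical datasets.
#' @return named list of class "SynthConfig".
#' @export
synthConfig <- function(nPlots = 2000,
                        nSpecies = 200,
                        typeProportions = c(euphytoid = 0.10,
                                            obligate_root = 0.03,
                                            vine = 0.015,
                                            mistletoe = 0.005),
                        prevalence = c(euphytoid = 0.15,
                                       obligate_root = 0.06,
                                       vine = 0.03,
                                       mistletoe = 0.01),
                        effectSpec = list(
                          euphytoid = c(bio10 = -1.5, bio12 = 0.8),
                          obligate_root = c(bio10 = 1.2, bio18 = -0.8),
                          vine = c(bio10 = 1.0)),
                        eiveShift = c(euphytoid = -0.5,
                                      obligate_root = 0.4,
                                      vine = 0.4,
                                      mistletoe = 0),
                        dupPairFraction = 0.02,
                        nLayersMax = 3,
                        spatiallyIid = FALSE,
                        missingEive = 0.1,
                        aggregateFraction = 0.03,
                        extentKm = 1000,
                        richnessTarget = 20,
                        seed = 1,
                        nicheStructure = TRUE) {
  if (nPlots <= 0 || nSpecies <= 0)
    stopf("synthConfig: nPlots and nSpecies must be positive")
  if (sum(typeProportions) > 1)
    stopf("synthConfig: typeProportions must sum to <= 1")
  if (!all(names(typeProportions) %in% parasiteTypes()))
    stopf("synthConfig: unknown functional type in typeProportions")
  if (length(effectSpec)) {
    if (!all(names(effectSpec) %in% parasiteTypes()))
      stopf("synthConfig: unknown functional type in effectSpec")
    for (v in effectSpec)
      if (!all(names(v) %in% envPredictorNames()))
        stopf("synthConfig: unknown predictor in effectSpec")
  }
  structure(list(nPlots = as.integer(nPlots), nSpecies = as.integer(nSpecies),
                 typeProportions = typeProportions, prevalence = prevalence,
                 effectSpec = effectSpec, eiveShift = eiveShift,
                 dupPairFraction = dupPairFraction,
                 nLayersMax = as.integer(nLayersMax),
                 spatiallyIid = spatiallyIid, missingEive = missingEive,
                 aggregateFraction = aggregateFraction,
                 extentKm = extentKm, richnessTarget = richnessTarget,
                 seed = as.integer(seed), nicheStructure = nicheStructure),
            class = "SynthConfig")
}

## standardised smooth spatial field: 3 planar sinusoids + white noise
smoothField <- function(xy, extent, iid = FALSE, noiseSd = 0.4) {
  n <- nrow(xy)
  if (iid) return(as.numeric(scale(stats::rnorm(n))))
  f <- numeric(n)
  for (h in 1:3) {
    amp <- stats::runif(1, 0.5, 1)
    lambda <- stats::runif(1, extent / 4, extent)
    theta <- stats::runif(1, 0, 2 * pi)
    phase <- stats::runif(1, 0, 2 * pi)
    proj <- xy[, 1] * cos(theta) + xy[, 2] * sin(theta)
    f <- f + amp * sin(2 * pi * proj / lambda + phase)
  }
  f <- f + noiseSd * stats::rnorm(n)
  as.numeric(scale(f))
}

clip01 <- function(x, lo, hi) pmin(hi, pmax(lo, x))

## solve for intercept a: mean(plogis(a + eta)) = target
calibrateIntercept <- function(eta, target) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lim <- 30 + max(abs(eta))
  stats::uniroot(f, c(-lim, lim), tol = 1e-10)$root
}

#' Generate a synthetic dataset with ground truth
#'
#' See [synthConfig()] for the generative model. Functional-type occupancy
#' probability is logistic in the configured standardised climate effects
#' plus a latent community-EIVE term whose coefficient is calibrated (by
#' root finding on the realised plot field) so the occupied-minus-unoccupied
#' difference in community-mean EIVE matches `eiveShift`; target marginal
#' prevalence is matched by intercept calibration.
#'
#' @param cfg a [synthConfig()].
#' @return list with `dataset` (a [VegDataset-class]) and `truth` (a list
#'   recording the drivers, calibrated coefficients, duplicate pairs,
#'   per-type occupancy and the latent community gradient).
#' @export
generateDataset <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  n <- cfg$nPlots
  types <- parasiteTypes()

  ## species pool
  nType <- round(cfg$nSpecies * cfg$typeProportions[types])
  nType[is.na(nType)] <- 0
  names(nType) <- types
  nAuto <- cfg$nSpecies - sum(nType)
  if (nAuto < 1) stopf("generateDataset: no autotroph species left in pool")
  for (t in types) {
    if (nType[t] == 0 &&
        ((t %in% names(cfg$eiveShift) && isTRUE(cfg$eiveShift[[t]] != 0)) ||
         t %in% names(cfg$effectSpec) && length(cfg$effectSpec[[t]])))
      stopf("generateDataset: %s has effects configured but 0 species", t)
  }
  ftype <- c(rep(types, times = nType), rep("autotroph", nAuto))
  taxa <- sprintf("sp%04d", seq_along(ftype))

  ## plots and environment
  xy <- cbind(x = stats::runif(n, 0, cfg$extentKm),
              y = stats::runif(n, 0, cfg$extentKm))
  envNames <- envPredictorNames()
  z <- sapply(envNames, function(nm)
    smoothField(xy, cfg$extentKm, iid = cfg$spatiallyIid))
  env <- cbind(bio2 = 8 + 2 * z[, "bio2"],
               bio4 = 6 + 1.5 * z[, "bio4"],
               bio10 = 15 + 4 * z[, "bio10"],
               bio12 = pmax(50, 700 + 250 * z[, "bio12"]),
               bio15 = pmax(5, 30 + 10 * z[, "bio15"]),
               bio18 = pmax(0, 80 + 40 * z[, "bio18"]),
               pet_penman = pmax(10, 80 + 25 * z[, "pet_penman"]),
               tri = 30 * exp(0.8 * z[, "tri"]))

  ## latent community gradient (fertility/microclimate proxy)
  g <- smoothField(xy, cfg$extentKm, iid = cfg$spatiallyIid)

  ## autotroph occupancy: Gaussian niche kernels on g (or uniform when the
  ## niche structure is off, i.e. occupancy independent of environment)
  isAuto <- ftype == "autotroph"
  center <- stats::rnorm(cfg$nSpecies, 0, 1.2)
  occRate <- clip01(stats::rlnorm(nAuto,
                                  log(cfg$richnessTarget / nAuto), 0.5),
                    0.005, 0.9)
  tau <- 1.5
  pAuto <- matrix(0, n, nAuto)
  autoCenters <- center[isAuto]
  for (j in seq_len(nAuto)) {
    kern <- if (cfg$nicheStructure)
      exp(-(g - autoCenters[j])^2 / (2 * tau^2)) else rep(1, n)
    p <- occRate[j] * kern / mean(kern)
    pAuto[, j] <- clip01(p, 0, 0.95)
  }
  occAuto <- matrix(stats::runif(n * nAuto), n, nAuto) < pAuto
  empty <- which(rowSums(occAuto) == 0)
  if (length(empty))
    occAuto[cbind(empty, max.col(pAuto[empty, , drop = FALSE]))] <- TRUE

  ## species EIVE: N/M/T/L track the niche centre, R is unstructured
  eive <- matrix(NA_real_, cfg$nSpecies, 5,
                 dimnames = list(taxa, eiveIndicators()))
  for (ind in eiveIndicators()) {
    eive[, ind] <- if (cfg$nicheStructure && ind != "r")
      clip01(5 + 1.2 * center + stats::rnorm(cfg$nSpecies), 0, 10)
    else
      clip01(5 + 1.5 * stats::rnorm(cfg$nSpecies), 0, 10)
  }
  eive[matrix(stats::runif(length(eive)) < cfg$missingEive,
              nrow(eive))] <- NA_real_

  ## realised community-mean field from autotrophs (indicator N)
  vN <- eive[isAuto, "n"]
  ok <- !is.na(vN)
  cnt <- occAuto[, ok, drop = FALSE] %*% rep(1, sum(ok))
  m <- as.numeric(occAuto[, ok, drop = FALSE] %*% ifelse(is.na(vN[ok]), 0, vN[ok]))
  m <- ifelse(cnt > 0, m / cnt, mean(vN[ok]))
  mStd <- if (stats::sd(m) > 0) as.numeric(scale(m)) else rep(0, n)

  ## parasite type occupancy
  occType <- matrix(FALSE, n, length(types), dimnames = list(NULL, types))
  gamma <- stats::setNames(rep(0, length(types)), types)
  alpha <- stats::setNames(rep(NA_real_, length(types)), types)
  for (t in types) {
    if (nType[t] == 0) next
    prev <- cfg$prevalence[[t]] %||% 0.05
    beta <- cfg$effectSpec[[t]]
    eta <- if (length(beta)) as.numeric(z[, names(beta), drop = FALSE] %*% beta)
           else rep(0, n)
    delta <- cfg$eiveShift[[t]] %||% 0
    if (delta != 0) {
      if (stats::sd(m) == 0)
        stopf("generateDataset: eiveShift for %s not achievable (no community variation)", t)
      achieved <- function(gm) {
        a <- calibrateIntercept(eta + gm * mStd, prev)
        p <- stats::plogis(a + eta + gm * mStd)
        sum(p * m) / sum(p) - sum((1 - p) * m) / sum(1 - p)
      }
      f <- function(gm) achieved(gm) - delta
      lo <- -30; hi <- 30
      if (f(lo) * f(hi) > 0)
        stopf("generateDataset: eiveShift %.2f for %s not achievable", delta, t)
      gamma[t] <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
    }
    alpha[t] <- calibrateIntercept(eta + gamma[t] * mStd, prev)
    p <- stats::plogis(alpha[t] + eta + gamma[t] * mStd)
    occType[, t] <- stats::runif(n) < p
  }

  ## assign member species within occupied plots
  propensity <- stats::rlnorm(cfg$nSpecies, 0, 1)
  occ <- matrix(FALSE, n, cfg$nSpecies, dimnames = list(NULL, taxa))
  occ[, isAuto] <- occAuto
  for (t in types) {
    idx <- which(ftype == t)
    if (!length(idx)) next
    plots <- which(occType[, t])
    for (i in plots) {
      kSp <- 1 + stats::rbinom(1, min(length(idx) - 1, 2), 0.2)
      sp <- if (length(idx) == 1) idx else
        sample(idx, kSp, prob = propensity[idx])
      occ[i, sp] <- TRUE
    }
  }

  ## covers and layers (long observation table)
  pairIdx <- which(occ, arr.ind = TRUE)
  nPair <- nrow(pairIdx)
  isAutoPair <- isAuto[pairIdx[, 2]]
  total <- ifelse(isAutoPair,
                  stats::rlnorm(nPair, log(8), 0.9),
                  stats::rlnorm(nPair, log(3), 0.8))
  total <- clip01(total, 0.1, 100)
  layerProb <- c(0.7, 0.2, 0.1)[seq_len(cfg$nLayersMax)]
  nl <- sample.int(cfg$nLayersMax, nPair, replace = TRUE,
                   prob = layerProb / sum(layerProb))
  rowOf <- rep(seq_len(nPair), nl)
  layerId <- sequence(nl)
  u <- stats::runif(length(rowOf), 0.2, 1)
  usum <- rowsum(u, rowOf)[, 1]
  coverL <- total[rowOf] * u / usum[rowOf]
  coverL <- clip01(coverL, 0.01, 100)
  obs <- data.frame(plot_id = sprintf("p%05d", pairIdx[rowOf, 1]),
                    taxon_id = taxa[pairIdx[rowOf, 2]],
                    layer_id = layerId,
                    cover_pct = coverL)

  ## aggregate taxa (trait-only members; aggregates sparsely observed)
  nAgg <- round(cfg$aggregateFraction * cfg$nSpecies)
  aggTraits <- NULL
  if (nAgg > 0) {
    for (a in seq_len(nAgg)) {
      aid <- sprintf("agg%03d", a)
      nm <- sample(2:3, 1)
      mids <- sprintf("%s_m%d", aid, seq_len(nm))
      memEive <- matrix(clip01(5 + 1.5 * stats::rnorm(nm * 5), 0, 10), nm, 5)
      memEive[stats::runif(length(memEive)) < cfg$missingEive] <- NA
      aggTraits <- rbind(aggTraits, data.frame(
        taxon_id = c(aid, mids),
        functional_type = "autotroph",
        eive_n = c(NA, memEive[, 1]), eive_m = c(NA, memEive[, 2]),
        eive_r = c(NA, memEive[, 3]), eive_t = c(NA, memEive[, 4]),
        eive_l = c(NA, memEive[, 5]),
        is_aggregate = c(TRUE, rep(FALSE, nm)),
        member_taxa = I(c(list(mids), replicate(nm, character())))))
      inPlots <- which(stats::runif(n) < 0.05)
      if (length(inPlots))
        obs <- rbind(obs, data.frame(
          plot_id = sprintf("p%05d", inPlots), taxon_id = aid, layer_id = 1L,
          cover_pct = clip01(stats::rlnorm(length(inPlots), log(5), 0.8),
                             0.1, 100)))
    }
  }

  ## headers
  ps <- clip01(stats::rlnorm(n, log(50), 1), 1, 1000)
  ps[stats::runif(n) < 0.2] <- NA
  headers <- data.frame(plot_id = sprintf("p%05d", seq_len(n)),
                        x = xy[, 1], y = xy[, 2],
                        plot_size_m2 = ps,
                        habitat_code = sample(paste0("H", 1:8), n, TRUE),
                        open = stats::rbinom(n, 1, 0.5),
                        wet = stats::rbinom(n, 1, 0.15),
                        saline = stats::rbinom(n, 1, 0.05))
  headers <- cbind(headers, as.data.frame(env))

  ## near-duplicate clones: same environment, jittered position, covers
  ## perturbed by +/-10% so Bray-Curtis stays well below 0.2
  nDup <- round(cfg$dupPairFraction * n)
  dupPairs <- data.frame(original = character(), clone = character())
  if (nDup > 0) {
    src <- sample.int(n, nDup)
    cloneIds <- paste0(headers$plot_id[src], "_dup")
    r <- stats::runif(nDup, 0.05, 0.45)
    th <- stats::runif(nDup, 0, 2 * pi)
    ch <- headers[src, ]
    ch$plot_id <- cloneIds
    ch$x <- ch$x + r * cos(th)
    ch$y <- ch$y + r * sin(th)
    headers <- rbind(headers, ch)
    srcIds <- sprintf("p%05d", src)
    co <- obs[obs$plot_id %in% srcIds, ]
    co$plot_id <- cloneIds[match(co$plot_id, srcIds)]
    co$cover_pct <- clip01(co$cover_pct * stats::runif(nrow(co), 0.9, 1.1),
                           0.01, 100)
    obs <- rbind(obs, co)
    dupPairs <- data.frame(original = srcIds, clone = cloneIds)
  }

  traits <- data.frame(taxon_id = taxa, functional_type = ftype,
                       eive_n = eive[, "n"], eive_m = eive[, "m"],
                       eive_r = eive[, "r"], eive_t = eive[, "t"],
                       eive_l = eive[, "l"],
                       is_aggregate = FALSE,
                       member_taxa = I(replicate(length(taxa), character())))
  if (!is.null(aggTraits)) traits <- rbind(traits, aggTraits)
  rownames(traits) <- NULL
  rownames(headers) <- NULL
  rownames(obs) <- NULL

  dataset <- vegDataset(headers, obs, traits, crsMode = "planar_km")
  truth <- list(seed = cfg$seed,
                prevalenceTarget = cfg$prevalence,
                prevalenceRealized = colMeans(occType),
                effectSpec = cfg$effectSpec,
                eiveShift = cfg$eiveShift,
                gamma = gamma, alpha = alpha,
                duplicatePairs = dupPairs,
                communityMean = m,
                envZ = z,
                typeOccupancy = occType,
                speciesCounts = c(table(factor(ftype, levels = functionalTypes()))))
  list(dataset = dataset, truth = truth)
}

#' Generate a null dataset (no environmental or indicator structure)
#'
#' As [generateDataset()] but with all EIVE shifts zero, no climate
#' effects, and species occupancy independent of environment and of
#' species EIVE values; used for type-I-error simulations.
#'
#' @param cfg a [synthConfig()]; its effectSpec/eiveShift/nicheStructure
#'   fields are overridden.
#' @return a [VegDataset-class].
#' @export
nullDataset <- function(cfg = synthConfig()) {
  cfg$effectSpec <- list()
  cfg$eiveShift <- stats::setNames(rep(0, 4), parasiteTypes())
  cfg$nicheStructure <- FALSE
  generateDataset(cfg)$dataset
}
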
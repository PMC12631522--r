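## Cover-weighted kernel-density niche ranges and optima.

#' Square-root cover weights for a species' occurrences
#'
#' w_i = sqrt(c_i) / sum_j sqrt(c_j) over the plots where the species
#' occurs; the weights sum to 1.
#'
#' @param covers positive relative covers, one per occupied plot.
#' @return weights summing to 1.
#' @export
speciesWeights <- function(covers) {
  if (length(covers) == 0) stopf("speciesWeights: no occurrences")
  if (any(covers <= 0)) stopf("speciesWeights: covers must be positive")
  s <- sqrt(covers)
  s / sum(s)
}

#' Silverman bandwidth for a weighted sample
#'
#' Rule-of-thumb bandwidth 0.9 * min(sd, IQR/1.34) * n_eff^(-1/5), with the
#' spread statistics computed under the weights and the effective sample
#' size n_eff = 1 / sum(w_i^2).
#'
#' @param values numeric sample.
#' @param weights weights summing to 1 (default uniform).
#' @return bandwidth (> 0 for non-degenerate samples).
#' @export
silvermanBandwidth <- function(values, weights = NULL) {
  n <- length(values)
  if (is.null(weights)) weights <- rep(1 / n, n)
  neff <- 1 / sum(weights^2)
  sdw <- weightedSd(values, weights)
  iqr <- diff(weightedQuantile(values, weights, c(0.25, 0.75)))
  spread <- min(sdw, iqr / 1.34)
  if (spread <= 0) spread <- sdw
  0.9 * spread * neff^(-1 / 5)
}

#' Weighted Gaussian kernel density on a regular grid
#'
#' Direct mixture sum: f(g) = sum_i w_i * dnorm(g; values_i, bandwidth),
#' evaluated on `gridSize` points spanning [min - 3h, max + 3h]. The
#' trapezoid integral of the result is 1 up to grid discretisation.
#'
#' @param values numeric sample (>= 2 distinct values).
#' @param weights weights summing to 1 (default uniform).
#' @param bandwidth kernel standard deviation; default Silverman
#'   ([silvermanBandwidth()]).
#' @param gridSize number of grid points (default 512).
#' @return data.frame with columns `x` (grid) and `density`.
#' @export
weightedKde <- function(values, weights = NULL, bandwidth = NULL,
                        gridSize = 512) {
  n <- length(values)
  if (length(unique(values)) < 2)
    stopf("weightedKde: need >= 2 distinct values")
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (abs(sum(weights) - 1) > 1e-8)
    stopf("weightedKde: weights must sum to 1")
  if (is.null(bandwidth)) bandwidth <- silvermanBandwidth(values, weights)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stopf("weightedKde: bandwidth must be positive")
  grid <- seq(min(values) - 3 * bandwidth, max(values) + 3 * bandwidth,
              length.out = gridSize)
  dens <- as.numeric(
    exp(-outer(grid, values, "-")^2 / (2 * bandwidth^2)) %*% weights
  ) / (bandwidth * sqrt(2 * pi))
  data.frame(x = grid, density = dens)
}

#' 95% niche interval from a gridded density
#'
#' Grid densities are normalised to sum to 1 (relative density); the lower
#' bound is the first grid value whose cumulative relative density reaches
#' 0.025, the upper bound the first to reach 0.975.
#'
#' @param kde data.frame from [weightedKde()] (columns x, density).
#' @param probs the two cumulative cut points (default c(0.025, 0.975)).
#' @return named numeric c(lower, upper).
#' @export
nicheInterval <- function(kde, probs = c(0.025, 0.975)) {
  rel <- kde$density / sum(kde$density)
  cum <- cumsum(rel)
  lower <- kde$x[which(cum >= probs[1])[1]]
  upper <- kde$x[which(cum >= probs[2])[1]]
  c(lower = lower, upper = upper)
}

#' Cover-weighted niche optimum
#'
#' Arithmetic mean of the variable weighted by the same square-root cover
#' weights used for the density estimate.
#'
#' @param values variable values at the occupied plots.
#' @param weights weights summing to 1.
#' @return weighted mean.
#' @export
nicheOptimum <- function(values, weights) {
  sum(weights * values)
}

#' Niche table for all qualifying parasitic species
#'
#' For every parasitic species with at least `minOccurrences` occurrences,
#' estimates the cover-weighted niche along each requested variable:
#' 0.025/0.975 bounds of the relative kernel density, the weighted-mean
#' optimum, plus the observed weighted minimum/maximum as metadata.
#' Environmental variables are read from the plot headers; EIVE variables
#' ("eive_n", ..., "eive_l") are plot means computed excluding the focal
#' species.
#'
#' @param dataset a [VegDataset-class].
#' @param cover a [VegCover-class] (default computed from `dataset`).
#' @param variables character vector of header covariate names and/or
#'   "eive_*" names.
#' @param minOccurrences occurrence threshold (default 50).
#' @param bandwidth optional fixed bandwidth (default Silverman per
#'   species x variable).
#' @return data.frame: taxon_id, variable, lower, optimum, upper,
#'   n_occurrences, obs_min, obs_max.
#' @export
nicheTable <- function(dataset, cover = aggregatePlots(dataset),
                       variables, minOccurrences = 50, bandwidth = NULL) {
  h <- plotHeaders(dataset)
  tr <- aggregateEive(speciesTraits(dataset))
  rel <- relativeCoverMatrix(cover)
  parasites <- tr$taxon_id[tr$functional_type %in% parasiteTypes()]
  parasites <- intersect(parasites, colnames(rel))
  occCounts <- Matrix::colSums(rel[, parasites, drop = FALSE] > 0)
  keepSp <- parasites[occCounts >= minOccurrences]
  rows <- list()
  for (sp in keepSp) {
    covSp <- rel[, sp]
    occ <- which(covSp > 0)
    w <- speciesWeights(covSp[occ])
    for (v in variables) {
      if (startsWith(v, "eive_")) {
        pm <- plotMeanEive(cover, tr, excludeTaxa = sp)
        vals <- pm[occ, sub("^eive_", "", v)]
      } else {
        if (!v %in% names(h)) stopf("nicheTable: unknown variable '%s'", v)
        vals <- h[[v]][match(rownames(rel)[occ], h$plot_id)]
      }
      ok <- !is.na(vals)
      if (sum(ok) < 2 || length(unique(vals[ok])) < 2) {
        val1 <- if (any(ok)) vals[ok][1] else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          taxon_id = sp, variable = v, lower = val1, optimum = val1,
          upper = val1, n_occurrences = sum(ok),
          obs_min = val1, obs_max = val1)
        next
      }
      vv <- vals[ok]
      ww <- w[ok] / sum(w[ok])
      kde <- weightedKde(vv, ww, bandwidth = bandwidth)
      ci <- nicheInterval(kde)
      rows[[length(rows) + 1]] <- data.frame(
        taxon_id = sp, variable = v,
        lower = ci["lower"], optimum = nicheOptimum(vv, ww),
        upper = ci["upper"], n_occurrences = length(occ),
        obs_min = min(vv), obs_max = max(vv))
    }
  }
  if (!length(rows))
    return(data.frame(taxon_id = character(), variable = character(),
                      lower = numeric(), optimum = numeric(),
                      upper = numeric(), n_occurrences = integer(),
                      obs_min = numeric(), obs_max = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
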
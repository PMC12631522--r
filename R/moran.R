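## Moran's I correlogram for model-residual spatial diagnostics.

## Moran's I with a binary neighbour matrix given as index pairs (i < j)
moranIPairs <- function(x, pi, pj) {
  n <- length(x)
  d <- x - mean(x)
  s0 <- 2 * length(pi)                       # symmetric binary weights
  num <- 2 * sum(d[pi] * d[pj])
  den <- sum(d^2)
  (n / s0) * (num / den)
}

#' Moran's I correlogram with permutation tests
#'
#' Distance classes follow Sturges's rule (k = ceiling(1 + log2(n)) classes),
#' by default equal-width bins over (0, max pairwise distance]. Within each
#' class, Moran's I is computed with binary weights; p-values come from a
#' two-sided permutation test of the residuals against the closed-form null
#' expectation E[I] = -1/(n-1). Classes containing fewer than 2 pairs get
#' NA statistics.
#'
#' @param residuals numeric vector (n >= 10).
#' @param coords n x 2 coordinate matrix.
#' @param crsMode "planar_km" or "degrees".
#' @param nPerm number of permutations (default 199).
#' @param seed RNG seed.
#' @param binning "equal_width" (default) or "equal_count" distance classes.
#' @return data.frame with columns class, d_min, d_max, n_pairs, I,
#'   expectation, p.
#' @export
moransICorrelogram <- function(residuals, coords,
                               crsMode = c("planar_km", "degrees"),
                               nPerm = 199, seed = 1,
                               binning = c("equal_width", "equal_count")) {
  crsMode <- match.arg(crsMode)
  binning <- match.arg(binning)
  n <- length(residuals)
  if (n < 10) stopf("moransICorrelogram: need n >= 10")
  coords <- as.matrix(coords)
  km <- planarKm(data.frame(x = coords[, 1], y = coords[, 2]), crsMode)
  D <- as.matrix(stats::dist(km))
  if (crsMode == "degrees") {
    ## exact haversine distances for the correlogram bins
    idx <- which(upper.tri(D), arr.ind = TRUE)
    dd <- geosphere::distHaversine(coords[idx[, 1], , drop = FALSE],
                                   coords[idx[, 2], , drop = FALSE],
                                   r = EARTH_RADIUS_KM * 1000) / 1000
    D[idx] <- dd
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
  }
  k <- ceiling(1 + log2(n))
  up <- which(upper.tri(D), arr.ind = TRUE)
  dvec <- D[upper.tri(D)]
  dmax <- max(dvec)
  if (binning == "equal_width") {
    edges <- seq(0, dmax, length.out = k + 1)
  } else {
    edges <- unique(c(0, stats::quantile(dvec, probs = seq_len(k) / k,
                                         names = FALSE)))
    k <- length(edges) - 1
  }
  cls <- findInterval(dvec, edges, left.open = TRUE, rightmost.closed = TRUE)
  cls[cls < 1] <- 1
  cls[cls > k] <- k

  expectation <- -1 / (n - 1)
  set.seed(seed)
  perms <- replicate(nPerm, sample.int(n))
  out <- lapply(seq_len(k), function(ci) {
    sel <- cls == ci
    np <- sum(sel)
    if (np < 2)
      return(data.frame(class = ci, d_min = edges[ci], d_max = edges[ci + 1],
                        n_pairs = np, I = NA_real_,
                        expectation = expectation, p = NA_real_))
    pi <- up[sel, 1]; pj <- up[sel, 2]
    Iobs <- moranIPairs(residuals, pi, pj)
    Iperm <- vapply(seq_len(nPerm), function(b) {
      moranIPairs(residuals[perms[, b]], pi, pj)
    }, 0)
    p <- (1 + sum(abs(Iperm - expectation) >= abs(Iobs - expectation))) /
      (nPerm + 1)
    data.frame(class = ci, d_min = edges[ci], d_max = edges[ci + 1],
               n_pairs = np, I = Iobs, expectation = expectation, p = p)
  })
  do.call(rbind, out)
}
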
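## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

## default-scale synthetic dataset with known structure
structuredFixture <- function() {
  fixture("structured", function() {
    out <- generateDataset(synthConfig(seed = 20260925))
    out$cover <- aggregatePlots(out$dataset)
    out
  })
}

## tiny hand-built dataset for exact-value unit tests
tinyDataset <- function() {
  headers <- data.frame(
    plot_id = c("pA", "pB", "pC"),
    x = c(0, 10, 20), y = c(0, 0, 0),
    plot_size_m2 = c(100, NA, 25),
    habitat_code = "H1", open = 1, wet = 0, saline = 0,
    bio10 = c(10, 15, 20), bio12 = c(500, 700, 900))
  observations <- data.frame(
    plot_id = c("pA", "pA", "pA", "pB", "pB", "pC"),
    taxon_id = c("auto1", "auto2", "hemi1", "auto1", "vine1", "auto2"),
    layer_id = 1L,
    cover_pct = c(50, 25, 25, 60, 40, 7))
  traits <- data.frame(
    taxon_id = c("auto1", "auto2", "hemi1", "vine1"),
    functional_type = c("autotroph", "autotroph", "euphytoid", "vine"),
    eive_n = c(2, 4, 5, 6), eive_m = c(5, 5, NA, 4),
    eive_r = c(NA, NA, NA, NA), eive_t = c(3, 7, 5, 5),
    eive_l = c(6, 6, 6, 6),
    is_aggregate = FALSE,
    member_taxa = I(list(character(), character(), character(), character())))
  vegDataset(headers, observations, traits, crsMode = "planar_km")
}

## synthetic single-species dataset with a Gaussian niche on bio10
gaussianNicheDataset <- function(n = 400, mu = 10, sigma = 2, seed = 30) {
  set.seed(seed)
  nTot <- n + 200
  headers <- data.frame(plot_id = sprintf("p%04d", 1:nTot),
                        x = runif(nTot, 0, 500), y = runif(nTot, 0, 500),
                        plot_size_m2 = 10, habitat_code = "H1",
                        open = 1, wet = 0, saline = 0,
                        bio10 = c(rnorm(n, mu, sigma), runif(200, -5, 25)))
  occ <- headers$plot_id[1:n]
  obs <- rbind(
    data.frame(plot_id = occ, taxon_id = "par", layer_id = 1L,
               cover_pct = pmin(60, rlnorm(n, log(5), 0.6))),
    data.frame(plot_id = headers$plot_id, taxon_id = "bg", layer_id = 1L,
               cover_pct = 40))
  tr <- data.frame(taxon_id = c("par", "bg"),
                   functional_type = c("euphytoid", "autotroph"),
                   eive_n = c(NA, 5), eive_m = NA_real_, eive_r = NA_real_,
                   eive_t = NA_real_, eive_l = NA_real_, is_aggregate = FALSE,
                   member_taxa = I(list(character(), character())))
  vegDataset(headers, obs, tr)
}

## inclusion-exclusion union oracle for layer-cover combination
unionOracle <- function(covers) {
  p <- covers / 100
  k <- length(p)
  tot <- 0
  for (mask in 1:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    tot <- tot + (-1)^(length(sel) + 1) * prod(p[sel])
  }
  100 * tot
}

## brute-force O(n^2) scan for thinning violations
thinningViolations <- function(dataset, cover, retained, distKm = 1,
                               simThreshold = 0.8) {
  h <- plotHeaders(dataset)
  h <- h[h$plot_id %in% retained, ]
  cov <- coverMatrix(cover)[h$plot_id, , drop = FALSE]
  viol <- 0
  n <- nrow(h)
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) {
    d <- sqrt((h$x[(i + 1):n] - h$x[i])^2 + (h$y[(i + 1):n] - h$y[i])^2)
    for (jj in which(d < distKm)) {
      j <- i + jj
      a <- cov[i, ]; b <- cov[j, ]
      bc <- sum(abs(a - b)) / sum(a + b)
      if ((1 - bc) > simThreshold) viol <- viol + 1
    }
  }
  viol
}
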
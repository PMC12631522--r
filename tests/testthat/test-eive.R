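test_that("aggregate taxa average their members' indicator values", {
  tr <- data.frame(
    taxon_id = c("agg", "m1", "m2", "agg2"),
    functional_type = "autotroph",
    eive_n = c(NA, 3, 5, NA), eive_m = c(NA, 3, NA, NA),
    eive_r = rep(NA_real_, 4), eive_t = c(NA, 2, 4, NA),
    eive_l = rep(NA_real_, 4),
    is_aggregate = c(TRUE, FALSE, FALSE, TRUE),
    member_taxa = I(list(c("m1", "m2"), character(), character(), c("m1"))))
  out <- aggregateEive(tr)
  expect_equal(out$eive_n[1], 4)        # mean(3, 5)
  expect_equal(out$eive_m[1], 3)        # only m1 has data
  expect_true(is.na(out$eive_r[1]))     # no member data
  expect_equal(out$eive_n[4], 3)
  expect_equal(out[2:3, ], tr[2:3, ])   # non-aggregates untouched
})

test_that("plot means exclude the focal type and propagate missingness", {
  ds <- tinyDataset()
  cv <- aggregatePlots(ds)
  tr <- speciesTraits(ds)
  ## pA holds auto1 (N=2), auto2 (N=4), hemi1 (N=5)
  pm <- plotMeanEive(cv, tr)
  expect_equal(unname(pm["pA", "n"]), mean(c(2, 4, 5)))
  pmx <- plotMeanEive(cv, tr, excludeType = "euphytoid")
  expect_equal(unname(pmx["pA", "n"]), 3)
  ## indicator with no data anywhere stays missing
  expect_true(all(is.na(pm[, "r"])))
  ## plot containing only the focal type -> missing
  dsOnly <- vegDataset(
    plotHeaders(ds)[1, ],
    data.frame(plot_id = "pA", taxon_id = "hemi1", layer_id = 1L,
               cover_pct = 30),
    tr)
  cvOnly <- aggregatePlots(dsOnly)
  expect_true(is.na(plotMeanEive(cvOnly, tr, excludeType = "euphytoid")["pA", "n"]))
})

test_that("observed differences compare occupied and unoccupied plot means", {
  expect_equal(observedDifference(c(4, 6, 3, 3), c(1, 1, 0, 0)), 2)
  expect_equal(observedDifference(c(5, 5, 5, 5), c(1, 0, 1, 0)), 0)
  expect_error(observedDifference(c(1, 2), c(1, 1)))
  ## NA means are dropped from both groups
  expect_equal(observedDifference(c(4, NA, 3, 3), c(1, 1, 0, 0)), 1)
})

test_that("the injected community shift is recovered at scale", {
  fx <- structuredFixture()
  tr <- aggregateEive(speciesTraits(fx$dataset))
  pm <- plotMeanEive(fx$cover, tr, excludeType = "euphytoid")
  occ <- typePresence(fx$cover)[, "euphytoid"]
  d <- observedDifference(pm[, "n"], occ)
  expect_equal(d, -0.5, tolerance = 0.2 / 0.5)   # within +/- 0.2 of target
})

test_that("exhaustive enumeration matches an independent brute-force oracle", {
  ## 3 species, all 3! = 6 value assignments enumerable by hand
  headers <- data.frame(plot_id = paste0("p", 1:4), x = (1:4) * 10, y = 0,
                        plot_size_m2 = 10, habitat_code = "H1",
                        open = 1, wet = 0, saline = 0, bio10 = 10)
  obs <- data.frame(
    plot_id = c("p1", "p1", "p2", "p2", "p3", "p4", "p4"),
    taxon_id = c("a", "b", "b", "c", "a", "a", "c"),
    layer_id = 1L, cover_pct = 20)
  ## hemiparasite occupies p1 and p3 but carries no indicator value
  obs <- rbind(obs, data.frame(plot_id = c("p1", "p3"), taxon_id = "hemi",
                               layer_id = 1L, cover_pct = 10))
  tr <- data.frame(taxon_id = c("a", "b", "c", "hemi"),
                   functional_type = c(rep("autotroph", 3), "euphytoid"),
                   eive_n = c(2, 5, 8, NA), eive_m = NA_real_,
                   eive_r = NA_real_, eive_t = NA_real_, eive_l = NA_real_,
                   is_aggregate = FALSE,
                   member_taxa = I(replicate(4, character())))
  ds <- vegDataset(headers, obs, tr)
  cv <- aggregatePlots(ds)
  res <- modifiedPermutationTest(cv, tr, "euphytoid", "n", exhaustive = TRUE)
  expect_equal(res@nPerm, 6L)

  ## oracle: enumerate all value assignments directly
  vals <- c(2, 5, 8)
  present <- list(p1 = c("a", "b"), p2 = c("b", "c"), p3 = "a", p4 = c("a", "c"))
  occupied <- c(TRUE, FALSE, TRUE, FALSE)
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  diffs <- apply(perms, 1, function(o) {
    v <- stats::setNames(vals[o], c("a", "b", "c"))
    m <- vapply(present, function(sp) mean(v[sp]), 0)
    mean(m[occupied]) - mean(m[!occupied])
  })
  dReal <- diffs[1]
  expect_equal(sort(res@nullDiffs), sort(diffs))
  expect_equal(res@diffReal, dReal)
  sesOracle <- (dReal - mean(diffs)) / sd(diffs)
  expect_equal(res@ses, sesOracle)
  pOracle <- if (sesOracle > 0) mean(diffs >= dReal) else mean(diffs <= dReal)
  expect_equal(res@p, pOracle)
})

test_that("a spread-free null gives p = 1 with a warning", {
  headers <- data.frame(plot_id = c("p1", "p2"), x = c(0, 10), y = 0,
                        plot_size_m2 = 10, habitat_code = "H1",
                        open = 1, wet = 0, saline = 0, bio10 = 10)
  ## both autotrophs in both plots: any permutation gives the same means
  obs <- data.frame(plot_id = c("p1", "p1", "p2", "p2", "p1"),
                    taxon_id = c("a", "b", "a", "b", "hemi"),
                    layer_id = 1L, cover_pct = 10)
  tr <- data.frame(taxon_id = c("a", "b", "hemi"),
                   functional_type = c("autotroph", "autotroph", "euphytoid"),
                   eive_n = c(3, 7, NA), eive_m = NA_real_, eive_r = NA_real_,
                   eive_t = NA_real_, eive_l = NA_real_, is_aggregate = FALSE,
                   member_taxa = I(replicate(3, character())))
  cv <- aggregatePlots(vegDataset(headers, obs, tr))
  expect_warning(res <- modifiedPermutationTest(cv, tr, "euphytoid", "n",
                                                nPerm = 20, seed = 1),
                 "zero spread")
  expect_equal(res@p, 1)
  expect_true(is.na(res@ses))
})

test_that("the permutation test is seed-reproducible", {
  fx <- structuredFixture()
  tr <- aggregateEive(speciesTraits(fx$dataset))
  r1 <- modifiedPermutationTest(fx$cover, tr, "obligate_root", "t",
                                nPerm = 99, seed = 5)
  r2 <- modifiedPermutationTest(fx$cover, tr, "obligate_root", "t",
                                nPerm = 99, seed = 5)
  expect_identical(r1@nullDiffs, r2@nullDiffs)
  expect_identical(r1@p, r2@p)
})

test_that("the indicator suite runs per indicator, optionally jointly", {
  fx <- structuredFixture()
  tr <- aggregateEive(speciesTraits(fx$dataset))
  res <- eiveTestSuite(fx$cover, tr, "euphytoid", indicators = c("n", "t"),
                       nPerm = 49, seed = 2)
  expect_named(res, c("n", "t"))
  expect_s4_class(res$n, "PermTestResult")
  ## the generator links N and T to the same latent gradient
  expect_lt(res$n@ses, 0)
})
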
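test_that("three-CSV round trip preserves a dataset", {
  ds <- tinyDataset()
  dir <- withr::local_tempdir()
  paths <- writeDatasetCsv(ds, dir)
  back <- readDataset(paths["plots"], paths["observations"], paths["traits"],
                      crsMode = "planar_km")
  expect_equal(plotHeaders(back), plotHeaders(ds))
  expect_equal(plotObservations(back), plotObservations(ds))
  tb <- speciesTraits(back); to <- speciesTraits(ds)
  expect_equal(tb[, setdiff(names(tb), "member_taxa")],
               to[, setdiff(names(to), "member_taxa")])
  expect_equal(unclass(tb$member_taxa), unclass(to$member_taxa))
})

test_that("single-row files produce a one-plot dataset", {
  dir <- withr::local_tempdir()
  writeLines(c("plot_id,x,y,plot_size_m2,habitat_code,open,wet,saline,bio10",
               "p1,0,0,10,H1,1,0,0,12.5"), file.path(dir, "plots.csv"))
  writeLines(c("plot_id,taxon_id,layer_id,cover_pct", "p1,t1,1,40"),
             file.path(dir, "observations.csv"))
  writeLines(c("taxon_id,functional_type,eive_n,eive_m,eive_r,eive_t,eive_l,member_taxa",
               "t1,autotroph,5,5,5,5,5,"), file.path(dir, "traits.csv"))
  ds <- readDataset(file.path(dir, "plots.csv"),
                    file.path(dir, "observations.csv"),
                    file.path(dir, "traits.csv"))
  expect_s4_class(ds, "VegDataset")
  expect_equal(nrow(plotHeaders(ds)), 1)
  expect_equal(nrow(plotObservations(ds)), 1)
  expect_equal(nrow(speciesTraits(ds)), 1)
})

test_that("referential integrity and value validation reject bad inputs", {
  ds <- tinyDataset()
  h <- plotHeaders(ds); o <- plotObservations(ds); tr <- speciesTraits(ds)

  o2 <- o; o2$plot_id[2] <- "ghost"
  expect_error(vegDataset(h, o2, tr), "ghost")

  o3 <- o; o3$taxon_id[1] <- "nobody"
  expect_error(vegDataset(h, o3, tr), "nobody")

  dir <- withr::local_tempdir()
  o4 <- o; o4$cover_pct[3] <- 150
  utils::write.csv(h, file.path(dir, "p.csv"), row.names = FALSE, na = "")
  utils::write.csv(o4, file.path(dir, "o.csv"), row.names = FALSE, na = "")
  tr2 <- tr; tr2$member_taxa <- ""
  utils::write.csv(tr2, file.path(dir, "t.csv"), row.names = FALSE, na = "")
  expect_error(readDataset(file.path(dir, "p.csv"), file.path(dir, "o.csv"),
                           file.path(dir, "t.csv")),
               "row\\(s\\) 3")

  ## schema error: missing column
  utils::write.csv(o[, -4], file.path(dir, "o2.csv"), row.names = FALSE)
  expect_error(readDataset(file.path(dir, "p.csv"), file.path(dir, "o2.csv"),
                           file.path(dir, "t.csv")),
               "cover_pct")
})

test_that("validity rejects exactly the invariant-violating perturbations", {
  ds <- tinyDataset()
  h <- plotHeaders(ds); o <- plotObservations(ds); tr <- speciesTraits(ds)
  expect_s4_class(vegDataset(h, o, tr), "VegDataset")

  bad <- list(
    function() { t2 <- tr; t2$eive_n[1] <- 11; vegDataset(h, o, t2) },
    function() { t2 <- tr; t2$eive_t[2] <- -0.5; vegDataset(h, o, t2) },
    function() { h2 <- h; h2$open[1] <- 2; vegDataset(h2, o, tr) },
    function() { h2 <- h; h2$plot_size_m2[1] <- 0; vegDataset(h2, o, tr) },
    function() { o2 <- o; o2$cover_pct[1] <- 0; vegDataset(h, o2, tr) },
    function() { o2 <- rbind(o, o[1, ]); vegDataset(h, o2, tr) },
    function() { t2 <- tr; t2$is_aggregate[1] <- TRUE; vegDataset(h, o, t2) },
    function() { t2 <- tr; t2$functional_type[1] <- "carnivore"; vegDataset(h, o, t2) }
  )
  for (f in bad) expect_error(f())

  ## benign perturbations still pass
  hOk <- h; hOk$plot_size_m2[1] <- NA
  expect_s4_class(vegDataset(hOk, o, tr), "VegDataset")
  tOk <- tr; tOk$eive_n[1] <- NA
  expect_s4_class(vegDataset(h, o, tOk), "VegDataset")
})

test_that("JSON results round-trip within 1e-9", {
  dir <- withr::local_tempdir()
  nt <- data.frame(taxon_id = c("a", "b"), variable = "bio10",
                   lower = c(1.123456789123, 2), optimum = c(5.5, 6.25),
                   upper = c(9.987654321987, 11), n_occurrences = c(60L, 80L))
  f <- file.path(dir, "niche.json")
  writeResults(nt, f)
  back <- readResults(f)
  expect_equal(back$lower, nt$lower, tolerance = 1e-9)
  expect_equal(back$optimum, nt$optimum, tolerance = 1e-9)
  expect_equal(back$taxon_id, nt$taxon_id)

  ## empty result list -> valid empty document
  f2 <- file.path(dir, "empty.json")
  writeResults(list(), f2)
  expect_equal(length(readResults(f2)), 0)
})

test_that("hex grids serialise to GeoJSON FeatureCollections", {
  grid <- buildHexGrid(c(0, 0, 120, 120), widthKm = 50)
  set.seed(1)
  xy <- cbind(runif(60, 0, 120), runif(60, 0, 120))
  tr <- matrix(runif(120, 0, 0.3), 60, 2,
               dimnames = list(NULL, c("euphytoid", "vine")))
  grid <- gridSummarise(grid, xy, tr, minPlots = 3)
  f <- withr::local_tempfile(fileext = ".geojson")
  writeResults(grid, f)
  gj <- readResults(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(nrow(gj$features), nrow(gridCenters(grid)))
  expect_true(all(c("n_plots", "mean_cover_euphytoid", "class_euphytoid") %in%
                  names(gj$features$properties)))
  expect_equal(gj$features$geometry$type[1], "Polygon")
})

test_that("permutation-test results serialise with their null distribution", {
  ds <- tinyDataset()
  cv <- aggregatePlots(ds)
  res <- modifiedPermutationTest(cv, speciesTraits(ds), "euphytoid", "n",
                                 nPerm = 50, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  writeResults(res, f)
  back <- readResults(f)
  expect_equal(back$diff_real, res@diffReal, tolerance = 1e-9)
  expect_equal(length(back$null_diffs), res@nPerm)
})
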
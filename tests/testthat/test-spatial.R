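test_that("plot distances are metric-correct in both CRS modes", {
  expect_equal(plotDistance(c(3, 7), c(3, 7)), 0)
  expect_equal(plotDistance(c(0, 0), c(3, 4)), 5)
  d <- plotDistance(c(0, 0), c(1, 0), crsMode = "degrees")  # 1 deg along equator
  expect_equal(d, 111.19, tolerance = 0.1 / 111.19)
})

test_that("Bray-Curtis dissimilarity matches definition and vegan", {
  expect_equal(brayCurtis(c(a = 2, b = 1), c(a = 2, b = 1)), 0)
  expect_equal(brayCurtis(c(a = 2), c(b = 3)), 1)
  expect_equal(brayCurtis(c(2, 0, 1), c(1, 1, 0)), 0.6)
  expect_error(brayCurtis(numeric(0), numeric(0)))

  skip_if_not_installed("vegan")
  set.seed(5)
  for (r in 1:20) {
    a <- round(runif(8, 0, 50), 2); b <- round(runif(8, 0, 50), 2)
    expect_equal(brayCurtis(a, b),
                 as.numeric(vegan::vegdist(rbind(a, b), "bray")),
                 tolerance = 1e-12)
  }
})

makeThinningDataset <- function(headers, covers) {
  taxa <- colnames(covers)
  obs <- do.call(rbind, lapply(seq_len(nrow(headers)), function(i) {
    pres <- which(covers[i, ] > 0)
    data.frame(plot_id = headers$plot_id[i], taxon_id = taxa[pres],
               layer_id = 1L, cover_pct = covers[i, pres])
  }))
  traits <- data.frame(taxon_id = taxa, functional_type = "autotroph",
                       eive_n = NA_real_, eive_m = NA_real_,
                       eive_r = NA_real_, eive_t = NA_real_,
                       eive_l = NA_real_, is_aggregate = FALSE,
                       member_taxa = I(replicate(length(taxa), character())))
  vegDataset(headers, obs, traits)
}

test_that("co-located identical plots are thinned to a single plot", {
  h <- data.frame(plot_id = c("p1", "p2"), x = c(0, 0.1), y = 0,
                  plot_size_m2 = 10, habitat_code = "H1",
                  open = 1, wet = 0, saline = 0, bio10 = 10)
  covers <- rbind(c(a = 30, b = 20), c(a = 30, b = 20))
  ds <- makeThinningDataset(h, covers)
  th <- thinPlots(ds, seed = 3)
  expect_equal(length(th$retained), 1)
  expect_equal(nrow(th$dropLog), 1)
})

test_that("well-separated plots are never thinned", {
  h <- data.frame(plot_id = paste0("p", 1:5), x = (0:4) * 10, y = 0,
                  plot_size_m2 = 10, habitat_code = "H1",
                  open = 1, wet = 0, saline = 0, bio10 = 10)
  covers <- matrix(20, 5, 2, dimnames = list(NULL, c("a", "b")))
  ds <- makeThinningDataset(h, covers)
  th <- thinPlots(ds)
  expect_equal(sort(th$retained), sort(h$plot_id))
})

test_that("conflict chains leave no conflicting pair (brute-force check)", {
  ## A ~ B ~ C where A and C are 1.2 km apart (not conflicting)
  h <- data.frame(plot_id = c("A", "B", "C"), x = c(0, 0.6, 1.2), y = 0,
                  plot_size_m2 = 10, habitat_code = "H1",
                  open = 1, wet = 0, saline = 0, bio10 = 10)
  covers <- rbind(c(a = 30, b = 20), c(a = 30, b = 20), c(a = 30, b = 20))
  ds <- makeThinningDataset(h, covers)
  for (s in 1:10) {
    th <- thinPlots(ds, seed = s)
    cv <- aggregatePlots(ds)
    expect_equal(thinningViolations(ds, cv, th$retained), 0)
  }
})

test_that("thinning is seed-reproducible and idempotent", {
  fx <- structuredFixture()
  th1 <- thinPlots(fx$dataset, fx$cover, seed = 9)
  th2 <- thinPlots(fx$dataset, fx$cover, seed = 9)
  expect_identical(th1$retained, th2$retained)

  ## idempotence: re-thinning the retained set removes nothing
  h <- plotHeaders(fx$dataset)
  keep <- h$plot_id %in% th1$retained
  o <- plotObservations(fx$dataset)
  ds2 <- vegDataset(h[keep, ], o[o$plot_id %in% th1$retained, ],
                    speciesTraits(fx$dataset))
  th3 <- thinPlots(ds2, seed = 10)
  expect_equal(length(th3$dropped), 0)
})

test_that("the dissimilarity reading of the threshold is selectable", {
  ## nearly disjoint close plots: BC ~ 1 -> conflict only under the
  ## dissimilarity interpretation
  h <- data.frame(plot_id = c("p1", "p2"), x = c(0, 0.1), y = 0,
                  plot_size_m2 = 10, habitat_code = "H1",
                  open = 1, wet = 0, saline = 0, bio10 = 10)
  covers <- rbind(c(a = 30, b = 0), c(a = 0, b = 30))
  ds <- makeThinningDataset(h, covers)
  expect_equal(length(thinPlots(ds)$retained), 2)
  expect_equal(length(thinPlots(ds, thresholdOn = "dissimilarity")$retained), 1)
})

test_that("hexagonal cells have the exact equal-area geometry", {
  grid <- buildHexGrid(c(0, 0, 500, 500), widthKm = 50)
  expect_equal(hexCellArea(grid), sqrt(3) / 2 * 50^2, tolerance = 1e-6)
  grid10 <- buildHexGrid(c(0, 0, 100, 100), widthKm = 10)
  expect_equal(hexCellArea(grid10), 86.60, tolerance = 1e-3)
  expect_error(buildHexGrid(c(0, 0, 10, 10), widthKm = 0))

  ## degenerate bbox: a point still gets one containing cell
  gpt <- buildHexGrid(c(5, 5, 5, 5), widthKm = 50)
  cell <- assignHexCells(gpt, cbind(5, 5))
  expect_equal(length(cell), 1)
  ctr <- gridCenters(gpt)[cell, ]
  expect_lt(sqrt(sum((ctr - c(5, 5))^2)), 50 / sqrt(3) + 1e-9)
})

test_that("every plot maps to exactly one cell and means match brute force", {
  set.seed(8)
  xy <- cbind(runif(400, 0, 300), runif(400, 0, 300))
  tr <- matrix(runif(800, 0, 0.4), 400, 2,
               dimnames = list(NULL, c("euphytoid", "vine")))
  grid <- buildHexGrid(c(0, 0, 300, 300), widthKm = 50)
  cellOf <- assignHexCells(grid, xy)
  expect_equal(length(cellOf), 400)
  expect_true(all(cellOf >= 1 & cellOf <= nrow(gridCenters(grid))))

  gs <- gridSummarise(grid, xy, tr, minPlots = 5)
  cells <- gridCells(gs)
  for (ci in unique(cellOf)) {
    idx <- which(cellOf == ci)
    if (length(idx) >= 5) {
      expect_equal(cells$mean_cover_euphytoid[ci], mean(tr[idx, "euphytoid"]))
    } else {
      expect_true(is.na(cells$mean_cover_euphytoid[ci]))
    }
  }
  expect_equal(cells$n_plots[match(seq_len(nrow(gridCenters(grid))),
                                   cells$cell)],
               tabulate(cellOf, nbins = nrow(gridCenters(grid))))
})

test_that("cells below the plot minimum get no mean", {
  grid <- buildHexGrid(c(0, 0, 10, 10), widthKm = 50)
  tr4 <- matrix(0.1, 4, 1, dimnames = list(NULL, "euphytoid"))
  gs4 <- gridSummarise(grid, cbind(rep(5, 4), rep(5, 4)), tr4, minPlots = 5)
  i4 <- assignHexCells(grid, cbind(5, 5))
  expect_true(is.na(gridCells(gs4)$mean_cover_euphytoid[i4]))

  tr5 <- matrix(c(0, 0, 0, 0, 0.5), 5, 1, dimnames = list(NULL, "euphytoid"))
  ## a single populated cell leaves one distinct nonzero mean -> class warning
  expect_warning(
    gs5 <- gridSummarise(grid, cbind(rep(5, 5), rep(5, 5)), tr5, minPlots = 5),
    "distinct")
  expect_equal(gridCells(gs5)$mean_cover_euphytoid[i4], 0.1)
})

test_that("quantile classes exclude zero cells and use interpolated breaks", {
  qc <- quantileClasses(rep(0, 6), k = 4)
  expect_true(all(qc$class == 0))
  expect_equal(length(qc$breaks), 0)

  qc <- quantileClasses(as.numeric(1:100), k = 4)
  expect_equal(qc$breaks, c(25.75, 50.5, 75.25))
  expect_equal(unname(as.vector(table(qc$class))), rep(25L, 4))

  expect_warning(qc1 <- quantileClasses(c(0, 0, 3), k = 4), "distinct")
  expect_equal(qc1$class, c(0L, 0L, 1L))

  qc2 <- quantileClasses(c(NA, 0, 1, 2, 3, 4), k = 2)
  expect_true(is.na(qc2$class[1]))
  expect_equal(qc2$class[-1], c(0L, 1L, 1L, 2L, 2L))
})
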
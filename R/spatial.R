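## Near-duplicate thinning, hexagonal gridding and grid-cell summaries.

EARTH_RADIUS_KM <- 6371

#' Distance between two plots in km
#'
#' Euclidean distance for planar-km coordinates, haversine (R = 6371 km)
#' for longitude/latitude in decimal degrees.
#'
#' @param a,b numeric `c(x, y)` vectors or one-row header data.frames.
#' @param crsMode "planar_km" or "degrees".
#' @return distance in km (non-negative, symmetric).
#' @export
plotDistance <- function(a, b, crsMode = c("planar_km", "degrees")) {
  crsMode <- match.arg(crsMode)
  xy <- function(p) if (is.data.frame(p)) c(p$x[1], p$y[1]) else as.numeric(p[1:2])
  a <- xy(a); b <- xy(b)
  if (crsMode == "planar_km") {
    sqrt(sum((a - b)^2))
  } else {
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM * 1000) / 1000
  }
}

#' Bray-Curtis dissimilarity between two cover vectors
#'
#' BC = sum(|a_i - b_i|) / sum(a_i + b_i) over the union of species.
#'
#' @param a,b named (or equal-length unnamed) numeric cover vectors.
#' @return dissimilarity in [0, 1]; 0 for identical, 1 for disjoint.
#' @export
brayCurtis <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    nm <- union(names(a), names(b))
    av <- stats::setNames(numeric(length(nm)), nm)
    bv <- av
    av[names(a)] <- a
    bv[names(b)] <- b
    a <- av; b <- bv
  }
  if (length(a) != length(b)) stopf("brayCurtis: incompatible vectors")
  tot <- sum(a + b)
  if (tot == 0) stopf("brayCurtis: both cover vectors are empty")
  sum(abs(a - b)) / tot
}

## approximate planar km coordinates for binning (exact for planar_km mode)
planarKm <- function(h, crsMode) {
  if (crsMode == "planar_km") return(cbind(h$x, h$y))
  latScale <- pi * EARTH_RADIUS_KM / 180
  cbind(h$x * latScale * cos(mean(h$y) * pi / 180), h$y * latScale)
}

## all index pairs within distKm, via 1-cell spatial binning + exact check
closePairs <- function(h, crsMode, distKm) {
  km <- planarKm(h, crsMode)
  cx <- floor(km[, 1] / distKm)
  cy <- floor(km[, 2] / distKm)
  key <- paste(cx, cy)
  byCell <- split(seq_len(nrow(km)), key)
  cellIndex <- new.env(parent = emptyenv())
  for (k in names(byCell)) assign(k, byCell[[k]], envir = cellIndex)
  out_i <- integer(); out_j <- integer()
  for (k in names(byCell)) {
    ij <- as.integer(strsplit(k, " ", fixed = TRUE)[[1]])
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) {
      nk <- paste(ij[1] + dx, ij[2] + dy)
      v <- get0(nk, envir = cellIndex, inherits = FALSE)
      if (!is.null(v)) cand <- c(cand, v)
    }
    for (i in byCell[[k]]) {
      js <- cand[cand > i]
      if (!length(js)) next
      d <- sqrt((km[js, 1] - km[i, 1])^2 + (km[js, 2] - km[i, 2])^2)
      keep <- js[d < distKm * 1.05]  # generous; refined below in degrees mode
      if (length(keep)) {
        out_i <- c(out_i, rep.int(i, length(keep)))
        out_j <- c(out_j, keep)
      }
    }
  }
  if (length(out_i) && crsMode == "degrees") {
    dd <- geosphere::distHaversine(cbind(h$x[out_i], h$y[out_i]),
                                   cbind(h$x[out_j], h$y[out_j]),
                                   r = EARTH_RADIUS_KM * 1000) / 1000
    sel <- dd < distKm
    out_i <- out_i[sel]; out_j <- out_j[sel]
  } else if (length(out_i)) {
    dd <- sqrt((km[out_i, 1] - km[out_j, 1])^2 + (km[out_i, 2] - km[out_j, 2])^2)
    sel <- dd < distKm
    out_i <- out_i[sel]; out_j <- out_j[sel]
  }
  cbind(i = out_i, j = out_j)
}

#' Thin spatially pseudo-replicated plots
#'
#' From every pair of plots closer than `distKm` whose compositional
#' similarity (1 - Bray-Curtis dissimilarity on layer-combined covers)
#' exceeds `simThreshold`, one plot is dropped at random (seeded).
#' Conflict chains are resolved by visiting conflict edges in shuffled
#' order and dropping a random endpoint of each edge whose endpoints both
#' survive so far; the retained set therefore contains no conflicting pair.
#'
#' @param dataset a [VegDataset-class].
#' @param cover optional precomputed [VegCover-class] (default
#'   `aggregatePlots(dataset)`).
#' @param distKm distance threshold in km (default 1).
#' @param simThreshold threshold (default 0.8).
#' @param thresholdOn apply the threshold to "similarity" (default; conflict
#'   when 1 - BC > threshold) or to "dissimilarity" (conflict when
#'   BC > threshold).
#' @param seed RNG seed for the random pair resolution.
#' @return list with `retained` (plot ids), `dropped` (plot ids) and
#'   `dropLog` (data.frame: dropped, conflictsWith, brayCurtis).
#' @export
thinPlots <- function(dataset, cover = aggregatePlots(dataset),
                      distKm = 1, simThreshold = 0.8,
                      thresholdOn = c("similarity", "dissimilarity"),
                      seed = 1) {
  thresholdOn <- match.arg(thresholdOn)
  h <- plotHeaders(dataset)
  cp <- closePairs(h, crsMode(dataset), distKm)
  cov <- coverMatrix(cover)[h$plot_id, , drop = FALSE]
  conflicts <- matrix(numeric(0), 0, 4)
  if (nrow(cp)) {
    bc <- vapply(seq_len(nrow(cp)), function(r) {
      a <- cov[cp[r, 1], ]; b <- cov[cp[r, 2], ]
      tot <- sum(a + b)
      if (tot == 0) 0 else sum(abs(a - b)) / tot
    }, 0)
    hit <- if (thresholdOn == "similarity") (1 - bc) > simThreshold else bc > simThreshold
    cp <- cp[hit, , drop = FALSE]
    bc <- bc[hit]
  } else bc <- numeric()

  retained <- rep(TRUE, nrow(h))
  dropLog <- data.frame(dropped = character(), conflictsWith = character(),
                        brayCurtis = numeric())
  if (nrow(cp)) {
    set.seed(seed)
    ord <- sample.int(nrow(cp))
    for (r in ord) {
      i <- cp[r, 1]; j <- cp[r, 2]
      if (retained[i] && retained[j]) {
        drop <- if (stats::runif(1) < 0.5) i else j
        keep <- if (drop == i) j else i
        retained[drop] <- FALSE
        dropLog <- rbind(dropLog, data.frame(
          dropped = h$plot_id[drop], conflictsWith = h$plot_id[keep],
          brayCurtis = bc[r]))
      }
    }
  }
  list(retained = h$plot_id[retained],
       dropped = h$plot_id[!retained],
       dropLog = dropLog)
}

## vertices of a flat-topped hexagon; flat-to-flat width (y direction) = widthKm
hexVertices <- function(center, widthKm) {
  R <- widthKm / sqrt(3)
  ang <- (0:5) * pi / 3
  cbind(x = center[1] + R * cos(ang), y = center[2] + R * sin(ang))
}

#' Build a hexagonal grid covering a bounding box
#'
#' Flat-topped hexagons whose flat-to-flat width (aligned with the y /
#' latitudinal axis) is `widthKm`; cell area is (sqrt(3)/2) * widthKm^2,
#' i.e. 2165.06 km^2 for the default 50-km cells.
#'
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)` in km. A degenerate
#'   (point) box yields the single cell containing it.
#' @param widthKm flat-to-flat cell width (default 50).
#' @return a [HexGrid-class].
#' @export
buildHexGrid <- function(bbox, widthKm = 50) {
  if (widthKm <= 0) stopf("buildHexGrid: widthKm must be positive")
  if (length(bbox) != 4 || bbox[3] < bbox[1] || bbox[4] < bbox[2])
    stopf("buildHexGrid: bbox must be c(xmin, ymin, xmax, ymax)")
  R <- widthKm / sqrt(3)
  dx <- 1.5 * R
  cols <- 0:max(0, ceiling((bbox[3] - bbox[1] + 2 * R) / dx))
  rows <- 0:max(0, ceiling((bbox[4] - bbox[2] + widthKm) / widthKm))
  centers <- do.call(rbind, lapply(cols, function(ci) {
    offs <- if (ci %% 2 == 1) widthKm / 2 else 0
    cbind(bbox[1] - R + ci * dx, bbox[2] - widthKm / 2 + rows * widthKm + offs)
  }))
  colnames(centers) <- c("x", "y")
  methods::new("HexGrid", centers = centers, widthKm = widthKm,
               cells = data.frame())
}

#' Planar area of a grid cell, computed from its polygon
#'
#' Shoelace area of the first cell's hexagon; all cells are congruent.
#' @param grid a [HexGrid-class].
#' @return area in km^2.
#' @export
hexCellArea <- function(grid) {
  v <- hexVertices(grid@centers[1, ], grid@widthKm)
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:6, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Assign points to hexagonal grid cells
#'
#' A hexagonal tiling is the Voronoi diagram of its cell centres, so each
#' point belongs to the nearest centre (ties broken by lowest cell index);
#' every point maps to exactly one cell.
#'
#' @param grid a [HexGrid-class].
#' @param xy n x 2 matrix of point coordinates (km frame).
#' @return integer vector of cell indices.
#' @export
assignHexCells <- function(grid, xy) {
  xy <- as.matrix(xy)
  ctr <- grid@centers
  vapply(seq_len(nrow(xy)), function(i) {
    d2 <- (ctr[, 1] - xy[i, 1])^2 + (ctr[, 2] - xy[i, 2])^2
    which.min(d2)
  }, 0L)
}

#' Summarise per-plot functional-type cover on a hexagonal grid
#'
#' Computes, per cell, the number of plots and the arithmetic mean relative
#' cover of each functional type; cells with fewer than `minPlots` plots get
#' NA means.
#'
#' @param grid a [HexGrid-class].
#' @param xy n x 2 plot coordinates (km frame, same frame as the grid).
#' @param typeRelative plots x type matrix (see [typeRelativeCover()]).
#' @param minPlots minimum plots per cell for a mean to be reported
#'   (default 5).
#' @param k number of quantile colour classes (default 5).
#' @return the grid with its `cells` slot filled: n_plots, mean_cover_<type>
#'   and class_<type> columns.
#' @export
gridSummarise <- function(grid, xy, typeRelative, minPlots = 5, k = 5) {
  cellOf <- assignHexCells(grid, xy)
  nCells <- nrow(grid@centers)
  nPlots <- tabulate(cellOf, nbins = nCells)
  cells <- data.frame(cell = seq_len(nCells), n_plots = nPlots)
  for (ty in colnames(typeRelative)) {
    s <- rowsum(typeRelative[, ty], cellOf)
    m <- rep(NA_real_, nCells)
    idx <- as.integer(rownames(s))
    m[idx] <- s[, 1] / nPlots[idx]
    m[nPlots < minPlots] <- NA_real_
    cells[[paste0("mean_cover_", ty)]] <- m
    qc <- quantileClasses(ifelse(is.na(m), NA, m), k = k)
    cells[[paste0("class_", ty)]] <- qc$class
  }
  grid@cells <- cells
  methods::validObject(grid)
  grid
}

#' Quantile colour classes for grid-cell means
#'
#' Cells with zero mean cover are excluded from break computation and
#' assigned class 0; the remaining values are split into `k` classes at
#' linear-interpolation quantiles. NA values stay NA.
#'
#' @param values numeric vector (e.g. per-cell mean covers).
#' @param k number of classes (>= 2).
#' @return list with `breaks` (inner break values) and `class` (integer
#'   vector: 0 for zeros, 1..k otherwise, NA preserved).
#' @export
quantileClasses <- function(values, k = 5) {
  if (k < 2) stopf("quantileClasses: k must be >= 2")
  cls <- rep(NA_integer_, length(values))
  nz <- which(!is.na(values) & values > 0)
  cls[!is.na(values) & values == 0] <- 0L
  if (!length(nz)) return(list(breaks = numeric(), class = cls))
  vals <- values[nz]
  kEff <- min(k, length(unique(vals)))
  if (kEff < k)
    warnf("quantileClasses: only %d distinct nonzero values; using %d class(es)",
          length(unique(vals)), kEff)
  if (kEff == 1) {
    cls[nz] <- 1L
    return(list(breaks = numeric(), class = cls))
  }
  breaks <- stats::quantile(vals, probs = seq_len(kEff - 1) / kEff,
                            type = 7, names = FALSE)
  cls[nz] <- findInterval(vals, unique(breaks), left.open = TRUE) + 1L
  list(breaks = breaks, class = cls)
}
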
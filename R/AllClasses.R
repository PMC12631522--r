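#' VegDataset: a validated vegetation-plot dataset
#'
#' Container for the three tables the pipeline operates on: plot headers
#' (coordinates, plot size, habitat descriptors and environmental
#' covariates), long-format species observations (plot x taxon x layer x
#' cover %) and a species trait table (functional type, the five EIVE
#' indicator values for soil nitrogen, moisture, reaction, temperature and
#' light, and aggregate membership).
#'
#' Validity enforces referential integrity (every observation resolves to a
#' known plot and taxon), cover percentages in (0, 100], binary habitat
#' descriptors, EIVE values in [0, 10] when present, uniqueness of
#' (plot, taxon, layer) and non-empty membership of aggregate taxa.
#'
#' @slot headers data.frame of plot headers, one row per plot.
#' @slot observations data.frame with columns plot_id, taxon_id, layer_id,
#'   cover_pct.
#' @slot traits data.frame with columns taxon_id, functional_type, the five
#'   eive_* columns, is_aggregate and member_taxa (list column).
#' @slot crsMode either "planar_km" (Euclidean distances on km coordinates)
#'   or "degrees" (haversine distances on longitude/latitude).
#'
#' @exportClass VegDataset
setClass("VegDataset",
  slots = c(
    headers = "data.frame",
    observations = "data.frame",
    traits = "data.frame",
    crsMode = "character"
  )
)

setValidity("VegDataset", function(object) {
  h <- object@headers; o <- object@observations; tr <- object@traits
  msgs <- character()
  if (!object@crsMode %in% c("planar_km", "degrees"))
    msgs <- c(msgs, "crsMode must be 'planar_km' or 'degrees'")
  needH <- c("plot_id", "x", "y", "plot_size_m2", "habitat_code",
             "open", "wet", "saline")
  if (!all(needH %in% names(h)))
    msgs <- c(msgs, paste("headers missing column(s):",
                          paste(setdiff(needH, names(h)), collapse = ", ")))
  needO <- c("plot_id", "taxon_id", "layer_id", "cover_pct")
  if (!all(needO %in% names(o)))
    msgs <- c(msgs, paste("observations missing column(s):",
                          paste(setdiff(needO, names(o)), collapse = ", ")))
  needT <- c("taxon_id", "functional_type", eiveColumns(),
             "is_aggregate", "member_taxa")
  if (!all(needT %in% names(tr)))
    msgs <- c(msgs, paste("traits missing column(s):",
                          paste(setdiff(needT, names(tr)), collapse = ", ")))
  if (length(msgs)) return(msgs)

  if (anyDuplicated(h$plot_id))
    msgs <- c(msgs, "duplicated plot_id in headers")
  if (anyDuplicated(tr$taxon_id))
    msgs <- c(msgs, "duplicated taxon_id in traits")
  bad <- which(!(o$cover_pct > 0 & o$cover_pct <= 100))
  if (length(bad))
    msgs <- c(msgs, sprintf("cover_pct outside (0,100] at observation row(s) %s",
                            paste(utils::head(bad, 5), collapse = ", ")))
  if (anyDuplicated(o[, c("plot_id", "taxon_id", "layer_id")]))
    msgs <- c(msgs, "duplicated (plot_id, taxon_id, layer_id) in observations")
  if (!all(o$plot_id %in% h$plot_id))
    msgs <- c(msgs, sprintf("observation plot_id not in headers: %s",
                            paste(utils::head(setdiff(o$plot_id, h$plot_id), 5),
                                  collapse = ", ")))
  if (!all(o$taxon_id %in% tr$taxon_id))
    msgs <- c(msgs, sprintf("observation taxon_id not in traits: %s",
                            paste(utils::head(setdiff(o$taxon_id, tr$taxon_id), 5),
                                  collapse = ", ")))
  if (!all(tr$functional_type %in% functionalTypes()))
    msgs <- c(msgs, "unknown functional_type in traits")
  for (cn in eiveColumns()) {
    v <- tr[[cn]]
    if (any(!is.na(v) & (v < 0 | v > 10)))
      msgs <- c(msgs, sprintf("%s outside [0,10]", cn))
  }
  if (!all(h$open %in% c(0, 1)) || !all(h$wet %in% c(0, 1)) ||
      !all(h$saline %in% c(0, 1)))
    msgs <- c(msgs, "habitat descriptors open/wet/saline must be 0/1")
  psz <- h$plot_size_m2
  if (any(!is.na(psz) & psz <= 0))
    msgs <- c(msgs, "plot_size_m2 must be > 0 when present")
  agg <- tr$is_aggregate
  if (any(agg & lengths(tr$member_taxa) < 1))
    msgs <- c(msgs, "aggregate taxa must list at least one member")
  if (length(msgs)) msgs else TRUE
})

#' VegCover: per-plot aggregated species and functional-type cover
#'
#' Result of [aggregatePlots()]: layer-combined absolute covers, relative
#' covers (each species' cover divided by the plot's summed species cover)
#' and per-plot relative cover and presence of each functional type.
#'
#' @slot cover sparse plots x taxa matrix of layer-combined cover percentages.
#' @slot relative sparse plots x taxa matrix of relative covers; rows sum
#'   to 1 for non-empty plots.
#' @slot typeRelative plots x functional-type matrix of summed relative
#'   covers (parasitic types plus autotrophs).
#' @slot typePresence plots x functional-type 0/1 matrix.
#' @exportClass VegCover
setClass("VegCover",
  slots = c(
    cover = "Matrix",
    relative = "Matrix",
    typeRelative = "matrix",
    typePresence = "matrix"
  )
)

setValidity("VegCover", function(object) {
  rs <- Matrix::rowSums(object@relative)
  if (any(abs(rs[rs > 0] - 1) > 1e-9))
    return("relative covers must sum to 1 per non-empty plot")
  if (any(object@typeRelative < -1e-12 | object@typeRelative > 1 + 1e-9))
    return("typeRelative outside [0,1]")
  TRUE
})

#' HexGrid: hexagonal summary grid over a planar frame
#'
#' Flat-topped hexagons with a configurable flat-to-flat width; the
#' flat-to-flat axis is aligned with the y (latitudinal) direction so a
#' 50-km grid spans 50 km in latitude. Cell area is (sqrt(3)/2) * width^2.
#'
#' @slot centers n x 2 matrix of cell centres (km frame).
#' @slot widthKm flat-to-flat cell width in km.
#' @slot cells data.frame of per-cell summaries (filled by
#'   [gridSummarise()]), or a zero-row placeholder.
#' @exportClass HexGrid
setClass("HexGrid",
  slots = c(centers = "matrix", widthKm = "numeric", cells = "data.frame")
)

setValidity("HexGrid", function(object) {
  if (length(object@widthKm) != 1 || object@widthKm <= 0)
    return("widthKm must be a single positive number")
  if (ncol(object@centers) != 2) return("centers must be n x 2")
  TRUE
})

#' BrtFit: a fitted weighted Bernoulli boosted regression tree model
#'
#' @slot model the underlying boosted ensemble (xgboost booster).
#' @slot nTreesSelected tree count minimising the mean weighted held-out
#'   Bernoulli deviance across cross-validation folds.
#' @slot cvDeviance data.frame (n_trees, deviance) of the CV curve.
#' @slot influence named per-predictor relative influence, summing to 100.
#' @slot config the BrtConfig list used.
#' @slot trainX training predictor matrix (kept for partial dependence).
#' @slot trainY binary response.
#' @slot trainW observation weights.
#' @exportClass BrtFit
setClass("BrtFit",
  slots = c(
    model = "ANY",
    nTreesSelected = "integer",
    cvDeviance = "data.frame",
    influence = "numeric",
    config = "list",
    trainX = "matrix",
    trainY = "numeric",
    trainW = "numeric"
  )
)

setValidity("BrtFit", function(object) {
  if (abs(sum(object@influence) - 100) > 1e-6)
    return("relative influence must sum to 100")
  TRUE
})

#' PermTestResult: species-level permutation test on community-mean EIVE
#'
#' Holds the observed difference in plot-mean indicator values between
#' plots with and without a parasitic functional type, the permutation null
#' distribution obtained by shuffling species-level indicator values, the
#' standardised effect size SES = (diff_real - mean(diff_rand)) / sd(diff_rand),
#' the directional p-value (count of null differences beyond the observed
#' one in the direction of the SES, divided by the number of permutations)
#' and its two-sided counterpart.
#'
#' @slot indicator one of "n", "m", "r", "t", "l".
#' @slot functionalType focal parasitic functional type.
#' @slot diffReal observed occupied-minus-unoccupied difference.
#' @slot nullDiffs numeric vector of permutation differences.
#' @slot ses standardised effect size (NA if the null has zero spread).
#' @slot p directional p-value.
#' @slot pTwoSided two-sided p-value, min(1, 2 * p).
#' @slot nPerm number of permutations actually used.
#' @slot seed RNG seed.
#' @exportClass PermTestResult
setClass("PermTestResult",
  slots = c(
    indicator = "character",
    functionalType = "character",
    diffReal = "numeric",
    nullDiffs = "numeric",
    ses = "numeric",
    p = "numeric",
    pTwoSided = "numeric",
    nPerm = "integer",
    seed = "integer"
  )
)

setValidity("PermTestResult", function(object) {
  if (object@p < 0 || object@p > 1) return("p must lie in [0,1]")
  TRUE
})
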
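#' @name accessors
#' @title Accessors for paraniche S4 containers
#' @param object a paraniche S4 object
#' @param x a paraniche S4 object
#' @description Slot accessors; user code should use these rather than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("plotHeaders", function(object) standardGeneric("plotHeaders"))
#' @rdname accessors
#' @export
setGeneric("plotObservations", function(object) standardGeneric("plotObservations"))
#' @rdname accessors
#' @export
setGeneric("speciesTraits", function(object) standardGeneric("speciesTraits"))
#' @rdname accessors
#' @export
setGeneric("crsMode", function(object) standardGeneric("crsMode"))
#' @rdname accessors
#' @export
setGeneric("coverMatrix", function(object) standardGeneric("coverMatrix"))
#' @rdname accessors
#' @export
setGeneric("relativeCoverMatrix", function(object) standardGeneric("relativeCoverMatrix"))
#' @rdname accessors
#' @export
setGeneric("typeRelativeCover", function(object) standardGeneric("typeRelativeCover"))
#' @rdname accessors
#' @export
setGeneric("typePresence", function(object) standardGeneric("typePresence"))
#' @rdname accessors
#' @export
setGeneric("nTreesSelected", function(object) standardGeneric("nTreesSelected"))
#' @rdname accessors
#' @export
setGeneric("cvDevianceCurve", function(object) standardGeneric("cvDevianceCurve"))
#' @rdname accessors
#' @export
setGeneric("relativeInfluence", function(object) standardGeneric("relativeInfluence"))
#' @rdname accessors
#' @export
setGeneric("gridCells", function(object) standardGeneric("gridCells"))
#' @rdname accessors
#' @export
setGeneric("gridCenters", function(object) standardGeneric("gridCenters"))

#' Serialise a result object to JSON or GeoJSON
#'
#' @param object a result object (data.frame, list, PermTestResult, HexGrid).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
setGeneric("writeResults", function(object, path) standardGeneric("writeResults"))

setMethod("plotHeaders", "VegDataset", function(object) object@headers)
setMethod("plotObservations", "VegDataset", function(object) object@observations)
setMethod("speciesTraits", "VegDataset", function(object) object@traits)
setMethod("crsMode", "VegDataset", function(object) object@crsMode)

setMethod("coverMatrix", "VegCover", function(object) object@cover)
setMethod("relativeCoverMatrix", "VegCover", function(object) object@relative)
setMethod("typeRelativeCover", "VegCover", function(object) object@typeRelative)
setMethod("typePresence", "VegCover", function(object) object@typePresence)

setMethod("nTreesSelected", "BrtFit", function(object) object@nTreesSelected)
setMethod("cvDevianceCurve", "BrtFit", function(object) object@cvDeviance)
setMethod("relativeInfluence", "BrtFit", function(object) object@influence)

setMethod("gridCells", "HexGrid", function(object) object@cells)
setMethod("gridCenters", "HexGrid", function(object) object@centers)

setMethod("show", "VegDataset", function(object) {
  cat(sprintf("VegDataset: %d plots, %d observations, %d taxa (%s coordinates)\n",
              nrow(object@headers), nrow(object@observations),
              nrow(object@traits), object@crsMode))
  tt <- table(object@traits$functional_type)
  cat("  taxa by functional type:",
      paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
})

setMethod("show", "VegCover", function(object) {
  cat(sprintf("VegCover: %d plots x %d taxa; functional types: %s\n",
              nrow(object@cover), ncol(object@cover),
              paste(colnames(object@typeRelative), collapse = ", ")))
})

setMethod("show", "HexGrid", function(object) {
  cat(sprintf("HexGrid: %d cells, %.0f km flat-to-flat (cell area %.2f km^2)\n",
              nrow(object@centers), object@widthKm,
              sqrt(3) / 2 * object@widthKm^2))
})

setMethod("show", "BrtFit", function(object) {
  cat(sprintf("BrtFit: %d trees (CV-selected), %d predictors\n",
              object@nTreesSelected, length(object@influence)))
  inf <- sort(object@influence, decreasing = TRUE)
  cat("  relative influence (%):\n")
  for (i in seq_along(inf))
    cat(sprintf("    %-14s %6.2f\n", names(inf)[i], inf[i]))
})

setMethod("show", "PermTestResult", function(object) {
  cat(sprintf(
    "PermTestResult [%s / EIVE-%s]: diff_real=%.4f, SES=%.3f, p=%.4g (two-sided %.4g), %d permutations\n",
    object@functionalType, toupper(object@indicator), object@diffReal,
    object@ses, object@p, object@pTwoSided, object@nPerm))
})
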
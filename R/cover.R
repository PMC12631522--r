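## Layer aggregation and relative cover.

#' Combine per-layer covers of one species into a total cover
#'
#' Uses the Jennings-Fischer overlap formula, which treats layers as
#' independently overlapping: combined = 100 * (1 - prod(1 - c_i / 100)).
#' The result always lies between the largest single-layer cover and the
#' (capped) sum of layer covers.
#'
#' @param covers numeric vector of cover percentages in (0, 100], one per layer.
#' @return combined cover percentage.
#' @examples
#' combineLayers(c(50, 50))     # 75
#' combineLayers(c(30, 20, 10)) # 49.6
#' @export
combineLayers <- function(covers) {
  if (length(covers) == 0) stopf("combineLayers: empty cover vector")
  if (any(!is.finite(covers) | covers <= 0 | covers > 100))
    stopf("combineLayers: covers must lie in (0,100]")
  100 * (1 - prod(1 - covers / 100))
}

#' Relative cover of each species in a plot
#'
#' Each species' combined cover divided by the sum of combined species
#' covers in the plot.
#'
#' @param covers named numeric vector of per-species combined covers (> 0).
#' @return named numeric vector of fractions summing to 1.
#' @export
relativeCover <- function(covers) {
  if (length(covers) == 0) stopf("relativeCover: empty plot")
  if (any(covers <= 0)) stopf("relativeCover: covers must be positive")
  covers / sum(covers)
}

#' Relative cover and presence of each functional type in a plot
#'
#' Sums the relative covers of all member species of each functional type.
#'
#' @param relative named numeric vector of species relative covers (from
#'   [relativeCover()]).
#' @param traits trait data.frame with taxon_id and functional_type.
#' @return list with elements `typeRelative` and `typePresence`, both named
#'   by [functionalTypes()].
#' @export
functionalTypeCover <- function(relative, traits) {
  ft <- traits$functional_type[match(names(relative), traits$taxon_id)]
  if (anyNA(ft))
    stopf("no trait record for taxon: %s",
          paste(names(relative)[is.na(ft)], collapse = ", "))
  types <- functionalTypes()
  tr <- vapply(types, function(t) sum(relative[ft == t]), 0)
  list(typeRelative = tr, typePresence = stats::setNames(as.numeric(tr > 0), types))
}

#' Aggregate a dataset's layer observations into per-plot covers
#'
#' Combines multi-layer records of each species with the Jennings-Fischer
#' formula, derives relative covers, and sums them into per-plot relative
#' cover and presence of each functional type.
#'
#' @param dataset a [VegDataset-class].
#' @return a [VegCover-class] with plots as rows (all header plots, in
#'   header order) and taxa as columns.
#' @export
aggregatePlots <- function(dataset) {
  o <- plotObservations(dataset)
  h <- plotHeaders(dataset)
  tr <- speciesTraits(dataset)
  plotIds <- h$plot_id
  taxa <- tr$taxon_id

  ## Jennings-Fischer per (plot, taxon) via sum of log(1 - c/100)
  grp <- paste(o$plot_id, o$taxon_id, sep = "\r")
  ls <- rowsum(log1p(-o$cover_pct / 100), grp)
  combined <- 100 * (1 - exp(ls[, 1]))
  keys <- strsplit(rownames(ls), "\r", fixed = TRUE)
  pid <- vapply(keys, `[`, "", 1)
  tid <- vapply(keys, `[`, "", 2)

  i <- match(pid, plotIds)
  j <- match(tid, taxa)
  cov <- Matrix::sparseMatrix(i = i, j = j, x = combined,
                              dims = c(length(plotIds), length(taxa)),
                              dimnames = list(plotIds, taxa))
  rs <- Matrix::rowSums(cov)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  rel <- Matrix::Diagonal(x = inv) %*% cov
  dimnames(rel) <- dimnames(cov)

  types <- functionalTypes()
  ind <- vapply(types, function(t) as.numeric(tr$functional_type == t),
                numeric(length(taxa)))
  typeRel <- as.matrix(rel %*% ind)
  dimnames(typeRel) <- list(plotIds, types)
  ## presence from the cover matrix (a type can be present with relative
  ## cover rounding to ~0 only if cover is 0, so > 0 on covers is exact)
  typePres <- (as.matrix(cov %*% ind) > 0) + 0
  dimnames(typePres) <- list(plotIds, types)

  methods::new("VegCover", cover = cov, relative = rel,
               typeRelative = typeRel, typePresence = typePres)
}
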
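#' Parasitic plant taxon counts in the European vegetation-plot flora
#'
#' Numbers of parasitic taxa per functional type identified in
#' continental-scale European vegetation-plot archives, and the total
#' vascular taxon count of that species pool. Used to fix the relative
#' ordering of the synthetic generator's default type proportions and for
#' summary arithmetic (parasites as a percentage of the flora).
#'
#' @return `euroParasiteCounts()`: named integer vector (euphytoid,
#'   obligate_root, vine, mistletoe). `euroFloraTaxa()`: total taxon count.
#' @export
euroParasiteCounts <- function() {
  c(euphytoid = 176L, obligate_root = 52L, vine = 12L, mistletoe = 4L)
}

#' @rdname euroParasiteCounts
#' @export
euroFloraTaxa <- function() 11126L

#' Share of parasitic taxa in a species pool, in percent
#'
#' 100 * parasites / total, rounded to one decimal place.
#'
#' @param nParasites number of parasitic taxa.
#' @param nTotal total taxon count.
#' @export
parasiteSharePct <- function(nParasites = sum(euroParasiteCounts()),
                             nTotal = euroFloraTaxa()) {
  round(100 * nParasites / nTotal, 1)
}
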
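## CSV readers/writers for the three input tables and JSON/GeoJSON output.
## Dialect: comma-separated, UTF-8, header row required, "." decimal point,
## missing values as empty fields. Missing EIVE is legal; missing cover is not.

headerEnvColumns <- function(h) {
  fixed <- c("plot_id", "x", "y", "plot_size_m2", "habitat_code",
             "open", "wet", "saline")
  setdiff(names(h), fixed)
}

#' Construct a VegDataset from in-memory tables
#'
#' @param headers plot-header data.frame (plot_id, x, y, plot_size_m2,
#'   habitat_code, open, wet, saline, plus environmental covariate columns).
#' @param observations long observation table (plot_id, taxon_id, layer_id,
#'   cover_pct).
#' @param traits trait table (taxon_id, functional_type, eive_n/m/r/t/l,
#'   is_aggregate, member_taxa as a list column or ";"-joined string).
#' @param crsMode "planar_km" or "degrees".
#' @return a validated [VegDataset-class] object.
#' @export
vegDataset <- function(headers, observations, traits,
                       crsMode = c("planar_km", "degrees")) {
  crsMode <- match.arg(crsMode)
  headers <- as.data.frame(headers)
  observations <- as.data.frame(observations)
  traits <- as.data.frame(traits)
  if (is.null(traits$member_taxa)) traits$member_taxa <- replicate(nrow(traits), character())
  if (!is.list(traits$member_taxa))
    traits$member_taxa <- as.character(traits$member_taxa)
  if (is.character(traits$member_taxa)) {
    traits$member_taxa <- lapply(traits$member_taxa, function(s) {
      if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
    })
  }
  if (is.null(traits$is_aggregate)) traits$is_aggregate <- lengths(traits$member_taxa) > 0
  traits$is_aggregate <- as.logical(traits$is_aggregate)
  for (cn in c("plot_id")) headers[[cn]] <- as.character(headers[[cn]])
  observations$plot_id <- as.character(observations$plot_id)
  observations$taxon_id <- as.character(observations$taxon_id)
  traits$taxon_id <- as.character(traits$taxon_id)
  methods::new("VegDataset", headers = headers, observations = observations,
               traits = traits, crsMode = crsMode)
}

checkColumns <- function(df, need, what, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("schema error in %s (%s): missing column(s) %s",
          what, path, paste(miss, collapse = ", "))
}

#' Read a vegetation-plot dataset from three CSV files
#'
#' Performs schema and value validation on load: unknown plot or taxon ids
#' in the observation table, covers outside (0, 100], EIVE values outside
#' [0, 10] and non-binary habitat descriptors all raise errors.
#'
#' @param plotPath CSV of plot headers.
#' @param obsPath CSV of layer observations.
#' @param traitPath CSV of species traits; member_taxa ";"-joined.
#' @param crsMode "planar_km" or "degrees".
#' @return a validated [VegDataset-class].
#' @export
readDataset <- function(plotPath, obsPath, traitPath,
                        crsMode = c("planar_km", "degrees")) {
  crsMode <- match.arg(crsMode)
  for (p in c(plotPath, obsPath, traitPath))
    if (!file.exists(p)) stopf("file not found: %s", p)
  h <- utils::read.csv(plotPath, stringsAsFactors = FALSE)
  o <- utils::read.csv(obsPath, stringsAsFactors = FALSE)
  tr <- utils::read.csv(traitPath, stringsAsFactors = FALSE)
  checkColumns(h, c("plot_id", "x", "y", "plot_size_m2", "habitat_code",
                    "open", "wet", "saline"), "plot headers", plotPath)
  checkColumns(o, c("plot_id", "taxon_id", "layer_id", "cover_pct"),
               "observations", obsPath)
  checkColumns(tr, c("taxon_id", "functional_type", eiveColumns()),
               "traits", traitPath)
  bad <- which(!(o$cover_pct > 0 & o$cover_pct <= 100) | is.na(o$cover_pct))
  if (length(bad))
    stopf("cover_pct outside (0,100] at row(s) %s of %s",
          paste(utils::head(bad, 10), collapse = ", "), obsPath)
  vegDataset(h, o, tr, crsMode = crsMode)
}

#' Write a VegDataset back to the three-CSV on-disk layout
#'
#' @param dataset a [VegDataset-class].
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
writeDatasetCsv <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- plotHeaders(dataset)
  o <- plotObservations(dataset)
  tr <- speciesTraits(dataset)
  tr$member_taxa <- vapply(tr$member_taxa, paste, "", collapse = ";")
  paths <- c(plots = file.path(dir, "plots.csv"),
             observations = file.path(dir, "observations.csv"),
             traits = file.path(dir, "traits.csv"))
  utils::write.csv(h, paths["plots"], row.names = FALSE, na = "")
  utils::write.csv(o, paths["observations"], row.names = FALSE, na = "")
  utils::write.csv(tr, paths["traits"], row.names = FALSE, na = "")
  invisible(paths)
}

jsonWrite <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @describeIn writeResults tables (e.g. niche tables) as a JSON array of rows.
setMethod("writeResults", "data.frame", function(object, path) {
  jsonWrite(object, path)
})

#' @describeIn writeResults plain lists of scalars/vectors as a JSON object.
setMethod("writeResults", "list", function(object, path) {
  jsonWrite(object, path)
})

#' @describeIn writeResults permutation-test results as a JSON object
#'   including the full null distribution.
setMethod("writeResults", "PermTestResult", function(object, path) {
  jsonWrite(list(indicator = object@indicator,
                 functional_type = object@functionalType,
                 diff_real = object@diffReal,
                 ses = object@ses, p = object@p,
                 p_two_sided = object@pTwoSided,
                 n_perm = object@nPerm, seed = object@seed,
                 null_diffs = object@nullDiffs), path)
})

#' @describeIn writeResults hexagonal grids as a GeoJSON FeatureCollection of
#'   cell polygons with per-cell summary properties.
setMethod("writeResults", "HexGrid", function(object, path) {
  cells <- object@cells
  feats <- lapply(seq_len(nrow(object@centers)), function(i) {
    v <- hexVertices(object@centers[i, ], object@widthKm)
    ring <- rbind(v, v[1, , drop = FALSE])
    props <- if (nrow(cells)) as.list(cells[i, , drop = FALSE]) else
      list(cell = i)
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
})

#' Read back a JSON/GeoJSON result written by writeResults
#'
#' @param path file path.
#' @return data.frame for JSON row arrays, otherwise a named list; GeoJSON
#'   is returned as its parsed list structure.
#' @export
readResults <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
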
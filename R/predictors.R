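## Predictor preparation and RDA-style forward selection of climate variables.

#' Build the predictor matrix for distribution modelling
#'
#' Collects environmental covariates and habitat descriptors from the plot
#' headers, applies per-predictor transformations, square-root transforms
#' plot size, and handles missing plot sizes by median imputation plus a
#' binary missingness indicator column (`plot_size_missing`).
#'
#' @param dataset a [VegDataset-class].
#' @param transforms named list/vector mapping predictor name to one of
#'   "none", "log", "sqrt".
#' @param includePlotSize include sqrt(plot_size_m2) and its missingness
#'   indicator (default TRUE).
#' @param includeHabitat include the open/wet/saline descriptors
#'   (default TRUE).
#' @return numeric matrix (plots x predictors) with rownames = plot ids and
#'   attribute "transforms" recording what was applied.
#' @export
preparePredictors <- function(dataset, transforms = list(),
                              includePlotSize = TRUE, includeHabitat = TRUE) {
  h <- plotHeaders(dataset)
  envCols <- headerEnvColumns(h)
  X <- as.matrix(h[, envCols, drop = FALSE])
  mode(X) <- "numeric"
  applied <- stats::setNames(rep("none", length(envCols)), envCols)
  for (p in names(transforms)) {
    if (!p %in% envCols) stopf("preparePredictors: unknown predictor '%s'", p)
    tfun <- match.arg(transforms[[p]], c("none", "log", "sqrt"))
    if (tfun == "log") {
      bad <- which(X[, p] <= 0)
      if (length(bad))
        stopf("log transform of nonpositive %s at plot %s", p,
              h$plot_id[bad[1]])
      X[, p] <- log(X[, p])
    } else if (tfun == "sqrt") {
      if (any(X[, p] < 0)) stopf("sqrt transform of negative %s", p)
      X[, p] <- sqrt(X[, p])
    }
    applied[p] <- tfun
  }
  if (includeHabitat)
    X <- cbind(X, open = h$open, wet = h$wet, saline = h$saline)
  if (includePlotSize) {
    ps <- h$plot_size_m2
    missing <- is.na(ps)
    med <- stats::median(ps, na.rm = TRUE)
    if (is.na(med)) med <- 0
    ps[missing] <- med
    X <- cbind(X, plot_size_sqrt = sqrt(ps),
               plot_size_missing = as.numeric(missing))
    applied["plot_size_m2"] <- "sqrt"
  }
  rownames(X) <- h$plot_id
  attr(X, "transforms") <- applied
  X
}

#' Ezekiel-adjusted R-squared
#'
#' 1 - (1 - R^2) (n - 1) / (n - p - 1).
#'
#' @param r2 unadjusted R-squared in [0, 1].
#' @param n number of observations.
#' @param p number of predictors.
#' @return adjusted R-squared (<= r2).
#' @export
adjustedR2 <- function(r2, n, p) {
  if (n <= p + 1) stopf("adjustedR2: requires n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

## trace R^2 of regressing every column of Z on the columns S (by QR);
## Z must be column-centred. Returns fitted SS / total SS over all columns.
traceR2 <- function(Z, S) {
  tot <- sum(Z^2)
  if (tot == 0) return(1)
  if (!length(S)) return(0)
  q <- qr(Z[, S, drop = FALSE])
  fit <- qr.fitted(q, Z)
  sum(fit^2) / tot
}

#' Forward selection of climate predictors by explained redundancy
#'
#' Greedy RDA-style selection: columns are standardised, and at each step
#' the unselected predictor that maximises the total variance of the
#' climate matrix explained by the selected set (trace R^2 of the
#' multivariate regression of all columns on the selected columns) is
#' added. Selection stops when the cumulative Ezekiel-adjusted R^2 reaches
#' `stopR2adj` or no candidate adds explained variance.
#'
#' Ties within `tol` are broken by the `priority` list (e.g. preferring
#' growing-season variables), then by column order.
#'
#' @param climate numeric matrix of candidate climate predictors (>= 2
#'   columns); constant columns are dropped with a warning.
#' @param stopR2adj cumulative adjusted-R^2 stopping threshold
#'   (default 0.95).
#' @param priority optional character vector of preferred predictors for
#'   tie-breaking, in decreasing preference.
#' @param tol tie tolerance on the selection statistic (default 1e-9).
#' @return list with `selected` (ordered names), `cumulativeR2` and
#'   `cumulativeR2adj` (per selection step).
#' @export
rdaForwardSelect <- function(climate, stopR2adj = 0.95, priority = NULL,
                             tol = 1e-9) {
  climate <- as.matrix(climate)
  if (ncol(climate) < 2) stopf("rdaForwardSelect: need >= 2 climate columns")
  sc <- scaleColumns(climate)
  if (any(sc$constant)) {
    warnf("rdaForwardSelect: dropping constant column(s): %s",
          paste(colnames(climate)[sc$constant], collapse = ", "))
  }
  Z <- sc$z[, !sc$constant, drop = FALSE]
  n <- nrow(Z)
  vars <- colnames(Z)
  rank <- function(v) {
    pr <- match(v, priority)
    ifelse(is.na(pr), length(priority) + match(v, vars), pr)
  }
  selected <- character()
  cumR2 <- numeric()
  cumR2adj <- numeric()
  current <- 0
  repeat {
    cand <- setdiff(vars, selected)
    if (!length(cand)) break
    scores <- vapply(cand, function(j) traceR2(Z, c(selected, j)), 0)
    best <- max(scores)
    if (best <= current + tol && length(selected)) break  # nothing added
    tied <- cand[scores >= best - tol]
    pick <- tied[order(rank(tied))][1]
    selected <- c(selected, pick)
    current <- traceR2(Z, selected)
    cumR2 <- c(cumR2, current)
    cumR2adj <- c(cumR2adj, adjustedR2(current, n, length(selected)))
    if (cumR2adj[length(cumR2adj)] >= stopR2adj) break
  }
  list(selected = selected, cumulativeR2 = cumR2, cumulativeR2adj = cumR2adj)
}
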
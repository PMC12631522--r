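## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Functional types recognised by the package
#'
#' @return Character vector of the four parasitic functional types followed
#'   by `"autotroph"`.
#' @export
functionalTypes <- function() c(parasiteTypes(), "autotroph")

#' @rdname functionalTypes
#' @export
parasiteTypes <- function() c("euphytoid", "obligate_root", "vine", "mistletoe")

eiveIndicators <- function() c("n", "m", "r", "t", "l")

eiveColumns <- function() paste0("eive_", eiveIndicators())

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

## weighted quantile, linear interpolation on the weighted ECDF midpoint
weightedQuantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w) - w / 2
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

weightedSd <- function(x, w) {
  w <- w / sum(w)
  mu <- sum(w * x)
  sqrt(sum(w * (x - mu)^2))
}

## standardize columns; constant columns flagged
scaleColumns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  list(z = sweep(sweep(X, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/"),
       constant = sdv == 0)
}
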
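## Plot-mean ecological indicator values and the species-level
## modified permutation test with standardised effect sizes.

#' Fill aggregate taxa's EIVE values from their members
#'
#' For each aggregate taxon, every indicator is set to the arithmetic mean
#' over the member taxa that have a value for it; it stays missing when no
#' member has data. Non-aggregate rows are untouched.
#'
#' @param traits trait data.frame (taxon_id, eive_*, is_aggregate,
#'   member_taxa list column).
#' @return the trait table with aggregate EIVE values filled in.
#' @export
aggregateEive <- function(traits) {
  aggIdx <- which(traits$is_aggregate)
  for (i in aggIdx) {
    members <- match(traits$member_taxa[[i]], traits$taxon_id)
    members <- members[!is.na(members)]
    for (cn in eiveColumns()) {
      v <- traits[[cn]][members]
      v <- v[!is.na(v)]
      traits[[cn]][i] <- if (length(v)) mean(v) else NA_real_
    }
  }
  traits
}

#' Unweighted plot-mean EIVE, optionally excluding a functional type
#'
#' For each plot and indicator, the unweighted mean over present species
#' that carry a value for the indicator, excluding species of
#' `excludeType`; NA when no eligible species remain.
#'
#' @param cover a [VegCover-class].
#' @param traits trait data.frame (run [aggregateEive()] first if aggregate
#'   taxa should contribute).
#' @param excludeType functional type to exclude (default none).
#' @param excludeTaxa additional taxa to exclude (e.g. a focal species).
#' @return matrix plots x indicators ("n","m","r","t","l").
#' @export
plotMeanEive <- function(cover, traits, excludeType = NULL,
                         excludeTaxa = NULL) {
  pres <- relativeCoverMatrix(cover) > 0
  taxa <- colnames(pres)
  ti <- match(taxa, traits$taxon_id)
  out <- matrix(NA_real_, nrow(pres), length(eiveIndicators()),
                dimnames = list(rownames(pres), eiveIndicators()))
  excl <- rep(FALSE, length(taxa))
  if (!is.null(excludeType))
    excl <- excl | traits$functional_type[ti] %in% excludeType
  if (!is.null(excludeTaxa)) excl <- excl | taxa %in% excludeTaxa
  for (ind in eiveIndicators()) {
    v <- traits[[paste0("eive_", ind)]][ti]
    ok <- !is.na(v) & !excl
    M <- pres[, ok, drop = FALSE]
    cnt <- Matrix::rowSums(M)
    s <- as.numeric(M %*% v[ok])
    out[, ind] <- ifelse(cnt > 0, s / cnt, NA_real_)
  }
  out
}

#' Observed difference in plot-mean EIVE between occupied and unoccupied plots
#'
#' mean(occupied) - mean(unoccupied); plots with missing means are dropped
#' from both groups.
#'
#' @param means per-plot indicator means (one indicator).
#' @param occupied logical/0-1 vector: plots where the focal type occurs.
#' @return the difference.
#' @export
observedDifference <- function(means, occupied) {
  occupied <- occupied > 0
  keep <- !is.na(means)
  means <- means[keep]; occupied <- occupied[keep]
  if (!any(occupied) || all(occupied))
    stopf("observedDifference: both occupied and unoccupied plots are required")
  mean(means[occupied]) - mean(means[!occupied])
}

#' Modified permutation test for community-mean indicator values
#'
#' Tests whether plots occupied by a parasitic functional type differ in
#' their unweighted plot-mean indicator value (computed excluding species
#' of the focal type) from unoccupied plots. The null model permutes
#' species-level indicator values among all species that possess a value
#' for the indicator, keeping plot composition fixed; plot means and the
#' occupied-minus-unoccupied difference are recomputed per permutation.
#'
#' SES = (diff_real - mean(diff_rand)) / sd(diff_rand). The directional
#' p-value counts null differences at or beyond the observed one in the
#' direction of the SES, divided by the number of permutations (no +1
#' smoothing). Because the direction is taken from the data, this p is
#' one-tailed; a two-sided version min(1, 2p) is also reported.
#'
#' @param cover a [VegCover-class].
#' @param traits trait table (aggregate EIVE already filled as needed).
#' @param type focal parasitic functional type.
#' @param indicator one of "n", "m", "r", "t", "l".
#' @param nPerm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param exhaustive if TRUE, enumerate all permutations of the value
#'   vector instead of sampling (only feasible for very small species
#'   pools; nPerm is ignored).
#' @param permutation optional n_universe x nPerm matrix of permutation
#'   orders to reuse (for joint tests across indicators).
#' @return a [PermTestResult-class].
#' @export
modifiedPermutationTest <- function(cover, traits, type,
                                    indicator = c("n", "m", "r", "t", "l"),
                                    nPerm = 1000, seed = 1,
                                    exhaustive = FALSE, permutation = NULL) {
  indicator <- match.arg(indicator)
  type <- match.arg(type, parasiteTypes())
  pres <- relativeCoverMatrix(cover) > 0
  taxa <- colnames(pres)
  ti <- match(taxa, traits$taxon_id)
  vAll <- traits[[paste0("eive_", indicator)]][ti]
  ftype <- traits$functional_type[ti]

  universe <- which(!is.na(vAll))               # species carrying a value
  if (length(universe) < 2)
    stopf("modifiedPermutationTest: need >= 2 species with %s values", indicator)
  eligible <- universe[!(ftype[universe] %in% type)]  # enter the plot means
  M <- pres[, eligible, drop = FALSE]
  cnt <- Matrix::rowSums(M)
  occupied <- typePresence(cover)[, type] > 0
  keep <- cnt > 0
  if (!any(occupied[keep]) || all(occupied[keep]))
    stopf("modifiedPermutationTest: need occupied and unoccupied plots")

  Mk <- M[keep, , drop = FALSE]
  cntk <- cnt[keep]
  occk <- occupied[keep]
  diffOf <- function(vals) {
    ## vals: values over `universe`; subset to the eligible columns
    m <- as.numeric(Mk %*% vals[match(eligible, universe)]) / cntk
    mean(m[occk]) - mean(m[!occk])
  }
  vU <- vAll[universe]
  diffReal <- diffOf(vU)

  if (exhaustive) {
    nu <- length(universe)
    if (nu > 8)
      stopf("modifiedPermutationTest: exhaustive enumeration limited to <= 8 species")
    perms <- allPermutations(nu)
    nullDiffs <- apply(perms, 1, function(o) diffOf(vU[o]))
    nPerm <- nrow(perms)
  } else if (!is.null(permutation)) {
    nPerm <- ncol(permutation)
    nullDiffs <- vapply(seq_len(nPerm), function(b) {
      vp <- vU[permutation[, b]]
      stopifnot(identical(sort(vp), sort(vU)))   # value multiset preserved
      diffOf(vp)
    }, 0)
  } else {
    set.seed(seed)
    nullDiffs <- vapply(seq_len(nPerm), function(b) {
      vp <- vU[sample.int(length(vU))]
      stopifnot(identical(sort(vp), sort(vU)))   # value multiset preserved
      diffOf(vp)
    }, 0)
  }

  sdNull <- stats::sd(nullDiffs)
  if (sdNull == 0 || !is.finite(sdNull)) {
    warnf("modifiedPermutationTest: null distribution has zero spread")
    ses <- NA_real_
    p <- 1
  } else {
    ses <- (diffReal - mean(nullDiffs)) / sdNull
    p <- if (ses > 0) {
      sum(nullDiffs >= diffReal) / nPerm
    } else if (ses < 0) {
      sum(nullDiffs <= diffReal) / nPerm
    } else 1
  }
  methods::new("PermTestResult",
               indicator = indicator, functionalType = type,
               diffReal = diffReal, nullDiffs = as.numeric(nullDiffs),
               ses = ses, p = p, pTwoSided = min(1, 2 * p),
               nPerm = as.integer(nPerm), seed = as.integer(seed))
}

## all permutations of 1..n as an n! x n matrix
allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Run the permutation test across indicators (and optionally jointly)
#'
#' With `joint = TRUE`, one set of species shuffles is drawn over the
#' species carrying values for all requested indicators and applied
#' identically to every indicator (values travel as tuples); otherwise
#' each indicator is permuted independently.
#'
#' @inheritParams modifiedPermutationTest
#' @param indicators indicators to test.
#' @param joint share permutations across indicators (default FALSE).
#' @return named list of [PermTestResult-class] objects.
#' @export
eiveTestSuite <- function(cover, traits, type,
                          indicators = c("n", "m", "r", "t", "l"),
                          nPerm = 1000, seed = 1, joint = FALSE) {
  res <- list()
  for (ind in indicators) {
    perm <- NULL
    if (joint) {
      pres <- relativeCoverMatrix(cover) > 0
      ti <- match(colnames(pres), traits$taxon_id)
      v <- traits[[paste0("eive_", ind)]][ti]
      nu <- sum(!is.na(v))
      set.seed(seed)                            # same stream per indicator
      perm <- replicate(nPerm, sample.int(nu))
    }
    res[[ind]] <- modifiedPermutationTest(cover, traits, type, ind,
                                          nPerm = nPerm, seed = seed,
                                          permutation = perm)
  }
  res
}
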
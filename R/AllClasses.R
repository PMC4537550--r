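#' @useDynLib ringscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats splinefun rnorm rexp runif sd
#' @importFrom utils head tail
NULL

#' Sliding-window point cloud
#'
#' An ordered set of delay vectors \code{[g(t), g(t+tau), ..., g(t+M*tau)]}
#' sampled over a grid of window start positions.  After pointwise
#' mean-centering and normalization every point lies on the unit sphere in
#' \code{R^(M+1)} and has zero coordinate mean, which makes the downstream
#' periodicity score blind to amplitude, offset, damping and trending.
#'
#' @slot points numeric matrix, one point per row, \code{M + 1} columns.
#' @slot normalized logical; \code{TRUE} once each row has been centered to
#'   coordinate mean zero and scaled to unit Euclidean norm.
#' @slot nDegenerate integer; number of zero-variance windows that were
#'   excluded during normalization (a flat window has no direction).
#'
#' @seealso [slidingWindowCloud()], [centerNormalize()], [meanShift()]
#' @export
setClass("PointCloud",
  representation(points = "matrix", normalized = "logical",
                 nDegenerate = "integer"),
  prototype(points = matrix(numeric(0), 0, 0), normalized = FALSE,
            nDegenerate = 0L))

setValidity("PointCloud", function(object) {
  pts <- object@points
  if (!is.numeric(pts)) return("points must be a numeric matrix")
  if (anyNA(pts)) return("points must not contain missing values")
  if (length(object@normalized) != 1L) return("normalized must be a flag")
  if (isTRUE(object@normalized) && nrow(pts) > 0L) {
    norms <- sqrt(rowSums(pts^2))
    if (any(abs(norms - 1) > 1e-9))
      return("normalized cloud must have unit-norm points")
    if (any(abs(rowMeans(pts)) > 1e-9))
      return("normalized cloud must have zero-mean points")
  }
  TRUE
})

#' Persistence diagram in dimension 1
#'
#' The multiset of (birth, death) intervals of the 1-dimensional persistent
#' homology of a Vietoris-Rips filtration, computed over the prime field
#' \code{Z/fieldChar}.  Zero-persistence pairs are dropped.  Cycles still
#' alive at \code{maxScale} are stored with death equal to \code{maxScale}
#' and flagged censored.
#'
#' @slot intervals two-column numeric matrix (birth, death), birth < death.
#' @slot censored logical vector, one flag per interval.
#' @slot fieldChar integer, the prime characteristic of the coefficients.
#' @slot maxScale numeric, the filtration cutoff.
#'
#' @seealso [ripsH1()], [maxDeath()]
#' @export
setClass("PersistenceDiagram",
  representation(intervals = "matrix", censored = "logical",
                 fieldChar = "integer", maxScale = "numeric"),
  prototype(intervals = matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("birth", "death"))),
            censored = logical(0), fieldChar = 2L, maxScale = sqrt(3)))

setValidity("PersistenceDiagram", function(object) {
  iv <- object@intervals
  if (ncol(iv) != 2L) return("intervals must have two columns")
  if (nrow(iv) != length(object@censored))
    return("one censored flag per interval required")
  if (nrow(iv) > 0L) {
    if (any(iv[, 1L] < 0)) return("births must be nonnegative")
    if (any(iv[, 1L] >= iv[, 2L]))
      return("each interval must satisfy birth < death")
    if (any(iv[, 2L] > object@maxScale + 1e-12))
      return("deaths cannot exceed maxScale")
  }
  if (length(object@fieldChar) != 1L || object@fieldChar < 2L)
    return("fieldChar must be a prime >= 2")
  TRUE
})

#' Periodicity score for one signal
#'
#' The end result of the scoring pipeline for a single time series: the
#' coverage radius \code{b} (max distance from a cloud point to its nearest
#' neighbor), the effective maximal death \code{d} of the dominant 1-cycle,
#' and the score \code{1 - (d^n - b^m) / 3^(n/2)} in [0, 1], where 0 means
#' periodic and 1 not periodic.
#'
#' @slot id character, signal identifier.
#' @slot b,d numeric; \code{0 <= b <= d} (both \code{NA} when the pipeline
#'   short-circuits on a degenerate signal).
#' @slot score numeric in [0, 1].
#' @slot nExp,mExp integer score exponents.
#' @slot params list; snapshot of the window parameters used
#'   (\code{M}, \code{w}, \code{tau}, \code{L}, \code{gridSize}, ...).
#' @slot flags character; markers such as \code{"degenerate"},
#'   \code{"censored"}, \code{"clipped"}, \code{"d_clamped"}.
#'
#' @seealso [scoreSignal()], [periodicityScore()]
#' @export
setClass("PeriodicityResult",
  representation(id = "character", b = "numeric", d = "numeric",
                 score = "numeric", nExp = "integer", mExp = "integer",
                 params = "list", flags = "character"))

setValidity("PeriodicityResult", function(object) {
  if (length(object@score) != 1L || is.na(object@score))
    return("score must be a single number")
  if (object@score < 0 || object@score > 1)
    return("score must lie in [0, 1]")
  if (!is.na(object@b) && !is.na(object@d)) {
    if (object@b < 0) return("b must be nonnegative")
    if (object@b > object@d + 1e-12) return("b must not exceed d")
  }
  TRUE
})

#' ROC curve and AUC for periodic / non-periodic classification
#'
#' Lower scores predict the positive (periodic) class.  The AUC equals the
#' trapezoidal area under the curve and coincides with the tie-corrected
#' Mann-Whitney statistic.
#'
#' @slot thresholds numeric score cutoffs swept.
#' @slot fpr,tpr numeric, nondecreasing from 0 to 1.
#' @slot auc numeric in [0, 1].
#'
#' @seealso [rocCurve()]
#' @export
setClass("RocResult",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric"))

setValidity("RocResult", function(object) {
  if (length(object@fpr) != length(object@tpr))
    return("fpr and tpr must have equal length")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    return("fpr and tpr must be nondecreasing")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' Synthetic benchmark grid
#'
#' Container for the synthetic evaluation: one cell per combination of
#' noise model, noise level and sampling density, each holding a
#' \linkS4class{SummarizedExperiment} of labeled signals (rows = signals,
#' columns = time points).  After scoring, the tidy per-signal score table
#' is kept in the \code{scores} slot.
#'
#' @slot cells named list of \code{SummarizedExperiment} objects.
#' @slot config list; the generation configuration, including the seed.
#' @slot scores data.frame; empty until [runGrid()] fills it.
#'
#' @seealso [buildBenchmark()], [runGrid()], [gridAUC()]
#' @export
setClass("BenchmarkGrid",
  representation(cells = "list", config = "list", scores = "data.frame"),
  prototype(cells = list(), config = list(),
            scores = data.frame()))

setValidity("BenchmarkGrid", function(object) {
  if (length(object@cells) > 0L) {
    ok <- vapply(object@cells, function(x)
      methods::is(x, "SummarizedExperiment"), logical(1))
    if (!all(ok)) return("all cells must be SummarizedExperiment objects")
    if (is.null(names(object@cells))) return("cells must be named")
  }
  TRUE
})

#' Repeated permutation test result
#'
#' Empirical p-values for a periodicity score: each of \code{R} repetitions
#' shuffles the signal values \code{N} times and reports the proportion of
#' permutations scoring at least as periodic (score less than or equal to
#' the original).
#'
#' @slot id character.
#' @slot originalScore numeric.
#' @slot N,R integer; permutations per repetition and repetitions.
#' @slot pValues numeric of length \code{R}.
#' @slot pCorrected numeric of length \code{R}; the conventional
#'   \code{(count + 1) / (N + 1)} estimates, reported alongside.
#' @slot meanP,stdP numeric summaries of \code{pValues}.
#' @slot seed integer master seed.
#'
#' @seealso [repeatedPermutation()]
#' @export
setClass("PermutationResult",
  representation(id = "character", originalScore = "numeric",
                 N = "integer", R = "integer", pValues = "numeric",
                 pCorrected = "numeric", meanP = "numeric", stdP = "numeric",
                 seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (length(object@pValues) != object@R)
    return("one p-value per repetition required")
  if (any(object@pValues < 0 | object@pValues > 1))
    return("p-values must lie in [0, 1]")
  if (abs(object@meanP - mean(object@pValues)) > 1e-12)
    return("meanP inconsistent with pValues")
  TRUE
})
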
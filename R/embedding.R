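#' Fit a continuous interpolant on [0, 2*pi]
#'
#' The sampling times are mapped linearly so that the first maps to 0 and
#' the last to \code{2*pi}, and a natural cubic spline (second derivative
#' zero at the endpoints) interpolates the values: the returned function
#' \code{g} satisfies \code{g(0) = values[1]}, \code{g(2*pi) =
#' values[length(values)]}, and reproduces every sample at its mapped knot.
#' Uneven spacing is allowed.  With fewer than 4 points the interpolant
#' degree is effectively lowered (natural splines through 2 or 3 points).
#'
#' @param times strictly increasing numeric vector (any units).
#' @param values numeric vector, same length, no missing values.
#' @return a function of one argument on \code{[0, 2*pi]}.
#' @examples
#' g <- fitSpline(c(0, 16, 32), c(1, 4, 9))
#' g(0); g(2 * pi)
#' @export
fitSpline <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) < 2L) stop("need at least 2 points")
  if (anyNA(values))
    stop("missing values must be imputed before spline fitting")
  checkStrictlyIncreasing(times)
  theta <- (times - times[1L]) / (times[length(times)] - times[1L]) * 2 * pi
  splinefun(theta, values, method = "natural")
}

#' Theoretical window size for a sliding-window embedding
#'
#' For an embedding into \code{R^(M+1)} of a signal expected to complete
#' \code{L} periods over the record, the window size (in the rescaled
#' domain \code{[0, 2*pi]}) maximizing the roundness of the resulting
#' point cloud is close to \code{2*pi*M / (L*(M + 1))}.
#'
#' @param M embedding dimension minus one (positive integer).
#' @param L expected number of periods in the record (>= 1).
#' @return the window size \code{w} in \code{(0, 2*pi)}.
#' @examples
#' defaultWindow(1, 1)    # pi
#' defaultWindow(47, 2)   # ~3.0761
#' @export
defaultWindow <- function(M, L) {
  stopifnot(M >= 1, L >= 1)
  2 * pi * M / (L * (M + 1))
}

#' Default embedding dimension
#'
#' The delay count \code{M} should comfortably exceed twice the number of
#' samples; the default is the smallest odd integer at least
#' \code{2*nSamples + 1}, with a floor of 23.
#'
#' @param nSamples number of time points in the series.
#' @param floor minimum M.
#' @return integer M.
#' @export
defaultEmbedDim <- function(nSamples, floor = 23L) {
  m <- 2L * as.integer(nSamples) + 1L   # always odd
  max(as.integer(floor), m)
}

#' Sliding-window point cloud of a continuous signal
#'
#' Evaluates the delay vector \code{[g(t), g(t + tau), ..., g(t + M*tau)]},
#' \code{tau = w/M}, on the grid \code{t_j = j*(2*pi - w)/gridSize},
#' \code{j = 0, ..., gridSize}, so the last window ends exactly at
#' \code{2*pi}.  The default grid has 201 start positions.
#'
#' @param g function on \code{[0, 2*pi]}, e.g. from [fitSpline()].
#' @param M embedding dimension minus one.
#' @param w window size in \code{(0, 2*pi)}.
#' @param gridSize number of window start positions minus one.
#' @return an unnormalized \linkS4class{PointCloud} with
#'   \code{gridSize + 1} points of dimension \code{M + 1}.
#' @examples
#' g <- function(t) cos(2 * t)
#' cloud <- slidingWindowCloud(g, M = 23, w = defaultWindow(23, 2))
#' cloud
#' @export
slidingWindowCloud <- function(g, M, w, gridSize = 200L) {
  stopifnot(M >= 1, gridSize >= 2)
  if (w <= 0 || w >= 2 * pi)
    stop("window size w must lie strictly between 0 and 2*pi")
  tau <- w / M
  starts <- (0:gridSize) * (2 * pi - w) / gridSize
  offsets <- (0:M) * tau
  # evaluate all windows at once: outer grid of start + offset
  pts <- matrix(g(rep(starts, each = M + 1L) + rep(offsets, gridSize + 1L)),
                nrow = gridSize + 1L, ncol = M + 1L, byrow = TRUE)
  methods::new("PointCloud", points = pts, normalized = FALSE,
               nDegenerate = 0L)
}

#' Pointwise mean-centering and normalization
#'
#' Each point \code{x} is replaced by \code{(x - mean(x)) / ||x - mean(x)||},
#' the mean taken over the point's own coordinates.  This makes the cloud
#' invariant to per-signal affine transforms \code{a*g + c} (a > 0) and
#' ameliorates damping and trending.  Windows with (numerically) zero
#' variance have no direction; they are excluded and counted in
#' \code{nDegenerate}.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param tol norm below which a centered point is considered degenerate.
#' @return a normalized \linkS4class{PointCloud}.
#' @export
centerNormalize <- function(cloud, tol = 1e-10) {
  stopifnot(methods::is(cloud, "PointCloud"))
  pts <- cloud@points
  if (nrow(pts) == 0L) stop("cannot normalize an empty cloud")
  centered <- pts - rowMeans(pts)
  norms <- sqrt(rowSums(centered^2))
  scale <- tol * max(1, max(abs(pts)))
  degenerate <- norms <= scale
  keep <- centered[!degenerate, , drop = FALSE] / norms[!degenerate]
  methods::new("PointCloud", points = keep, normalized = TRUE,
               nDegenerate = cloud@nDegenerate + sum(degenerate))
}

#' Simple moving average of a time series
#'
#' Local smoothing: value \code{s} becomes the mean of values
#' \code{s - l, ..., s + l} with \code{l = min(s, S - s, k)} (0-based), so
#' the endpoints are left unchanged.  When window parameters are supplied
#' the averaging window may not span more than a third of the sliding
#' window size in original time units, protecting peak-like features.
#'
#' @param values numeric vector.
#' @param k half-width (window is \code{2k + 1} samples).
#' @param times sampling times; needed only to enforce the span constraint.
#' @param w window size in \code{(0, 2*pi)}; when supplied together with
#'   \code{times}, \code{k} is validated against the \code{w/3} rule and
#'   violations are rejected with the maximal admissible \code{k}.
#' @return smoothed numeric vector of the same length.
#' @examples
#' movingAverage(c(0, 3, 6), k = 1)  # endpoints kept, middle averaged
#' @export
movingAverage <- function(values, k, times = NULL, w = NULL) {
  S <- length(values) - 1L
  stopifnot(k >= 0, 2 * k + 1 <= length(values))
  if (k == 0L) return(values)
  if (!is.null(times) && !is.null(w)) {
    checkStrictlyIncreasing(times)
    maxSpan <- w / (2 * pi) * (times[length(times)] - times[1L]) / 3
    spanOf <- function(kk) {
      idx <- seq_along(times)
      lo <- pmax(idx - kk, 1L); hi <- pmin(idx + kk, length(times))
      full <- (hi - lo) == 2L * kk  # only full windows are constrained
      if (!any(full)) return(0)
      max(times[hi[full]] - times[lo[full]])
    }
    if (spanOf(k) > maxSpan) {
      kmax <- 0L
      while (kmax + 1L <= S %/% 2L && spanOf(kmax + 1L) <= maxSpan)
        kmax <- kmax + 1L
      stop(sprintf(
        "smoothing window of k = %d spans more than a third of the sliding window; maximal admissible k is %d",
        k, kmax))
    }
  }
  out <- values
  for (s in 0:S) {
    l <- min(s, S - s, k)
    if (l > 0L) out[s + 1L] <- mean(values[(s - l + 1L):(s + l + 1L)])
  }
  out
}

#' Mean-shift denoising on the unit sphere
#'
#' Each point of a normalized cloud is replaced by the average of all
#' points (itself included) whose spherical angle to it is below the
#' threshold; the result is rescaled to unit norm (no re-centering).  Dot
#' products are clamped to \code{[-1, 1]} before \code{acos}.  This
#' tightens the cloud against point-level noise; the default angle pi/16
#' was tuned on synthetic data.
#'
#' @param cloud a normalized \linkS4class{PointCloud}.
#' @param angleThreshold neighborhood angle in radians (strict inequality).
#' @param rounds number of mean-shift passes.
#' @return a normalized \linkS4class{PointCloud}.
#' @export
meanShift <- function(cloud, angleThreshold = pi / 16, rounds = 1L) {
  stopifnot(methods::is(cloud, "PointCloud"))
  if (!cloud@normalized) stop("mean-shift expects a normalized cloud")
  pts <- cloud@points
  if (nrow(pts) == 0L) stop("cannot mean-shift an empty cloud")
  for (r in seq_len(rounds)) {
    dots <- pmin(pmax(tcrossprod(pts), -1), 1)
    nbr <- acos(dots) < angleThreshold
    avg <- (nbr %*% pts) / rowSums(nbr)
    norms <- sqrt(rowSums(avg^2))
    pts <- avg / norms
  }
  methods::new("PointCloud", points = unname(as.matrix(pts)),
               normalized = TRUE, nDegenerate = cloud@nDegenerate)
}
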
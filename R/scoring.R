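#' Effective (b, d) pair for scoring
#'
#' Extracts the maximal death \code{d} from the diagram and clamps it below
#' by the coverage radius \code{b}, honoring the ordering
#' \code{0 <= b <= d}.  With an empty diagram \code{d = b}, which forces
#' score 1 (not periodic) when \code{n = m}.
#'
#' @param b coverage radius (>= 0).
#' @param diagram a \linkS4class{PersistenceDiagram}.
#' @return named list with \code{b}, \code{d} and a logical
#'   \code{clamped} marker.
#' @export
effectiveBD <- function(b, diagram) {
  stopifnot(b >= 0)
  d <- maxDeath(diagram)
  if (is.na(d)) return(list(b = b, d = b, clamped = FALSE))
  list(b = b, d = max(b, d), clamped = d < b)
}

#' Periodicity score from (b, d)
#'
#' \code{s(n, m) = 1 - (d^n - b^m) / 3^(n/2)}, between 0 (periodic) and 1
#' (not periodic).  For pointwise-normalized sliding-window clouds
#' \code{0 <= b <= d <= sqrt(3)}, so the score lands in [0, 1]; any
#' numerical overshoot is clipped and flagged via the \code{"clipped"}
#' attribute.  The default exponents are \code{n = m = 2}.
#'
#' @param b,d coverage radius and effective death, \code{0 <= b <= d}.
#' @param n,m integer exponents, \code{n >= m >= 1}.
#' @return the score, with attribute \code{clipped}.
#' @examples
#' periodicityScore(0, sqrt(3))  # 0: perfectly periodic
#' periodicityScore(1, sqrt(3))  # 1/3: the regular-hexagon cloud
#' @export
periodicityScore <- function(b, d, n = 2L, m = 2L) {
  if (is.na(b) || is.na(d)) stop("b and d must be numbers")
  if (b < 0) stop("b must be nonnegative")
  if (b > d + 1e-12) stop("b must not exceed d (clamp first, see effectiveBD)")
  n <- as.integer(n); m <- as.integer(m)
  if (n < m || m < 1L) stop("exponents must satisfy n >= m >= 1")
  s <- 1 - (d^n - b^m) / 3^(n / 2)
  clipped <- s < 0 || s > 1
  structure(min(1, max(0, s)), clipped = clipped)
}

#' Score the periodicity of one time series
#'
#' The end-to-end pipeline: optional simple moving average, natural cubic
#' spline onto \code{[0, 2*pi]}, sliding-window embedding, pointwise
#' centering/normalization, optional mean-shift, Rips 1-persistence, and
#' the \code{(b, d)} score.  0 means periodic, 1 not periodic.  The score
#' is invariant to affine transforms \code{a*g + c} (a > 0) of the values.
#'
#' Missing values are imputed by a natural cubic spline through the
#' observed points (at least 4 observations required).  If more than half
#' of the windows are degenerate (zero variance) or fewer than 4 usable
#' points remain -- e.g. for a constant signal -- the pipeline
#' short-circuits to score 1.0 with a \code{"degenerate"} flag.
#'
#' @param times strictly increasing sampling times.
#' @param values signal values (may contain \code{NA}; imputed).
#' @param L expected number of periods covered by the record (>= 1); the
#'   method scans at this period length and does not estimate it.
#' @param M embedding dimension minus one; default
#'   [defaultEmbedDim()]\code{(length(times))}.
#' @param gridSize window start positions minus one (default 200).
#' @param smaK moving-average half-width (0 = off).
#' @param useMeanShift apply one mean-shift pass (default off).
#' @param nExp,mExp score exponents.
#' @param fieldChar prime field for homology.
#' @param maxScale filtration cutoff.
#' @param id signal identifier carried into the result.
#' @return a \linkS4class{PeriodicityResult}.
#' @examples
#' t <- sampleTimes(25)
#' res <- scoreSignal(t, generateShape("cos", t), L = 2)
#' scoreValue(res)   # close to 0: strongly periodic
#' @export
scoreSignal <- function(times, values, L, M = NULL, gridSize = 200L,
                        smaK = 0L, useMeanShift = FALSE, nExp = 2L,
                        mExp = 2L, fieldChar = 2L,
                        maxScale = sqrt(3) + 1e-6, id = "signal") {
  stopifnot(L >= 1)
  checkStrictlyIncreasing(times)
  if (length(values) != length(times))
    stop("times and values must have the same length")
  flags <- character(0)

  if (anyNA(values)) {
    obs <- !is.na(values)
    if (sum(obs) < 4L)
      stop("fewer than 4 observed values; cannot impute")
    imp <- splinefun(times[obs], values[obs], method = "natural")
    values[!obs] <- imp(times[!obs])
    flags <- c(flags, sprintf("imputed:%d", sum(!obs)))
  }

  if (is.null(M)) M <- defaultEmbedDim(length(times))
  M <- as.integer(M)
  w <- defaultWindow(M, L)
  params <- list(M = M, w = w, tau = w / M, L = L, gridSize = gridSize,
                 smaK = smaK, meanShift = useMeanShift,
                 fieldChar = as.integer(fieldChar), maxScale = maxScale)

  if (smaK > 0L)
    values <- movingAverage(values, smaK, times = times, w = w)

  g <- fitSpline(times, values)
  cloud <- slidingWindowCloud(g, M = M, w = w, gridSize = gridSize)
  norm <- centerNormalize(cloud)
  total <- nrow(cloud@points)
  if (norm@nDegenerate > 0L)
    flags <- c(flags, sprintf("degenerate_points:%d", norm@nDegenerate))
  if (norm@nDegenerate > total / 2 || nrow(norm@points) < 4L) {
    return(methods::new("PeriodicityResult", id = id, b = NA_real_,
                        d = NA_real_, score = 1.0, nExp = as.integer(nExp),
                        mExp = as.integer(mExp), params = params,
                        flags = unique(c(flags, "degenerate"))))
  }
  if (useMeanShift) norm <- meanShift(norm)

  dm <- pairwiseDistances(norm)
  b <- coverageRadius(dm)
  diagram <- ripsH1(dm, maxScale = maxScale, fieldChar = fieldChar)
  if (any(diagram@censored)) flags <- c(flags, "censored")
  bd <- effectiveBD(b, diagram)
  if (bd$clamped) flags <- c(flags, "d_clamped")
  s <- periodicityScore(bd$b, bd$d, n = nExp, m = mExp)
  if (attr(s, "clipped")) flags <- c(flags, "clipped")

  methods::new("PeriodicityResult", id = id, b = bd$b, d = bd$d,
               score = as.numeric(s), nExp = as.integer(nExp),
               mExp = as.integer(mExp), params = params, flags = flags)
}

#' Score every row of an expression table
#'
#' Applies [scoreSignal()] to each row of a genes-by-timepoints matrix (or
#' the first assay of a \code{SummarizedExperiment} whose \code{colData}
#' carries a \code{time} column).  Rows with fewer than 4 observed values
#' are skipped with \code{NA} score and a \code{"skipped"} flag.  Row order
#' does not influence any per-row result.
#'
#' @param x numeric matrix with rownames, or a \code{SummarizedExperiment}.
#' @param times sampling times (taken from \code{colData(x)$time} when
#'   \code{x} is a \code{SummarizedExperiment}).
#' @param L expected number of periods.
#' @param ... further options passed to [scoreSignal()].
#' @param verboseEvery log progress to stderr every this many rows
#'   (0 = silent).
#' @return \code{data.frame} with columns \code{id}, \code{score},
#'   \code{b}, \code{d}, \code{M}, \code{w}, \code{L}, \code{flags}; one
#'   row per input row, in input order.  Scores are reported to 6
#'   decimals; \code{rank} (1 = most periodic) uses average ties.
#' @export
scoreExperiment <- function(x, times = NULL, L, ..., verboseEvery = 0L) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (is.null(times)) {
      cd <- SummarizedExperiment::colData(x)
      if (!"time" %in% colnames(cd))
        stop("colData must contain a 'time' column")
      times <- as.numeric(cd$time)
    }
    x <- SummarizedExperiment::assay(x, 1L)
  }
  x <- as.matrix(x)
  if (is.null(times)) {
    times <- suppressWarnings(as.numeric(colnames(x)))
    if (anyNA(times))
      stop("provide times explicitly or as numeric column names")
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(x)))

  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    vals <- x[i, ]
    if (sum(!is.na(vals)) < 4L) {
      message(sprintf("row '%s': fewer than 4 observed values, skipped",
                      ids[i]))
      rows[[i]] <- data.frame(id = ids[i], score = NA_real_, b = NA_real_,
                              d = NA_real_, M = NA_integer_, w = NA_real_,
                              L = L, flags = "skipped",
                              stringsAsFactors = FALSE)
      next
    }
    res <- scoreSignal(times, vals, L = L, id = ids[i], ...)
    rows[[i]] <- data.frame(
      id = res@id, score = round(res@score, 6), b = res@b, d = res@d,
      M = res@params$M, w = res@params$w, L = L,
      flags = paste(res@flags, collapse = ";"), stringsAsFactors = FALSE)
    if (verboseEvery > 0L && i %% verboseEvery == 0L)
      message(sprintf("scored %d/%d signals", i, nrow(x)))
  }
  out <- do.call(rbind, rows)
  out$rank <- rank(out$score, ties.method = "average", na.last = "keep")
  rownames(out) <- NULL
  out
}
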
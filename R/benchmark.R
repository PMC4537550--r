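#' ROC curve for periodic / non-periodic classification
#'
#' Lower scores predict the periodic (positive) class.  All distinct score
#' cutoffs are swept; a signal is called periodic when its score is less
#' than or equal to the cutoff.  Tied scores advance the curve diagonally,
#' so the trapezoidal area equals the tie-corrected Mann-Whitney statistic
#' \code{P(score_pos < score_neg) + 0.5 P(score_pos = score_neg)}.
#'
#' @param scores numeric periodicity scores (0 = periodic).
#' @param labels logical, \code{TRUE} for the periodic class; both classes
#'   must be present.
#' @return a \linkS4class{RocResult}.
#' @examples
#' rocCurve(c(0.1, 0.4, 0.2, 0.9), c(TRUE, FALSE, TRUE, FALSE))  # AUC 1
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to form a ROC curve")
  o <- order(scores)
  thr <- scores[o]
  keep <- !duplicated(thr, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(labels[o])[keep]
  fp <- cumsum(!labels[o])[keep]
  thresholds <- c(-Inf, thr[keep])
  tpr <- c(0, tp / nPos)
  fpr <- c(0, fp / nNeg)
  a <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  methods::new("RocResult", thresholds = thresholds, fpr = fpr, tpr = tpr,
               auc = a)
}

#' Tie-corrected Mann-Whitney AUC
#'
#' Rank-based identity for the area under the ROC curve of [rocCurve()]:
#' the probability that a random periodic signal scores below a random
#' non-periodic one, counting ties half.
#'
#' @inheritParams rocCurve
#' @return numeric AUC in [0, 1].
#' @export
aucMannWhitney <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  # positives ranked low = periodic = correct
  (sum(r[!labels]) - nNeg * (nNeg + 1) / 2) / (nPos * nNeg)
}

#' Score a benchmark grid
#'
#' Scores every signal of every cell with the expected-period setting
#' \code{L} (default 2: the benchmark's records cover two true periods)
#' and stores the tidy per-signal score table in the grid.
#'
#' @param grid a \linkS4class{BenchmarkGrid} from [buildBenchmark()].
#' @param L expected periods used for every signal.
#' @param ... further options for [scoreSignal()].
#' @param verboseEvery log progress every this many signals (0 = silent).
#' @return the grid with its \code{scores} slot filled: columns
#'   \code{cell}, \code{id}, \code{shape}, \code{periodic},
#'   \code{noise_model}, \code{noise_level}, \code{n_samples},
#'   \code{score}.
#' @export
runGrid <- function(grid, L = 2, ..., verboseEvery = 0L) {
  stopifnot(methods::is(grid, "BenchmarkGrid"))
  if (length(grid@cells) == 0L) stop("empty benchmark grid")
  done <- 0L
  out <- lapply(names(grid@cells), function(nm) {
    se <- grid@cells[[nm]]
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    times <- as.numeric(SummarizedExperiment::colData(se)$time)
    mat <- SummarizedExperiment::assay(se)
    sc <- numeric(nrow(mat))
    for (i in seq_len(nrow(mat))) {
      sc[i] <- scoreValue(scoreSignal(times, mat[i, ], L = L, ...))
      done <<- done + 1L
      if (verboseEvery > 0L && done %% verboseEvery == 0L)
        message(sprintf("scored %d signals", done))
    }
    data.frame(cell = nm, id = rd$id, shape = rd$shape,
               periodic = rd$periodic, noise_model = rd$noise_model,
               noise_level = rd$noise_level, n_samples = rd$n_samples,
               score = sc, stringsAsFactors = FALSE)
  })
  grid@scores <- do.call(rbind, out)
  methods::validObject(grid)
  grid
}

#' Per-cell AUC summaries of a scored grid
#'
#' Pooled AUC per cell (all periodic shapes vs all non-periodic) and
#' per-shape AUCs (each periodic shape vs all non-periodic signals of the
#' same cell).
#'
#' @param grid a scored \linkS4class{BenchmarkGrid} (see [runGrid()]).
#' @return \code{data.frame} with columns \code{cell}, \code{shape}
#'   (\code{"pooled"} or a periodic shape name) and \code{auc}.
#' @export
gridAUC <- function(grid) {
  sc <- if (methods::is(grid, "BenchmarkGrid")) grid@scores else grid
  if (nrow(sc) == 0L) stop("grid has not been scored; run runGrid() first")
  res <- lapply(split(sc, sc$cell), function(cellDf) {
    pooled <- aucMannWhitney(cellDf$score, cellDf$periodic)
    neg <- cellDf[!cellDf$periodic, ]
    shapes <- unique(cellDf$shape[cellDf$periodic])
    perShape <- vapply(shapes, function(sh) {
      pos <- cellDf[cellDf$shape == sh, ]
      aucMannWhitney(c(pos$score, neg$score),
                     c(rep(TRUE, nrow(pos)), rep(FALSE, nrow(neg))))
    }, numeric(1))
    data.frame(cell = cellDf$cell[1L],
               shape = c("pooled", shapes),
               auc = c(pooled, perShape), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-shape score histograms on a log axis
#'
#' Bins \code{log(score + offset)} per shape per cell, mirroring the
#' score-distribution view used to inspect shape bias: the better (lower)
#' scores sit to the left.
#'
#' @param grid a scored \linkS4class{BenchmarkGrid}.
#' @param bins number of bins.
#' @param offset added before taking the log (scores can be 0).
#' @return \code{data.frame} with columns \code{cell}, \code{shape},
#'   \code{bin_lo}, \code{bin_hi} (log-score bin edges) and \code{count};
#'   counts per (cell, shape) sum to the number of that shape's signals.
#' @export
scoreHistograms <- function(grid, bins = 50L, offset = 1e-6) {
  sc <- if (methods::is(grid, "BenchmarkGrid")) grid@scores else grid
  if (nrow(sc) == 0L) stop("grid has not been scored; run runGrid() first")
  ls <- log(sc$score + offset)
  edges <- seq(min(ls), max(ls), length.out = bins + 1L)
  edges[length(edges)] <- edges[length(edges)] + 1e-9  # include the max
  res <- lapply(split(seq_len(nrow(sc)), paste(sc$cell, sc$shape, sep = "\r")),
    function(idx) {
      h <- findInterval(ls[idx], edges, rightmost.closed = TRUE)
      counts <- tabulate(h, nbins = bins)
      data.frame(cell = sc$cell[idx[1L]], shape = sc$shape[idx[1L]],
                 bin_lo = head(edges, -1L), bin_hi = tail(edges, -1L),
                 count = counts, stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write tidy per-signal scores and per-cell AUC summaries
#'
#' @param grid a scored \linkS4class{BenchmarkGrid}.
#' @param scoresPath,summaryPath output TSV paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
writeGridResults <- function(grid, scoresPath = NULL, summaryPath = NULL) {
  stopifnot(methods::is(grid, "BenchmarkGrid"))
  written <- character(0)
  if (!is.null(scoresPath)) {
    utils::write.table(grid@scores, scoresPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, scoresPath)
  }
  if (!is.null(summaryPath)) {
    utils::write.table(gridAUC(grid), summaryPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, summaryPath)
  }
  invisible(written)
}
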
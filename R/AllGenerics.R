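#' @rdname PointCloud-class
#' @param object,x a \linkS4class{PointCloud}
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname PointCloud-class
#' @export
setMethod("cloudPoints", "PointCloud", function(x) x@points)

#' @rdname PointCloud-class
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname PointCloud-class
#' @export
setMethod("isNormalized", "PointCloud", function(x) x@normalized)

#' @rdname PointCloud-class
#' @export
setGeneric("nDegenerate", function(x) standardGeneric("nDegenerate"))

#' @rdname PointCloud-class
#' @export
setMethod("nDegenerate", "PointCloud", function(x) x@nDegenerate)

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points in R^%d (%s%s)\n",
              nrow(object@points), ncol(object@points),
              if (object@normalized) "normalized" else "raw",
              if (object@nDegenerate > 0L)
                sprintf(", %d degenerate excluded", object@nDegenerate)
              else ""))
})

#' @rdname PersistenceDiagram-class
#' @param x a \linkS4class{PersistenceDiagram}
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))

#' @rdname PersistenceDiagram-class
#' @export
setMethod("intervals", "PersistenceDiagram", function(x) x@intervals)

#' @rdname PersistenceDiagram-class
#' @export
setGeneric("isCensored", function(x) standardGeneric("isCensored"))

#' @rdname PersistenceDiagram-class
#' @export
setMethod("isCensored", "PersistenceDiagram", function(x) x@censored)

#' @rdname PersistenceDiagram-class
#' @export
setGeneric("fieldChar", function(x) standardGeneric("fieldChar"))

#' @rdname PersistenceDiagram-class
#' @export
setMethod("fieldChar", "PersistenceDiagram", function(x) x@fieldChar)

setMethod("show", "PersistenceDiagram", function(object) {
  cat(sprintf("PersistenceDiagram (dim 1, Z/%d): %d interval(s)\n",
              object@fieldChar, nrow(object@intervals)))
  if (nrow(object@intervals) > 0L) {
    top <- order(object@intervals[, 2L] - object@intervals[, 1L],
                 decreasing = TRUE)
    show_n <- min(5L, length(top))
    for (i in top[seq_len(show_n)]) {
      cat(sprintf("  (%.4f, %.4f)%s\n", object@intervals[i, 1L],
                  object@intervals[i, 2L],
                  if (object@censored[i]) " [censored]" else ""))
    }
    if (length(top) > show_n) cat(sprintf("  ... %d more\n",
                                          length(top) - show_n))
  }
})

#' @rdname PeriodicityResult-class
#' @param x a \linkS4class{PeriodicityResult}
#' @export
setGeneric("periodicityFlags", function(x) standardGeneric("periodicityFlags"))

#' @rdname PeriodicityResult-class
#' @export
setMethod("periodicityFlags", "PeriodicityResult", function(x) x@flags)

#' @rdname PeriodicityResult-class
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))

#' @rdname PeriodicityResult-class
#' @export
setMethod("scoreValue", "PeriodicityResult", function(x) x@score)

#' @rdname PeriodicityResult-class
#' @export
setGeneric("coverageB", function(x) standardGeneric("coverageB"))

#' @rdname PeriodicityResult-class
#' @export
setMethod("coverageB", "PeriodicityResult", function(x) x@b)

#' @rdname PeriodicityResult-class
#' @export
setGeneric("deathD", function(x) standardGeneric("deathD"))

#' @rdname PeriodicityResult-class
#' @export
setMethod("deathD", "PeriodicityResult", function(x) x@d)

setMethod("show", "PeriodicityResult", function(object) {
  cat(sprintf("PeriodicityResult '%s': score = %.6f (0 = periodic)\n",
              object@id, object@score))
  cat(sprintf("  b = %s, d = %s, (n, m) = (%d, %d)\n",
              format(object@b, digits = 4), format(object@d, digits = 4),
              object@nExp, object@mExp))
  if (length(object@flags) > 0L)
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' @rdname RocResult-class
#' @param x a \linkS4class{RocResult}
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname RocResult-class
#' @export
setMethod("auc", "RocResult", function(x) x@auc)

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.4f (%d thresholds)\n", object@auc,
              length(object@thresholds)))
})

#' @rdname BenchmarkGrid-class
#' @param x a \linkS4class{BenchmarkGrid}
#' @export
setGeneric("gridCells", function(x) standardGeneric("gridCells"))

#' @rdname BenchmarkGrid-class
#' @export
setMethod("gridCells", "BenchmarkGrid", function(x) x@cells)

#' @rdname BenchmarkGrid-class
#' @export
setGeneric("gridConfig", function(x) standardGeneric("gridConfig"))

#' @rdname BenchmarkGrid-class
#' @export
setMethod("gridConfig", "BenchmarkGrid", function(x) x@config)

#' @rdname BenchmarkGrid-class
#' @export
setGeneric("gridScores", function(x) standardGeneric("gridScores"))

#' @rdname BenchmarkGrid-class
#' @export
setMethod("gridScores", "BenchmarkGrid", function(x) x@scores)

setMethod("show", "BenchmarkGrid", function(object) {
  cat(sprintf("BenchmarkGrid: %d cell(s)%s\n", length(object@cells),
              if (nrow(object@scores) > 0L)
                sprintf(", %d scored signals", nrow(object@scores))
              else " (unscored)"))
  for (nm in head(names(object@cells), 8L))
    cat("  ", nm, ": ", nrow(object@cells[[nm]]), " signals\n", sep = "")
  if (length(object@cells) > 8L)
    cat(sprintf("  ... %d more cells\n", length(object@cells) - 8L))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult '%s': mean p = %.6g (sd %.3g) over R = %d, N = %d\n",
    object@id, object@meanP, object@stdP, object@R, object@N))
})
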
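#' Euclidean distance matrix of a point cloud
#'
#' @param cloud a \linkS4class{PointCloud} or a numeric matrix of points
#'   (one per row).
#' @return symmetric numeric matrix with zero diagonal (symmetry enforced
#'   exactly).
#' @export
pairwiseDistances <- function(cloud) {
  pts <- if (methods::is(cloud, "PointCloud")) cloud@points else
    as.matrix(cloud)
  if (nrow(pts) < 1L) stop("need at least one point")
  dm <- as.matrix(stats::dist(pts))
  dm <- (dm + t(dm)) / 2
  diag(dm) <- 0
  dimnames(dm) <- NULL
  dm
}

#' Coverage radius of a finite metric space
#'
#' The maximum over points of the distance to its nearest (other) point:
#' how far one must inflate balls around the points before every point is
#' within reach of a neighbor.  This is the birth proxy \code{b} of the
#' periodicity score.
#'
#' @param dm symmetric distance matrix with at least 2 points.
#' @return nonnegative scalar.
#' @examples
#' hex <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
#' coverageRadius(pairwiseDistances(hex))  # hexagon side = 1
#' @export
coverageRadius <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("coverage radius needs at least 2 points")
  diag(dm) <- Inf
  max(apply(dm, 1L, min))
}

#' 1-dimensional persistent homology of the Vietoris-Rips filtration
#'
#' Computes the (birth, death) intervals of the 1-dimensional homology of
#' the Rips filtration restricted to simplices of dimension at most 2
#' (vertices at scale 0, edges at their length, triangles at their longest
#' edge), over the prime field \code{Z/fieldChar}, by boundary-matrix
#' column reduction (implemented via the dual coboundary reduction with
#' the clearing of tree-edge columns; see the package vignette).  The
#' simplex order is deterministic: filtration value, then dimension, then
#' lexicographic vertex tuple.  Zero-persistence pairs are dropped; cycles
#' alive beyond \code{maxScale} are reported censored at \code{maxScale}.
#'
#' The default cutoff \code{sqrt(3) + 1e-6} reflects the bound
#' \code{d <= sqrt(3)} for pointwise-normalized sliding-window clouds.
#'
#' @param dm symmetric nonnegative distance matrix.
#' @param maxScale filtration cutoff (> 0).
#' @param fieldChar prime coefficient field characteristic.
#' @return a \linkS4class{PersistenceDiagram}.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' ripsH1(pairwiseDistances(sq), maxScale = 2)  # one interval (1, sqrt(2))
#' @export
ripsH1 <- function(dm, maxScale = sqrt(3) + 1e-6, fieldChar = 2L) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("distance matrix must be square")
  if (any(dm < 0)) stop("distances must be nonnegative")
  if (max(abs(dm - t(dm))) > 1e-9) stop("distance matrix must be symmetric")
  if (maxScale <= 0) stop("maxScale must be positive")
  fieldChar <- as.integer(fieldChar)
  if (!isPrime(fieldChar)) stop("fieldChar must be prime")
  dm <- (dm + t(dm)) / 2

  res <- .rips_h1_cpp(dm, maxScale, fieldChar)
  iv <- cbind(birth = res$birth, death = res$death)
  cens <- res$censored
  # deterministic presentation order
  o <- order(iv[, 1L], iv[, 2L])
  methods::new("PersistenceDiagram", intervals = iv[o, , drop = FALSE],
               censored = cens[o], fieldChar = fieldChar,
               maxScale = maxScale)
}

#' Largest death in a persistence diagram
#'
#' Censored intervals count at their recorded (cutoff) death, the
#' conservative reading for scoring.
#'
#' @param diagram a \linkS4class{PersistenceDiagram}.
#' @return the maximal death, or \code{NA} for an empty diagram.
#' @export
maxDeath <- function(diagram) {
  stopifnot(methods::is(diagram, "PersistenceDiagram"))
  if (nrow(diagram@intervals) == 0L) return(NA_real_)
  max(diagram@intervals[, 2L])
}

#' Write a persistence diagram as two-column delimited text
#'
#' @param diagram a \linkS4class{PersistenceDiagram}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeDiagram <- function(diagram, path) {
  stopifnot(methods::is(diagram, "PersistenceDiagram"))
  df <- data.frame(birth = diagram@intervals[, 1L],
                   death = diagram@intervals[, 2L],
                   censored = diagram@censored)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
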
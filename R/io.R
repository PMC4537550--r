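#' Read a delimited expression time-series table
#'
#' Expects rows = probes/genes and columns = time points.  The header row
#' carries the sampling times as numbers (the first header field names the
#' id column and may be anything, including empty); times must be strictly
#' increasing but may be unevenly spaced.  The delimiter is auto-detected
#' (tab or comma) unless given.  Empty cells and \code{NA} become missing
#' values, to be imputed downstream by the spline stage.
#'
#' Time units are never rescaled on input; only the internal mapping onto
#' \code{[0, 2*pi]} inside the embedding touches them.
#'
#' @param path file to read.
#' @param delim field delimiter, or \code{NULL} to auto-detect.
#' @return a \code{SummarizedExperiment}: assay \code{"exprs"} (one row
#'   per probe), \code{colData} column \code{time}, rownames = ids.
#' @export
readExpressionTable <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
                 lengths(regmatches(header, gregexpr(",", header)))) "\t"
             else ","
  }
  fields <- strsplit(header, delim, fixed = TRUE)[[1L]]
  if (length(fields) < 3L)
    stop("need an id column and at least 2 time columns")
  times <- suppressWarnings(as.numeric(fields[-1L]))
  if (anyNA(times)) {
    bad <- which(is.na(times)) + 1L
    stop("non-numeric time header in column(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(fields[bad], collapse = ", "))
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L]
    stop(sprintf(
      "header times must be strictly increasing; columns %d and %d hold %g and %g",
      bad + 1L, bad + 2L, times[bad], times[bad + 1L]))
  }
  df <- utils::read.table(path, sep = delim, skip = 1L, header = FALSE,
                          colClasses = c("character",
                                         rep("numeric", length(times))),
                          na.strings = c("", "NA", "na", "NaN"),
                          quote = "", comment.char = "")
  ids <- df[[1L]]
  dup <- duplicated(ids)
  if (any(dup)) {
    stop("duplicate ids at line(s) ",
         paste(which(dup) + 1L, collapse = ", "), ": ",
         paste(unique(ids[dup]), collapse = ", "))
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(mat) <- list(ids, as.character(times))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(time = times))
}

#' Write an expression table as delimited text
#'
#' Inverse of [readExpressionTable()]: id column first, then one column
#' per time point with the numeric time as header.
#'
#' @param x \code{SummarizedExperiment} or numeric matrix with numeric
#'   column names.
#' @param path output file.
#' @param delim field delimiter.
#' @param times sampling times; defaults to the numeric column names (or
#'   \code{colData(x)$time} for a \code{SummarizedExperiment}).
#' @return invisibly, \code{path}.
#' @export
writeExpressionTable <- function(x, path, delim = "\t", times = NULL) {
  if (methods::is(x, "SummarizedExperiment")) {
    if (is.null(times))
      times <- as.numeric(SummarizedExperiment::colData(x)$time)
    mat <- SummarizedExperiment::assay(x, 1L)
  } else {
    mat <- as.matrix(x)
    if (is.null(times))
      times <- suppressWarnings(as.numeric(colnames(mat)))
  }
  if (length(times) != ncol(mat) || anyNA(times))
    stop("supply sampling times (or numeric column names)")
  header <- paste(c("id", format(times, digits = 15, trim = TRUE)),
                  collapse = delim)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- sprintf("row%d", seq_len(nrow(mat)))
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(ids[i], format(mat[i, ], digits = 15, trim = TRUE)),
          collapse = delim), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Drop the first k time points of a table
#'
#' Used to discard an initial stress response, e.g. keeping only the last
#' 13 of 15 cell-cycle samples.
#'
#' @param x \code{SummarizedExperiment}.
#' @param k number of leading time columns to drop; must leave at least
#'   2 columns.
#' @return the truncated object.
#' @export
dropLeadingSamples <- function(x, k) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  k <- as.integer(k)
  if (k < 0L) stop("k must be nonnegative")
  if (k >= ncol(x) - 1L)
    stop(sprintf("cannot drop %d of %d columns; at least 2 must remain",
                 k, ncol(x)))
  if (k == 0L) return(x)
  x[, -seq_len(k)]
}

#' Write a JSON sidecar describing a run
#'
#' Every output of the command-line tools is accompanied by a sidecar
#' holding the full configuration, master seed, and package version, so
#' the output can be regenerated bit-identically.
#'
#' @param config named list.
#' @param path output path (conventionally \code{<output>.json}).
#' @return invisibly, \code{path}.
#' @export
writeSidecar <- function(config, path) {
  config$package_version <-
    as.character(utils::packageVersion("ringscore"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
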
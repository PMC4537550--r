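#' Permutation p-value for a periodicity score
#'
#' Shuffles the signal values uniformly (Fisher-Yates) \code{N} times,
#' keeping the time stamps fixed, rescoring each permuted signal, and
#' reports the proportion of permutations whose score is better than or
#' equal to (i.e. less than or equal to, 0 = periodic) the original's.
#' This is the plain proportion without small-sample correction, so
#' \code{p = 0} is attainable; the conventional \code{(count + 1)/(N + 1)}
#' estimate is returned alongside.
#'
#' Permutation \code{i} draws its RNG stream from a child seed indexed by
#' \code{i}, so results are reproducible also under parallel evaluation.
#'
#' @param times,values the signal; see [scoreSignal()].
#' @param L expected periods.
#' @param N number of permutations (>= 1).
#' @param seed integer seed for the permutation streams.
#' @param ... further options for [scoreSignal()].
#' @return list with \code{p}, \code{pCorrected}, \code{originalScore} and
#'   the vector \code{permScores}.
#' @export
permutationPValue <- function(times, values, L, N, seed, ...) {
  stopifnot(N >= 1)
  orig <- scoreValue(scoreSignal(times, values, L = L, ...))
  seeds <- childSeeds(seed, N)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restoreRNG(old))
  permScores <- vapply(seq_len(N), function(i) {
    set.seed(seeds[i])
    perm <- sample(values)
    scoreValue(scoreSignal(times, perm, L = L, ...))
  }, numeric(1))
  hits <- sum(permScores <= orig)
  list(p = hits / N, pCorrected = (hits + 1) / (N + 1),
       originalScore = orig, permScores = permScores)
}

#' Repeated permutation testing
#'
#' Runs [permutationPValue()] \code{R} times with disjoint seeded streams
#' (repetition \code{r} derives its seed from the master seed and \code{r})
#' and reports the per-repetition p-values with their mean and standard
#' deviation.  With \code{R = 1} the standard deviation is 0 by convention.
#'
#' @param times,values the signal.
#' @param L expected periods.
#' @param N permutations per repetition.
#' @param R repetitions (default 5).
#' @param seed master seed.
#' @param id signal identifier.
#' @param ... further options for [scoreSignal()].
#' @return a \linkS4class{PermutationResult}.
#' @export
repeatedPermutation <- function(times, values, L, N, R = 5L, seed,
                                id = "signal", ...) {
  stopifnot(R >= 1)
  repSeeds <- childSeeds(seed, R)
  runs <- lapply(seq_len(R), function(r)
    permutationPValue(times, values, L = L, N = N, seed = repSeeds[r], ...))
  pv <- vapply(runs, `[[`, numeric(1), "p")
  pc <- vapply(runs, `[[`, numeric(1), "pCorrected")
  methods::new("PermutationResult", id = id,
               originalScore = runs[[1L]]$originalScore,
               N = as.integer(N), R = as.integer(R), pValues = pv,
               pCorrected = pc, meanP = mean(pv),
               stdP = if (R == 1L) 0 else sd(pv),
               seed = as.integer(seed))
}

#' Serialize permutation results as TSV
#'
#' Columns: id, original_score, N, R, p_1..p_R, mean_p, std_p.
#'
#' @param results a list of \linkS4class{PermutationResult} objects (or a
#'   single one).
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePermutationResults <- function(results, path) {
  if (methods::is(results, "PermutationResult")) results <- list(results)
  R <- max(vapply(results, function(x) x@R, integer(1)))
  rows <- lapply(results, function(x) {
    p <- c(x@pValues, rep(NA_real_, R - x@R))
    df <- data.frame(id = x@id, original_score = round(x@originalScore, 6),
                     N = x@N, R = x@R, stringsAsFactors = FALSE)
    for (r in seq_len(R)) df[[paste0("p_", r)]] <- p[r]
    df$mean_p <- x@meanP
    df$std_p <- x@stdP
    df
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
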
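# internal helpers: seeding, Laplace sampling, small checks

# One master seed expands to per-task child seeds by counter, so datasets
# and permutation streams are reproducible even if tasks were farmed out.
childSeeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 0L)
  if (n == 0L) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restoreRNG(old))
  set.seed(as.integer(master %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n, replace = n > 2e9)
}

restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# zero-mean Laplace draws with spread b (variance 2 b^2), as the difference
# of two unit exponentials scaled by b
rlaplace <- function(n, b) {
  b * (rexp(n) - rexp(n))
}

isPrime <- function(p) {
  p <- as.integer(p)
  if (p < 2L) return(FALSE)
  if (p < 4L) return(TRUE)
  if (p %% 2L == 0L) return(FALSE)
  k <- 3L
  while (as.double(k) * k <= p) {
    if (p %% k == 0L) return(FALSE)
    k <- k + 2L
  }
  TRUE
}

checkStrictlyIncreasing <- function(times, what = "times") {
  if (anyNA(times)) stop(what, " must not contain missing values")
  d <- diff(times)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1L]
    stop(sprintf("%s must be strictly increasing (positions %d and %d: %g, %g)",
                 what, bad, bad + 1L, times[bad], times[bad + 1L]))
  }
  invisible(TRUE)
}
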
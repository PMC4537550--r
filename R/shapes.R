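#' Synthetic signal shapes
#'
#' The synthetic benchmark uses 14 signal shapes: 10 periodic (cosine,
#' two-harmonic cosine, one and two peaks per period, linearly and
#' exponentially trending cosines, damped cosine, sawtooth, square wave,
#' contracting cosine) and 4 non-periodic (flat, line, exponential decay,
#' sigmoid).  All are parameterized by a period (default 100 time units), a
#' peak-to-trough amplitude (default 100 expression units, i.e. semi-
#' amplitude A = 50 around baseline 0, so the additive noise SD grid
#' 0..50 spans 0--100\% of the semi-amplitude), and a phase offset.
#'
#' Closed forms, with \code{theta = 2*pi*(t - phase)/period} and
#' \code{A = amplitude/2}:
#' \describe{
#'   \item{cos}{\code{A*cos(theta)} (crest at the origin for phase 0).}
#'   \item{cos2}{\code{cos(theta) + 0.5*cos(2*theta)}, midrange-centered
#'     and rescaled to the target peak-to-trough; two unequal extrema per
#'     period.}
#'   \item{peak}{periodic von-Mises-style bump
#'     \code{exp(kappa*(cos(theta) - 1))}, \code{kappa = 5}, rescaled.}
#'   \item{peak2}{two bumps per period with height ratio 1 : 0.6,
#'     rescaled.}
#'   \item{trend_lin}{cosine plus a linear drift \code{A*t/span}.}
#'   \item{trend_exp}{cosine plus \code{A*(3^(t/span) - 1)/2}, an
#'     exponential drift reaching \code{A} at the end of the record.}
#'   \item{damp}{\code{exp(-lambda*t)*A*cos(theta)} with
#'     \code{lambda = log(2)/period}: the amplitude halves every period.}
#'   \item{saw}{rising sawtooth, peak-to-trough \code{amplitude},
#'     zero-mean.}
#'   \item{square}{50\% duty cycle: \code{+A} on the first half-period,
#'     \code{-A} on the second.}
#'   \item{contract}{cosine of an accumulated phase whose instantaneous
#'     period shrinks linearly from \code{period} to
#'     \code{contractFactor*period} (default 0.7) over the span.}
#'   \item{flat}{constant baseline 0.}
#'   \item{line}{linear ramp covering the peak-to-trough range over the
#'     span, zero-centered.}
#'   \item{exp_decay}{\code{A*exp(-t/(span/3))}.}
#'   \item{sigmoid}{logistic centered at \code{span/2} with steepness
#'     \code{10/span}, zero-centered, range \code{amplitude}.}
#' }
#'
#' @param name one of [shapeNames()].
#' @param times numeric vector of sampling times (default within
#'   \code{[0, span]}).
#' @param period period length in time units.
#' @param amplitude peak-to-trough amplitude in expression units.
#' @param phase time offset in \code{[0, period)}; ignored by the
#'   non-periodic shapes.
#' @param span record length in time units; enters the trend, decay and
#'   contraction constants.
#' @param shapeParams optional list overriding per-shape constants:
#'   \code{kappa} (peak sharpness, 5), \code{peak2Ratio} (0.6),
#'   \code{dampRate} (\code{log(2)/period}), \code{trendSlope}
#'   (\code{amplitude/2/span}), \code{contractFactor} (0.7),
#'   \code{decayTau} (\code{span/3}), \code{sigmoidSteepness}
#'   (\code{10/span}).
#'
#' @return numeric vector of noiseless signal values, one per time.
#' @examples
#' t <- sampleTimes(25)
#' generateShape("cos", t)[1]   # crest: +50
#' generateShape("flat", t)     # constant baseline
#' @export
generateShape <- function(name, times, period = 100, amplitude = 100,
                          phase = 0, span = 200, shapeParams = list()) {
  name <- match.arg(name, shapeNames())
  stopifnot(period > 0, amplitude >= 0, length(times) >= 1L)
  if (phase < 0 || phase >= period)
    stop("phase must lie in [0, period)")
  A <- amplitude / 2
  sp <- shapeParams
  kappa <- sp$kappa %||% 5
  ratio <- sp$peak2Ratio %||% 0.6
  lambda <- sp$dampRate %||% (log(2) / period)
  slope <- sp$trendSlope %||% (A / span)
  cf <- sp$contractFactor %||% 0.7
  tau <- sp$decayTau %||% (span / 3)
  steep <- sp$sigmoidSteepness %||% (10 / span)

  theta <- 2 * pi * (times - phase) / period
  frac <- ((times - phase) / period) %% 1

  # rescale a raw periodic waveform to peak-to-trough = amplitude, midrange 0
  rescale <- function(raw, lo, hi) (raw - (hi + lo) / 2) / (hi - lo) * amplitude

  switch(name,
    cos = A * cos(theta),
    cos2 = {
      # extrema of cos(x) + 0.5 cos(2x): max 1.5 at 0, min -0.75 at
      # acos(-1/2)
      raw <- cos(theta) + 0.5 * cos(2 * theta)
      rescale(raw, -0.75, 1.5)
    },
    peak = {
      raw <- exp(kappa * (cos(theta) - 1))
      rescale(raw, exp(-2 * kappa), 1)
    },
    peak2 = {
      raw <- exp(kappa * (cos(theta) - 1)) +
        ratio * exp(kappa * (cos(theta - pi) - 1))
      # valley between the bumps at cos(theta) = log(ratio)/(2 kappa)
      cstar <- log(ratio) / (2 * kappa)
      lo <- exp(kappa * (cstar - 1)) + ratio * exp(-kappa * (cstar + 1))
      hi <- 1 + ratio * exp(-2 * kappa)
      rescale(raw, lo, hi)
    },
    trend_lin = A * cos(theta) + slope * times,
    trend_exp = A * cos(theta) + A * (3^(times / span) - 1) / 2,
    damp = exp(-lambda * times) * A * cos(theta),
    saw = amplitude * frac - A,
    square = ifelse(frac < 0.5, A, -A),
    contract = {
      # instantaneous period P(t) = period * (1 - (1 - cf) t / span);
      # accumulated phase = integral of 2 pi / P
      u <- pmin(times / span, 1 - 1e-9)
      acc <- -2 * pi * span / (period * (1 - cf)) * log(1 - (1 - cf) * u)
      A * cos(acc - 2 * pi * phase / period)
    },
    flat = rep(0, length(times)),
    line = amplitude * (times / span) - A,
    exp_decay = A * exp(-times / tau),
    sigmoid = amplitude / (1 + exp(-steep * (times - span / 2))) - A
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Admissible shape names and their periodicity labels
#'
#' @return \code{shapeNames()}: character vector of the 14 shape names.
#'   \code{periodicShapes()} / \code{nonPeriodicShapes()}: the 10 periodic
#'   and 4 non-periodic subsets.
#' @export
shapeNames <- function() c(periodicShapes(), nonPeriodicShapes())

#' @rdname shapeNames
#' @export
periodicShapes <- function() {
  c("cos", "cos2", "peak", "peak2", "trend_lin", "trend_exp", "damp",
    "saw", "square", "contract")
}

#' @rdname shapeNames
#' @export
nonPeriodicShapes <- function() c("flat", "line", "exp_decay", "sigmoid")

#' Apply a noise model to a signal
#'
#' Four zero-mean noise models: Gaussian or Laplace, additive
#' (\code{value + eta}) or multiplicative (\code{value * (1 + eta)}).  The
#' level is the standard deviation for the Gaussian models and the spread
#' \code{b} for the Laplace models; paired levels are variance-matched via
#' \code{SD = sqrt(2) * b}.  Level 0 returns the input unchanged.
#'
#' @param values numeric signal values.
#' @param model one of \code{"gaussian_additive"}, \code{"laplace_additive"},
#'   \code{"gaussian_multiplicative"}, \code{"laplace_multiplicative"}.
#' @param level nonnegative noise level (SD or spread).
#' @return numeric vector with noise applied, drawn from the current RNG
#'   stream.
#' @examples
#' set.seed(1)
#' applyNoise(rep(0, 5), "gaussian_additive", 12)
#' @export
applyNoise <- function(values,
                       model = c("gaussian_additive", "laplace_additive",
                                 "gaussian_multiplicative",
                                 "laplace_multiplicative"),
                       level) {
  model <- match.arg(model)
  if (length(level) != 1L || is.na(level) || level < 0)
    stop("noise level must be a single nonnegative number")
  if (level == 0) return(values)
  n <- length(values)
  eta <- switch(model,
    gaussian_additive = ,
    gaussian_multiplicative = rnorm(n, sd = level),
    laplace_additive = ,
    laplace_multiplicative = rlaplace(n, level))
  if (model %in% c("gaussian_additive", "laplace_additive"))
    values + eta
  else
    values * (1 + eta)
}

#' Variance-matched Laplace spread for a Gaussian SD
#'
#' A Laplace distribution with spread \code{b} has variance \code{2 b^2};
#' matching a Gaussian with standard deviation \code{SD} gives
#' \code{b = SD / sqrt(2)}, reported rounded to two decimals (the printed
#' grid for SD = 12, 25, 37, 50 is 8.49, 17.68, 26.16, 35.36).
#'
#' @param sd nonnegative Gaussian standard deviation(s).
#' @return the matched spread(s), rounded to 2 decimals.
#' @examples
#' matchLaplaceSpread(c(12, 25, 37, 50))
#' @export
matchLaplaceSpread <- function(sd) {
  if (any(is.na(sd)) || any(sd < 0)) stop("sd must be nonnegative")
  round(sd / sqrt(2), 2)
}

#' Evenly spaced sampling times over a record
#'
#' \code{n} evenly spaced times including both endpoints 0 and \code{span};
#' the benchmark uses n = 50, 25, 17 over a 200-unit record (two
#' 100-unit periods), giving spacings 200/49, 25/3 and 12.5.
#'
#' @param n number of samples (>= 2).
#' @param span record length in time units.
#' @return numeric vector of length \code{n}.
#' @examples
#' diff(sampleTimes(17))[1]  # 12.5
#' @export
sampleTimes <- function(n, span = 200) {
  if (length(n) != 1L || is.na(n) || n < 2)
    stop("n must be at least 2")
  seq(0, span, length.out = as.integer(n))
}

#' The benchmark's default noise grids
#'
#' Five levels per model; the Laplace grids are the variance-matched,
#' 2-decimal-rounded counterparts of the Gaussian grids.
#'
#' @return named list of numeric level vectors, one per noise model.
#' @export
defaultNoiseGrids <- function() {
  list(
    gaussian_additive = c(0, 12, 25, 37, 50),
    laplace_additive = c(0, matchLaplaceSpread(c(12, 25, 37, 50))),
    gaussian_multiplicative = c(0, 0.12, 0.25, 0.37, 0.5),
    laplace_multiplicative = c(0, matchLaplaceSpread(c(0.12, 0.25, 0.37, 0.5)))
  )
}

#' Generate the labeled synthetic benchmark
#'
#' For every cell (noise model, level, sampling density) and every shape,
#' draws \code{perShape} signals with phases uniform on \code{[0, period)}
#' and the requested noise applied.  One master seed expands to per-signal
#' child seeds by counter, so the dataset is bit-identical across runs and
#' under parallel generation.
#'
#' @param shapes character vector of shape names.
#' @param noise data.frame with columns \code{model} and \code{level}, one
#'   row per noise condition; default: no noise.
#' @param samplings integer vector of samples-per-record.
#' @param perShape signals per shape per cell.
#' @param seed master seed (required).
#' @param period,amplitude,span signal geometry, see [generateShape()].
#' @return a \linkS4class{BenchmarkGrid} whose cells are
#'   \code{SummarizedExperiment}s: assay \code{"exprs"} (signals x times),
#'   \code{rowData} columns \code{id}, \code{shape}, \code{periodic},
#'   \code{noise_model}, \code{noise_level}, \code{n_samples},
#'   \code{phase}; \code{colData} column \code{time}.
#' @examples
#' bg <- buildBenchmark(perShape = 2, samplings = 17, seed = 7)
#' bg
#' @export
buildBenchmark <- function(shapes = shapeNames(),
                           noise = data.frame(model = "gaussian_additive",
                                              level = 0),
                           samplings = 25, perShape = 1000, seed,
                           period = 100, amplitude = 100, span = 200) {
  if (missing(seed)) stop("a master seed is required for reproducibility")
  if (length(shapes) == 0L || nrow(noise) == 0L || length(samplings) == 0L)
    stop("shapes, noise grid and samplings must be non-empty")
  shapes <- vapply(shapes, function(s) match.arg(s, shapeNames()),
                   character(1))
  nCells <- nrow(noise) * length(samplings)
  nSignals <- nCells * length(shapes) * perShape
  seeds <- childSeeds(seed, nSignals)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restoreRNG(old))

  cells <- list()
  counter <- 0L
  for (ns in samplings) {
    times <- sampleTimes(ns, span)
    for (ci in seq_len(nrow(noise))) {
      model <- as.character(noise$model[ci])
      level <- noise$level[ci]
      mat <- matrix(NA_real_, nrow = length(shapes) * perShape,
                    ncol = length(times))
      meta <- vector("list", length(shapes) * perShape)
      row <- 0L
      for (sh in shapes) {
        for (i in seq_len(perShape)) {
          counter <- counter + 1L
          row <- row + 1L
          set.seed(seeds[counter])
          phase <- runif(1, 0, period)
          vals <- generateShape(sh, times, period = period,
                                amplitude = amplitude, phase = phase,
                                span = span)
          mat[row, ] <- applyNoise(vals, model, level)
          meta[[row]] <- data.frame(
            id = sprintf("%s_%03d", sh, i), shape = sh,
            periodic = sh %in% periodicShapes(),
            noise_model = model, noise_level = level,
            n_samples = as.integer(ns), phase = phase,
            stringsAsFactors = FALSE)
        }
      }
      rd <- do.call(rbind, meta)
      rownames(mat) <- rd$id
      colnames(mat) <- as.character(times)
      se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = mat),
        rowData = S4Vectors::DataFrame(rd),
        colData = S4Vectors::DataFrame(time = times))
      cells[[sprintf("%s_%g_n%d", model, level, ns)]] <- se
    }
  }
  methods::new("BenchmarkGrid", cells = cells,
               config = list(shapes = shapes, noise = noise,
                             samplings = samplings, perShape = perShape,
                             seed = seed, period = period,
                             amplitude = amplitude, span = span))
}

#' Write a benchmark grid as delimited text plus a JSON sidecar
#'
#' One TSV per cell (columns: \code{id}, \code{shape}, \code{label},
#' \code{noise_model}, \code{noise_level}, then one column per time point
#' with a numeric-time header) and one \code{config.json} holding the
#' generation configuration and seed.
#'
#' @param grid a \linkS4class{BenchmarkGrid}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeBenchmark <- function(grid, dir) {
  stopifnot(methods::is(grid, "BenchmarkGrid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(grid@cells)) {
    se <- grid@cells[[nm]]
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    mat <- SummarizedExperiment::assay(se)
    out <- data.frame(id = rd$id, shape = rd$shape,
                      label = ifelse(rd$periodic, "periodic", "non-periodic"),
                      noise_model = rd$noise_model,
                      noise_level = rd$noise_level,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(mat))
    path <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  cfg <- file.path(dir, "config.json")
  jsonlite::write_json(grid@config, cfg, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, cfg))
}
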
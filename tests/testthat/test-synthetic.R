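test_that("shape catalog has 10 periodic and 4 non-periodic shapes", {
  expect_length(shapeNames(), 14L)
  expect_length(periodicShapes(), 10L)
  expect_length(nonPeriodicShapes(), 4L)
  expect_error(generateShape("wiggle", 0:10), "cos")
})

test_that("closed forms hit their documented anchor values", {
  # crest at the origin, zero-mean convention: A cos(2 pi t / T), A = 50
  expect_equal(generateShape("cos", 0), 50)
  expect_equal(generateShape("cos", 50), -50)
  # flat is a constant baseline
  expect_equal(generateShape("flat", c(0, 13, 77)), rep(0, 3))
  # square, 50% duty cycle: high on the first half-period
  expect_equal(generateShape("square", 25), 50)
  expect_equal(generateShape("square", 75), -50)
  # sawtooth rises from -A to +A across one period
  expect_equal(generateShape("saw", 0), -50)
  expect_lt(generateShape("saw", 99.9), 50 + 1e-9)
  # damped cosine halves its amplitude each period
  expect_equal(generateShape("damp", 100), 25)
})

test_that("periodic shapes repeat over one period (up to their modulation)", {
  t <- seq(0, 100, by = 0.5)  # first period; repeat at t + 100
  for (sh in c("cos", "cos2", "peak", "peak2", "saw", "square")) {
    v1 <- generateShape(sh, t, phase = 17)
    v2 <- generateShape(sh, t + 100, phase = 17)
    expect_equal(v1, v2, tolerance = 1e-12, label = sh)
  }
  # damping modulates by exactly exp(-log(2)) = 1/2 per period
  d1 <- generateShape("damp", t)
  d2 <- generateShape("damp", t + 100)
  expect_equal(d2, d1 / 2, tolerance = 1e-12)
  # linear trend shifts by slope * period
  l1 <- generateShape("trend_lin", t)
  l2 <- generateShape("trend_lin", t + 100)
  expect_equal(l2 - l1, rep(0.25 * 100, length(t)), tolerance = 1e-12)
})

test_that("peak-to-trough amplitude is respected", {
  t <- seq(0, 200, length.out = 4001)
  for (sh in c("cos", "cos2", "peak", "peak2", "saw", "square")) {
    v <- generateShape(sh, t)
    expect_equal(diff(range(v)), 100, tolerance = 1e-3, label = sh)
  }
})

test_that("phase must lie in [0, period) and shifts the waveform", {
  expect_error(generateShape("cos", 0:10, phase = 100), "phase")
  expect_error(generateShape("cos", 0:10, phase = -1), "phase")
  expect_equal(generateShape("cos", 25, phase = 25), 50)
})

test_that("noise models are zero-mean with the advertised variance", {
  set.seed(101)
  n <- 1e6
  eta <- applyNoise(rep(0, n), "gaussian_additive", 12)
  expect_equal(var(eta), 144, tolerance = 0.01)
  etaL <- applyNoise(rep(0, n), "laplace_additive", 8.49)
  expect_equal(var(etaL), 2 * 8.49^2, tolerance = 0.01)
  # variance matching: the Laplace grid reproduces the Gaussian variances
  expect_equal(2 * matchLaplaceSpread(12)^2, 144, tolerance = 0.002)
  # multiplicative: value * (1 + eta)
  set.seed(102)
  vm <- applyNoise(rep(10, n), "gaussian_multiplicative", 0.25)
  expect_equal(mean(vm), 10, tolerance = 0.01)
  expect_equal(var(vm), 100 * 0.25^2, tolerance = 0.05)
})

test_that("zero noise level returns the input unchanged", {
  v <- generateShape("cos", sampleTimes(17))
  for (m in names(defaultNoiseGrids()))
    expect_identical(applyNoise(v, m, 0), v)
  expect_error(applyNoise(v, "gaussian_additive", -1), "nonnegative")
})

test_that("Laplace spreads match the printed grids", {
  expect_equal(matchLaplaceSpread(c(12, 25, 37, 50)),
               c(8.49, 17.68, 26.16, 35.36))
  expect_equal(matchLaplaceSpread(c(0.12, 0.25, 0.37, 0.5)),
               c(0.08, 0.18, 0.26, 0.35))
  expect_equal(matchLaplaceSpread(0), 0)
  expect_error(matchLaplaceSpread(-3), "nonnegative")
})

test_that("sampling grids are inclusive of both endpoints", {
  expect_equal(sampleTimes(2), c(0, 200))
  expect_equal(diff(sampleTimes(17))[1], 12.5)
  expect_equal(diff(sampleTimes(25))[1], 25 / 3)
  expect_equal(diff(sampleTimes(50))[1], 200 / 49)
  expect_error(sampleTimes(1), "at least 2")
})

test_that("benchmark generation is reproducible and fully labeled", {
  g1 <- buildBenchmark(perShape = 2, samplings = 17, seed = 99)
  g2 <- buildBenchmark(perShape = 2, samplings = 17, seed = 99)
  expect_identical(
    SummarizedExperiment::assay(gridCells(g1)[[1]]),
    SummarizedExperiment::assay(gridCells(g2)[[1]]))
  se <- gridCells(g1)[[1]]
  expect_equal(nrow(se), 28L)  # 14 shapes x 2
  rd <- SummarizedExperiment::rowData(se)
  expect_equal(sum(tapply(rd$periodic, rd$shape, all)), 10L)
  expect_error(buildBenchmark(shapes = character(0), seed = 1), "non-empty")
  expect_error(buildBenchmark(perShape = 1), "seed")
})

test_that("phases are drawn uniformly over [0, period)", {
  g <- buildBenchmark(shapes = "cos", perShape = 1000, samplings = 17,
                      seed = 4242)
  ph <- SummarizedExperiment::rowData(gridCells(g)[[1]])$phase
  expect_true(all(ph >= 0 & ph < 100))
  ks <- suppressWarnings(ks.test(ph, "punif", 0, 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("benchmark grids round-trip through the TSV writer", {
  g <- buildBenchmark(perShape = 1, samplings = 17, seed = 5,
                      noise = data.frame(model = "laplace_additive",
                                         level = 8.49))
  dir <- withr::local_tempdir()
  paths <- writeBenchmark(g, dir)
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[1], check.names = FALSE)
  expect_equal(nrow(tab), 14L)
  expect_equal(sum(tab$label == "periodic"), 10L)
  mat <- as.matrix(tab[, -(1:5)])
  orig <- SummarizedExperiment::assay(gridCells(g)[[1]])
  expect_equal(unname(mat), unname(orig), tolerance = 1e-12)
})
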
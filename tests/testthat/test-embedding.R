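test_that("spline maps the record onto [0, 2*pi] and interpolates knots", {
  times <- c(0, 16, 32, 48, 64)
  values <- c(1, 4, 9, 2, -3)
  g <- fitSpline(times, values)
  expect_equal(g(0), 1)
  expect_equal(g(2 * pi), -3)
  theta <- (times - times[1]) / diff(range(times)) * 2 * pi
  expect_equal(g(theta), values, tolerance = 1e-9)
  # uneven spacing is allowed
  gu <- fitSpline(c(0, 3, 40, 41, 100), values)
  expect_equal(gu(2 * pi), -3)
  # constant series stays constant everywhere
  gc <- fitSpline(times, rep(7, 5))
  expect_equal(gc(seq(0, 2 * pi, length.out = 11)), rep(7, 11))
})

test_that("spline rejects unusable input", {
  expect_error(fitSpline(c(0, 0, 1), 1:3), "strictly increasing")
  expect_error(fitSpline(c(0, 2, 1), 1:3), "strictly increasing")
  expect_error(fitSpline(c(0, 1, 2), c(1, NA, 3)), "imputed")
  expect_error(fitSpline(1:3, 1:2), "same length")
})

test_that("window-size rule follows 2*pi*M / (L*(M+1))", {
  expect_equal(defaultWindow(1, 1), pi)
  expect_equal(defaultWindow(47, 2), 2 * pi * 47 / 96)
  # approaches pi from below as M grows at L = 2
  expect_lt(defaultWindow(1e6, 2), pi)
  expect_gt(defaultWindow(1e6, 2), pi - 1e-5)
})

test_that("default embedding dimension is odd, above 2n, floored at 23", {
  expect_equal(defaultEmbedDim(25), 51L)
  expect_equal(defaultEmbedDim(17), 35L)
  expect_equal(defaultEmbedDim(5), 23L)
  expect_true(all(sapply(c(5, 13, 17, 25, 50),
                         function(n) defaultEmbedDim(n) %% 2 == 1)))
})

test_that("sliding-window cloud covers the grid and ends at 2*pi", {
  g <- function(t) cos(2 * t)
  w <- defaultWindow(23, 2)
  cloud <- slidingWindowCloud(g, M = 23, w = w)
  pts <- cloudPoints(cloud)
  expect_equal(dim(pts), c(201L, 24L))
  # first window starts at 0, last ends exactly at 2*pi
  expect_equal(pts[1, 1], g(0))
  expect_equal(pts[201, 24], g(2 * pi))
  # constant signal gives identical points
  cc <- slidingWindowCloud(function(t) rep(5, length(t)), M = 5, w = 1)
  expect_true(all(cloudPoints(cc) == 5))
  expect_error(slidingWindowCloud(g, M = 23, w = 7), "between 0 and 2")
})

test_that("cosine cloud is planar after centering (two dominant svals)", {
  # cos(L t) embeds as cos(Lt) u - sin(Lt) v for fixed u, v: an exactly
  # planar curve.  The sweep of the phase angle L (2 pi - w) exceeds a
  # full turn for L >= 2 (circle); at L = 1 it is only 2 pi/(M+1) (arc),
  # so the two-dominant-direction check applies from L = 2 up.
  for (L in c(1, 2, 3)) {
    M <- 47
    w <- defaultWindow(M, L)
    cloud <- slidingWindowCloud(function(t) cos(L * t), M = M, w = w)
    centered <- centerNormalize(cloud)
    sv <- svd(cloudPoints(centered))$d
    expect_lte(sv[3] / sv[1], 1e-6)
    if (L >= 2) expect_gt(sv[2] / sv[1], 0.5)
  }
})

test_that("centering/normalization is exact and affine-invariant", {
  set.seed(7)
  pts <- matrix(rnorm(50 * 10), 50)
  cloud <- methods::new("PointCloud", points = pts, normalized = FALSE,
                        nDegenerate = 0L)
  norm <- centerNormalize(cloud)
  np <- cloudPoints(norm)
  expect_equal(sqrt(rowSums(np^2)), rep(1, 50), tolerance = 1e-12)
  expect_equal(rowMeans(np), rep(0, 50), tolerance = 1e-12)
  # a*x + c*(1,...,1) normalizes to the same point for a > 0
  cloud2 <- methods::new("PointCloud", points = 3.7 * pts + 11,
                         normalized = FALSE, nDegenerate = 0L)
  expect_equal(cloudPoints(centerNormalize(cloud2)), np, tolerance = 1e-9)
})

test_that("zero-variance windows are excluded and counted", {
  pts <- rbind(c(1, 2, 3), c(4, 4, 4), c(0, 1, 0))
  cloud <- methods::new("PointCloud", points = pts, normalized = FALSE,
                        nDegenerate = 0L)
  norm <- centerNormalize(cloud)
  expect_equal(nrow(cloudPoints(norm)), 2L)
  expect_equal(nDegenerate(norm), 1L)
})

test_that("moving average follows the truncated-window formula", {
  expect_equal(movingAverage(c(0, 3, 6), k = 1), c(0, 3, 6))
  v <- c(1, 2, 6, 4, 10)
  expect_equal(movingAverage(v, k = 1),
               c(1, 3, 4, 20 / 3, 10))
  expect_equal(movingAverage(v, k = 0), v)
  # endpoints always unchanged (l = 0 there)
  set.seed(1)
  r <- rnorm(13)
  sm <- movingAverage(r, k = 3)
  expect_equal(sm[c(1, 13)], r[c(1, 13)])
  expect_error(movingAverage(1:3, k = 2), "2 \\* k")
})

test_that("moving-average span is capped at a third of the window", {
  times <- sampleTimes(25)  # spacing 25/3 over 200 units
  w <- defaultWindow(51, 2) # ~3.02 rad -> w/3 in time units ~32
  # k = 1 spans ~16.7 units: fine; k = 3 spans 50: rejected, max named
  expect_silent(movingAverage(rnorm(25), k = 1, times = times, w = w))
  err <- tryCatch(movingAverage(rnorm(25), k = 3, times = times, w = w),
                  error = conditionMessage)
  expect_match(err, "maximal admissible k is 1")
})

test_that("mean-shift averages strict angular neighborhoods", {
  # two unit vectors at angle pi/32 (< pi/16): both map to the normalized
  # midpoint direction.  Build them in the zero-mean plane of R^3.
  u <- c(1, -1, 0) / sqrt(2)
  v <- c(1, 1, -2) / sqrt(6)
  p1 <- u
  p2 <- cos(pi / 32) * u + sin(pi / 32) * v
  pts <- methods::new("PointCloud", points = rbind(p1, p2),
                      normalized = TRUE, nDegenerate = 0L)
  shifted <- meanShift(pts)
  mid <- (p1 + p2) / sqrt(sum((p1 + p2)^2))
  expect_equal(unname(cloudPoints(shifted)[1, ]), mid, tolerance = 1e-12)
  expect_equal(unname(cloudPoints(shifted)[2, ]), mid, tolerance = 1e-12)
  # isolated points are self-averages: unchanged
  iso <- methods::new("PointCloud",
    points = rbind(c(1, -1, 0) / sqrt(2), c(-1, 1, 0) / sqrt(2),
                   c(0, 1, -1) / sqrt(2)),
    normalized = TRUE, nDegenerate = 0L)
  expect_equal(cloudPoints(meanShift(iso)), cloudPoints(iso),
               tolerance = 1e-12)
  # duplicated points are unchanged
  dup <- methods::new("PointCloud",
    points = rbind(c(1, -1, 0) / sqrt(2), c(1, -1, 0) / sqrt(2)),
    normalized = TRUE, nDegenerate = 0L)
  expect_equal(cloudPoints(meanShift(dup)), cloudPoints(dup))
  expect_error(meanShift(methods::new("PointCloud",
    points = matrix(1, 1, 2), normalized = FALSE, nDegenerate = 0L)),
    "normalized")
})

test_that("mean-shift never increases the maximum pairwise angle", {
  set.seed(11)
  for (rep in 1:20) {
    pts <- matrix(rnorm(30 * 6), 30)
    cl <- centerNormalize(methods::new("PointCloud", points = pts,
                                       normalized = FALSE,
                                       nDegenerate = 0L))
    ang <- function(x) {
      d <- pmin(1, pmax(-1, tcrossprod(cloudPoints(x))))
      max(acos(d))
    }
    expect_lte(ang(meanShift(cl)), ang(cl) + 1e-9)
  }
})

test_that("periodic spline cloud closes up when L divides the record", {
  closureGap <- function(nSamples) {
    t <- sampleTimes(nSamples)
    g <- fitSpline(t, generateShape("cos", t))
    M <- defaultEmbedDim(nSamples)
    cloud <- slidingWindowCloud(g, M = M, w = defaultWindow(M, 2))
    pts <- cloudPoints(centerNormalize(cloud))
    sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
  }
  # first and last window differ only by natural-spline boundary error:
  # small against the cloud diameter (2), and shrinking as sampling grows
  g25 <- closureGap(25)
  g50 <- closureGap(50)
  expect_lt(g25, 0.15)
  expect_lt(g50, g25)
})
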
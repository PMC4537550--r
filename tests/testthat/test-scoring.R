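test_that("score identities hold exactly", {
  expect_equal(as.numeric(periodicityScore(0, sqrt(3))), 0)
  expect_equal(as.numeric(periodicityScore(0.3, 0.3)), 1)
  expect_equal(as.numeric(periodicityScore(1.1, 1.1)), 1)
  expect_equal(as.numeric(periodicityScore(1, sqrt(3))), 1 / 3)
  # generic exponents: s = 1 - (d^n - b^m)/3^(n/2)
  expect_equal(as.numeric(periodicityScore(0.5, 1.2, n = 3, m = 2)),
               1 - (1.2^3 - 0.5^2) / 3^1.5)
  expect_error(periodicityScore(1.5, 1.2), "clamp")
  expect_error(periodicityScore(-0.1, 1), "nonnegative")
  expect_error(periodicityScore(0.2, 0.5, n = 1, m = 2), "n >= m")
})

test_that("numerical overshoot is clipped and flagged", {
  s <- periodicityScore(0, sqrt(3) + 1e-3)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "clipped"))
  expect_false(attr(periodicityScore(0.5, 1), "clipped"))
})

test_that("effective (b, d) honors the ordering 0 <= b <= d", {
  sq <- pairwiseDistances(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  dg <- ripsH1(sq, maxScale = 2)
  bd <- effectiveBD(0.3, dg)
  expect_equal(bd$d, sqrt(2))
  expect_false(bd$clamped)
  # empty diagram: d = b, score 1 when n = m
  tri <- ripsH1(pairwiseDistances(rbind(c(0, 0), c(1, 0), c(0.5, 1))),
                maxScale = 3)
  bd0 <- effectiveBD(0.3, tri)
  expect_equal(bd0$d, 0.3)
  expect_equal(as.numeric(periodicityScore(bd0$b, bd0$d)), 1)
  # max death below b: clamped up to b
  bd2 <- effectiveBD(2, dg)
  expect_equal(bd2$d, 2)
  expect_true(bd2$clamped)
})

test_that("hexagon cloud scores 1/3 through the full (b, d) path", {
  th <- 2 * pi * (0:5) / 6
  dm <- pairwiseDistances(cbind(cos(th), sin(th)))
  bd <- effectiveBD(coverageRadius(dm), ripsH1(dm, maxScale = 2))
  expect_equal(as.numeric(periodicityScore(bd$b, bd$d)), 1 / 3,
               tolerance = 1e-12)
})

test_that("a clean cosine scores as strongly periodic", {
  t <- sampleTimes(25)
  res <- scoreSignal(t, generateShape("cos", t), L = 2)
  expect_lt(scoreValue(res), 0.15)
  expect_lt(coverageB(res), 0.1)
  expect_gt(deathD(res), 1.6)
})

test_that("damping barely moves the score", {
  t <- sampleTimes(25)
  sCos <- scoreValue(scoreSignal(t, generateShape("cos", t), L = 2))
  sDamp <- scoreValue(scoreSignal(t, generateShape("damp", t), L = 2))
  expect_lt(abs(sCos - sDamp), 0.1)
})

test_that("constant signals short-circuit to score 1 with a flag", {
  t <- sampleTimes(25)
  res <- scoreSignal(t, rep(3.2, 25), L = 2)
  expect_equal(scoreValue(res), 1.0)
  expect_true("degenerate" %in% periodicityFlags(res))
  expect_true(is.na(coverageB(res)))
})

test_that("the score is invariant to positive affine transforms", {
  t <- sampleTimes(25)
  set.seed(55)
  for (i in 1:5) {
    v <- generateShape(sample(shapeNames(), 1), t,
                       phase = runif(1, 0, 100)) + rnorm(25, sd = 5)
    s1 <- scoreValue(scoreSignal(t, v, L = 2))
    s2 <- scoreValue(scoreSignal(t, 3 * v + 7, L = 2))
    expect_equal(s1, s2, tolerance = 1e-10)
  }
})

test_that("score decreases in d and increases in b", {
  d <- seq(0.5, sqrt(3), length.out = 9)
  s <- vapply(d, function(x) as.numeric(periodicityScore(0.2, x)),
              numeric(1))
  expect_true(all(diff(s) < 0))
  b <- seq(0, 1.2, length.out = 9)
  s2 <- vapply(b, function(x) as.numeric(periodicityScore(x, 1.3)),
               numeric(1))
  expect_true(all(diff(s2) > 0))
})

test_that("noiseless periodic shapes separate from non-periodic ones", {
  t <- sampleTimes(25)
  per <- vapply(periodicShapes(), function(sh)
    scoreValue(scoreSignal(t, generateShape(sh, t), L = 2)), numeric(1))
  non <- vapply(nonPeriodicShapes(), function(sh)
    scoreValue(scoreSignal(t, generateShape(sh, t), L = 2)), numeric(1))
  expect_lt(max(per), min(non))
})

test_that("missing values are spline-imputed with a flag", {
  t <- sampleTimes(25)
  v <- generateShape("cos", t)
  v[c(5, 12)] <- NA
  res <- scoreSignal(t, v, L = 2)
  expect_match(paste(periodicityFlags(res), collapse = ";"), "imputed:2")
  expect_lt(scoreValue(res), 0.15)
  expect_error(scoreSignal(t, c(v[1:3], rep(NA, 22)), L = 2), "fewer than 4")
})

test_that("table scoring preserves row identity regardless of order", {
  t <- sampleTimes(13)
  set.seed(77)
  mat <- rbind(cosA = generateShape("cos", t),
               rampB = generateShape("line", t),
               noisy = rnorm(13))
  df1 <- scoreExperiment(mat, times = t, L = 2)
  df2 <- scoreExperiment(mat[c(3, 1, 2), ], times = t, L = 2)
  expect_equal(df1[df1$id == "cosA", "score"],
               df2[df2$id == "cosA", "score"])
  expect_equal(df1[df1$id == "noisy", "score"],
               df2[df2$id == "noisy", "score"])
  # ranks: 1 = most periodic
  expect_equal(df1$id[which.min(df1$rank)], "cosA")
})

test_that("rows with too few observations are skipped, not fatal", {
  t <- sampleTimes(13)
  mat <- rbind(good = generateShape("cos", t),
               bad = c(1, 2, 3, rep(NA, 10)))
  expect_message(df <- scoreExperiment(mat, times = t, L = 2), "skipped")
  expect_true(is.na(df$score[df$id == "bad"]))
  expect_equal(df$flags[df$id == "bad"], "skipped")
  expect_false(is.na(df$score[df$id == "good"]))
})

test_that("SummarizedExperiment input uses colData time", {
  t <- sampleTimes(13)
  mat <- rbind(a = generateShape("cos", t), b = generateShape("flat", t))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(time = t))
  df <- scoreExperiment(se, L = 2)
  expect_equal(nrow(df), 2L)
  expect_lt(df$score[1], df$score[2])
})
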
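# ringscore

Shape-agnostic periodicity scoring for gene-expression time series via
sliding-window embeddings and 1-dimensional persistent homology.

## What it does, and for whom

Screens for periodically expressed genes — cell cycle, metabolic cycle,
circadian — must cope with signals that are peaked, sawtooth-like,
damped, trending, or contracting, and with short, unevenly sampled, noisy
records.  Detectors that compare against a template (cosine fits, rank
correlation with a reference curve) are biased toward the shapes they
assume.

`ringscore` measures periodicity geometrically instead.  A time series
`g0..gS` is spline-interpolated onto `[0, 2π]` and embedded as the
sliding-window point cloud of delay vectors
`[g(t), g(t+τ), ..., g(t+Mτ)]` over 201 window start positions, with the
window size `w = 2πM/(L(M+1))` for `L` expected periods.  Each vector is
centered to zero coordinate mean and scaled to unit norm, which makes the
score exactly invariant to `a·g + c` (a > 0) and resistant to damping and
trending.  A periodic signal traces a closed loop on the unit sphere;
1-dimensional persistent homology of the Vietoris–Rips filtration
measures that loop through the coverage radius `b` (largest
nearest-neighbor distance) and the dominant cycle's death scale `d`, and

```
s(n, m) = 1 − (dⁿ − bᵐ) / 3^(n/2),   n = m = 2 by default,
```

gives a score in `[0, 1]`: **0 = periodic, 1 = not periodic**.  For these
clouds `0 ≤ b ≤ d ≤ √3`; a dense circle gives `s → 0`, a regular hexagon
gives exactly `1/3`, an arc or blob gives `s ≈ 1`.

The package also ships the surrounding study harness: a synthetic
benchmark generator (14 shapes — 10 periodic, 4 non-periodic — at period
100 over a 200-unit record; four variance-matched noise models at five
levels; 50/25/17-sample designs), permutation significance testing, and a
ROC/AUC evaluation layer.  The Rips reduction engine is implemented in
the package (Rcpp) and verified against an independent brute-force
reduction in the tests.

## Worked example

```r
library(ringscore)

t <- sampleTimes(25)                      # 25 samples over 2 periods
cosine <- generateShape("cos",  t)        # crest +50 at t = 0
damped <- generateShape("damp", t)        # amplitude halves each period
ramp   <- generateShape("sigmoid", t)     # non-periodic

scoreValue(scoreSignal(t, cosine, L = 2))
#> [1] 0.0003411
scoreValue(scoreSignal(t, damped, L = 2))
#> [1] 0.0004261
scoreValue(scoreSignal(t, ramp,   L = 2))
#> [1] 1
```

The damped cosine scores essentially as well as the pure cosine — the
pointwise normalization absorbs the decay — while the monotone ramp is
maximally non-periodic.  Scoring a whole table:

```r
se  <- readExpressionTable("expression.tsv")  # rows = genes, header = times
res <- scoreExperiment(se, L = 2)             # id, score, b, d, rank, flags
```

A small benchmark with ROC/AUC:

```r
grid   <- buildBenchmark(perShape = 50, samplings = 25, seed = 1)
scored <- runGrid(grid, L = 2)
gridAUC(scored)[1, ]
#>                      cell  shape auc
#> 1 gaussian_additive_0_n25 pooled   1
```

Permutation significance (proportion of value-shuffles scoring at least
as periodic; `p = 0` attainable by design):

```r
set.seed(1)
noisy <- cosine + rnorm(25, sd = 12)
permutationPValue(t, noisy, L = 2, N = 1000, seed = 2)$p
#> [1] 0
```

A command-line wrapper with `score`, `perm`, `synth` and `bench`
subcommands is installed at
`system.file("scripts", "ringscore-cli.R", package = "ringscore")`.

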
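# gaitsplice

Nonlinear measures of gait — the largest Lyapunov exponent (LyE,
dynamic stability) and sample entropy (SE, regularity) — require long,
uninterrupted series of consecutive gait cycles. Standard overground
walking protocols deliver the opposite: several short marker-trajectory
recordings, interrupted whenever the subject leaves the capture volume.
`gaitsplice` joins such short 3-D multi-marker segments into one
continuous series so that dynamic stability can still be estimated, and
ships the statistics needed to judge how much the joining costs.

It is aimed at movement scientists working with optical motion-capture
data (frames x markers x 3 coordinates in metres, e.g. 100 Hz
whole-body marker sets).

## The method

For consecutive segments $C_1, C_2$, the last $n$ frames of $C_1$ are
compared against every $n$-frame window of $C_2$ (offset $v$) with the
weighted squared pose distance

$$D(v) = \sum_{m=0}^{M-1}\sum_{j=0}^{n-1} w_m\,
  \lVert p_{m,j} - T^v p'_{m,j}\rVert^2 ,$$

where $T^v$ is the closed-form optimal rigid alignment — rotation about
the vertical axis plus horizontal translation, the freedom a walking
direction has — and $w_m \in [0,1]$ weight reliable (bony) markers
above soft-tissue ones. The transition starts at the first qualifying
local minimum $v = V$ of $D$; the incoming segment is rigidly aligned
and the two are cross-faded over the $n$-frame window with the cubic
coefficient $\alpha(j) = 2((j{+}1)/n)^3 - 3((j{+}1)/n)^2 + 1$. The
procedure chains left to right across all segments
($n = \mathrm{round}(\mathrm{rate}/3)$, i.e. 33 frames at 100 Hz).

Downstream, the vertical heel trajectory is analysed with Wolf's
fiducial-trajectory LyE (divergence over 3 consecutive samples, noise
floor $10^{-4}$, maximal probe one tenth of the data range) and a
delayed sample entropy ($r = 0.2\,\mathrm{SD}$), with the embedding lag
and dimension selected per series by average mutual information and
false nearest neighbours. Agreement between uninterrupted and
concatenated estimates is quantified with ICC(3,1), SEM, Bland-Altman
bias/limits of agreement, and pooled-SD effect sizes.

## Worked example

Everything is testable without recorded data via the synthetic walker
rig (quasi-periodic heel bump pinned to a floor each stance, rigidly
co-moving auxiliary markers, seeded stride-time variability):

```r
library(gaitsplice)

# a cohort of 8 distinct synthetic walkers, 300 cycles each
cohort <- walker_cohort(8, n_cycles = 300, seed = 5)

# full pipeline: heel strikes -> cut (3 preset schemes) -> concatenate
# -> crop to common length -> LyE and SE per condition
res <- run_experiment(cohort)
ev  <- evaluate_experiment(res)
ev$agreement
#>   metric condition n       icc         sem relative_sem         bias
#> 1    lye   cut1001 8 0.9661269 0.003329081   0.08961343 -0.000754098
#> 2    lye   cut0803 8 0.9205877 0.004671083   0.13294802  0.003275309
#> 3    lye   cut0605 8 0.9486604 0.004172783   0.11528476  0.001153731
#> 4     se   cut1001 8 0.6758072 0.020306704   0.06053948  0.003224843
#> 5     se   cut0803 8 0.9243205 0.008939033   0.02630872 -0.005466021
#> 6     se   cut0605 8 0.1728196 0.028656851   0.08540200  0.002978102
```

Read: after cutting a walker's recording into short pieces (keep 10
cycles / drop 1, 8/3, or 6/5) and splicing them back together, the LyE
computed on the concatenated series ranks subjects almost exactly as the
uninterrupted recording does (ICC 0.92-0.97, relative SEM about 10%).
SE is noticeably more sensitive to concatenation (ICC 0.17-0.92) — so
absolute SE values from spliced data deserve caution, while relative
LyE comparisons survive splicing well.

Single pieces are available individually, e.g.:

```r
g   <- gen_walker(walker_spec(n_cycles = 60, seed = 101))
ev  <- detect_heel_strikes(g$series)           # vertical-velocity detector
segs <- cut_series(g$series, ev, cut_scheme(6, 5))
out <- concatenate_all(segs, n = 33)
sapply(out$transitions, `[[`, "distance")      # pose distance at each joint
#> [1] 0.00091 0.00134 0.00060 0.00052
z   <- marker_coordinate(out$series, "RHEE")   # vertical heel trajectory
nonlinear_measures(z)[c("lye", "se")]
```

A thin command-line interface over the same functions lives at
`inst/cli/gaitsplice.R` (subcommands `simulate`, `cut`, `join`, `nld`,
`run`, `evaluate`). An example marker-weight configuration is in
`inst/extdata/example_weights.json`.

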
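---
title: "Concatenating interrupted gait recordings for nonlinear stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concatenating interrupted gait recordings for nonlinear stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nonlinear measures of gait — the largest Lyapunov exponent (LyE) as a
measure of dynamic stability and sample entropy (SE) as a measure of
regularity — assume a long, *uninterrupted* time series of consecutive
gait cycles. Overground walking protocols rarely deliver one: subjects
leave the capture volume, turn, or rest, so a session produces several
short marker-trajectory recordings instead of a single continuous one.

`gaitsplice` implements a concatenation algorithm that joins short
3-D multi-marker segments into one continuous series by (1) finding, for
each pair of consecutive segments, the offset in the incoming segment
whose whole-body pose sequence best matches the end of the outgoing
segment, (2) rigidly aligning the incoming segment onto the outgoing one,
and (3) cross-fading the two over a short transition window. The package
also provides the full downstream tool chain — heel-strike detection,
keep/exclude segmentation schemes, AMI/FNN embedding selection, Wolf's
LyE, delayed sample entropy — plus the agreement statistics (ICC(3,1),
SEM, Bland-Altman, paired effect sizes) used to judge whether measures
from concatenated data agree with those from uninterrupted data.

## The pose distance and its alignment group

Let $p_{m,j}$ be the position of marker $m$ at frame $j$ of the window
$C_1^n$ (the last $n$ frames of the outgoing segment) and $p'_{m,j}$ the
corresponding position in the candidate window $C_2^{n,v}$ starting at
offset $v$ of the incoming segment. The pose distance is

$$D(v) \;=\; \sum_{m=0}^{M-1} \sum_{j=0}^{n-1} w_m \,
  \lVert p_{m,j} - T^v p'_{m,j} \rVert^2,$$

where $w_m \in [0,1]$ are marker weights (high for bony landmarks and
markers near the analysed heel, low for soft-tissue placements) and $T^v$
is the rigid motion — a rotation about the vertical axis plus a
horizontal translation — that minimises the sum. This group is exactly
the freedom a walking direction has in overground protocols; vertical
coordinates contribute to $D$ but are never modified by $T$.

The minimising transform has a closed form (a weighted 2-D point-cloud
alignment): with weighted horizontal centroids removed, the optimal
rotation is $\theta^* = \operatorname{atan2}(S, C)$ with
$C = \sum w\,(a_x b_x + a_y b_y)$ and $S = \sum w\,(a_y b_x - a_x b_y)$,
and the translation maps the weighted centroid of the rotated source onto
the target's. The test suite checks this against a brute-force rotation
grid (step $10^{-3}$ rad, per-angle closed-form translation) on random
window pairs.

A note on an ambiguity: with one transform per frame inside the sum, the
distance is smaller, but applying frame-wise rigid motions would distort
the very dynamics being measured. `gaitsplice` fits **one transform per
candidate window**, applies it rigidly to the entire remainder of the
incoming segment, and exposes the per-frame variant only as a diagnostic
distance mode (`per_frame = TRUE`).

## Transition choice and blending

The transition offset is the first local minimum of $D(v)$ over
$v \in [0, N-n]$, with two concretisations that the raw rule needs in
practice:

* **Boundary.** With segments cut at heel strikes, the best alignments
  lie near $v \equiv \text{cycle} - n$, which leaves $v = 0$ on a slope
  descending towards unreachable negative offsets; $v=0$ is therefore a
  *structural* boundary dip that is not a pose match. The boundary is
  accepted only when it also attains the global minimum (the
  exact-overlap splice case, where $D(0) = 0$).
* **Depth.** Gait profiles are bimodal: genuine matches sit orders of
  magnitude below the shallow dips produced by components with sub-stride
  periodicity (the trunk bobs twice per stride, so half-stride offsets
  half-match). `concatenate_all()` therefore requires a qualifying local
  minimum to lie within 25% of the profile range above the global
  minimum. `select_transition()` called directly applies the plain rule.

Blending uses the cubic coefficient
$\alpha(j) = 2\left(\tfrac{j+1}{n}\right)^3 -
3\left(\tfrac{j+1}{n}\right)^2 + 1$, strictly decreasing with
$\alpha(n-1) = 0$, so the blended window
$\alpha(j)\,C^n_{1,j} + (1-\alpha(j))\,T C^{n,V}_{2,j}$ hands over
smoothly and ends exactly on the aligned incoming segment. The default
window is $n = \operatorname{round}(\text{rate}/3)$ — 33 frames at
100 Hz, about a third of a second. An exact-overlap construction (two
segments that share their last/first $n$ frames) must reconstruct the
original series to below $10^{-9}$ m; this splice identity is asserted in
the tests and the acceptance script.

## Nonlinear measures

All measures operate on the raw (unfiltered) vertical heel trajectory;
any smoothing in the package is confined to detector internals and never
touches analysed data.

**Embedding selection.** The lag $\tau$ is the first local minimum of the
average mutual information (64 equal-width bins, lags up to 200). Two
regularisations stabilise the histogram estimator: the profile is
averaged over eight seeded uniform dithers of two bin widths — for
quantised or noise-free signals (a sampled sine has only one support atom
per distinct phase) this recovers the smooth continuous-MI profile whose
minimum for a sine lies at the quarter period, while for ordinarily noisy
data the dither is far below the intrinsic noise and changes nothing —
and the profile is smoothed with a 3-point moving average before the
minimum rule. The dimension comes from false nearest neighbours with the
Kennel-standard settings ($r_{tol} = 15$, $a_{tol} = 2$, threshold 1%,
$\text{max dim} = 12$, Theiler window $\tau$); stochastic signals never
settle and saturate, flagged, at the maximum.

**Wolf LyE.** The fiducial-trajectory estimator tracks the divergence of
the nearest admissible neighbour (separation within a probe annulus of
$[10^{-4}, 0.1 \times \text{range}]$ in data units, temporal exclusion
$\dim\cdot\tau$) over 3 consecutive samples at a time, accumulating
$\ln(d'/d)$ with separations clamped below at the noise floor, and
replaces the neighbour when the separation exceeds the maximal probe —
preferring the closest candidate within a 30° orientation cone, per
Wolf's prescription. When a neighbour runs off the end of the data it is
replaced rather than terminating the pass; truncating there makes the
estimate hostage to a single unlucky neighbour choice. The result is in
nats per sample; the CLI also reports nats per second.

On the classical Lorenz system ($\sigma=10$, $\rho=28$, $\beta=8/3$,
$dt = 0.01$; parameters chosen once as the canonical chaotic benchmark)
the estimate at these gait-tuned settings runs 1.07-1.14 nats per unit
time against the known $\lambda_1 \approx 0.906$ (verified in the tests
by an independent Benettin two-trajectory integration). The 3-sample
evolution is far shorter than what Wolf used for Lorenz, and short
evolutions bias the estimate high on strongly chaotic data; the tests
therefore assert agreement with the oracle within an honest estimator
band rather than pretending these gait-tuned settings are unbiased on
this benchmark.

**Delayed sample entropy.** Template vectors are built with lag $\tau$
and dimension $m = \dim$; $B$ counts pairs within Chebyshev tolerance
$r = 0.2\,\mathrm{SD}$ at length $m$, $A$ at length $m+1$, self-matches
excluded, over the index set for which the $(m{+}1)$-template exists, and
$\mathrm{SE} = -\ln(A/B)$. The implementation sorts on the first template
coordinate so only pairs already within $r$ there are examined; the
counts are exact and are checked pair-for-pair against a brute-force
double loop. Zero match counts are never reported as zero entropy: they
yield $+\infty$ with a warning and an `undefined` flag. This situation is
real, not hypothetical — white noise at the FNN-saturated dimension 12
has an expected $B$ of order $10^{-3}$ at $n = 30\,000$ — and treating it
as "more irregular than the tolerance can resolve" keeps the
predictability ordering meaningful while still surfacing the condition.

## The synthetic walker

No recorded data ship with the package; a synthetic multi-marker
"walker" makes every stage testable against known ground truth. Each
gait cycle (one stride) is 60% stance — heel vertical pinned to a floor
level plus measurement noise, reproducing the repetitive convergence of
a real heel marker to the floor — and 40% swing, during which the heel
rises along $16u^2(1-u)^2$ (zero value and slope at both ends; peak =
`step_height_m`). Cycle durations are i.i.d. Gaussian with mean
`mean_cycle_s` and CV `cycle_cv`. Rhythmic components are one-stride
periodic (fore-aft and mediolateral excursions) except the trunk-like
vertical bob at two per stride; a slow drift common to all markers
emulates treadmill station-keeping and is invisible to the pose distance
(it lies in the alignment group). Auxiliary markers sit at fixed rigid
offsets from a common moving origin. Measurement noise is i.i.d.
Gaussian, added after the `amplitude_gain` scaling so the noiseless
vertical range scales exactly with the gain.

Defaults were chosen once as a realistic healthy treadmill walker:
1.2 s mean cycle, 3% stride-time CV, 0.15 m peak heel lift, 0.5 mm
marker noise (typical optical-system precision), 8 markers (1 heel + 7
auxiliary — enough to exercise weighted pose matching without pretending
to be a full 62-marker set).

What the walker does *not* emulate matters for interpreting results.
Real stride timing is anti-persistent — a treadmill bounds how far a
walker's phase can drift — whereas i.i.d. cycle durations make the
cumulative phase a random walk. Divergence of neighbouring trajectories
is correspondingly faster in the walker than in comparable human data:
at 3% CV its Wolf LyE is roughly 0.03 nats/sample, while real gait sits
near 0.009. One consequence is visible in the known-signal benchmark:
the walker's LyE lands *above* Lorenz-at-$dt{=}0.01$ (about 0.011
nats/sample), so the full predictability ordering
white noise > Lorenz > walker > sine holds for sample entropy but fails
at the Lorenz-walker link for LyE. This is a property of the synthetic
timing model, not of the estimators; passing ordering tests on the
walker says nothing about anti-persistent real data.

The reliability experiment uses `walker_cohort()`: a pool of walkers
whose parameters are drawn per subject (stride-time CV 0.015-0.045
centred on 0.03, cycle duration 1.1-1.3 s, heel lift 0.12-0.18 m).
Between-subject spread is not a convenience but a requirement: ICC is a
variance ratio, and for a pool of identical walkers the true
between-subject variance is zero, so the ICC of *any* estimator — however
faithful the concatenation — degenerates towards zero and the experiment
would measure nothing.

## The validation experiment

`run_experiment()` mirrors the validation design: detect heel strikes
(vertical-velocity crossing detector; smoothing affects only the
detector's internal velocity), cut with the preset schemes
(`cut1001` = keep 10/drop 1, `cut0803` = 8/3, `cut0605` = 6/5),
concatenate, crop the uninterrupted series and all concatenated variants
of a recording to a common length, and compute both measures with
per-series re-estimated embeddings. Transition counts are reported
within the cropped window — all three presets share
$C_{in}+C_{ex} = 11$, so their raw segment counts coincide and the
different concatenation densities only become visible after cropping to
the shortest variant. `evaluate_experiment()` computes ICC(3,1) (via the
two-way `aov` decomposition), SEM $= \mathrm{SD}\sqrt{1-\mathrm{ICC}}$
with the relative SEM normalised by the grand mean of the two compared
conditions, Bland-Altman bias and limits of agreement with
Student-$t$ confidence intervals ($n-1$ SD denominator), pooled-SD
effect sizes between condition groups, and the CoV of the effect size
across cutting conditions. Reliability is always computed on the
unperturbed reference group.

At the packaged problem size (20-subject cohorts, 300 cycles each, one
unperturbed and one amplitude-perturbed set — sizes chosen to keep a
full run on a single CPU in minutes) the LyE ICC between fullTS and
every cutting condition is 0.96-0.98 with relative SEM around 10%,
while SE reliability is fair to good (ICC roughly 0.6-0.75) — the same
qualitative picture as with recorded data: concatenation is serviceable
for stability, but regularity measures are sensitive to it. An
amplitude perturbation (gain 1.4) keeps its effect-size direction under
every cutting condition for both measures in this configuration, but
the LyE effect of a pure amplitude scaling is intrinsically near zero
(the measure is scale invariant up to noise-floor effects), so that
sign check is fragile by construction; a variability perturbation would
produce a robust LyE effect.

## Numerical choices and degenerate inputs

* Frame indexing is 0-based with half-open intervals everywhere.
* Vertical axis defaults to the third coordinate (Z-up); loaders accept
  a scale flag for mm-unit files; the gap policy defaults to rejection,
  with opt-in, logged linear interpolation of interior gaps only.
* The FNN ratio test floors distances at $10^{-8}\,\mathrm{SD}$:
  exactly periodic signals produce duplicate embedded points whose
  separations are double-rounding noise carrying no geometry.
* Constant series are errors for every estimator (AMI, FNN, Wolf, SE)
  rather than silently zero results.
* `cohens_d_pooled` refuses zero pooled SD; `cov_of_es` flags a zero
  mean; Bland-Altman uses the $n-1$ SD and $t$-based intervals.
* Ties in the heel-strike candidate merge keep the earlier frame; the
  detector compensates the known group delay of its smoothing kernel.

## Limitations

* C3D input is not supported; convert to wide CSV/TSV first.
* The walker is a test rig, not a physiological model: no joint
  kinematics, no anti-persistent stride timing, no soft-tissue artefact.
* Concatenation assumes all segments come from one subject and session
  with a consistent marker set.
* The Wolf estimator's accuracy at the gait-tuned 3-sample evolution is
  benchmark-dependent (high bias on Lorenz); comparisons should rely on
  within-study contrasts rather than absolute values, which is also how
  the agreement statistics are framed.
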
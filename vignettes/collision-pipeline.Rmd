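---
title: "Modeling and analysing collision-trajectory experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and analysing collision-trajectory experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomsight)
```

`loomsight` implements the computational chain of a looming-stimulus
collision-detection experiment: an object approaches an observer on either a
direct-collision ("hit") course or a trajectory that narrowly misses the
head, and the question is how precisely behaviour, pupillary reflexes and
region-of-interest (ROI) brain responses distinguish the two. This vignette
explains the models behind each stage, the tunable parameters and their
defaults, the numerical choices, what the synthetic generators do and do not
emulate, and the known limitations.

## Stimulus geometry

A sphere of diameter $d$ at viewing-axis distance $D$ subtends the full
visual angle $2\,\mathrm{atan}\!\big(\tfrac{d/2}{D}\big)$; the remaining
time to collision at speed $v$ is $D/v$. Trajectories are straight 3D lines
from a start position (quadrant-signed lateral/vertical offsets, +x
rightward, +y upward) to the would-be impact point at distance zero; the
impact point's horizontal offset from the nasion (0, 3, 6, 12 cm in the
emulated behavioural task) is the experimental variable. Projection uses a
cyclopean pinhole eye — angular coordinates are
$\mathrm{atan}(\text{offset}/D)$ — with no binocular disparity; stereoscopic
presentation is out of scope.

Because hit and near-miss paths traverse slightly different retinal regions,
conditions from the same quadrant are aligned on the centre of mass of the
projected images: each path is rigidly shifted so its time-averaged,
area-weighted disc centroid (weights $\propto$ angular size$^2$, the area of
a solid disc) matches the across-condition mean. The alignment is exact to
1e-9 degrees and idempotent.

Printed-value checks round half away from zero, matching how stimulus
parameters are conventionally reported. One reconstruction is deliberately
not forced: a published 33 ms vanishing-point time-to-collision alongside
0.75 m at 24 m/s (= 31.25 ms) is display-quantized; the package asserts the
frame count of the rendered sequence (20 frames at 60 Hz for an 8 m travel
at 24 m/s), not the rounded milliseconds.

Rendering (`render_frames()`) draws an anti-aliased disc (one-pixel linear
coverage ramp) on a constant background, defaulting to 60 Hz, 256×256
pixels, 12° field of view; a disc that exceeds the field of view is clipped
with a warning, so flow diagnostics should use a raster wide enough to
contain the final frames (the shipped diagnostic uses 24°).

## Optical-flow diagnostics

`horn_schunck_flow()` is the classical dense optical-flow estimator:
brightness constancy plus a quadratic smoothness penalty with weight
$\alpha^2$, solved by Jacobi iteration with the original
forward-difference averaging stencils and edge replication. Defaults are
$\alpha = 1$ and 100 iterations; the stimulus diagnostic uses 150
iterations, because with a solid (textureless) disc the translational flow
must propagate from the rim into the interior through the smoothness term,
and the interior is what dominates the summed squared modulus. Per-pixel
"speed" follows the squared-modulus convention ($u^2 + v^2$), summed over
pixels for the overall magnitude and over pixels × frames within
eccentricity rings for the profiles.

With these settings the re-rendered hit/near-miss pair reproduces the
expected qualitative ordering: the near-miss stimulus, which sweeps
laterally while expanding, carries more overall flow and more
central-field integrated flow than the pure-expansion hit stimulus. The
magnitude is only approximately invariant to mirroring the frames (the
derivative stencils sit on a half-pixel staggered grid), so the test
tolerance there is 1%.

## Psychometric model

Hit/miss discrimination is modelled as
$P(\text{hit}\mid x) = 1 - \Phi\!\big(\tfrac{x-\mu}{\sigma}\big)$ over
impact-point offset $x$ (cm): $\mu$ is the offset at 50% hit responses
(about the edge of the head) and $\sigma$ the discrimination spread. The
sensitivity statistic is $\ln(1/\sigma)$ (occasionally typeset as
"ln(1 σ)" in print — it is the log reciprocal SD). Fitting is binomial
maximum likelihood via bounded quasi-Newton on $(\mu, \log\sigma)$
(tolerance ~1e-8), multistarted from probit-scale moment estimates; no
lapse or guess parameters are included. A probit GLM is the independent
cross-check in the test suite.

One identification caveat, documented because it shapes the tests: with the
coarse 4-level placement \{0, 3, 6, 12\} cm and $\sigma = 1$, the flanking
levels are saturated and the profile likelihood is flat in $\sigma$ below
about 0.7 — $\sigma$ is identified only from above. The recovery tests
therefore assert $\mu$ tightly under that design and recover both
parameters only under threshold-centred placement, which is what the
emulated task's adaptive near/far-miss placement produces in practice.

Paired sensitivities (e.g. upper vs lower visual field) are compared with
`exact_sign_permutation()`: the null is all $2^n$ sign flips of the paired
differences when $n \le 15$ (enumeration matrices are cached), otherwise
10,000 seeded Monte Carlo flips.

## Pupil preprocessing and cluster-length inference

Preprocessing is fixed-order: linear interpolation of blink gaps, zero-phase
4th-order Butterworth low-pass (default cutoff 40 Hz, suppressing
shutter-glass artifacts; zero-phase avoids latency shifts in cluster
timing), baseline subtraction (−200–0 ms) and division by the trace SD.
Whole-trace SD is the default normalizer (configurable to baseline-window
SD; the choice is not pinned down by convention). Before filtering, the
trace is demeaned and padded by odd reflection so filter start-up
transients do not leak into the baseline; traces that are numerically
constant are left at zero rather than having round-off amplified by the SD
division. A trial whose entire baseline is missing is flagged invalid.

Between-condition inference uses cluster *length* over time (distinct from
the voxel statistic, which is mass): pointwise paired t tests at each
sample, clusters as maximal runs with $p <$ 0.05, and a max-cluster-length
null built from within-subject condition-label sign flips (10,000 by
default). The p-value uses the add-one convention so it lies in (0, 1].

## Voxel statistics and cross-validated ROI readout

GLM amplitudes use fixed HRFs: a canonical double-gamma (peak delay 6 s,
dispersion 1, undershoot 16/1, ratio 1/6; peak ≈ 5 s) and a faster,
narrower `subcortical_fast` variant (peak delay 4 s, dispersion 0.9,
undershoot 8/0.9, ratio 0.35; peak ≈ 3 s). The subcortical parameters are
a configurable stand-in — published subcortical kernels vary and no exact
parameter set is canonical — so they are exposed, not hard-coded.
Regressors are boxcars convolved with the kernel on a 0.1 s grid, sampled
at the scan times; per-run scaling to percent signal change
(`100 (x − mean)/mean`) is applied upstream.

Small-volume family-wise inference uses the cluster-mass permutation test:
within an ROI mask, the group one-sample t-map of subject hit−miss
difference maps is thresholded two-sided at voxel $p < 0.05$ (the sidedness
of the cluster-defining test is not fixed by convention; two-sided is the
default here), clusters are face-connected (6-connectivity by default,
configurable to 18/26) and scored by $\sum |t|$. The null flips each
subject's condition labels after subtracting the group-average map from
every subject map (demeaning), and permutations flipping fewer than 15% or
more than 85% of subjects are discarded — both steps stabilize the null
when effects are large. Same seed gives a bit-identical null.

Two cross-validation schemes decouple voxel selection from effect readout:
leave-one-subject-out (group-level selection at uncorrected $p < 0.05$,
positive direction, on the remaining subjects; readout on the held-out
subject) and leave-one-run-out within subject (top-N voxels, default 10, or
a responsiveness criterion on the selection runs; readout on the left-out
run). The deliberately biased variant — selection and readout on the same
runs — is retained behind `cross_validated = FALSE` purely as a negative
control; under pure noise it shows a strong positive bias while the
cross-validated path is unbiased, and that contrast is a regression test.

ROI-averaged condition means feed a 2×2 within-subject ANOVA
(`stats::aov` with error strata) reporting partial eta squared
$SS_e/(SS_e+SS_{err})$, with post-hoc paired t tests (Cohen's
$d = \bar{d}/SD_d$) computed only for effects significant at 0.05
(Fisher-protected logic). Holm and Benjamini–Hochberg corrections wrap
`stats::p.adjust`. Bivariate outliers are removed by FAST-MCD robust
Mahalanobis distances with a 1.5-IQR fence on the distance distribution;
the MCD subset search is seeded for reproducibility.

## Beta series and path-model search

Per-trial amplitudes are estimated with one HRF-convolved regressor per
trial; the resulting beta series are z-scored within each trajectory
condition (removing mean-amplitude differences) before a second-level
regression whose slope — the Pearson correlation, for z-scored inputs — is
the functional connectivity.

Effective connectivity is searched over an explicit model space of directed
path models $x = Bx + e$ over the five ROIs \{SC, vmPul, VTA, VC, AttNet\}
(superior colliculus, ventromedial pulvinar, ventral tegmental area, visual
cortex, frontoparietal attention network), with diagonal residual
variances for endogenous variables and free covariances among exogenous
ones. The default space fixes the tectofugal edges SC→vmPul and SC→VTA in
every model; three connections (SC–VC, vmPul–VC, VTA–VC) take one of two
directions, and three (vmPul–AttNet, VTA–AttNet, VC–AttNet) take one of
two directions or are absent: $2^3 3^3 = 216$ candidates. The slot
assignment is a reconstruction from the anatomical candidate connections
(the exact figure-level assignment is not published as a table) and is
fully overridable via `model_space_spec()` or a YAML config. With all
edges present a model has 8 path coefficients + 5 residual variances = 13
free parameters, hence df = 15 − 13 = 2, matching the published
best-model df. Note that a space with six two-way direction slots over
five nodes necessarily contains combinations that close a directed loop
(a forest admits at most four undirected edges); such nonrecursive members
are well-defined ML problems, are fitted as such, and are flagged
`recursive = FALSE` with a logged count (110 in the default space) —
`drop_cyclic = TRUE` removes them if a strictly recursive space is wanted.

Fitting minimizes the ML discrepancy
$F = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p$ with implied
covariance $\Sigma = (I-B)^{-1}\Psi(I-B)^{-\top}$, by BFGS on the free
coefficients, log residual variances and exogenous covariances, starting at
$B = 0$, $\Psi = \mathrm{diag}(S)$, with up to five jittered restarts
(tolerance ~1e-9 on the relative objective). $\chi^2 = (N-1)F$ at the
optimum, with $N$ the concatenated trial count. Fit indices follow the
standard definitions: CFI against the independence (diagonal) baseline,
$GFI = 1 - \mathrm{tr}((\Sigma^{-1}S-I)^2)/\mathrm{tr}((\Sigma^{-1}S)^2)$,
$AGFI = 1 - \frac{p(p+1)}{2\,df}(1-GFI)$,
$PGFI = \frac{df}{p(p+1)/2}\,GFI$,
$RMSEA = \sqrt{\max(\chi^2-df,0)/(df\,(N-1))}$, and RMR as the RMS residual
of $S-\Sigma$ over the lower triangle including the diagonal. For
recursive models with diagonal $\Psi$ the ML solution has a closed form
(per-equation OLS on $S$); the test suite uses that closed form as an
independent oracle and requires agreement within 1e-3 on batches of random
models.

Selection filters out models with PGFI above a threshold and ranks the
survivors by AGFI (descending), with alternate rankings (χ², CFI, GFI,
RMSEA, RMR) reported so ranking-invariance of the winner can be checked.
The threshold is a genuine design decision: the published rule ("exclude
PGFI > 0.1") is incompatible with the published winner's own PGFI of
0.133, which is the *minimum attainable* value in a five-variable space
(df = 2 stratum). `select_best_model()` therefore keeps 0.1 as the literal
default — erroring with guidance when it empties the space — while the
shipped recovery experiments use 0.15, which keeps exactly the minimal-df
stratum the published winner belonged to. A related subtlety shapes the
recovery experiment itself: reversing one edge without changing the
skeleton often yields a Markov-equivalent model with identical fit, so the
experiment uses a small space whose competitors are not
covariance-equivalent to the generating model; under that construction the
truth is recovered in essentially every seed at N = 1000.

Across-subject correlation matrices of collision-sensitive effects are
FWE-corrected by a max-statistic permutation null: every column's subject
correspondence is shuffled independently and the largest |r| in the matrix
recorded; corrected p-values are read off that null and floored at the
uncorrected value (the max-statistic guarantee is asymptotic, so the floor
enforces the monotonicity contract exactly).

## Synthetic cohorts: what they emulate, and what they do not

Every generator is a pure function of (config, seed). Defaults mirror the
emulated study scale: behavioural cohort n = 15 with per-subject
psychometric truth ($\mu = 6$ cm; upper-field $\sigma$ 0.8 cm vs
lower-field 1.5 cm, between-subject SDs 0.5 cm and 0.15 log units — the
field asymmetry is calibrated, no numeric $\sigma$ being published, so that
the exact sign-flip test detects it in well over 80% of simulated cohorts,
mirroring the robustness of the reported finding); pupil
traces at 1 kHz with AR(1) coefficient 0.95, a Gaussian-bump hit-condition
constriction of −0.8 SD units at 1100 ms latency and 150 ms width; imaging
cohort n = 20 on a 20×20×20 grid of 1.5 mm voxels with a spherical
effect cluster of radius 1.3 voxels (≈ 9 voxels ≈ 30 µl) at voxelwise
Cohen's d = 0.7, and spatial smoothing of 2 voxels FWHM; beta series of 16
trials per condition from a recursive generating model; BOLD at TR = 2 s
with AR(1) 0.3 and a slow cosine drift. Smoothed noise is standardized by
the *exact* per-voxel variance of the smoothing operator (edge
renormalization otherwise leaves interior voxels under-dispersed and biases
the realized effect size).

The generators reproduce the statistical structure the analyses assume —
binomial responses on a normal-CDF curve, autocorrelated pupil noise with a
transient condition effect, spatially smooth subject maps with a localized
effect, beta series with a model-implied covariance, HRF-convolved trial
responses. They do not emulate pupil foreshortening, gaze-contingent
artifacts, realistic blink dynamics, physiological BOLD noise spectra,
inter-regional HRF variability, or any retinotopic organization beyond the
single effect cluster. Passing calibration and recovery tests therefore
demonstrates correctness of the statistical machinery under its own
assumptions, not robustness to real-data violations of them.

Calibration experiments in the test-suite and acceptance script run at
reduced size so the whole suite stays desk-scale: pupil traces at 250 Hz
with 12 subjects and 300–400 permutations per test, voxel cohorts of
10 subjects on an 8×8×8 grid with 300 permutations, 500–2000 simulated
null datasets per calibration, and selection recovery over 12–15 seeds at
N = 1000. These sizes put the Monte Carlo SE of an empirical type-I rate
near 0.05 at roughly 0.006–0.010, comfortably inside the asserted
[0.03, 0.07] band.

## Known limitations

* The optical-flow magnitudes depend on raster resolution, field of view
  and iteration count; only orderings and calibrated statistics are
  asserted, never absolute flow values.
* Nonrecursive path models are fitted by the same ML machinery but their
  identification is not checked beyond df ≥ 0; interpret coefficients of
  cyclic members with care.
* The exchange-fraction filter and demeaning of the cluster-mass null
  follow the published recipe; for very small cohorts (n < 7) the filter
  can leave few admissible sign patterns and p-values become coarse.
* `fit_psychometric()` deliberately omits lapse/guess parameters; data with
  non-zero lapse rates will bias $\sigma$ upward.
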
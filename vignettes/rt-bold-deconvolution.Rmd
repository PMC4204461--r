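---
title: "RT-modulated deconvolution of event-related BOLD: model, assumptions and validation"
author: "rtbold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-modulated deconvolution of event-related BOLD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtbold)
```

## The problem

Event-related fMRI ordinarily estimates one response amplitude per condition:
a canonical hemodynamic response function (HRF) is superposed at trial onsets
and regressed on each voxel's BOLD time-series. That average hides
*intra-subject* variability — the trial-to-trial fluctuation in how strongly a
region responds, and whether that fluctuation tracks behaviour. `rtbold`
implements the amplitude-modulated deconvolution approach to this question for
a speeded verification task: each trial's HRF is proportionally rescaled by
the trial's (log) reaction time, the rescaled model is residualized against
the canonical model, and the residual series becomes a second regressor whose
voxel-wise slope measures trial-level RT–BOLD coupling. A positive slope means
slower trials evoke larger percent signal change.

## The model

**HRF.** A gamma variate, $h(t) = t^{b}e^{-t/c}$, with $b = 8.6$ and
$c = 0.547$ s, rescaled analytically by its peak value $(bc)^b e^{-b}$ so the
maximum amplitude is 1.0 at $t^\ast = bc = 4.7042$ s. `gammaHRF()` evaluates
it in log space, so large shape exponents cannot overflow.

**Regressors.** For trial onsets $\tau_k$ (correct responses only),

$$y_{\mathrm{task}}(t) = \sum_k h(t - \tau_k), \qquad
  y_{\mathrm{mod}}(t) = \sum_k h(t - \tau_k)\,\log(\mathrm{RT}_k),$$

both built on a fine grid (default $dt = 0.1$ s, required to divide the TR)
and sampled at the volume acquisition times, volume $i$ at $i \times$TR
(frame-onset convention). Overlapping responses add linearly. The RT
regressor is the least-squares residual of $y_{\mathrm{mod}}$ on
$y_{\mathrm{task}}$ *and run-wise intercepts*: the defining property the rest
of the pipeline relies on is that the residual is orthogonal to the canonical
regressor and to every run's constant. We fit the projection rather than
subtracting the canonical series outright, because plain subtraction leaves a
residual that still correlates with the canonical regressor whenever the mean
log-RT differs from one; the projection guarantees the two effect columns
separate cleanly in the GLM. Natural log is used; any other base is a
constant factor absorbed by the slope. Mean-centering or z-scoring of log-RT
before modulation is available (`center`, `zscore`) but off by default, so
the default regressor is literally the log-RT-scaled model.

**Percent signal change.** Per run and voxel, $100\,y_t/M_y$ with $M_y$ the
run temporal mean, so every in-mask voxel has mean exactly 100 and betas are
in percent-signal-change units. We deliberately keep the printed form
(mean 100) rather than the common $100(y-M)/M$ (mean 0): run-wise intercepts
in the design absorb the offset, so effect betas are identical either way.
Voxels with near-zero mean are dropped from the mask (counted, reported).
Smoothing precedes PSC, mirroring the usual preprocessing order.

**Smoothing.** Separable Gaussian convolution, per-axis
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})/\mathrm{voxdim}$, with half-sample
reflected boundaries. Reflection makes each axis operator symmetric with unit
row sums, so constant images are fixed points and the spatial mean of every
volume is preserved — both are tested properties.

**Subject GLM.** Ordinary least squares per voxel on: one intercept per run,
per-run Legendre drift up to order 2, six motion nuisances (roll, pitch, yaw,
x, y, z; constant columns are dropped with a message), an incorrect-trial
nuisance regressor (on by default), and the two effect columns. The drift
order is our convention — low-order per-run polynomials are standard
deconvolution practice and absorb the generator's slow cosine drift. No
prewhitening: AR noise costs efficiency, not unbiasedness, and inference is
across subjects. Residual degrees of freedom are volumes minus design rank,
and the design's condition number is recorded.

**Group inference.** Voxel-wise one-sample t ($t = \bar\beta/(s/\sqrt n)$,
two-sided p on $n-1$ df). Zero-variance voxels get $t = \pm\infty$ (0 if the
mean is 0 too), are counted, and p is clamped into $(0,1]$. Cluster-extent
thresholding follows the Monte-Carlo simulation approach: fill the mask's
bounding grid with unit Gaussian noise, smooth to the nominal applied FWHM,
re-standardize within the mask, threshold two-sided at the voxel p (default
0.005), label positive and negative excursions separately under the chosen
neighbourhood (default "corners" = 26-connectivity, i.e. voxels joined by
faces, edges or corners), and record the largest cluster; the extent
threshold is the smallest $k$ whose exceedance fraction is $\le \alpha$
(default 0.05). We use the *applied* kernel width as the smoothness input
rather than residual-estimated smoothness, matching the convention of the
simulator era this procedure comes from; synthetic cohorts share a native
grid, so no resampling is done and extent thresholds are grid-specific.
Surviving clusters are reported with peak coordinate (mm in the grid's own
space, voxel (1,1,1) at the origin), voxel count, peak t, and the
across-subject mean (SD) of the within-cluster mean effect.

## The synthetic generator

With no public data for this design, every stage is validated against a
generator that emulates the acquisition protocol: 3 runs × 52 trials of
3.5 s, 23 jittered rests per run from {0.5, 4.5, 8.5, 12.5} s, TR = 2 s, 150
volumes per run, 30 subjects, ~94% accuracy, subject mean RT near 1696 ms
(between-subject SD 273 ms), within-subject RT SD near 380 ms, and a strong
positive correlation (0.84) between a subject's mean and SD RT.

Two protocol facts cannot hold simultaneously in the strictest reading: 23
rests with mean 6.5 s plus 182 s of trials overshoot a 300 s run by ~30 s on
average. Our convention: 22 interior rests are drawn uniformly from the four
durations but restricted, draw by draw, to durations that keep the remaining
trials (plus minimal remaining rests) inside the run; the 23rd rest is the
run tail, padded or truncated so the run is exactly `volumesPerRun * tr`.
This keeps "randomly intermixed" rests, the exact rest count and the exact
acquisition length; the realized rest-duration mix is consequently skewed
toward the shorter values late in a run.

Trial RTs are lognormal (right-skewed, positive; the moment inversion in
`lognormalFromMoments()` makes the realized mean controllable to within 5%).
RTs beyond the 3.5 s response window become no-response trials. Incorrect
and no-response trials are still *rendered* in the BOLD signal — the brain
responded — but are excluded from the analysis regressors and picked up by
the incorrect-trial nuisance; fitting without that nuisance measurably
biases the task beta, which is itself a test.

Voxel signal: `baseline * (1 + [betaTask*xTask + betaRt*xRt + drift]/100)`
plus AR(1) Gaussian noise (default 1% of baseline, lag-1 coefficient 0.3,
the minimal temporally correlated model) and a run-centered slow cosine
drift (default 0.5%). The rendered task and drift components are centered
within each run, so the run temporal mean is exactly `baseline` and the
PSC + GLM pipeline inverts the generator *exactly* in the noiseless case
(the run intercepts absorb the centering; the residual RT regressor is
run-centered by construction). This noiseless invertibility, to 1e-6 and in
practice to machine precision, is the generator's defining contract.

What the generator does not emulate: scanner artifacts, physiological noise,
spatial noise correlations (noise is voxel-independent; smoothness enters
only through the applied kernel), motion-correlated signal (available as a
stress-test option but off by default), and between-subject anatomical
variability. Passing tests therefore demonstrate the estimator and its
calibration under the stated noise model, not robustness to every property
of real data.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen as the smallest sizes at
which each property is meaningful: exact identities (orthogonality, oracle
equivalence, noiseless invertibility) use tiny grids (1–8³ voxels, 40–450
volumes); parameter recovery uses the full 3 × 150-volume protocol on an
8×8×8 grid with 30 subjects and planted betas 0.5 (task) and 0.3 (RT),
checked to within 2 cohort standard errors with smoothing off — smoothing a
piecewise-constant effect map attenuates boundary voxels by construction, so
kernel behaviour is tested separately (impulse FWHM, mean preservation).
Calibration uses two all-null 30-subject cohorts on a 10³ grid for the
voxel-level rejection rate at p < 0.005, and a 500-iteration Monte-Carlo
threshold on a 12×12×10 mask followed by 200 fresh null cohorts for the
familywise rate; the null subject maps there are white noise on the mask —
exactly the distribution the subject GLM produces under pure noise — with
the Monte-Carlo smoothness matched (FWHM 0) to the data smoothness. Cluster
labeling is checked exhaustively against brute-force flood fill on all 256
binary 2×2×2 fields and on hundreds of random 4³ and 6³ fields across
densities.

Other numerical conventions: the oversampling step must divide the TR so
stick functions land on grid points (onsets are rounded to the nearest fine
step); the HRF kernel is truncated at 32 s, where the unit-peak response is
~3e-15; regressor construction warns (all-zero regressor) when no trial
contributes; an identically zero canonical regressor makes residualization
fall back to run-centering with a warning; `alphaFwe` below `1/nIterations`
is rejected as an unresolvable tail; ties in the extent threshold resolve to
the smallest k meeting the bound, and a threshold one larger than anything
observed is returned when no k qualifies.

## Known limitations

Single-subject inference is not provided (no prewhitening, so subject-level
t-statistics would be optimistic); group inference is the supported path.
The Monte-Carlo threshold assumes stationary smoothness equal to the applied
kernel; a residual-smoothness estimator hook would be needed for real data
smoothed by acquisition. Peak coordinates are reported in the data's own
grid space — no template registration or anatomical labeling. The events
format follows the common neuroimaging events-table convention (onset and
duration in seconds, one file per run; response time in ms), chosen for
interoperability.
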
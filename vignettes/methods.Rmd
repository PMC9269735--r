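---
title: "Gait and balance features from wearable and mocap recordings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait and balance features from wearable and mocap recordings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsense)
```

## The measurement problem

Clinical gait and balance assessment traditionally relies on laboratory
instruments: a pressure-sensitive force plate and a full-body inertial
motion-capture (mocap) suit. A waist-worn smartphone records only one
tri-axial accelerometer near the body's centre of mass (COM), yet if the
same summary variables — stride time, cadence, gait velocity, postural sway
area and sway velocity — can be extracted from it reliably, gait monitoring
becomes possible outside the laboratory. `gaitsense` implements the two
extraction pipelines (smartphone acceleration and mocap positions), the
calibration procedure that tunes the smartphone step detector against
ground-truth stride timing, and the statistical layer that quantifies
between-system agreement and pre/post change. A synthetic-recording
generator with exactly known ground truth ties the pieces together so every
stage can be validated end to end.

## Smartphone pipeline

Raw acceleration is resampled to a common 100 Hz grid (devices record at
100–252 Hz; 100 Hz is the lowest rate encountered, and a fixed grid makes
thresholds in seconds map to fixed sample counts), then band-pass filtered
at 0.8–20 Hz. This band retains locomotor content while removing the
gravitational (DC) component and high-frequency sensor noise. The filter is
a 4th-order Butterworth applied forward–backward: the band edges are the
protocol's; family, order and phase handling are this package's choices,
zero-phase because it leaves peak times unbiased for step detection. Each
signal is reflect-padded by 1 s and demeaned before filtering to suppress
start-up transients, and the first/last second of a window is excluded from
peak statistics.

**Step detection.** Steps appear as peaks of the Euclidean norm of the
filtered acceleration. A sample is a step peak if it is a local maximum at
or above `mean + k_sd * SD` of the norm over the task samples, and at least
`min_dist` seconds from any taller accepted peak (greedy, taller peak wins,
ties keep the earlier peak — deterministic). The threshold is relative, so
detection is invariant to amplitude scaling. We read "SD relative to the
mean signal" as `mean + k·SD` of the filtered norm; since the filtered
signal has near-zero mean the alternative reading (k·SD about zero) is
close but not identical. Defaults are the calibrated task settings:
2.3 SD / 0.38 s for normal and backward gait, 2.7 SD / 0.42 s for tandem
gait.

**Stride metrics.** Inter-step times are successive peak differences;
a stride is two steps, so stride times are sums of adjacent inter-step
pairs; the mean stride interval (MSI) is their mean and cadence is the
inverse of the mean inter-step time. When lane windows are known (turns
identified), intervals are pooled within windows and never bridge a turn.

**Calibration.** `calibrate_grid()` scans peak height 1.5–3.0 SD in steps
of 0.1 and peak distance 0.20–0.44 s in steps of 0.02, computing for each
cell the Pearson correlation between detected and ground-truth MSIs across
the calibration recordings (one overall correlation per cell;
pairwise-complete when a cell loses recordings to sparse detection, flagged
below 3). The optimum is the cell with maximal correlation; exact ties go
to the smallest peak height, then the smallest distance.

**Velocity.** Acceleration is integrated to velocity and again to
displacement (trapezoidal rule, first point as reference), re-applying the
band-pass after each stage so residual gravitational and reintroduced
low-frequency content is removed. We interpret the re-filtering as
per-integration-stage, not per-footstep. Distance is the summed
point-to-point 3-D path length of the displacement — net displacement of a
band-passed signal is zero by construction — and mean velocity is distance
over duration. A single waist-worn sensor cannot observe true forward
progression once gravity and drift are filtered out, so this velocity is an
oscillation-based proxy: useful for correlation across subjects, biased in
absolute terms. Windows under 5 s are flagged unstable.

## Mocap pipeline

Input is 60 Hz pelvis + feet positions (x anterior–posterior, y
medial–lateral, z vertical); the pelvis approximates the COM.

**Lane splitting.** Walking tasks traverse the walkway back and forth, so
turning points sit at the extreme x positions. We smooth pelvis x with a
0.5 s moving average and cut at sign changes of its slope, discarding runs
whose x-extent is below 2 m (turn jitter). One metre is excluded at each
lane end ("the first and last meters") before feature extraction; both the
exclusion and the minimum extent are configurable.

**Drift correction.** Heading drift rotates a lane's apparent direction
away from the travel axis. Each lane is rotated in the x–y plane by the
angle aligning the pelvis net-displacement vector (first to last sample)
with +x; z is untouched and the angle is recorded. We use the net
displacement rather than a principal-axis fit — both agree on straight
lanes and the former is simpler and exactly invertible. Backward-direction
lanes come out facing +x as well, so downstream logic always sees forward
progression.

**Features.** COM step cycles are local maxima of pelvis z with a minimum
topographic prominence (default 0.005 m) and spacing (0.3 s; 0.45 s for
tandem, where steps are slow and deliberate) — fixed defaults replace the
original per-participant visual tuning, which is not reproducible
engineering. Lane velocity is endpoint displacement over elapsed time, and
the task velocity an unweighted mean over lanes (the protocol does not say
whether lanes were weighted; unweighted is the simplest reading). Step
width pairs each foot's vertical minima (mid-stance) by nearest time and
averages `|y_left − y_right|`.

## Balance features

Mocap stance tasks use pelvis x–y in mm: path length is the sum of
successive point distances, sway velocity path length over duration, and
the sway ellipse area `π · AP · ML` with AP/ML equal to half the x/y range —
the ellipse encloses 100% of the points axis-wise, which is why an
SD-based "sway" would not match the stated convention.

The smartphone's orientation is not fixed, so its sway is summarised in
3-D: acceleration → displacement via the same filtered double integration
(output in mm), then a principal component analysis of the displacement
cloud. The 95% ellipsoid has semi-axes `sqrt(qchisq(0.95, 3)) · σᵢ ≈
2.7955 σᵢ` along the principal axes and volume `(4/3)π · ∏ semi-axes`. The
chi-square quantile is a joint 95% statement; a per-axis `1.96σ` scaling
would differ only by a constant factor, and the constant used is recorded
in the output so volumes remain comparable. Smartphone sway is a volume in
mm³ while mocap sway is an area in mm² — the unit mismatch is deliberate
and preserved. Rank-deficient clouds yield volume 0 with a degeneracy flag.

## Statistical layer

Extreme outliers are values strictly above `Q3 + 3·IQR` — an upper-side
rule only; low outliers stay. Quartiles interpolate linearly between order
statistics (type 7), and the convention is recorded because the choice is
not standardised. Pre/post change is tested on paired differences:
Shapiro–Wilk (α = 0.05) gates between an ordinary paired t-test and a
Wilcoxon signed-rank test. The normality test and the decision to assess
differences rather than raw scores are this package's choices; Shapiro–Wilk
for its small-sample power. Significance uses the Bonferroni-corrected
level `α/m` with m the number of variables per system (4 with step width,
3 without); the reported thresholds round half-away-from-zero to three
decimals, which is what turns 0.0125 into 0.013 and 0.0167 into 0.017.
All-zero differences report statistic 0, p = 1, not significant.
Between-system agreement is the Pearson correlation over pairwise-complete
subjects, labelled by |r|: below 0.10 negligible, 0.10–0.39 weak, 0.40–0.69
moderate, 0.70–1.00 strong (negative correlations are classified by
magnitude; the taxonomy itself starts at 0.10).

## Synthetic recordings and what they do (and do not) show

The generator exists so that every stage has exactly known ground truth.

* **Gait acceleration** — inter-step intervals are Gaussian with mean
  `1/cadence` and SD `stride_cv/cadence` drawn per lane; each step places a
  raised-cosine burst (width 0.15 s, band-limited, peak exactly at the step
  time) on the vertical axis over a constant gravity offset and white
  noise. Two-second turns of irregular low-amplitude (0.3× burst) signal
  separate lanes and are flagged in the ground truth, so turn removal can
  be exercised. Defaults (cadence 1.7 steps/s, CV 3%, 10 m lanes at
  1.2 m/s, bursts 3 m/s² over 0.3 m/s² noise, 100 Hz) describe an ordinary
  walking task; raw smartphone signal morphology is not documented
  anywhere, so burst amplitude and noise level were chosen once for
  detectability rather than realism.
* **Mocap walk** — constant-velocity lanes with sub-millimetre lateral
  oscillation (lanes progress straight: net per-lane y-displacement stays
  below 1 mm), vertical COM cosine peaking at each step time, feet at
  `±step_width/2` with one vertical bump per stride (minima mark
  mid-stance). A configurable heading error rotates every lane about its
  start, emulating IMU drift.
* **Stance acceleration** — per-axis sway displacement is an analytic sum
  of eight random sinusoids in 1.2–2.0 Hz scaled to the requested SD; the
  recording is its exact second derivative plus gravity and noise, so the
  double-integration path has a closed-form oracle. The band sits inside
  the 0.8–20 Hz analysis passband: placing sway energy below ~1 Hz would
  conflate generator truth with filter attenuation (~30% at 0.9 Hz for the
  zero-phase filter) and make displacement recovery untestable. Real quiet
  stance has most energy below 1 Hz — recovered absolute sway magnitudes
  on real data will be attenuated accordingly, which is a property of the
  0.8 Hz high-pass edge, not of the geometry code.
* **Paired study** — per-subject baselines vary log-normally (CV 5%)
  around the base parameters; nominal T2 parameters are T1 scaled exactly
  by the configured effects, and each visit's realized recording
  parameters add within-subject log-normal variation (CV 2%).

Passing tests on these signals demonstrate that the algorithms recover what
they are defined to recover; they do not demonstrate robustness to soft
tissue artefact, device orientation changes mid-task, missing samples, or
pathological gait, none of which the generator emulates.

## Numerical choices and degenerate inputs

Filtering uses reflect padding (1 s) plus demeaning; integration is
trapezoidal with `out[1] = initial`; non-uniform time bases (beyond 5%
step deviation) are refused rather than silently interpolated. Peak
thinning and the grid tie-break are fully deterministic. Constant signals
yield no peaks; constant samples are "degenerate, not normal" in the
normality check; zero net lane displacement refuses alignment; trims that
empty a recording are errors. All generator randomness flows from one seed
per call (`withr::with_seed`), so equal seeds give byte-identical output
and studies are reproducible from a single master seed.

## Problem sizes used in validation

The shipped test-suite and acceptance script exercise: 20-seed cadence/MSI
recovery on 60 s walks; the full 16 × 13 calibration grid on 15
distinct-cadence noiseless recordings; drift angles −30°…30°; a
100 000-point Gaussian cloud for the ellipsoid closed form; 200 simulated
null studies (n = 21, four variables) for the type-I rate; 50 replicate
studies for the power of a 3% cadence effect at 2% within-subject SD; and
500 random arrays against an exhaustive peak-detection oracle. These sizes
were chosen as the package's own validation conditions and give Monte-Carlo
error well inside the asserted margins.

## Known limitations

Smartphone velocity is a path-length proxy (see above) and not comparable
in absolute terms to walkway-based velocity. The 95% ellipsoid scaling
constant is a convention; absolute volumes are comparable across
implementations only up to that constant. Lane splitting assumes
back-and-forth traversal along a dominant axis. No gyroscope or
magnetometer fusion is attempted, and mvnx/proprietary report parsing is
out of scope — recordings enter as plain CSV.
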
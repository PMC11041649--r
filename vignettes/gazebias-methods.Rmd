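---
title: "Gaze-bias analysis of covert attention in working memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-bias analysis of covert attention in working memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazebias)
```

## The scientific problem

When people hold two visual items in working memory — one encoded to the
left and one to the right of fixation — and a non-spatial retro-cue later
tells them which item will be probed, their fixational eye movements
betray the cued item's encoded location: small microsaccades become
directionally biased toward that side, even though nothing appears there
and location is never asked about. `gazebias` implements the complete
analysis chain for this phenomenon: from 1000 Hz binocular gaze traces
with event markers, through calibration-based normalization, epoching and
trial exclusion, to the *towardness* gaze-bias statistic, microsaccade
rate and magnitude analyses, cluster-based permutation inference and
Bayes-factor model comparison. Because human raw data cannot accompany a
software package, a generative simulator with full ground truth stands in
for participants, which makes every stage of the chain testable.

## Coordinate frame and preprocessing model

Gaze is expressed in *normalized units*: central fixation is 0 and the
centres of the two encoding positions map to -100 and +100, corresponding
to +/-8 degrees of visual angle (so 12.5 units = 1 degree). The mapping is
estimated per axis from seven-point calibration sweeps: the median
binocular gaze 400-1000 ms after each `CALIB_POINT` onset is regressed on
the nominal target coordinates, giving a per-axis affine
`normalized = gain * (raw - offset)`. Only the nominal coordinates are
assumed; the layout itself (centre, +/-100 horizontal, +/-60 vertical, two
diagonals) is a simulator choice.

Blinks are interpolated before anything else. Blink intervals (from
markers or runs of missing samples) are padded by 50 ms on either side —
eyelid closure corrupts samples before the signal is lost and after it
returns — and replaced by a natural cubic spline anchored on 100 ms of
clean samples on each flank. A cubic interpolant through collinear anchors
reproduces linear trends exactly, which the tests exploit as an oracle.
Gaps longer than 500 ms are treated as unrecoverable: they are filled by
nearest-value fill only so the series stays finite, and the affected
trials are flagged for gaze exclusion.

Epochs span -500 to 1500 ms (half-open) around each retro-cue onset and
are baseline-corrected by subtracting the per-trial mean over the 500 ms
before the cue, removing residual fixation offsets. The two eyes are
averaged per axis after interpolation; when one eye is missing the other
carries the estimate. The recording format never states a binocular
combination rule, so averaging — the variance-optimal choice for
comparable eyes — is used and documented here.

Two exclusion rules then apply. The *gaze rule* drops any trial whose
horizontal position exceeds 50 normalized units (4 degrees) at any sample
of the post-cue window `[0, 1500)` ms; pre-cue baseline noise is
deliberately not allowed to void trials, and whether the rule inspects
one or both axes is configurable (horizontal-only is the default, since
the design separates items horizontally). The *attentiveness rule*
iteratively removes trials whose response onset exceeds the mean + 4 SD
of the remaining trials, recomputing mean and SD after each pass until no
outlier remains. The rules are idempotent, and on default simulated
sessions total exclusion stays in the low single-digit percent range
typical of this paradigm. The magnitude-resolved saccade analysis
deliberately reuses the trials removed by the gaze rule (only the
attentiveness rule applies there), so that large gaze shifts can be
visualised rather than censored.

## The towardness statistic

For a set of epochs containing both cue sides,

\[ T(t) = \frac{\bar{x}_{\text{right-cued}}(t) -
              \bar{x}_{\text{left-cued}}(t)}{2}, \]

with rightward gaze positive, so positive towardness means gaze is biased
toward the cued item's encoded side regardless of which side that is.
Two exact symmetries are tested: flipping every cue label negates
\(T\!\), and so does mirroring the gaze itself. Scalar condition
contrasts average \(T(t)\) over the full post-cue delay `[0, 1500)` ms —
the window from cue onset to the end of the epoch is the only consistent
reading of "the entire delay period" given the epoch definition.

## Microsaccade detection and rate analysis

Velocity is estimated with a 5-sample symmetric difference filter, and a
trial-adaptive threshold is set per axis at \(\lambda = 5\) times a
median-based (outlier-resistant) velocity SD, combined elliptically
across axes — the standard Engbert-Kliegl-style scheme. Supra-threshold
runs closer than 20 ms are merged, runs shorter than 6 ms discarded,
events overlapping the epoch edges dropped (their displacement is
undefined), and only events with horizontal displacement magnitude above
1 normalized unit are kept. All of these are configuration keys: the
underlying study describes its detector only as velocity thresholding, so
the parameters are documented free choices rather than reproductions.

Saccade onsets are accumulated per 1-ms bin across trials, converted to
Hz, and smoothed with a 100 ms moving average implemented as
mass-conserving spreading: each count is spread uniformly over its
(edge-truncated) 100-ms window. Away from the edges this equals the usual
centred moving average, but unlike a shrinking-window average it
preserves the time-integral exactly, so `sum(rate) * dt` always equals
events per trial — an invariant the tests assert to machine precision.
The *saccade effect* is the toward-minus-away rate; the magnitude-
resolved map repeats this per saccade-size bin (half-open bins from 2 to
110 units in steps of 4).

## Group inference

**Cluster-based sign-flip permutation test.** Per-sample paired t
statistics are thresholded two-sidedly at the cluster-forming alpha
(0.05, i.e. \(|t| > t_{0.975,\,n-1}\); the threshold is configurable
because toolbox defaults vary), contiguous supra-threshold samples form
clusters scored by their summed t, and the null is built by randomly
sign-flipping the participant difference curves (10,000 permutations by
default), keeping the maximal cluster mass of each sign per permutation.
Each sign is evaluated at alpha 0.025. Monte-Carlo p values follow the
\((b+1)/(m+1)\) convention; for small groups an exhaustive mode
enumerates all \(2^n\) sign patterns, and the tests verify that the
Monte-Carlo p converges to that exact p and that the familywise error
over simulated null groups sits inside the binomial confidence band of
0.05.

**JZS Bayes factors.** The default-prior Bayes factor for a one-sample t
test places a Cauchy(0, r) prior on the standardized effect, computed by
writing the Cauchy as a normal mixed over an inverse-gamma(1/2, r²/2)
variance and integrating the resulting one-dimensional marginal
likelihood ratio by adaptive quadrature on the log-substituted mixing
variable (relative tolerance 1e-8, so two-decimal reporting is stable).
The package reports `bf01`, evidence *for* the null, which is how the
underlying study interprets its values even while labelling them BF10;
`bf10 = 1/bf01` is always attached. The sensitivity analysis recomputes
the factor at scales r = 0.5, 0.707, 1 and 2. An independent oracle in
the test suite integrates the noncentral-t likelihood over the Cauchy
prior directly and agrees to five decimals.

**Power sensitivity.** The minimal detectable effect size solves
\(\text{power}(d) = 0.80\) for a two-sided paired t test on the
noncentral t distribution by monotone root-finding; at n = 25 and alpha
0.05 this gives d = 0.584, cross-checked against `stats::power.t.test`
and by Monte-Carlo rejection rates.

## The synthetic generator: what it emulates, and what it does not

Each simulated session contains per-block seven-point calibration sweeps
and the full trial structure of the paradigm: variable intertrial
interval (500-800 ms), two 250 ms encoding frames separated by 750 ms,
a 250 ms retro-cue 1250 ms after the second frame, a second 1250 ms
delay, then the response period. Experiment 1 has 500 trials in 10 blocks
of 50, five presentation subtypes (three simultaneous, two sequential)
in equal numbers; Experiment 2 has 480 trials in 10 alternating colour
and order blocks. Cue sides are balanced within condition.

Gaze is modelled as Ornstein-Uhlenbeck fixational drift plus white
per-eye measurement noise plus a microsaccade process: Poisson onsets at
1.5 Hz, lognormal amplitudes (median 5 units, sdlog 0.6 — about 94%
below 1 degree), and a smooth raised-cosine displacement waveform over
20 ms whose velocity peaks mid-flight, so a velocity-threshold detector
sees one clean pulse per event. After the cue, each saccade's direction
is toward the cued side with probability following a raised-cosine bump:
0.5 until 300 ms, peaking at 0.75 at 600 ms, back to 0.5 by 800 ms.
Every saccade spawns a return saccade toward fixation after an
exponential delay (mean 100 ms), which keeps simulated gaze stationary
and produces the late away-directed rebound in the rate contrast. The
return delay and the decay width of the bias bump were fixed once, by
reasoning about the convolution of the direction-bias profile with the
exponential return kernel: a position bias is the integral of recent
unreturned displacements, so its peak lags the direction-bias peak by
roughly the mean return delay, and a short delay with a 200 ms decay
keeps the emergent towardness peak at the empirically reported ~600 ms.
Longer return delays (several hundred ms) would separate the positive
and negative lobes of the rate effect more cleanly but displace the
towardness peak toward 750-800 ms; with the short default the two lobes
partially cancel, which is the main respect in which the simulated rate
contrast is weaker than real data.

Blinks arrive as a Poisson process (0.1 Hz, 150 ms), blank all four
channels, and corrupt 50 ms pads on either side with eyelid-artifact
ramps, exercising the padded interpolation. Raw tracker units are
produced by inverting a per-axis affine (gain 0.05, offsets 512/384), so
calibration recovery can be scored against the generating parameters.
Orientation reports are the target plus Gaussian noise (SD 17 degrees,
mean absolute error about 13.6 degrees in the 180-degree circular space,
comfortably above the 45-degree chance level); response onsets are
lognormal around 220 ms.

Ground truth records every injected saccade (onset, displacement,
toward/away/base/return label), every blink, and the affine, so detector
recall, direction tallies and the event-based towardness prediction can
be scored without re-simulation. One deliberate symmetry is built in:
regenerating a session with all cue sides flipped consumes the identical
random stream and negates exactly the displacements of direction-biased
saccades, leaving everything else untouched.

What the generator does *not* emulate: main-sequence kinematics,
saccadic suppression, binocular disconjugacy, pupil dynamics, vertical
bias structure, or slow oculomotor nonstationarities. Passing tests
therefore demonstrate that the pipeline recovers what was injected under
realistic noise — not that real human data would show these effects.

## Numerical choices and problem sizes

All times are integer milliseconds on the 1000 Hz grid; intervals are
half-open `[start, end)`; time 0 is cue onset; rightward/upward are
positive. The recording dialect quantizes samples to four decimals on
write, which makes write-read-write byte-stable. Permutation draws are
seeded explicitly and restore the caller's RNG state, so pipelines are
bytewise reproducible end to end. Degenerate inputs fail loudly:
calibration with collinear targets, towardness with a single cue side,
zero-variance paired differences, exclusion of every trial.

The test suite and examples run reduced problem sizes chosen to keep the
full suite in a few minutes while leaving the assertions well-powered:
sessions of 40-100 trials, groups of 6 participants for morphology
recovery, 200 simulated null groups at 1000 sign-flips for the
familywise-error calibration, and 20,000 permutations where Monte-Carlo
p values are compared with exhaustive enumeration. The statistical
reproductions (power solver, Bayes factors, Cohen's d) are analytic and
run at full precision.

## Known limitations

* The saccade detector's parameters (lambda = 5, 6 ms minimum duration,
  20 ms merge) are defensible defaults, not fitted values; overlapping
  saccade-return pairs closer than the merge window are unresolvable by
  construction and are excluded from recall scoring.
* The magnitude-resolved map is reported descriptively; no 2-D cluster
  inference is provided.
* Towardness scalar contrasts assume the two conditions share the epoch
  grid; resampling across different rates is out of scope.
* The generator's condition labels carry no true effect difference, so
  condition contrasts on simulated data exercise the null path (as in
  the empirical finding they emulate); injecting condition differences
  requires two configs and manual stacking.
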
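---
title: "The two-phase rest/sleep model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-phase rest/sleep model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysleep)
```

## The model

A resting fly is in one of two behavioral phases. During the *sleep
latency* phase the probability of resuming movement falls with the time
already spent resting: the survival function of rest-bout durations is a
power law,
$$P(X > t) = \left(\frac{t}{x_{\min}}\right)^{-\beta}, \qquad x_{\min} \le t \le K,$$
with $\beta$ the **active index**. Past the changepoint $K$ (the **sleep
latency**) the fly is asleep and wakes with a constant, memoryless rate:
$$P(X > t) = P(X > K)\, e^{-(t - K)/\lambda}, \qquad t > K,$$
with $\lambda$ the mean **sleep duration**. The implied rest-to-move switch
rate (hazard) is $w(t) = \beta/t$ in the latency phase and $w(t) =
1/\lambda$ in the sleep phase — `switchRate()` computes exactly this. With
the count $N$ of bouts exceeding $K$ and $\mathrm{Total} = N \lambda$, the
five quantities $(\beta, K, \lambda, N, \mathrm{Total})$ summarise one
fly's sleep architecture in one circadian phase. Total deliberately
excludes time spent in the latency phase.

### Which quantity is glued continuously at K

The two-branch law can be made continuous at $K$ either in the survival
function or in the density; the two choices are different distributions
unless $\lambda = K/\beta$. We glue the **survival function** (the form
above). This is the only choice under which the head survival is exactly
$\propto t^{-\beta}$ (log–log linear) and the switch rate is exactly
$\beta/t$ then $1/\lambda$; the price is a density jump at $K$, which is
invisible to every statistic the pipeline uses. Gluing the density instead
adds a constant to the head survival, so the head is no longer log–log
linear near $K$ and the hazard deviates from $\beta/t$ by tens of percent
for realistic parameters ($K = 200$ s, $\lambda = 1000$ s). The
density-continuous variant remains available via
`sampleTwoPhase(..., continuity = "density")` for sensitivity analyses.

### Conventions that are easy to get wrong

* $\beta$ is the **survival** exponent. Off-the-shelf power-law fitters
  (and the continuous MLE inside `fitActiveIndex()`) estimate the
  *density* exponent $\alpha = \beta + 1$; the package converts before
  reporting.
* The head MLE is a Pareto likelihood **truncated to $[x_{\min}, K]$**,
  solved numerically. The closed-form Hill/Clauset estimator assumes an
  unbounded tail and overestimates $\beta$ badly when $K/x_{\min}$ is only
  ~50–100, which is exactly the regime here.
* By default the head is fit on $[x_{\min}, \hat K]$ (`head_mode =
  "truncated"`), which keeps exponential-tail samples out of the power-law
  fit; `head_mode = "pooled"` (all durations $\ge x_{\min}$, untruncated
  MLE) is kept for sensitivity checks.

## Fitting procedure and its statistical character

`findSleepLatency()` scans candidate changepoints upward from
`scan_start = 50` s. The candidate grid is `scan_start` followed by every
unique observed duration above it, so each candidate changes the tail set
and the scan is deterministic and exhaustive; the grid stops when fewer
than `min_tail = 10` excesses remain. At each candidate $K$ the excesses
$X - K$ are tested against an exponential with mean estimated *from the
same excesses* (one-sample KS, asymptotic p-value); the smallest candidate
whose test fails to reject at the 10% level is $\hat K$, and the mean
excess there is $\hat\lambda$.

Estimating the exponential mean from the tested sample makes this KS test
conservative (the Lilliefors effect), and testing many candidates gives
early candidates repeated chances to be accepted. Both effects bias
$\hat K$ (and hence $\hat\lambda$) somewhat low: on synthetic data with
$K = 200$–$300$ s and $\lambda = 1000$ s the median $\hat K$ sits roughly
10–20% below the generating value, comfortably inside the ±25% band the
recovery checks use. We reproduce this procedure as published rather than
correcting it; a Monte-Carlo–calibrated variant would recover $K$ with
less bias but would no longer be the same estimator.

The lower bound of power-law behavior is fixed at $x_{\min} = 3$ s for
fitting. Durations shorter than the 1 s detection floor never reach the
fitter; whether sub-3 s rests follow the same law is not testable from the
data this pipeline targets, so the generator supports `xmin` down to 1 s
and the fitter simply ignores the 1–3 s range.

Frame-grid quantization produces ties that a continuous MLE/KS machinery
dislikes; `fitSleepModel(dequantize = TRUE)` (the default) adds
$U(0, 1/\mathrm{fps})$ to tied samples before fitting. This is a no-op for
continuous synthetic samples.

The tail-model diagnostic `tailAICCompare()` fits the excesses by maximum
likelihood under an exponential and under a half-gaussian (a gaussian
decay law restricted to positive excesses), one free parameter each, and
reports $\Delta\mathrm{AIC} = \mathrm{AIC}_{\mathrm{gauss}} -
\mathrm{AIC}_{\mathrm{exp}}$; positive values support the memoryless sleep
phase. With a few hundred excesses the discrimination is essentially
certain; below ~50 excesses the sign is right in only ~80% of replicates,
which is why property checks use 1000 excesses.

## The synthetic-data generator

`sampleTwoPhase()` draws i.i.d. durations by inverse-CDF sampling of the
two-phase law (tested against an independent rejection sampler).
`makeTrajectory()` embeds those rest durations in an alternating move/rest
trajectory: movement is waypoint walking at constant speed toward
uniformly drawn interior targets; active-bout lengths are log-normal
(movement is a spacer, not part of the fitted model, so its law is a free
choice); rests hold position with per-frame noise uniform in a disk of
radius `jitter_px`. Defaults: 25 fps; 1D chamber 5 × 78 mm (2D ellipse
50 × 30 mm) at 1.25 px/mm; walking speed 30 px/s (24 mm/s, a brisk but
realistic pace); jitter 0.5 px of sub-pixel centroid flutter. Rest
durations are quantized to the frame grid and the planted list
(`bouts_truth`) records onset, duration and anchor on that grid; rests are
planted so the fly stops one stride away from its last walking frame,
making the anchor a genuinely new location. A trailing rest that does not
fit in the recording is replaced by movement, so the planted list contains
only complete bouts (a mild censoring of long bouts in short recordings —
fitting tests therefore use `sampleTwoPhase()` directly).

`renderFrames()` draws the fly as a bright disk on a dark chamber interior
with a brighter surround, which is the geometry the masking step assumes.
The renderer is noiseless by default (`noise_sd = 0`); synthetic frames
therefore have exact zero differences where nothing moved, which real
sensors never produce. What passing round-trip tests show is that the
geometry pipeline (render → track → extract) is self-consistent to
sub-pixel accuracy; they do not certify performance under real sensor
noise, compression artifacts, occlusion or multi-fly scenes.

## Tracking design choices

* Background: pixel-wise mean of the first frame of each hour (per light
  phase on long recordings; `bg_sample_s` shortens the interval for short
  clips so the background averages over several fly positions).
* Chamber mask: grayscale morphological opening (disc, radius 3 px by
  default — larger than the fly) removes residual fly brightness; the mask
  is the largest connected region darker than the mid-range threshold.
  An empty or uniform image raises "chamber not found".
* Detection: among in-mask pixels, the 100 largest *positive*
  frame-minus-background differences (ties at the cutoff all included, for
  order-independence) are binarized; the centroid of the largest
  8-connected component is the fly. Restricting to positive differences
  matters on noiseless synthetic frames, where the zero-difference
  background would otherwise tie into the candidate set.
* Missing detections (maximum difference below `noise_floor = 5` gray
  levels) carry the last known location forward — a stationary,
  undetectable fly must accumulate rest time, not gaps. Leading gaps are
  back-filled from the first detection.
* The virtual DAMS beam is the midline of the chamber's long axis; a
  crossing is a sign change of $y - \mathrm{midline}$ between consecutive
  off-midline frames.

Rest bouts are maximal runs of frames within `tol_px` of the run's *first*
frame (the anchor). An anchor-based tolerance cannot mistake slow drift
for rest, unlike frame-to-frame displacement. With centroid flutter of
radius $j$ and tracking error $e$, any `tol_px` $\ge 2(j + e)$ keeps a
bout in one piece; `tol_px = 1` suits clean trajectories and `tol_px = 2`
tracked video at the default jitter. Bouts spanning a light transition
keep their onset phase label. Under constant darkness, phase labels follow
the hypothetical entrained light schedule.

## The brain-state random-walk model

Each hemisphere occupies one of $L$ quietness states ($L = 50$ by
default); the joint state $(i, j)$ performs a nearest-neighbor random walk
with exponential dwell times of mean $\theta = (i^2 + j^2)^{a/2}$ —
quieter states are slower to leave. A bout ends when either hemisphere
reaches state 0. Beyond a distance threshold $w$ from the origin the fly
is asleep and additionally wakes at constant rate $\varepsilon$. Choices
the source description leaves open, and what we picked:

* **Start state** $(1, 1)$: the walk must start inside the rest space, and
  the state adjacent to the wake boundary is the natural entry point from
  movement.
* **Moves**: von Neumann steps (±1 in one coordinate), uniform over
  admissible moves, reflecting at $i$ or $j = L$; steps onto the boundary
  are what ends the bout.
* **Sleep dynamics**: by default the walk continues past the threshold
  (it may re-cross inward) while an independent $\varepsilon$ clock runs
  only inside the sleep region (`sleep_dynamics = "continue"`). The
  simpler variant — absorb at the first crossing and add an
  $\mathrm{Exp}(1/\varepsilon)$ sleep time — is `"absorb"`. Only under
  `"absorb"` is the sleep tail exactly exponential with mean
  $1/\varepsilon$; under `"continue"` re-crossings shorten it.
* **Threshold metric**: Euclidean distance from the origin by default
  ("distance" reading); `"manhattan"` ($i + j$) is available.
* **Units**: $\theta$ in seconds, $\varepsilon$ in 1/s; no further
  calibration is attempted. $\varepsilon = 10^{-3}$/s puts the sleep
  duration near the observed $\lambda \approx 1000$ s.

`meanFirstPassageOracle()` solves the absorbing-chain linear system
exactly on lattices up to $L = 12$ and is the independent check of the
Monte-Carlo simulator (the C++ walker and the dense solve share nothing
but the model definition). `sweepParameters()` maps $(a, w)$ to fitted
$(\hat\beta, \hat K, \hat\lambda)$ and flags cells whose latency falls in
the experimentally observed 80–300 s band; with $a \in [0.2, 1.2]$,
$w \in \{10, 20, 30, 40\}$ and $\varepsilon = 10^{-3}$/s the feasible set
is non-empty and includes cells with $\hat\beta$ in the observed 0.7–1
range.

## Summary statistics

Sleep and activity profiles live on the 30-minute Zeitgeber grid and are
averaged across recording days before any across-fly averaging. A bout
qualifies as sleep when its duration exceeds a threshold — the fly's own
fitted $K$ by default; passing 300 s reproduces the legacy 5-minute
convention — and contributes its full span proportionally to the bins it
covers. Parameter correlation structure uses tie-corrected Spearman rank
correlations with average-linkage clustering on $1 - \rho$ (the linkage is
our choice; constant columns are flagged and treated as maximally
distant). Group comparisons are two-tailed two-sample t tests, Welch by
default, Student's under `equal_var = TRUE`. The sleep-history check
correlates each sleep bout's sleep-phase time ($X - K$) with the sleep
accumulated before its onset, and consecutive 12 h day/night totals with
each other; under the memoryless model all of these hover near zero.

## Problem sizes and numerical choices in the test suite

Property checks run at sizes chosen to make Monte-Carlo noise small
relative to the tolerances they assert: 5,000 durations per fit for
recovery checks (150 replicate scenarios for the random-parameter
recovery medians and the latency hit rates, so the estimated median and
rate are stable), $10^6$ durations for the numerical hazard check,
$10^5$ bouts per configuration for simulator-vs-oracle comparisons, and a
10-minute, 10 fps, reduced-resolution clip for the imaging round trip.
Statistical tests on null hypotheses that are true by construction are
given a single replication step before being declared failures, keeping
the false-alarm rate of the suite low without losing power against real
defects.

## Known limitations

* The tracker is single-fly, single-chamber; there is no identity
  management, posture, or ceiling-walking detection.
* The latency scan inherits the conservatism discussed above; $\hat K$
  and $\hat\lambda$ are 10–20% low at realistic sample sizes. Comparisons
  between groups fitted with the same procedure are unaffected in
  practice, but absolute values should be read with that bias in mind.
* The generator's movement model (waypoint walking, log-normal active
  bouts) is a convenience, not biology; only the rest-duration law is
  meant to be realistic.
* `sleepHistoryCorrelation()` needs uninterrupted recordings; gaps are
  not modeled.
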
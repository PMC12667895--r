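---
title: "Pose-track behavioral metrics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pose-track behavioral metrics: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prelever)
```

## The problem

In rodent cocaine self-administration experiments instrumented with
overhead video and markerless pose estimation, every 30-minute recording
yields a per-frame table of keypoint pixel coordinates (nose, ears, neck,
paws, tail base, a back-mounted catheter port, the two levers, and the cue
light). During self-administration sessions the levers extend into the
chamber only after the first 15 minutes, so the first half of each
recording captures *pre-lever* behavior: what the animal does in the drug
context before any drug is available. Two pre-lever readouts operationalize
incentive salience — the motivational pull of the drug-associated context:

* **locomotion**: total distance traveled by the catheter node (the most
  reliably tracked body point), in meters;
* **active lever entrances per meter**: nose entrances into a box around
  the active lever, normalized by locomotion so that seeking is corrected
  for general activity.

A separate probe — noncontingent sessions with Baseline, Saline, and Drug
phases of 30 minutes each — measures the psychomotor response to a fixed
experimenter-delivered dose, from which each subject is labeled as
expressing **sensitization** (locomotor response grows with drug history)
or **tolerance** (it shrinks). `prelever` implements the full path from
raw coordinate tables to these subject-level scores, together with the
session-design arithmetic (timeline, dosing, progressive-ratio schedule,
footshock contingency) and a synthetic-data generator that makes the whole
pipeline testable without any raw video.

## From pixels to metrics

**Repair.** Missing detections are linearly interpolated per node and
axis over the frame index; missing runs at the edges hold the nearest
observed value. A node never observed in a file is irreparable and the
file is skipped with a logged reason.

**Calibration.** The cm-per-pixel factor is the mean of per-measurement
ratios `known_cm / measured_px` over the supplied chamber measurements
(two lengths, three widths in the standard setup, about 0.111 cm/px).
Averaging ratios rather than dividing summed quantities tolerates mixing
measurements of different physical sizes, which matters under fisheye
barrel distortion. The alternative convention can be supplied by passing a
single pooled measurement.

**Alignment.** Lever-session recordings are split at the lever-extension
frame into a pre-lever and a post-lever segment of `segment_min` minutes
each (default 12.5 at 10 fps; the trim relative to the nominal 15 minutes
absorbs ragged recording edges and is configurable). A side with too few
frames is truncated with a logged warning, never a hard failure, so one
short recording cannot abort a cohort run.

**Smoothing and distance.** Positions are smoothed with a centered
10-frame moving average before path-length accumulation; frame-level
keypoint jitter otherwise inflates distance traveled. We smooth positions
and then sum Euclidean steps (rather than smoothing a step-length series)
because position averaging is what actually cancels zero-mean jitter; by
the triangle inequality it can only shorten a path, a property the test
suite asserts on arbitrary inputs. The window is fixed in frames and the
frame rate is configurable; at the default 10 fps a 10-frame window spans
one second.

**Zones and entrances.** The lever zone is an axis-aligned box of
half-extents 30 px (x) and 18 px (y) centered on the per-session median of
the tracked lever coordinates — the lever is static, so the median resists
tracking jitter. Membership is boundary-inclusive (deterministic on
integer pixels). An entrance is an outside-to-inside transition of the
nose between consecutive frames; a series that starts inside counts
nothing until it first exits, since entrances are events and the pre-lever
segment begins mid-exploration. Entrances are counted on raw nose
coordinates by default (`smooth_entrances` switches this), as smoothing
near a boundary can suppress genuine crossings. Below 0.01 m of locomotion
the per-meter rate is returned as `NA` and excluded (not zeroed) from
downstream summaries.

## Subject-level scores

**Composite pre-lever score.** For each subject, pre-lever locomotion and
entrances per meter are averaged over Short Access sessions 07–09 (the
scoring window is configurable), each mean is standardized across the
cohort, and the two z-scores are averaged. Subjects at or above the cohort
median composite are labeled High, the rest Low; ties sit with High. With
n distinct composites the split is ⌈n/2⌉ against ⌊n/2⌋ — 19/18 for a
37-subject cohort. Missing window sessions are averaged over whichever of
the three exist (and the realized count reported) rather than dropping the
subject. A cohort with zero variance in either variable has no meaningful
z-score and raises a degenerate-cohort error.

**Sensitization/tolerance.** Noncontingent Drug-phase locomotion is
expressed as percent change from the first Drug session; subjects whose
third Drug session is above that baseline are labeled Sensitization, below
it Tolerance. An exact zero change or a missing session leaves a subject
Unclassified — the definition covers only increase and decrease, and we do
not guess.

**Abstinence.** The gap between one session's end and the next session's
start maps to the categorical codes 18, 66, and 90 hours (consecutive
days, two-day weekend, three-day weekend) when within ±6 h of an anchor,
else `other`. The band absorbs session-length arithmetic: 2-hour sessions
on consecutive days at fixed start times produce 22-hour gaps that are
still, categorically, consecutive days. Contiguous recordings (the three
phases of one noncontingent session) are not abstinence intervals and are
skipped.

**Winsorization.** Dependent variables can be capped at the cohort's 95th
percentile (linear-interpolation empirical quantile, R type 7 — the
convention is configurable because several exist) before export; only the
upper tail is capped, so minima and the ranks of uncapped values are
untouched.

## Session-design arithmetic

The canonical timeline holds 30 self-administration sessions (10 Short
Access of 2 h, 15 Long Access of 6 h, one Preshock and one Shock of 1 h,
three Progressive Ratio of 6 h) on Monday–Friday slots, interleaved with
three noncontingent blocks of three 30-minute phases. Three anchors are
fixed: the first noncontingent block precedes Short Access 01, the second
follows Short Access 09, the third follows Long Access 14; other
placements are label-driven from the manifest. One holiday Monday is
placed before the closing Preshock/Shock/Progressive-Ratio week so the
schedule exhibits a three-day weekend alongside its ordinary two-day
weekends; the published timeline figure marks such gaps without fixing
their calendar dates, so the placement is a package choice.

The progressive-ratio requirement for the n-th infusion is
5·e^(0.2·n) − 5, rounded to the nearest integer and floored at one
response — response counts are integers and the first infusion must be
attainable (the continuous curve gives ≈1.11 at n = 1). The breakpoint is
the last completed ratio before a 60-minute period with no completion; the
window is also checked between the final completion and the session end so
that simulated or truncated logs that did not terminate at the lapse are
still scored. Infusion dosing (0.5 mg/kg self-administered over 6 s with a
20 s timeout; 1.5 mg/kg noncontingent, a 3× ratio) and the 30% footshock
pairing at 0.3 mA for 0.5 s are package constants, overridable through
`drug_config()` and `shock_config()`.

## The synthetic rat

`simulate_trajectory()` generates the catheter anchor as a correlated
random walk: heading is the normalized blend `rho * h(t-1) +
(1 - rho) * noise`, steps are exponential with mean `step_scale *
locomotor_gain` px/frame, and chamber walls reflect. Two planted knobs
drive the phenotypes the scores must recover:

* `lever_attraction` (λ) controls *seeking bouts*: while exploring, a bout
  starts with per-frame probability λ/50; during a bout a drift term
  (weight 0.8) points the heading at the active-lever zone center and the
  mean step length rises 1.5×; the bout ends on arrival within 30 px.
  Bouts rather than continuous drift are essential: a continuously
  attracted walker parks in a tight oscillation at the lever, which the
  10-frame smoother collapses, and measured locomotion then *drops* with
  attraction — the composite's two z-scores cancel and planted groups
  become unrecoverable. Discrete approach bouts with a speed premium make
  attraction express in both entrances and locomotion, the coupled
  phenotype observed in high-salience animals and the structure the
  composite score assumes.
* `locomotor_gain` (g) scales step length — the drug-state and
  sensitization proxy. Planting g ratios of 1.5 vs 0.6 between the first
  and third Drug phases separates Sensitization from Tolerance labels
  with at most one error per 20-subject replicate in the test suite.

Body nodes ride as rigid offsets from the anchor in the heading frame
(nose 18 px forward, etc.) with 0.5 px Gaussian jitter; lever and cue
nodes are static with jitter; detections drop out i.i.d. per node-frame at
`dropout_p`. Whole-file failures (catheter or IR disconnection in the real
apparatus) are emulated separately by an exclusion list in
`fixture_spec()`: flagged files are written but skipped, with a logged
count, by `run_metrics()`.

Defaults emulate the study conditions: 10 fps, 30-minute recordings
(18,000 frames) with lever extension at the 15-minute mark, a 270 × 162 px
chamber at ~0.111 cm/px, 37-subject cohorts over the canonical timeline,
and Poisson press streams pushed through FR1 or progressive-ratio
schedules honoring the 26 s pump-plus-timeout lockout. Baseline
`persistence` 0.7, `step_scale` 3 px/frame (~20 m per 12.5-minute
pre-lever segment) and `dropout_p` 0.02 were chosen once as realistic for
chamber locomotion and detection reliability of a well-trained pose model.

What the generator does *not* emulate: thigmotaxis and corner preference,
rearing and grooming bouts, stereotypy, pharmacokinetic within-session
dynamics, or inter-individual baseline variation (unless planted through
`param_fn`). Passing recovery tests therefore show that the measurement
pipeline extracts planted effects of realistic size from realistically
noisy tracks — not that the generator reproduces the published group
means, whose raw data are unavailable.

## Statistical utilities

Correlations are gated on normality: Shapiro–Wilk on each variable, and
Pearson only when both pass at α = 0.05 (the conservative both-pass
reading; the gate α and rule are arguments). `shapiro.test()` accepts at
most 5000 points, so longer vectors are gated on a deterministic evenly
spaced subsample. Spearman p-values use the large-sample t approximation,
with an exact mode behind a flag for n ≤ 10. Benjamini–Yekutieli
adjustment (valid under arbitrary dependence) is applied across each
correlation table. Power-transform selection maximizes the Box-Cox or
Yeo-Johnson profile log-likelihood on a λ grid over [−2, 2] with step
0.01, refined by golden-section search — the grid bounds and step are
stated here because only the selection criterion, not its tolerance, is
conventional. Mixed-effects modeling, Type III tests, and marginal-means
contrasts are deliberately out of scope: the pipeline exports tidy tables
for those fits rather than re-implementing routine package statistics.

## Numerical choices and degenerate inputs

* Track files serialize coordinates with 17 significant digits, so a
  write/read round trip is bit-exact; empty fields are missing detections
  and zeros are data.
* The moving average shrinks symmetrically at series edges, keeping each
  output centered on its frame.
* Median ties in the High/Low split go High; exact zero deltas in
  expression labeling go Unclassified.
* `entrances_per_meter` guards division with ε = 0.01 m; undefined rates
  propagate as `NA` and are excluded, with counts, from summaries.
* Occupancy grids clip out-of-bounds positions onto the boundary and
  count them, so bin totals always equal frames tallied; grids with equal
  edges add bin-wise for session overlays. For display the y axis should
  be flipped (video origin is top-left).
* Per-file fixture seeds come from a stable 31-bit polynomial hash of
  (master seed, subject, session label), so any single file can be
  regenerated in isolation.

## Problem sizes in the test suite

The suite favors a few deep, parameterized checks. Entrance counting is
compared against a literal state-machine oracle on 10^4 random
trajectories; path shortening under smoothing on 500 mixed-regime series;
planted λ-group recovery on 50 replicates of 20 subjects × 3 sessions at
7,500 frames per segment (the full pre-lever length); sensitization
recovery on 20 replicates at 3,000 frames; the shock-pairing rate on
>10^4 simulated infusions; and the full-scale file-count check generates
all 1,443 files with 24-frame tracks, since the count, not the track
length, is under test. These sizes are the package's choices for a
thorough default run; every simulation is seeded and none is gated on
environment variables.

## Known limitations

* Only the delimited-text track dialect is read; the manifest and
  pipeline are format-agnostic, so an HDF5 reader would slot in behind
  `read_track_csv()`'s interface.
* Zone geometry is axis-aligned; rotated chambers require rectified
  coordinates upstream.
* The generator's bout model has a single attraction target (the active
  lever); inactive-lever entrances arise only from undirected wandering,
  which is sufficient for the per-meter contrasts the tests exercise but
  underestimates investigative checking of the inactive lever.
* Printed degrees of freedom in published correlation tables of this
  design can reflect model-derived bookkeeping that a plain
  correlation cannot reproduce; `choose_and_correlate()` reports its own
  n alongside the estimate.
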
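---
title: "Detecting honeybee encounter behaviours from barcode tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting honeybee encounter behaviours from barcode tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(beetrax)
```

# The problem

Worker honeybees interact through short head-to-head contacts in which
their antennae touch: antennation, begging, offering and trophallaxis.
Collectively these are *encounter behaviours* (EB); everything else a
worker does on the comb (sitting, walking, grooming) is *non-encounter*
(NEB). Encounters are frequent, brief and performed by every bee in the
colony at once, which makes exhaustive manual annotation from video
impractical. With tag-based tracking, however, each bee's position and
body orientation are available at 4 frames/s, and the encounter
configuration — two bees facing one another head to head at antennal
range — is largely visible in those trajectories.

`beetrax` turns tracking tables into per-frame EB/NEB scores, bouts, and
duration statistics. This vignette records the models behind each stage,
the parameters that matter, the numerical conventions, and what the
synthetic testbed does and does not demonstrate.

# Data model and conventions

A tracking table has one row per *detection*: `bee_id`, `frame` (0-based),
`time` (UNIX seconds at 0.01 s resolution), `x`, `y` (mm, origin at the
top-left of the comb image, y downward), `orientation` (degrees in
[0, 360), 0° along +x, counter-clockwise). Missing detections are absent
rows, never sentinel values — this is what makes a per-frame *detection
rate* well defined. Label intervals are inclusive frame spans
`[start_frame, end_frame]` attached to a focal bee (and optionally a
partner), so an interval of `k` frames lasts `k / fps` seconds. The
default arena is 370 × 200 mm, one side of a standard one-frame
observation comb; it is configurable everywhere.

Files are delimited text (comma by default, tab accepted) with a header.
The writer emits time at 0.01 s, coordinates at 0.001 mm and orientation
at 0.001°; the simulator quantises its output to the same grids, so
write → read is an exact identity on everything the package produces.

Gap interpolation (`interpolate_gaps()`) linearly fills positional gaps of
at most `max_gap` frames and interpolates orientation along the shortest
circular arc; inserted rows are flagged `synthetic`. It is **off by
default**: the postprocessing applied by upstream tracking software is
generally unspecified, so any smoothing here is an explicit, opt-in
stand-in rather than a default behaviour.

# The comb simulator

No tracking dataset of this kind is publicly deposited, so the package
carries a simulator whose defaults *are* the study conditions reported
for tagged colonies; it is first-class, tested code, and the ground truth
for every downstream stage.

## Movement: a two-state correlated random walk

Each bee alternates between **resting** (2-D positional jitter with
per-axis SD `rest_jitter_sd` = 0.05 mm; heading jitter SD 1.5°/frame) and
**walking** (heading change ~ N(0, `heading_sd`), step length ~ N(mean,
0.8 mm) truncated at zero). Switches follow a two-state Markov process
with overall rate 0.2 events/s split so that the stationary resting
occupancy is `p_rest` = 0.4 — a colony of young bees spends much of its
time sitting, and the 0.2/s rate gives rest and walk episodes on the
scale of ten seconds, comfortably longer than the ≥ 5 s immobility used
to define "resting" in detection-rate measurements.

Two published aggregates calibrate the free parameters analytically:
mean per-frame displacement 0.9 mm and mean per-frame |Δorientation| 6°.
Given `p_rest`, the walking step mean solves

    p_rest · E[Rayleigh(rest_jitter_sd)] + (1 − p_rest) · E[TN(m, s)] = 0.9

by `uniroot` on the truncated-normal mean, and the walking heading SD
solves the analogous mixture equation with E|N(0, σ)| = σ·√(2/π). The
defaults land at a walking step of ≈ 1.46 mm/frame (≈ 5.8 mm/s) and a
heading SD of ≈ 11.5°/frame.

Three structural features perturb the free-walk mixture slightly: soft
wall avoidance (inside a 12 mm buffer, outward headings are rotated
toward the nearer tangent, which prevents bees accumulating along walls
without the heading jumps of a hard reflection), a 4 mm centre-to-centre
floor between bees (resolved by minimal push-outs, free bees yielding to
encounter-engaged ones), and the encounter choreography itself. Across
seeds these leave the realised mean step within ±0.04 mm of 0.9 and the
realised mean |Δorientation| within ≈ +0.0 to +0.45° of 6 — inside the
calibration tolerances the tests enforce (±0.05 mm, ±0.5°).

**Known limitation:** only the two published *means* are calibration
targets. The two-state mixture reproduces the displacement SD (≈ 0.9 mm)
as a by-product, but its |Δorientation| SD is ≈ 7–8° versus the published
4°; with resting bees nearly motionless, a two-state model cannot match
all four moments at once. Tests therefore assert means, not SDs.

## Encounter scheduling and choreography

While free, each bee initiates encounters as a Poisson process at
`encounter_rate` = 3.76 bouts per bee-hour — the rate implied by 658
encounters among 100 bees in 105 min. An initiation that finds no free
partner within 25 mm is retried each frame until one appears, so the
realised rate tracks the nominal one. Bout classes follow the published
57/26/9/8 % mix (antennation/offering/begging/trophallaxis) via a
deterministic largest-deficit quota rather than iid draws: ground truth
is a planted schedule, not an estimate, and the quota keeps every
prefix's empirical mix within one bout of target (an iid multinomial
would miss a 2-percentage-point check roughly one run in three at
realistic bout counts).

A planted bout has three phases. **Approach** (≤ 12 frames = 3 s): both
bees steer toward slots placed `body_length + 2.5` mm apart around their
midpoint (clamped 12 mm off the walls and only accepted if no bystander
is within 25 mm and no other engaged pair within 35 mm), turning ≤ 45°
per frame, and snap into the slots on the final frame. **Hold** (the
sampled duration): positions jitter by 0.1 mm, headings face the partner
±2°; with a 13 mm body this leaves head points ≈ 2.5 mm apart and facing
angles within a few degrees — safely inside the default head-to-head
thresholds (4.5 mm, 25°). **Release**: both bees resume walking, turned
180° so they separate cleanly. Free bees keep a 16 mm berth around
engaged bees so that during a hold each partner remains the other's
closest bee. Antennae are not modelled — the tags carry only body pose —
so ground truth is the planted schedule itself, exactly as manual labels
outrank geometry in annotated video.

The EB ground-truth interval covers the hold phase of each participant;
NEB intervals (sitting/walking, from the scheduled movement states) tile
all remaining time. Bouts still unfinished when the recording ends are
discarded rather than truncated, so every ground-truth trophallaxis bout
really lasts ≥ 5 s.

## Bout durations

Per class, durations follow a **shifted log-normal truncated to the
observed support**: `d = min_s + X`, `X ~ LN(μ, σ)` upper-truncated at
`max_s − min_s`, with supports [0.25, 9.25] (antennation), [0.25, 4.5]
(offering), [0.75, 6.75] (begging) and [5, 30.5] s (trophallaxis). μ and
σ are fitted numerically (Nelder–Mead on the truncated CDF) so that the
truncated distribution hits the published median and 75th percentile of
each class exactly — e.g. 8 s and 12.9 s for trophallaxis. Draws are
quantised to the 0.25 s frame clock and clamped to the support. The
published histograms are right-skewed but not tabulated, so the
log-normal family is a modelling choice; only the four quantiles per
class are facts.

## Detection dropout

Each record is dropped independently with probability 0.018 if resting
and 0.092 if moving, reproducing the published detection rates (98.2 %
and 90.8 %). A bee counts as "moving" in a frame when its step exceeds
0.25 mm; `movement_states()` recomputes this flag from the dropout-free
trajectories, which is exactly what the scheduler knows.

# Features

`compute_per_frame()` produces nine channels per (bee, frame): `speed`
and `angular_speed` from consecutive detected frames × fps; and, relative
to the closest detected nestmate (ties broken by lower id):
`dist_center`, `dist_head`, `facing_angle`, `partner_facing_angle`,
`orientation_diff` (all angles wrapped to [0, 180]), `closing_speed`
(the discrete derivative of `dist_center`; negative = approaching) and
`n_neighbors` within 30 mm. Frames whose focal bee or neighbour is
undetected carry `NA`, never a fabricated value. The channel set is the
minimal one that spans "distance, orientation and speed toward another
worker" and makes the head-to-head configuration learnable; it is far
smaller than the full catalogues of general-purpose annotation tools.

`compute_window_features()` summarises each channel over radii {1, 2, 4}
frames (0.25–1 s — from the shortest observed bout to the antennation
median) by mean, min, max, sd and central difference, truncating at
trajectory ends and skipping missing frames. The sd is the population
form √(E[x²] − E[x]²), so radius 0 reproduces the raw channel with sd
and difference exactly zero. 9 channels × 3 radii × 5 statistics = 135
feature columns.

`head_to_head()` (head distance ≤ 4.5 mm and both facing angles ≤ 25°,
boundaries inclusive) is deliberately exposed: it is the transparent
geometric baseline, and the predicate the simulator's holds are built to
satisfy. On simulator output it is true for ≥ 99 % of hold frames and
< 1 % of NEB frames — the separability precondition the classifier tests
lean on.

# The classifier

`train_encounter_classifier()` fits gentle boosting over depth-1 stumps —
the standard core of window-feature behaviour annotators. Initial weights
give each class half of the total mass regardless of imbalance. Each
round selects, over all features and thresholds (scanned via cumulative
sums in feature order; thresholds at midpoints between distinct values),
the stump minimising the weighted squared error to the ±1 targets; its
outputs are the weighted means of each side, so they live in [−1, 1] and
training is numerically stable without clipping. Weights update as
`w ← w·exp(−y·f(x))` and renormalise. A constant "no-split" stump is
always a candidate, which makes degenerate inputs (identical features in
both classes) converge gracefully to zero scores and 50 % balanced error.

Decision rule: EB iff the summed score is strictly positive — a tie goes
to NEB, the conservative direction for the rarer positive class. Frames
inside no labelled interval are excluded from training; labelled frames
with missing feature values are dropped from training, and at prediction
time any frame missing a feature the ensemble actually uses gets an `NA`
score and the NEB label. The interactive label-a-bit/train-a-bit loop of
GUI annotators is replaced by batch training; its stopping rule survives
only as the cross-validation report. Models serialise to JSON and reload
to bit-identical predictions.

`cross_validate()` re-splits the labelled *intervals* (never frames) into
k = 10 folds per class, 10 independent rounds by default, pools held-out
frames per round into a 2 × 2 row-normalised percentage matrix and
reports mean ± SD across rounds. Pooling is over frames, matching
confusion estimates expressed as "percentage of frames".

# Bouts, durations, statistics

`extract_bouts()` takes maximal per-bee EB runs, merges runs separated by
at most `gap_fill` = 2 NEB/missing frames, drops merged runs shorter than
`min_len` = 1 frame, and assigns as partner the modal closest bee over
the bout. With `gap_fill = 0, min_len = 1` it inverts frame-label
expansion exactly (for non-adjacent bouts), which the tests exploit as a
round-trip identity.

`match_bouts()` scores bout-level detection: a manual EB is detected iff
some predicted bout of the same focal bee overlaps it by ≥ 1 frame
(one-to-many allowed in both directions); false positives are predicted
bouts overlapping no manual EB, as a share of predicted bouts.
Percentages are reported rounded to integers with exact fractions kept
internally. The ≥ 1-frame/same-bee overlap rule is the package's own
convention — published tables report the rates but not the matching rule.

`classify_by_duration()` labels a bout trophallaxis iff its duration is
**≥ 5 s, boundary inclusive**. `duration_summary()` reports n, rounded
percentage share, min/max/median/75th percentile per class, with
quantiles by linear interpolation between order statistics (`quantile`
type 7; the original analysis software's rule is not published).
`kruskal_wallis()` delegates to `stats::kruskal.test` (tie-corrected H,
χ² p-value, df = groups − 1), with H = 0 by convention on fully tied
data. `dunn_test()` implements Dunn's tie-corrected standardized
mean-rank difference; p-values are unadjusted two-sided normal by
default (rank-based post hoc output is conventionally reported this way,
with decisions at α), and any `p.adjust` method can be requested.

# Pipeline, seeds, determinism

`run_pipeline()` chains simulate → (optional dropout) → featurize →
bout-split → train → predict → segment → match → duration statistics,
writes each artifact, and emits a `report.json` mirroring the four
evaluation surfaces (cross-validation matrix, bout detection, duration
table with rank tests, duration rule). The single config seed is split
into per-stage substreams by a deterministic hash, so any stage re-run in
isolation reproduces its part; identical config + seed gives
byte-identical reports. All randomness runs in private RNG scopes that
restore the caller's `.Random.seed`. Training labels take the planted EB
intervals of the training half plus a seeded sample of at most
`max_neb_intervals` = 200 NEB intervals — class weighting makes the
classifier indifferent to the exact cap; it only bounds training cost.

# What the synthetic tests do and do not show

The simulator's encounters are geometrically clean: partners hold an
ideal head-to-head pose, third bees keep their distance, and there is no
tag-decoding noise unless dropout is switched on. Held-out bout-level
detection on this world therefore sits at or near 100 %, and the
published real-data detection rate (93 %) serves as a *floor* in the
acceptance tests, not as an equality target; frame-wise accuracy
likewise exceeds the published 77.3 %. Passing these tests shows the
pipeline is correct and well calibrated, not that it would reach the
same numbers on video-derived tracking, where encounters are blurred by
imperfect poses, antennal contact invisible to geometry, and detection
gaps. The duration-threshold results transfer more directly, since they
depend only on the duration model, which is fitted to published
quantiles.

Problem sizes in the shipped tests were chosen to exercise every code
path at comfortable statistical power: calibration checks use a 20-bee,
10-minute colony (≈ 48 000 steps), the class-mix check a 100-bee hour,
and the end-to-end floor three 30-bee hours; duration-model checks use
10⁴–10⁵ draws.

# Parameter reference

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fps` | 4 | frames/s | recording rate of the tag tracker |
| `arena` | 370 × 200 | mm | one side of a one-frame observation comb |
| `body_length` | 13 | mm | worker scale; head offset is half this |
| `p_rest` | 0.4 | — | resting occupancy of young workers |
| `walk_step_sd` | 0.8 | mm | walking step spread; mean is calibrated |
| `switch_rate` | 0.2 | 1/s | rest/walk episodes ~10 s |
| `encounter_rate` | 3.76 | bouts/bee-h | 658 bouts / (100 bees × 1.75 h) |
| `class_mix` | .57/.26/.09/.08 | — | published encounter-class shares |
| `miss_prob` | .018 / .092 | — | 98.2 % / 90.8 % detection rates |
| `max_head_dist` | 4.5 | mm | head-to-head range (antennal reach) |
| `max_facing` | 25 | deg | facing tolerance of the predicate |
| `neighbor_radius` | 30 | mm | ~two body lengths |
| `window_radii` | 1, 2, 4 | frames | 0.25–1 s bout time-scales |
| `n_rounds` | 100 | — | boosting rounds |
| `gap_fill`, `min_len` | 2, 1 | frames | bout post-processing |
| `duration_threshold_s` | 5 | s | trophallaxis rule, inclusive |

Each is exposed through `pipeline_config()` and the YAML config of the
command-line interface.
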
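# beetrax

Automated detection of worker–worker **encounter behaviours** in groups of
barcode-tracked honeybees (*Apis mellifera*).

Worker bees exchange information and food through brief head-to-head
contacts: **antennation**, **begging**, **offering** and **trophallaxis**
(mouth-to-mouth nectar transfer). These encounters are so frequent that
manual scoring from video covers only a small fraction of what a colony
displays. Given tracking tables from 2D-barcode tags (tag id, frame,
timestamp, centre position in mm, body orientation in degrees, recorded at
4 frames/s), `beetrax` classifies every (bee, frame) as encounter (EB) vs
non-encounter (NEB), segments the frame scores into bouts, and separates
trophallaxis from the shorter encounter classes with a duration threshold.
It is aimed at behavioural ecologists and bee researchers who run small
observation hives with tag-based tracking.

## The method

1. **Social per-frame features.** For each bee and frame, kinematics
   (speed, angular speed) and geometry relative to the *closest* nestmate:
   centre distance, head-to-head distance (head = centre + ½ body length
   along the heading), the facing angle of each partner toward the other,
   the difference of body orientations, closing speed and neighbour count.
   An encounter configuration is head-to-head: both facing angles small,
   orientation difference near 180°, head distance a few mm.
2. **Window features.** Each channel is summarised over windows of radius
   *w* ∈ {1, 2, 4} frames by mean, min, max, sd and central difference,
   mirroring window-feature behaviour annotation systems.
3. **Gentle boosting.** The classifier is an additive ensemble of
   regression stumps, `F(x) = Σₘ fₘ(x)` with
   `fₘ(x) = a·1[xⱼ ≤ θ] + b·1[xⱼ > θ]`, fitted round by round to
   weight-balanced EB/NEB frames with the update `w ← w·exp(−y·fₘ(x))`.
   A frame is EB iff `F(x) > 0` (ties go to NEB). Accuracy is estimated by
   repeated bout-wise k-fold cross-validation (whole bouts never straddle
   a split) reported as a frame-wise confusion matrix in percent.
4. **Bouts.** Maximal EB runs per bee, merging gaps ≤ 2 frames; a manual
   bout counts as detected iff a predicted bout of the same bee overlaps
   it by ≥ 1 frame.
5. **Durations.** Bout durations per class are summarised (n, %, min,
   max, median, 75th percentile), compared with Kruskal–Wallis ANOVA on
   ranks (tie-corrected H) and Dunn's pairwise Q, and any encounter bout
   lasting **≥ 5 s** is classified as trophallaxis.

Because real tracking data of this kind is rarely deposited, the package
ships a seeded **comb simulator**: a two-state (rest/walk) correlated
random walk per bee, calibrated so that the per-frame mixture reproduces
published movement statistics (mean step 0.9 mm, mean |Δorientation| 6°),
with planted encounter bouts whose classes follow the published 57/26/9/8 %
mix, whose durations follow per-class shifted truncated log-normal laws
fitted to published quantiles, and a detection-dropout model (resting
98.2 %, moving 90.8 % detection). The planted schedule is the ground truth
every stage is tested against.

## Worked example

```r
library(beetrax)
sim <- simulate_colony(n_bees = 15, duration_s = 900, seed = 7)
sim$tracking
#> Tracking dataset: 54000 detections, 15 bees, frames [0, 3599], 4 fps, arena 370 x 200 mm
table(sim$bouts$behavior)
#>  antennation      begging     offering trophallaxis
#>            7            1            3            1

fs <- frame_step_stats(sim$tracking)
# mean step 0.89 mm, mean |dOri| 6.1 deg  -- the calibrated movement scale

pf <- compute_per_frame(sim$tracking)     # social per-frame features
wf <- compute_window_features(pf)         # 135 windowed channels

# train on half of the planted bouts (plus sitting/walking intervals),
# hold the other half out
model <- train_encounter_classifier(wf, train_labels, n_rounds = 100, seed = 7)
model
#> Gentle-boosting encounter classifier: 100 stumps over 135 feature channels
#> Balanced training error: 0.000
head(coef(model), 3)
#>                       feature  threshold     out_le     out_gt
#> 1            dist_head_w1_min   2.743565  0.9831638 -1.0000000
#> 2    orientation_diff_w1_mean 173.206333 -0.9672504  0.9650512
#> 3 partner_facing_angle_w1_min   3.394031  0.9333170 -1.0000000

scores <- predict(model, wf)
pred <- extract_bouts(scores, gap_fill = 2, min_len = 1)
match_bouts(pred, heldout_labels)
#> Bout matching: 12/12 manual EBs detected (100%), FN 0%, FP 59% of 29 predicted bouts

classify_by_duration(pred$duration_s)     # trophallaxis* iff >= 5 s
duration_summary(sim$bouts$behavior, sim$bouts$duration_s)
#>       behavior n rel_pct min_s max_s median_s q75_s
#> 1  antennation 7      58  1.00  4.00     1.75 2.625
#> 2     offering 3      25  1.25  3.50     1.25 2.375
#> 3      begging 1       8  4.75  4.75     4.75 4.750
#> 4 trophallaxis 1       8  7.50  7.50     7.50 7.500
```

The first stump already reads like the biology: a small windowed
head-to-head distance (≤ 2.7 mm) votes for "encounter". All 12 held-out
planted bouts are recovered; the bouts flagged "false positive" here are
mostly the *training*-half bouts, which are absent from the held-out
reference list. One whole-pipeline wrapper, `run_pipeline()`, executes
simulate → featurize → train → predict → evaluate → duration-classify and
writes every intermediate artifact plus a machine-readable `report.json`.

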
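---
title: "Quantifying infant movements toward the midline: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infant movements toward the midline: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmpose)
```

`mtmpose` turns 33-landmark 2D pose output for supine, top-down infant
videos into movement-toward-the-midline (MTM) features and statistics.
This vignette records the model the package implements, the decisions
taken where the underlying observational protocol leaves details open,
and what the synthetic test bed does and does not establish.

## The geometric model

All coordinates are normalized image coordinates (origin top-left, x
rightward, y downward). The protocol assumes a roughly vertical body axis
in the image: the infant lies supine, filmed from above, head toward one
edge of the frame.

**Midbody line.** The body's left–right divider is the line through the
shoulder midpoint (mean of landmarks 11 and 12) and the hip midpoint
(mean of 23 and 24). We parameterize it as

$$x = a\,y + b$$

rather than the more familiar $y = m x + c$. The two forms are
algebraically interchangeable ($a = 1/m$, $b = -c/m$), but the slope $m$
diverges exactly where this protocol's data lives — a near-vertical
midline — while $a$ stays near zero there. A truly *horizontal* body
axis (shoulder and hip midpoints at equal y within $10^{-6}\times$ body
length, or coincident midpoints) is outside the protocol's assumptions
and is treated as a degenerate frame: `midbody_line()` raises an error,
and `frame_features()` flags the frame invalid instead.

**Signed distances.** For each distal limb landmark (15 left wrist, 16
right wrist, 27 left ankle, 28 right ankle) the feature is the
*horizontal offset* from the line at the landmark's own height,

$$d_{\ell} = x_{\text{line}}(y_\ell) - x_\ell,$$

not the perpendicular point–line distance. This is the natural quantity
when the midline is near-vertical (the two agree up to the factor
$\sqrt{1+a^2} \approx 1$), and it is what the x-substitution construction
of the observational method computes. A perpendicular mode
(`distance_mode = "perpendicular"`) is provided; it is the
rotation-invariant variant and is what the rotation-invariance tests
assert on. Distances are kept **signed**, not absolute: the left and
right limbs of one infant sit on opposite sides of the line, and
averaging absolute values would erase exactly the left/right asymmetry
(e.g. asymmetric tonic neck posture) that per-video means can reveal.
Under mirror reflection of the skeleton about the midline (with
left/right labels swapped), the wrist pair and ankle pair negate into
each other — a property the test suite checks to $10^{-9}$.

**Normalization.** Every frame's features are divided by that frame's
body length, the mean of the two shoulder–hip Euclidean distances
($\|p_{11}-p_{23}\|$ and $\|p_{12}-p_{24}\|$). Using the per-frame value
rather than a per-video average compensates frame-to-frame
camera-distance changes of a hand-held phone; for a steady camera the
two choices coincide. This makes normalized distances invariant to
uniform scaling of the image.

**Areas.** Three region features per frame: the absolute shoelace area
of the quadrilateral traversed wrist 15 → wrist 16 → ankle 28 → ankle 27
(the fixed traversal avoids self-intersecting orderings), and the two
triangles formed by the wrist pair and by the ankle pair with the body
centre (the arithmetic mean of all 33 landmarks). Areas are divided by
body length to the power `area_norm_exponent`. The default is `k = 1` —
a literal "normalized by body length" — although `k = 2` is the
dimensionally consistent choice and is one flag away. Under `k = 1` a
uniform image rescaling by $c$ scales normalized areas by $c$; under
`k = 2` they are scale-invariant. Nothing downstream depends on the
choice as long as it is held fixed across a cohort, because the
statistics used (rank correlations, rank tests, and a t-test within one
cohort) are at most location–scale sensitive.

**Validity and aggregation.** A landmark is missing when its coordinates
are non-finite or its pose-model confidence falls below
`visibility_threshold` (default 0.5, the usual detection cutoff).
Distance features need landmarks 11, 12, 23, 24, 15, 16, 27, 28; area
features additionally need all 33 (for the centre). Each feature family
is averaged over the frames valid *for it*; a video whose overall
invalid fraction exceeds `max_invalid_fraction` (default 10%) is flagged
unusable, mirroring the exclusion of footage a pose model cannot fully
analyse. No smoothing, interpolation or gap-filling is applied — the
features are means of raw per-frame geometry.

## MTM scoring

Ten behaviours are scored, split into a lower-limb group (foot-to-foot,
foot-to-leg, pedipulation) and an upper-limb group (hand-to-hand,
-face, -mouth, -trunk, -leg, manipulation, fiddling). Annotated events
are half-open frame intervals `[start, end)`, 0-based — a convention
chosen once to remove off-by-one ambiguity.

The counting rule is: an item must persist 30 consecutive frames (one
second at 30 fps) to be counted, and each event contributes
$\lfloor \text{frames}/\text{fps} \rfloor$ whole seconds. Flooring is
the reading consistent with both "30 continuous frames = 1 s" and
"below 30 frames = excluded"; whether a 59-frame run should count 1 s
(flooring, as implemented) or require disjoint full-second blocks is
genuinely ambiguous, so the rule is isolated in `event_seconds()` and a
fractional mode is available for sensitivity analysis. Overlapping
annotations of the *same* item are merged before counting (one behaviour
annotated twice is one behaviour); simultaneous events of *different*
items each count in full, since per-item times are summed.

From per-item seconds: occurrence percentage
$= \text{total s} / \text{duration} \times 100$ and per-minute rates
$= \text{group s} / \text{duration} \times 60$ for total, lower and
upper groups. The reference duration is 120 s; other durations
substitute their actual length. `rate_total = rate_lower + rate_upper`
holds exactly by construction. A video "shows" a category when the
corresponding rate is positive.

## Statistics

- **Normality screen**: one-sample KS against a normal with the sample
  mean and SD plugged in (Lilliefors-style composite test, p-values via
  `nortest`); a fixed-parameter KS variant is available. Which variant a
  given desktop statistics package would have used is not knowable, so
  neither is asserted — they share the same statistic here.
- **Correlation**: Spearman, computed as Pearson on mid-ranks (average
  ranks under ties), p from the t approximation on $n-2$ df. The 95% CI
  uses the Fisher z transform,
  $\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})$. This CI
  method reproduces published interval bounds from their printed $r$ at
  $n = 94$ to the printed precision, which is why it is the one
  implemented.
- **Group comparisons**: whole area by Student's pooled-variance
  two-sample t-test (Welch configurable), upper and lower areas by the
  Mann–Whitney U test with tie-corrected normal approximation and
  continuity correction (exact enumeration available for small
  samples). The split — parametric for the one measure that tends to
  pass the normality screen, rank-based for the others — follows the
  source protocol rather than any automatic rule.
- **No multiple-testing correction** is applied across the 16
  correlation cells or 9 comparisons; cells are flagged at p < 0.01
  (correlations) and p < 0.05 (comparisons) individually. This matches
  the analysis the package reproduces and is a documented limitation,
  not a recommendation.

Degenerate inputs (constant vectors, single-member groups) yield `NA`
cells in the tables rather than aborting a cohort analysis; the
underlying functions themselves raise classed errors when called
directly.

## The synthetic test bed

There is no deposited infant-landmark dataset, so the package carries a
generator whose output exercises every pipeline stage with known ground
truth. It emulates, per video:

- a bilaterally symmetric 33-landmark supine rest pose (trunk length =
  `body_scale`, default 0.3 of the frame; orientation and position
  configurable);
- **baseline motility**: each distal driver landmark (wrists, ankles,
  elbows, knees) wanders as a mean-reverting exponentially smoothed
  Gaussian (AR(1)) process — stationary SD `baseline_amplitude` (default
  0.08 trunk units, elbows/knees at 60%), correlation time
  `baseline_timescale` (default 1.5 s). Hand and foot landmarks ride
  along with their wrist/ankle. This is the simplest process giving
  smooth, bounded, plausible limb wander; it is the generator's own
  modelling assumption, and amplitude/timescale defaults are plausible
  placeholders rather than values estimated from infant data;
- **contact events**: scheduled explicitly or drawn from per-item
  Poisson rates (durations 1 s + exponential excess, mean 1.5 s;
  same-item overlaps dropped). During an event the item's contact
  landmarks ease onto their targets (0.3 s on each side, *outside* the
  annotated interval, so contact holds throughout it) — e.g.
  foot-to-foot brings both ankles to a shared midline point,
  hand-to-trunk brings one wrist to the trunk midline. Contact fidelity
  (staying within `contact_radius_factor` × body length of target,
  default 0.25) is an asserted test property;
- **camera jitter**: a slow rigid per-frame rotation + translation
  (AR(1), SDs 0.01 rad and 0.004 image units), matching a hand-held
  phone and preserving the geometry module's invariances;
- **measurement noise**: i.i.d. Gaussian per landmark per frame
  (SD 0.002 image units), added last; optional per-frame landmark
  dropout emulates pose-model failures.

`make_cohort()` draws per-video burdens: a video has zero lower-limb
MTM with probability 0.6 (zero upper-limb with probability 0.2),
otherwise group rates uniform up to 3 (lower) or 4 (upper) events/min
split across items weighted toward foot-to-foot and hand-to-trunk. The
zero-probabilities echo the shows/no-shows mix reported for 8–16-week
cohorts (roughly 40% of videos showing lower-limb MTM and 80%
upper-limb). Crucially, the association between event burden and area
features is *emergent from the kinematics* — ankles held at the midline
necessarily shrink the ankle triangle — not painted onto the feature
values. `coupling = "none"` keeps the same kinematics but randomly
reassigns the annotation sets across videos, giving an honest null.

What passing tests on this bed shows: the geometry is exact (invariance
and oracle properties at $10^{-9}$), the scoring rules are exact, the
statistical machinery is calibrated (label-shuffling rejection rate at
nominal 5% within [3%, 7%] over 1000 shuffles), and a
by-construction lower-area effect at n = 60 is recovered with
Mann–Whitney p < 0.05 in ≥ 90% of 100 replicate cohorts. What it does
*not* show: performance on real pose-model output (correlated,
heavy-tailed, occlusion-structured errors; limb crossings; out-of-frame
excursions), nor anything about the published cohort's effect sizes,
which cannot be reproduced without the original videos.

## Problem sizes and numerical choices

Verification uses full-protocol videos (120 s × 30 fps = 3600 frames,
118,800 coordinate records) for the counting and power checks, and
shorter durations for unit tests where only code paths are at stake.
The power study is 100 cohorts of 60 videos; the null calibration is
1000 label shuffles of one decoupled 60-video cohort. Coordinates are
written to CSV with 17 significant digits so read∘write is bit-exact.
The line-fit degeneracy threshold is $10^{-6}\times$ body length;
feature invariances are asserted at $10^{-9}$.

## Known limitations

- The x-offset distance is not rotation-invariant (by design; use the
  perpendicular mode if your camera orientation varies strongly).
- Whether areas should be normalized by body length or its square is
  left configurable because the source protocol's wording supports
  either; defaults favour the literal reading.
- MTM events are consumed as annotations; automatic MTM *detection*
  from landmarks is out of scope.
- No trajectory filtering or gap interpolation is performed; heavily
  occluded videos should be excluded upstream or will be flagged
  unusable.
- The synthetic generator's motility parameters are plausibility
  choices, not estimates fitted to infant recordings.
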
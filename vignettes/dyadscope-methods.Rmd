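---
title: "Methods: models, conventions and design choices in dyadscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in dyadscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadscope)
```

`dyadscope` quantifies parent–infant interaction during a three-phase
tabletop play protocol (free interactive play, 4 min; directed game,
2 min; free play with the parent occupied, 2 min) recorded by two RGB-D
sensors, one facing each participant across the table. This vignette is
the package's own account of the models it implements, the parameters
that matter, what the synthetic generator does and does not emulate, and
the design choices made where the design was genuinely open.

## Coordinate and clock conventions

All downstream features assume a **world frame anchored to the play
table**: origin at the table center, y up, z along the column direction
of the calibration chessboard laid on the table. Each sensor's pose is
estimated from the ordered chessboard corners by the SVD-based orthogonal
Procrustes (Kabsch) solution with a determinant correction, so the
estimate is always a proper rotation — a reflection can never masquerade
as a calibration. The corner order is part of the on-disk dialect
(row-major over the declared grid), which removes the orientation
ambiguity a symmetric board would otherwise leave.

Sensor clocks start when each device is connected, so they are offset by
an unknown constant. Both devices hear the same hand clap; the first
10 ms analysis window whose RMS exceeds `max(20 × median RMS of the first
500 ms, 0.05 full scale)` stamps the clap on each clock, the difference
is the inter-sensor offset, and world time zero is the clap on sensor A's
clock. The floor of 0.05 protects against recordings whose lead-in is
digitally silent, where any finite threshold multiple of a zero baseline
would fire on the first breath of noise.

With the default seats at (0.6, 0, 0.6) m and (0.6, 0, −0.6) m — 90°
apart as seen from the table, matching the protocol's seating — the
orientation conventions follow: a torso facing the table center has its
shoulder line at 45° to z; facing the partner's seat gives 90°; two
torsos facing each other give a relative orientation of 0°.

## Skeleton pipeline

**Identity.** Slots are labelled parent/child by horizontal proximity of
their 1 s-median shoulder center to the manifest seats. Seat proximity
(rather than body size) is robust to the session variability the protocol
anticipates — a child standing on the chair is still nearest the child
seat. Confidence is the margin between the two seat distances normalised
by the seat separation; two slots claiming one seat beyond 2 s flags the
stream (`AmbiguousIdentity`) and leaves the farther slot unassigned
rather than guessing.

**Inconsistent skeletons.** Three explicit, configurable rules: a joint
jumping > 0.5 m within < 100 ms of the previous kept frame; a
shoulder-to-shoulder distance outside [0.15, 0.75] m (merged-track
artefacts); a shoulder center > 1.5 m horizontally from the assigned
seat. The thresholds come from seated adult/child anthropometry; the
acquisition literature gives no criterion, so ours is a documented
stand-in. The rule set is monotone: adding an outlier frame never changes
the fate of other frames.

**Fusion.** On a common 30 Hz clock (the sensors' nominal rate), per tick
and joint: nearest-neighbour resampling within 50 ms (1.5 frame periods);
when both sensors contribute, the *facing* sensor (A for the parent, B
for the child) wins if they agree within 10 cm, otherwise the tick
becomes a gap and the disagreement is logged. Fusion never averages the
two sensors — every fused sample is one sensor's sample, so provenance is
always exact and nothing is fabricated.

**Gaps.** Gaps propagate everywhere and are never imputed. This
preserves the semantics of the protocol's figures, where uncollected data
(child off camera, occlusions) appear as blanks; a smoothed-over gap
would silently manufacture behavioural evidence.

**Smoothing.** A centered 5-frame (167 ms) moving average per joint
coordinate, computed only over non-gap samples. Window 1 is the identity;
the window must be odd so the filter is phase-neutral.

## Features

Distances are 3D Euclidean by default (`planar = TRUE` restricts to the
horizontal plane; the source material does not say which was used, and on
table-plane geometry the two coincide). Orientation features project the
shoulder line onto the horizontal plane and fold to the acute angle
`arccos |û·ẑ| ∈ [0°, 90°]`, making them invariant to left/right shoulder
relabelling and to which direction along the line is "left"; projections
shorter than 1 cm are degenerate and become gaps.

Contribution to movement uses mean speeds over a **trailing** 1 s window
("who moved most in the previous frames"): `c_child = v̄_c/(v̄_c + v̄_p)`,
`c_parent = 1 − c_child`, undefined (gap) when the summed speed is below
1 mm/s — a ratio of noise floors is not leadership. Hand contacts are
detected on the minimum of the two cross-pair hand distances with a 10 cm
threshold, 2 cm release hysteresis and 250 ms debounce; the published
account reports counts but no criterion, so these are explicit and
configurable defaults.

Voice activity is a transparent short-time energy detector (25 ms frames,
10 ms hop): probability `plogis((E_dB − floor_dB − 10)/2)` against a
10th-percentile noise floor, active when ≥ 0.5 sustained ≥ 100 ms. We
deliberately re-specified VAD instead of wrapping an opaque toolkit: the
original treats it as a black box, and a testable pipeline needs every
threshold visible. Attribution compares the measured source azimuth with
each head's azimuth in the sensor frame (15° tolerance, 5° margin);
distinguishing voices from object noises is imperfect, which is exactly
what the explicit `unattributed` class encodes. A speech turn is a change
of attributed speaker between consecutive utterances (minimum 200 ms,
within-speaker silences < 150 ms bridged).

## CIB aggregation

The eight composites are arithmetic means of their published item lists;
items listed under several composites count in each. Forty-two distinct
items appear in the published composite table; the scale has 43 codes, so
the record schema carries one published parent code outside the table
(`parent_depressed_mood`) that contributes to no composite. No reverse
scoring is applied — the composite table states no reversal rules, and
inventing them would change scores invisibly; this is flagged as a known
limitation. Composites with more than half their items missing are
undefined with a warning (our policy; missingness is not addressed in the
source).

## The synthetic generator: what it states, and what it does not

The generator *is* the package's stated world, not a tuning dial. Seated
torsos sit at the profile's mean shoulder-center-to-table distance along
their seat direction with mean-reverting (Ornstein–Uhlenbeck) jitter
(sd 3 cm, reversion time 2 s — seat-bound like real seated adults);
attention alternates between table, partner and elsewhere with
exponential dwell times; hands rest near the table edge with OU jitter
whose amplitude is split between the participants by the
movement-leadership ratio; scripted contact events are *initiated* by one
partner (the child with the leadership odds) reaching to the other's
resting hand, so contacts respect the stated leadership rather than
diluting it. Torso points are modelled relative to table-plane height, so
the profile's distance parameters are realised directly as the 3D
distances the features measure.

The two default profiles encode the published behavioural contrasts:
control — parent at 0.50 m, balanced leadership (0.5), dialog-like
alternating speech, 25 scripted contacts; pathological — parent at
0.80 m and nearly static, child leadership 0.9, child at 0.40 m, sparse
parent speech giving exactly four speech turns, 20 scripted contacts.

Sensor imperfections: per-coordinate joint noise as OU with 5 mm
amplitude and 0.6 s correlation (structured-light joint jitter is slowly
varying, not white — white noise of that amplitude would dominate any
differentiated speed), 5% random frame drops, occasional teleported
frames (exercising the rejection rules), a scripted 10 s child-off-camera
hole, corner noise of 1 mm on the calibration points, and an
inter-sensor clock offset drawn from [0.2, 3] s. Speech bursts are
amplitude-modulated tone+noise at the speaking seat, with matching
source-angle samples (1.5° noise); nobody utters a seat-anchored burst
while the child is scripted off-seat, and scripted contacts dodge the
hole too — the stated world stays self-consistent.

What the generator does **not** emulate: real skeleton-tracker failure
modes (label swaps, mirrored limbs), room acoustics and reverberation,
overlapping speech, the psychologist moving through the scene, gross
posture changes (climbing on the parent's knees). A green end-to-end test
therefore establishes that the pipeline recovers the stated world's
parameters through realistic noise, drops and clock/frame misalignment —
not that it is robust to every clinical artefact.

## Numerical choices and degenerate inputs

* Rigid estimation rejects < 3 or collinear correspondences
  (`DegenerateConfiguration`) and non-finite points (`InvalidPoint`);
  permutation invariance holds to LAPACK rounding (~1e-15).
* Resampling is nearest-neighbour with a hard `max_gap`; ties between
  two equally near samples take the earlier one.
* `closest_hand_to_table` uses the surviving hand when one is a gap; a
  tie between hands is harmless (the minimum is unique as a value).
* The contact detector treats gap ticks as non-contact: a contact can
  neither start nor be sustained on unobserved data, and brief
  (sub-debounce) gaps inside a contact merge back into one event.
* Phase segmentation is half-open `[start, end)`, truncated at the
  recording end with a warning; an entirely uncovered plan is an error,
  not an empty answer.

## Known limitations

Identity assignment assumes both participants stay near their manifest
seats; long role swaps would need re-identification, which is out of
scope. Attribution relies on the azimuth separation of the two heads as
seen from sensor A (~20° at the default geometry); seats closer together
would push legitimate speech into `unattributed`. The CIB module
aggregates given codes only — it does not rate items from video, and no
internal-consistency estimation is attempted on two-profile synthetic
data.
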
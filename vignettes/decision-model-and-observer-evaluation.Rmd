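---
title: "Costing camera-trap programs and evaluating human vs machine observers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing camera-trap programs and evaluating human vs machine observers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrapdecide)
```

## The problem

A monitoring network of hundreds of motion-triggered cameras produces two
recurring costs that dwarf the hardware: staff driving to every camera to
swap SD cards and batteries, and staff classifying the resulting flood of
images, most of which are empty. Two technologies attack these costs — cloud
AI classifiers that label species automatically, and 4G-connected
solar-powered cameras that upload images directly, removing routine site
visits. `camtrapdecide` answers the two questions a program manager needs
before adopting either: *what does each design cost over the program's
life?* and *can the machine observer be trusted, and at what human review
effort?*

## The cost model

Each of the three scenarios (`manual_manual`, `manual_ai`, `connected_ai`)
is costed as a sum of seven components. With cameras $N$, years $Y$, service
rounds per year $r_s$ (scenario-specific), staff-days per round $d$, round
distance $L$ km, image volume $I$ per year and a manual classification rate
$m$ images per staff-day:

| component | formula | who pays it |
|---|---|---|
| hardware | one-off units: basic camera + SD card, or 4G camera + solar panel + SD card + antenna share | all |
| consumables | $N \cdot b \cdot r_s Y \cdot c_{bat}$ battery sets | manual scenarios |
| staff_field | $d \cdot r_s Y \cdot c_{day}$ (+ upload days for `manual_ai`) | all |
| staff_processing | $\frac{IY}{m} c_{day}$ | `manual_manual` (AI scenarios: optional verification share) |
| travel | $L \cdot r_s Y \cdot c_{km}$ | all |
| ai_fees | $IY \cdot c_{img}$ | AI scenarios |
| connectivity | $N Y \cdot c_{sim}$ | `connected_ai` |

Assumptions worth making explicit:

- **Deployment travel is excluded.** Driving cameras to their sites costs
  the same in every scenario, so it cancels out of a comparison.
- **Connected cameras keep a maintenance-round rate.** Solar panels remove
  routine battery changes; `service_rounds_per_year` is per-scenario, with
  the connected rate near zero (the preset uses one visit per year) rather
  than a hard zero, because field hardware still fails.
- **SD cards are one-off hardware in every scenario** (4G cameras also
  buffer to SD when connectivity drops); **battery sets are per-round
  consumables in the manual scenarios only**. `battery_sets_per_round` may
  be fractional to express change-every-*n*-rounds schedules.
- **Staff-days are fractional.** Processing days are $IY/m$, not a ceiling:
  these are program-scale averages, not per-trip head counts.
- **AI output is treated as final by default.** `verification_fraction`
  (default 0) exists for programs that re-check a share of AI calls; the
  scenario comparison that motivated the model excludes it.
- **Negative savings are reported, not suppressed** — the tool's purpose is
  comparison.

Savings are relative to the `manual_manual` baseline, $S = C_0 - C$ and
$S\% = 100\,S/C_0$. Emissions convert distance with a manufacturer factor,
$\mathrm{CO_2\,(kg)} = \mathrm{km} \times EF_{\mathrm{g/km}} / 1000$.

The published program totals themselves depend on an unavailable input
workbook, so they enter the package only as a *calibration fixture*: given
the three totals, `compare_scenarios()` must (and does) reproduce the
published savings arithmetic exactly. The model's own correctness is
established structurally — component-sum conservation, non-negativity,
monotonicity in volumes and unit prices, and equality with an independently
written straight-line re-summation over hundreds of random configurations.

### Rounding

Currency totals are reported to the nearest whole unit and percentages to
one decimal, rounded half *away from zero* (`round_half_up()`), matching
the convention of published program tables; base R's banker's rounding
would turn 10.25 into 10.2. Thousands separators appear only in rendered
text tables, never in CSV. One published figure, 97.9% for 482/492
(= 97.97), appears truncated rather than rounded; the package does not
replicate truncation.

## Observer evaluation

The unit of capture is the **trigger set**: up to three images from one
camera activation. The unit of ecological interest is the **sequence**: a
run of same-species trigger sets on one camera in which the animal stayed in
view. Two timing rules govern aggregation:

- **Trigger bundling** (only when no `trigger_id` column exists):
  consecutive same-camera images ≤ 2 s apart are bundled greedily, capped at
  3 images. Two seconds is the widest window that can never bridge the 5 s
  sequence gap, so bundling can never merge what the sequence rule must
  split.
- **Sequence splitting**: the gap is measured from one trigger's *last*
  image to the next trigger's *first* image, and a gap ≥ 5 s (inclusive)
  splits. The boundary is tested both sides: 4 s merges, 5 s splits. The
  threshold is an argument (`gap_seconds`) for programs that define visits
  differently.

Scoring is one-vs-rest per target species. At the image level, `correct`
counts true images of the species the observer also labelled as it, type II
is the remainder, and type I counts any *other* image the observer labelled
as the species. At the sequence level a sequence is correct as soon as one
of its images was labelled — a deliberate leniency reflecting how detections
are acted on: one flagged image triggers the response.

**Sequence-level type I** has no published definition (the source tables
report machine image false positives collapsing to zero sequence false
positives without stating the rule). This package counts *maximal runs of
observer-positive triggers containing no true image of the species*, merged
under the same gap rule — so a burst of consecutive false triggers counts
once, mirroring how true sequences are counted. This is one defensible
choice, documented and tested as such, not reverse-engineered from the
published counts.

Records whose ground truth is `UNKNOWN` are excluded from every score,
workload and histogram, mirroring the removal of ambiguous images from the
original comparison.

Review workloads are **inclusive**: `review_workload()` flags images
labelled as the species with confidence ≥ t. With the threshold at 0 the
workload equals all observer-positive images (correct + type I), and it is
non-increasing in t. Histogram bins are half-open deciles `(low, high]`
over (0, 100] with 100% in the top bin and an exact 0 kept in the lowest.

`observer_score()` also accepts counts from external sources. One published
row (the human cat images) does not satisfy `correct + type II = total`;
such rows are carried with a warning rather than rejected, because derived
percentages are still well defined. Scores produced by the package's own
scorers always conserve, and that identity is asserted property-style
against a naive quadratic re-scorer on random record tables.

## What the synthetic generator does and does not emulate

`simulate_records()` draws, per camera-day, a Poisson number of trigger
arrivals placed on distinct minute slots; each arrival carries a species
from `species_mix` and, if non-empty, chains into further triggers with
probability `sequence_continuation_prob` at 1–4 s gaps (capped at 8
triggers, which keeps a whole visit inside its minute slot). This makes the
generator's chain count *provably identical* to what `build_sequences()`
recovers under the 5 s rule — an invariant the tests assert — at the price
of two simplifications: arrivals are homogeneous in time (no diel activity
cycle) and two independent animal visits can never occur within one minute
on one camera. Observer labels are independent Bernoulli draws per image
(miss with `miss_prob`, false-positive with `fp_rate_per_empty`), and
confidences come from beta distributions per outcome class.

`kifcep_like_preset()` reproduces the case study's aggregate shape: 42
cameras over 302 days at 2.65 arrivals/camera-day gives ~10⁵ images;
trigger-level species fractions of 0.002 (cat) and 0.0008 (echidna) inflate
through the 0.6 continuation probability (mean chain length 2.5, matching
the published ~2.4 triggers per sequence) to image-level shares of ~0.5%
and ~0.2%. The AI observer misses 2% of cats, false-alarms on 2.7% of other
images with confidence spread over ~0.4–1 (beta(6,2)), and concentrates
~90% of its correct-classification confidence mass above 0.9 (beta(21,1));
the human misses more (4% of cats, 30% of echidnas), almost never
false-alarms, and reports no confidences. These rates are read off the
published error table's margins; the *joint* behaviour of real observers
(fatigue runs, correlated errors within a sequence, image-quality effects)
is not modelled, so passing tests demonstrate correct accounting, not
ecological realism. One `UNKNOWN`-truth record per preset run exercises the
exclusion rule.

Unit costs in `kifcep_preset()` (the cost-model preset) are likewise
plausible placeholders — the audited figures live in an unpublished
workbook — so its outputs illustrate magnitudes, not calibrated totals.

## Problem sizes and determinism

The test suite uses 200 random program configurations against the cost
oracle, 100 random record tables against the quadratic re-scorer, one
~30,000-image simulation for error-rate recovery (±3 binomial standard
errors around the generating rates at ~10⁴ target images) and one full
preset run (~10⁵ images, a few seconds); all random draws sit under fixed
seeds, and `simulate_records()` restores the caller's RNG state. Identical
seeds give byte-identical record tables.

## Known limitations

- Sequence-level correct *rates* need not dominate image-level rates in
  aggregate, even though each individual sequence is scored at least as
  leniently as its images: a missed single-image sequence next to a
  fully-correct three-image sequence gives a sequence rate of 1/2 against
  an image rate of 3/4. Only the conservation identities are invariant.
- The cost model is linear and undiscounted: no net-present-value
  adjustment, salary inflation or currency conversion.
- Inter-observer agreement statistics (e.g. kappa) and downstream occupancy
  or density modelling are out of scope; the package evaluates observers
  against a fixed ground truth, not against each other.
- The review-workload worked examples treat the published 40%/80%
  thresholds as inclusive; the source prose is ambiguous ("above the 40%
  confidence level") and the inclusive reading is the one consistent with
  its printed counts.
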
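---
title: "Quantifying the Drosophila egg-laying motor programme"
author: "ovibout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the Drosophila egg-laying motor programme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovibout)
```

## The data model

The input boundary of `ovibout` is the annotation table, not the video: one
row per *bout*, a maximal contiguous episode of one behaviour for one fly,
encoded as an inclusive 0-based frame interval `[start_frame, end_frame]`.
A one-frame bout has `start_frame == end_frame`. Eight canonical behaviour
labels are recognised (`canonical_behaviours`); unknown labels are accepted
and flagged as notes. Frame rate lives on the *recording*, not globally,
because experiments mix 20 fps and 15 fps acquisitions.

Two conventions deserve emphasis because they interact subtly:

- **Same-behaviour bouts never overlap or touch.** Two frame-adjacent bouts
  of one behaviour are by definition one bout; `validate_ethogram()` treats
  them as a data error, and `on_overlap = "merge"` unions them instead.
  Bouts of *different* behaviours co-occur freely (ovipositor extrusion
  happens during abdominal contortions, burrowing accompanies ovipositor
  contact).
- **Durations subtract, they do not count.** The duration of a bout is
  `(end_frame − start_frame) / fps`. Under the inclusive-interval encoding
  a pedant would add one frame, but the subtraction convention is the one
  the field's formulas use, so a one-frame bout has duration zero. The
  package applies it everywhere and documents it rather than silently
  "fixing" it.

## Per-fly metrics

`inter_egg_intervals()` returns, per fly, the first frame of each egg
expulsion minus the last frame of the previous one — `n − 1` intervals for
`n` expulsions, always positive on valid annotations. Binned rates
(`counts_per_bin()`, e.g. eggs per 5 min) assign each bout to the bin
containing its start frame; bouts are short relative to 5-min bins and no
splitting rule is established in the field, so proportional splitting is
deliberately not attempted. A trailing partial bin is excluded from binned
rates.

One genuine ambiguity exists in the binned-count and per-egg formulas: the
quantity is named "# Bouts" while the literal formula text reads "sum #
behaviour frames". Figure axes in the literature report bout counts, so
`ovibout` counts **bout onsets** by default and provides
`count_frames = TRUE` for the literal frames reading — label over typo,
with the alternative preserved.

Per-egg normalisations are undefined for flies that laid no egg. Such
values are `NA` with an explicit `defined = FALSE` row in
`bout_metric_table()` and a logged warning — never silently dropped,
because dropping them silently biases group comparisons toward
better-laying flies.

Egg burial is an attribute of the expulsion bout (`buried` ∈ yes/no/
unknown); expulsions whose burial status could not be determined are
excluded from both numerator and denominator of
`proportion_eggs_not_buried()`.

## Peri-event probability curves

`perievent_probability()` aligns all egg expulsions at their **last frame**
(the expulsion moment; offset 0) and reports, for every offset in ±W
frames, the fraction of expulsions during which the behaviour was active.
W defaults to 1200 frames (one minute at 20 fps). Events closer than W
frames to either end of the recording are excluded so that every included
event contributes a complete window — the curve is a proper probability at
every offset, not a ratio with varying denominators.

Normalisation pools expulsions across flies by default, which matches how
the pooled event count is reported (n = events, not flies). The
`per_fly = TRUE` variant computes one curve per fly and averages, with an
across-fly standard error of the mean; which unit the s.e.m. of a pooled
curve should refer to is ambiguous in the literature, so the package only
attaches an s.e.m. to the per-fly variant, where its meaning is exact.
No smoothing is applied; the curves are raw per-frame proportions.

## Phase sequences and the transition matrix

Three phases are defined through representative elements: egg expulsion
marks deposition, abdominal-contortion bouts mark contortions, and
ovipositor contacts that do **not** progress to an expulsion mark
exploration. Proboscis extension is excluded (it occurs throughout
egg-laying and in other contexts entirely) and burrowing is excluded (it
accompanies ovipositor contact at lower frequency and adds no information).

"Progressing" needs an operational definition that the qualitative
description — deposition elements "progress in a continuous sequence" to
expulsion — does not quantify. `ovibout` uses a chain rule: a contact
progresses if it connects to a subsequent expulsion through
deposition-sequence bouts (contact, burrowing, egg pushing, expulsion) in
which consecutive bouts are separated by at most `linkage_gap` frames and
no abdominal-contortions bout intervenes (once contortions start, the
deposition attempt is over). The default gap is **2 s × fps**: long enough
to absorb annotation slack between elements of one deposition, an order of
magnitude shorter than the pauses separating phases.
`linkage_gap_sensitivity()` recomputes the matrix over a grid of gaps so
the stability of this choice can be inspected on any dataset.

Sequences are run-length collapsed (consecutive same-phase events merge,
keeping the earliest onset), which makes self-transitions structurally
impossible: the estimated matrix has a zero diagonal by construction, not
by luck. Adjacent-pair counts are pooled across flies but never across fly
boundaries; a trailing phase at the end of a recording simply contributes
no outgoing transition (no censoring correction is attempted). Pooling
before normalisation is the default; whether published transition diagrams
pooled or averaged per fly is not stated anywhere we know of, so the
per-fly route can be had by calling `transition_matrix()` on single-fly
subsets of the sequence table.

## Optogenetic protocols and stimulus-locked metrics

Protocols are explicit epoch lists. `build_protocol()` produces the pulsed
activation protocol (defaults: 60 s baseline, 6 × 10 s stimuli, 20 s ISIs,
no trailing ISI — total 230 s) and `build_constant_protocol()` the
constant-light silencing protocol (10 / 15 / 5 min). Conversion to frames
uses half-open windows `[round(t·fps), round(t'·fps))`, which tile the
protocol exactly; an expulsion ending precisely on a boundary belongs to
the epoch that starts there.

A stimulation "has" a behaviour when at least one frame of a bout overlaps
the ON window — no minimum-duration or onset-inside requirement is imposed
by default because none is established; both are available
(`min_overlap_frames`, `require_onset_inside`). Egg allocation assigns
each expulsion to the epoch containing its end frame (the expulsion moment
used throughout), and latency is measured from the first stimulus onset to
the start of the first expulsion at or after it. For constant-light
protocols per-stimulus metrics are trivially single-windowed; 16-h
activation assays reduce to whole-period egg counts and are out of the
per-stimulus interface.

## The simulator: what it emulates, and what it does not

`simulate_ethogram()` is a seeded semi-Markov generator whose **defaults
are the study conditions**: 45-min recordings at 20 fps; the cyclic phase
structure with P(deposition→contortions) = 1, P(contortions→deposition) =
P(contortions→exploration) = 0.5, P(exploration→deposition) = 1; the fixed
deposition element order; optional grooming (p = 0.5); 94% of eggs buried;
and dwell/duration medians chosen once so that the per-fly median
inter-egg interval lands in the 2–3 min band (the simulated median is
≈148 s over 200 flies; ≈17–18 eggs per fly per 45 min).

Distribution families are not reported for real dwell times, only medians
and ranges; log-normal is used throughout as the standard positive,
right-skewed choice matching the long-tailed interval scatter of real
recordings, with `meanlog` equal to the log median in seconds. Two
structural guards keep the generated annotations consistent with the
phase-extraction semantics:

- within-deposition gaps are capped at 1.8 s, so a deposition's ovipositor
  contact always chains to its expulsion under the default 2-s linkage
  gap;
- phases are separated by a buffer of at least 2.5 s and exploration
  contacts by at least 3 s, so exploration bouts never chain into the next
  deposition.

These guards are what make the ground-truth phase sequence recoverable
*exactly* by `extract_phase_sequence()` — a deliberate design choice: the
simulator tests the estimator's correctness, and parameter-recovery error
should come from sampling noise, not from ambiguous corner cases planted
by the generator itself. Real annotations carry no such guarantee; on real
data the linkage-gap sensitivity report is the honest check.

Other simplifications, stated plainly: exploration is generated as
independent probing bouts with no spatial model (the arenas are small);
proboscis extension is a background renewal process overlapping all
phases; egg-pushing and expulsion are sequential rather than overlapping
postures; a deposition whose expulsion would start after the recording end
is dropped wholesale rather than half-emitted. Passing recovery tests on
simulated data therefore demonstrates estimator correctness under the
declared generative assumptions — not that real egg-laying follows a
first-order semi-Markov process.

Determinism: all sampling happens in seconds as doubles; frames are
produced by integer rounding only at emission. Per-fly seeds derive
deterministically from the master seed, so `(config, seed)` fixes the
dataset bit-for-bit across runs.

## Statistics

`compare_groups()` reproduces the automated test-selection logic used for
pairwise comparisons of per-fly metrics: both samples must pass
Shapiro–Wilk **and** D'Agostino–Pearson normality at α = 0.05 (the gate α
is conventionally unstated; 0.05 is assumed and configurable) to proceed to
Bartlett's variance test — Bartlett being the variance gate appropriate for
normal data — and then to Student's or Welch's t; otherwise Mann–Whitney.
D'Agostino's K² is implemented in-package (skewness and kurtosis Z
transformations, K² ~ χ²(2)) and verified against an independent reference
implementation in the test suite; it requires n ≥ 8, below which the gate
falls back to Shapiro alone and says so in the decision trail. For n < 3
the comparison refuses to run. Two identical samples yield p = 1 ("ns"),
including the degenerate all-tied case.

No multiple-testing correction is applied, matching the per-comparison
reporting convention of the analyses this package mirrors. This is worth
restating: every p-value is marginal, and users running many comparisons
should correct downstream.

`fisher_2x2()` delegates to the standard two-sided exact test (sum of
hypergeometric probabilities no larger than the observed table's); the
test suite checks it against a from-scratch enumeration to 10⁻¹².

## The pipeline, reproducibility, and problem sizes

`run_pipeline()` executes simulate/read → validate → metrics → peri-event
→ transitions (→ optostim) and writes every table only after all stages
succeed, so a failed stage leaves no partial run directory. Equal-seed
runs are byte-identical; to keep that guarantee the run log records stage
events without wall-clock timestamps.

The test suite sizes its simulations to what the checks need: 200 random
small datasets for the oracle-fidelity battery, 60 flies of 45 min (≈2500 transitions, ≥ 2000
required) for transition recovery at max-abs-error < 0.05, 200 flies for
the dwell-time calibration band,
1000 null replicates for the empirical type-I error of the selection gate
(0.05 ± 0.02), and 100-fly overlays (600 stimuli) for response-rate
recovery within two binomial standard errors.

## Known limitations

- The phase-extraction chain rule is an operational reconstruction of a
  qualitative description; its `linkage_gap` is a free parameter with a
  sensitivity report, not a measured constant.
- Pooled peri-event curves carry no uncertainty band (see above); use the
  per-fly variant when error bars are needed.
- No kinematics: distances, velocities and postural detail are outside the
  annotation data model.
- The simulator is first-order in phases by construction and cannot, and
  should not, be used to argue that real behaviour is.
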
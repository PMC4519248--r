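---
title: "Behavioral phenotyping of adult zebrafish: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral phenotyping of adult zebrafish: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finquant)
```

## What this package computes

`finquant` quantifies the spontaneous swimming behavior of individually
recorded adult zebrafish from tracked 2-D coordinates, and carries the
companion arithmetic used to genotype splice-site mutants. The behavioral
battery is the standard one for hypoxia-response phenotyping:

* **Kinematics** — total distance swum (summed Euclidean distances between
  consecutive frames), per-second instantaneous velocity (sum of the
  inter-frame distances within each non-overlapping 1-s window), maximum
  instantaneous speed, and the cumulated-time speed histogram in 1 cm/s
  bins.
* **Speed activity profiles (SAP)** — each observed second is classed as
  rest, moderate or fast relative to body length (bl): rest below
  0.5 bl/s, fast at or above 3 bl/s. For a ~2 cm fish (3 months
  post-fertilization, mpf) the thresholds are 1 and 6 cm/s; for a ~4 cm
  fish (9 mpf), 2 and 12 cm/s.
* **Occupancy** — time in the upper quarter of the water column
  (vertical-plane recordings; the aquatic-surface-respiration proxy,
  because dissolved oxygen is highest near the surface) and time in the
  open center of the tank footprint (horizontal plane; centrophobia /
  thigmotaxis, a stress index).
* **Respiration** — opercular movement counts per minute, compared across
  genotypes.
* **Statistics** — pairwise Mann–Whitney tests on per-fish scalars, a
  pooled chi-square comparison of SAP distributions, and an exact
  two-tailed Freeman–Halton Fisher test for small r×c count tables.

Because raw video recordings of such assays are rarely deposited, the
package ships a first-class synthetic cohort generator. Every analysis
stage is exercised and validated against data whose ground truth is known
exactly.

## The cohort simulator

Each fish is driven by a hidden three-state behavioral process (rest /
moderate / fast). After an exponential holding time with state-specific
mean $d_i$ (`state_mean_dwell_s`), the next state is drawn independently
with probability $\nu_i \propto \pi_i / d_i$, where $\pi$ is the target
long-run occupancy (`state_occupancy`). By renewal–reward, the long-run
fraction of time in state $i$ is $\nu_i d_i / \sum_j \nu_j d_j = \pi_i$
— *exactly*, for any target, which is what makes parameter recovery a
meaningful acceptance surface. Self-transitions are permitted (the draw is
independent of the current state), so an uninterrupted sojourn in one
state is a geometric sum of exponential segments; the dwell parameter is
the mean of one segment. A burn-in of 20 maximal dwell times absorbs the
non-length-biased start before the process is sampled at 1-s marks.

Within each second, a speed is drawn from the current state's
distribution (truncated normal by default, gamma optional) truncated to
that state's body-length band, so the hidden state is recoverable from the
observed speed alone. The speed is then realised as `fps` equal-length
inter-frame steps along a correlated-random-walk heading (per-frame
heading increments $\mathcal N(0, 1/\sqrt{\kappa})$ with
`turning_concentration` $\kappa$). A step that would leave the tank has
its offending velocity component reflected *before* it is taken, so every
inter-frame step keeps its exact length; the per-second sum of step
distances therefore equals the drawn speed to machine precision, and the
kinematics stage recovers the simulator's hidden speeds exactly (this is
tested). For vertical recordings, a two-state surface/column bout process
(mean surface bout `surface_mean_dwell_s`, long-run surface share
`vertical_preference`) confines the vertical coordinate to the upper
quarter during surface bouts.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `fps` | 25 | standard infrared tracking frame rate for this assay |
| `duration_s` | 3600 | one-hour free-swimming recording |
| `body_length_cm` | 4 (9 mpf), 2 (3 mpf) | typical standard lengths at those ages |
| tank (9 mpf) | 18 × 24 cm | footprint of the larger individual tank |
| tank (3 mpf) | 8.8 × 11.8 cm | footprint of the smaller individual tank |
| `state_occupancy` | 70/25/5 (WT, HT 9 mpf), 5/75/20 (HM 9 mpf), 15/70/15 (3 mpf) | qualitative genotype pattern of the assay: affected homozygotes nearly stop resting and swim at moderate speed most of the time |
| `state_mean_dwell_s` | 0.3 s | zebrafish locomotion is organised in sub-second beat-and-glide bouts; see below |
| `speed_cap_cm_s` | 21 | ceiling of the 1 cm/s speed histogram |
| `turning_concentration` | 4 | moderate heading persistence (≈ 29° r.m.s. per frame) |
| `vertical_preference` | 0.25 (WT), 0.65 (HT), 0.50 (HM) | genotype ordering of surface preference in the assay (HT > HM > WT) |
| `respiration_rate_per_min` | 110 (WT), 115 (HT), 220 (HM) | affected homozygotes roughly double their opercular rate |
| `between_fish_cv` | 0.10 | between-fish heterogeneity is not constrained by published summaries; a mild 10% lognormal scatter on respiration rates is a realistic default and is deliberately *not* applied to occupancy targets (see the chi-square note) |

The preset occupancies are illustrative fixtures reproducing the
qualitative structure of the published genotype contrast, not estimates
fitted to any recording. Group sizes in the presets (15/19/7 fish at
9 mpf, 12/16/11 at 3 mpf) mirror the study design this battery comes
from.

**Why sub-second dwells.** The pooled chi-square construction (below)
treats each observed second as an independent draw. That is an honest
description of the data-generating process only if the behavioral state
decorrelates on a time scale at or below the 1-s analysis window. Bout
durations of a few hundred milliseconds are the biologically typical
regime for adult zebrafish swimming, and with $d_i = 0.3$ s the lag-1
autocorrelation of the sampled state is $\approx e^{-1/0.3} < 0.04$, so
the generator and the statistical layer describe the same study
conditions. Users modelling slow macro-states (long quiescent bouts)
should increase the dwells *and* expect the pooled chi-square to become
anticonservative — that is a property of the pooled test, not of the
simulator.

## Design decisions in the analysis stages

* **"Triangulation" distance** is the straight-line Euclidean distance
  between consecutive frame coordinates — the only reading consistent with
  per-frame 2-D coordinates.
* **Windows** for instantaneous velocity are non-overlapping, aligned to
  the first frame; a trailing partial window is discarded rather than
  rescaled.
* **SAP band edges.** Verbal definitions of the three classes leave the
  boundary speeds ambiguous (a speed of exactly 0.5 bl/s is excluded by
  both a "< 0.5" rest class and a "> 0.5" moderate class). The package
  resolves the bands as half-open intervals $[0, 0.5\,\mathrm{bl})$,
  $[0.5\,\mathrm{bl}, 3\,\mathrm{bl})$, $[3\,\mathrm{bl}, \infty)$, which
  partition all speeds — a requirement for pie-chart fractions that sum
  to 100%.
* **Histogram bins** are half-open $[i, i+1)$ cm/s with one overflow bin
  at the cap (default 21 cm/s); a boundary speed belongs to the bin whose
  lower edge it equals.
* **Zone membership is per frame** (each tracked frame contributes
  1/fps s), because occupancy is a property of position; SAP is per
  second because velocity is defined per second. The published assay
  scored surface time from accelerated manual viewing; the per-frame
  computation here is the exact version of that measurement and will
  differ from a human count by at most the human's scoring resolution.
* **Center zone** is the concentric rectangle with the tank's aspect
  ratio scaled by $\sqrt{0.5}$ per side, giving exactly half the surface;
  the boundary counts as inside.
* **Missing data.** Tracking losses are explicit `NA`s. Runs of at most
  `max_gap_frames` (default 5, i.e. 0.2 s at 25 fps) are linearly
  interpolated; longer runs are excluded from numerator *and* denominator
  of every downstream fraction, and all summaries carry the effective
  observed time. Conservative exclusion avoids biasing occupancy metrics
  toward the interpolation path.
* **Water-column height** is metadata, not derived: a water volume does
  not determine a column height without the tank's full geometry, so the
  vertical extent must be supplied with the recording.

## The statistical layer

**Mann–Whitney.** Exact null distribution when the smaller group has at
most 8 fish and the pooled sample is tie-free; otherwise the normal
approximation with tie correction and continuity correction. The U
statistic is reported for the first group. An exhaustive-permutation
oracle (all $\binom{n_a+n_b}{n_a}$ relabelings) checks the exact branch in
the test suite.

**Chi-square on SAP distributions.** The 2×3 table pools integer seconds
per class over the fish of each genotype — the construction that matches a
per-genotype SAP pie chart and yields df = 2 per pairwise comparison. The
caveat is stated prominently: seconds within one fish are
pseudo-replicates, so with systematic between-fish differences the pooled
test overstates significance. The per-fish Mann–Whitney comparisons of
class seconds are the complementary fish-level analysis, and the simulator
consequently keeps within-genotype fish exchangeable. Expected cells
below 5 raise a flag but the statistic is still returned.

**Exact r×c Fisher (Freeman–Halton).** All tables with the observed
margins are enumerated recursively (the last row and last cell of each row
are forced by the margins); each table's probability is
$\prod_i r_i!\,\prod_j c_j! \,/\, (N!\prod_{ij} n_{ij}!)$, computed in log
space. The two-tailed p sums every table whose probability does not exceed
the observed table's (relative tolerance $10^{-9}$ guards floating-point
equality) — the probability-ordering convention, the most common
definition of the two-sided exact test. Enumeration is guarded at
$N \le 500$; beyond that a chi-square test is the appropriate tool. The
enumerated probabilities summing to 1 (±10⁻⁹) is asserted in tests, and
`stats::fisher.test` serves as an independent cross-check, never as the
implementation.

**No multiplicity correction is applied by default**, matching the
analysis convention this battery reproduces; `stats::p.adjust` composes
trivially with the returned tables if a user wants Holm-adjusted reports.

## Genotyping arithmetic

The sequence module operates on a fully synthetic locus
(`synthetic_splice_locus()`) emulating a col6a1-like exon 10–16 region
with a 54 bp central exon: the genotyping amplicon is 246 bp with the
exon/intron junction 136 bp from the forward primer (so a junction-located
heteroduplex cut yields 136 + 110 bp T7EI fragments), and the RT-PCR
product across exons 10–16 is 298 bp intact and 244 bp after skipping the
central exon. These numbers arise from the planted construction, and the
package recomputes them from the sequences at run time rather than
asserting them.

* **Indel calling** globally aligns read to reference
  (`Biostrings::pairwiseAlignment`, match 2 / mismatch −3 / gap open 10 /
  extend 1), reports contiguous gap runs, merges same-kind runs separated
  by fewer than 3 aligned matching nucleotides (one repair event), and
  normalises each event to its **leftmost equivalent placement** — the
  standard representation for ambiguous indels in repeat context.
  The minimum reported event length is mode-dependent: 2 bp in mosaic F0
  screening (single-base events are indistinguishable from polymerase
  slippage there) and 1 bp for directly sequenced non-mosaic F1 material.
* **Splice-donor rule.** A mutation touching either of the first two
  intron nucleotides predicts skipping of the preceding exon; frame
  preservation is decided by the exon length modulo 3. The donor window
  is widenable to a consensus of configurable width. The outcome is
  explicitly heuristic — a donor mutation can instead destabilise the
  transcript (nonsense-mediated decay) and never appear as a skipped
  band — so every prediction carries a caveat field, never a silent
  override.
* **Coordinates** are 1-based inclusive throughout, with
  `as_zero_based()` / `as_one_based()` converters.
* The **T7EI cut position** is an input (or derived as the indel midpoint
  by `t7ei_cut_site()`), not predicted from mismatch thermodynamics.

## What the synthetic data does and does not show

The generator reproduces: genotype-dependent rest/moderate/fast occupancy,
body-length-scaled speed bands, surface preference, respiration contrast,
bounded-tank geometry, seeded reproducibility, and tracking-loss handling
(when gaps are introduced). It does **not** emulate hydrodynamics,
wall-following kinematics (thigmotaxis beyond zone fractions),
fish–fish interaction, habituation across the recording, or diurnal
effects. Passing the recovery and calibration suites therefore
demonstrates the correctness of the *analysis* under its stated
assumptions, not the behavioral realism of any particular preset.

## Problem sizes used in validation

The shipped validation suite uses 10 fish × 3600 s cohorts for occupancy
recovery (tolerance ±3 percentage points per class), 1000 null replicates
for Mann–Whitney calibration (acceptance band 3–7% at α = 0.05), 200
replicates of 7–15 fish × 3600 s speed processes for the chi-square
power (≥95% at α = 0.01) and null (≤10% rejection at α = 0.05) studies,
30 simulated minutes of uniform positions for the zone Monte-Carlo
(±2 points), and 100 random 220–280 nt references with planted 1–20 bp
indels for exact indel recovery. These sizes give comfortable margins
between the statistical noise floor and the stated tolerances.

## Known limitations

* The pooled chi-square inherits the pseudo-replication caveat above.
* `predict_transcript_outcome()` scores full indel length modulo 3 for
  events spanning an exon boundary without donor involvement, a
  simplification documented in its help page.
* The simulator's vertical mode targets the surface-bout share; transit
  frames between bands dilute the realised upper-quarter fraction
  slightly below the bout share for short recordings.
* Exact Mann–Whitney p-values are unavailable with ties (the corrected
  normal approximation is used), matching standard practice.
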
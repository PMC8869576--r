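---
title: "Staging sleep and quantifying abnormal REM from a wrist-worn sensor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging sleep and quantifying abnormal REM from a wrist-worn sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnograph)
```

## The problem

REM sleep behavior disorder (RBD) — pathological movement during REM sleep —
is strongly associated with Parkinson's disease, but its gold-standard
diagnosis needs laboratory polysomnography. A consumer smartwatch records
two signals that carry most of the needed information: wrist acceleration
(movement) and PPG-derived heart rate. `somnograph` implements a
three-stage epoch classifier over those two signals and an *abnormal-REM
percentage*: the fraction of REM minutes in which wrist activity exceeds a
G-value threshold. Elevated values of that index are a screening signal for
RBD.

All processing operates on non-overlapping 30-second epochs. Each epoch
carries a **G-value** — a non-negative activity magnitude in device activity
units — and a mean heart rate in beats/minute.

## The classifier

### Stage 1: sleep/awake (Cole–Kripke)

Each epoch is scored with a weighted window over its own and six
neighbouring epochs' activity,

$$D_t = P\,(W_{-4}A_{t-4} + W_{-3}A_{t-3} + W_{-2}A_{t-2} + W_{-1}A_{t-1} +
W_{0}A_{t} + W_{+1}A_{t+1} + W_{+2}A_{t+2}),$$

with $D \ge 1$ scored WAKE and $D < 1$ SLEEP. The default weights are
$(50, 30, 14, 28, 121, 8, 50)$ for offsets $-4 \dots +2$ and the default
scale factor is $P = 0.01076$. Epochs outside the record contribute zero
activity — the standard actigraphy convention for record boundaries.

Two numerical points. First, the weight list is taken as strictly one weight
per offset $-4\dots+2$; the centre epoch dominates ($W_0 = 121$). Second,
the wake rule is evaluated with an absolute tolerance of $10^{-9}$, so an
activity of exactly $1/(P\,W_0)$ in an otherwise quiet record — whose exact
score is the boundary value $D = 1$ — classifies WAKE rather than falling a
unit-in-the-last-place short of it.

**The scale factor is device-specific.** $P$ converts a weighted sum of
device activity units into the dimensionless wake score, and its published
default was fitted to one particular device's unit scale. No single scale
makes that default coexist with the light/deep score bins below (40–600
device units) — with $\sum_k W_k = 301$, $P = 0.01076$ puts the sleep
boundary at a mean epoch activity of about $0.31$ units, orders of magnitude
below the bins. We therefore treat $P$ exactly as it was produced: a
per-device calibration constant. The default stays at the published value;
`sim_staging_config()` documents the calibration for the package's own
synthetic device ($P = 1.5\times10^{-6}$, below).

### Stage 2: light/deep by cumulative G-value score

Over the sleep epochs in time order a running score starts at 0 and adds the
increment of the bin containing the epoch's G-value:

| G-value | increment |
|---|---|
| $[0, 40)$ | $+1$ |
| $[40, 50)$ | $-2$ |
| $[50, 80)$ | $-3$ |
| $[80, 200)$ | $-5$ |
| $[200, 400)$ | $-10$ |
| $[400, 600)$ | $-20$ |
| $[600, \infty)$ | $-20$ (the published bins stop at 600; we extend the last increment) |

The score is clamped below at 0 and an epoch is DEEP iff its post-update
score exceeds `deep_score_threshold` (default 0), LIGHT otherwise; wake
epochs are untouched. The mapping from the running score to the
light/deep label was a genuinely open design point: we chose the cumulative
clamped score with a strict zero threshold because it makes quiescent runs
accumulate evidence for deep sleep while single active epochs reset toward
light sleep. The threshold is configurable and the choice is flagged here
deliberately: it gives the classifier *hysteresis* — after a long quiescent
run, a brief movement does not immediately leave deep sleep. That hysteresis
is physiologically sensible and turns out to matter for the abnormal-REM
index (below).

### Stage 3: REM by per-night heart-rate clustering

Heart rate is elevated in REM relative to slow-wave sleep, so the DEEP
epochs of each night are split by a two-cluster one-dimensional k-means on
their heart rates, trained per subject-night; the higher-centroid cluster
is relabelled REM. The clustering is the classical Lloyd iteration with the
following concrete choices:

* **Initialisation**: a seeded draw of two distinct observed values
  (`rng_seed`); `kmeans_restarts` (default 10) independent initialisations
  are run and the lowest within-cluster sum of squares kept. One-dimensional
  two-means has local optima, and restarts are the standard cure; the test
  suite checks the result against an exhaustive contiguous-split oracle.
* **Assignment ties**: a point equidistant from both centroids joins the
  lower-valued centroid (deterministic).
* **Termination**: memberships unchanged for `kmeans_stable_iters`
  (default 100) consecutive iterations, or `kmeans_max_iter` (default 300).
* **Degenerate nights**: if the DEEP heart rates have fewer than two
  distinct values, no split is attempted; the night keeps its DEEP labels
  and is flagged (`rem_degenerate`), rather than fabricating clusters.
* **Scale**: clustering runs on beats/minute by default. The RR-interval
  scale (milliseconds) is a monotone transform with potentially different
  cluster memberships; `cluster_on = "rr"` exposes it.

### REM cleanup rules

Three rules are applied once each, in order:

1. **Onset lockout.** REM within the first 45 minutes after sleep onset
   (the first non-WAKE epoch) is demoted — REM pressure this early is
   implausible and early high-heart-rate clusters are usually
   misclassification.
2. **Separated short REM.** *Separated* REM shorter than 5 minutes is
   demoted. We read "separated" structurally: REM segments lying within the
   rule-3 merge distance (3 minutes) of one another form one REM *period*,
   and a period is demoted only if its whole span is under 5 minutes. The
   alternative reading — demote every short fragment regardless of context —
   makes rule 3 unreachable for precisely the pattern the abnormal-REM index
   must count (a movement arousal splitting an ongoing REM period into short
   fragments), and we verified empirically that it collapses burst detection.
3. **Short gaps.** A non-REM gap of at most 3 minutes between two REM
   segments is promoted to REM, *overruling* the upstream classifiers. By
   default this includes WAKE gaps (`rem_gap_include_wake = TRUE`): a
   movement arousal inside REM is exactly what the index must keep inside
   REM. Setting it `FALSE` preserves WAKE gaps.

Demoted REM becomes DEEP, which is what it was before the heart-rate split,
keeping the relabelling history consistent. The composed operator is
idempotent (property-tested on 1000 random hypnograms), so the cleanup is a
projection: applying it to already-clean data changes nothing.

## Cross-device scaling

Activity recorded by a different sensor is mapped into the range the
thresholds assume by a constant factor fitted from device extrema: the
range ratio $(G_{max}-G_{min})/(G_{dmax}-G_{dmin})$, the maximum ratio
$G_{max}/G_{dmax}$, or the minimum ratio $G_{min}/G_{dmin}$. The minimum
ratio is the default (it performed best in the original wearable-vs-PSG
benchmark). Scaling is linear and order-preserving; the min-ratio fit maps
the source minimum exactly onto the reference minimum. Extrema default to
the subject-night being scaled — the smallest self-contained unit — and can
be supplied explicitly to pool recordings.

## The abnormal-REM index

$$\%\,\text{abnormal REM} = 100 \cdot n / T,$$

where $T$ is the night's total REM minutes and $n$ the number of those
minutes whose G-value exceeds a threshold (default 1500). The pipeline is
epoch-based while the index is defined per minute, so a minute is two
consecutive REM epochs within a segment (a trailing odd epoch counts as one
minute), aggregated by the maximum G-value of its epochs (`"mean"` is
available). A night with no REM reports 0% with an explicit `no_rem` flag
rather than an undefined ratio. The index is non-increasing in the
threshold, which the tests check as a property.

### Threshold selection

The screening threshold is chosen by a sweep: for each candidate (default
1200 to 4500 in steps of 300) every subject's abnormal-REM summary is
computed and the control and patient groups are compared with a two-sided
Mann–Whitney U test; the chosen threshold minimises the p-value, ties going
to the smaller threshold. The per-subject summary defaults to the
*percentage*: raw suprathreshold-minute counts confound the burst rate with
total REM duration, and the groups differ roughly two-fold in REM time, so
counts can equalise even when rates clearly differ. `"abnormal_minutes"`
and `"g_median"` are exposed for sensitivity analyses.

The Mann–Whitney test itself is implemented in-package because the sweep
needs an exact small-sample null that handles ties: for combined $n \le 20$
the null distribution of U is enumerated over all group assignments of the
pooled observations (midranks, so ties are exact); larger samples use the
normal approximation with tie correction and continuity correction. When
every observation is tied the tie-corrected variance is zero and the
p-value is defined as 1. Exactness is verified against brute-force
enumeration for all group sizes up to 8.

## Evaluation tools

Confusion matrices against reference hypnograms are computed at three
resolutions: wake/sleep over all epochs; NREM/REM and light/deep/REM over
the epochs both hypnograms score as sleep. Accuracy is the diagonal
fraction. Reference labels in polysomnography dialects (`0/W`, `1/2/N1/N2`,
`3/4/N3`, `5/R/REM`) are mapped on read. Sleep summaries use half-minute
epochs: total sleep time, time in bed, their ratio as sleep efficiency, and
stage percentages over sleep epochs (these sum to 100 exactly). Two-group
cohort comparisons use the rank-sum test above; three-group designs use
Kruskal–Wallis (`stats::kruskal.test`); device-vs-reference agreement
reports MAE, MAPE, RMSE and Spearman's rho (`stats::cor.test`, exact for
$n \le 9$ without ties).

## The synthetic-data generator

`simulate_night()` generates the statistical structure the classifier
consumes, nothing more:

* an epoch-level Markov chain over WAKE/LIGHT/DEEP/REM whose self-transition
  probabilities produce realistic run lengths and a cyclic architecture,
  with REM transitions redirected to LIGHT until 45 minutes after sleep
  onset (so ground-truth REM never violates the lockout);
* stage-conditional heart rate, normal with REM > LIGHT > DEEP means,
  clamped to the physiological window (20, 250) bpm;
* stage-conditional log-normal G-values: wake around 8000 units, light
  sleep around 130 (inside the negative score bins), deep sleep and REM
  around 8 (REM atonia);
* per REM minute, with probability `abnormal_rem_burst_prob`, the minute's
  G-values are replaced by a burst drawn uniformly from 1600–3200 — above
  the 1500 screening threshold.

The default profiles encode the study conditions the package targets: an
8-hour in-bed protocol (960 epochs); burst probabilities of 0.016 per REM
minute for controls and 0.038 for the PD profile (0.020 and 0.057 for the
clonazepam subgroup profiles), matching the reported group abnormal-REM
percentages; transition rows calibrated so the control architecture is
deep/REM-rich (roughly 26/38/36 light/deep/REM) and the PD architecture
light-dominated (roughly 60/22/18), with sleep efficiencies in the low-to-mid
80s percent. The PD profile also carries the reported phenotype of lower
deep-sleep heart rate and more variable REM heart rate.

**The synthetic device's unit scale.** The generator defines its G-value
unit so that the score bins are meaningful (sleep activity spanning roughly
5–400 units) and calibrates the Cole–Kripke factor accordingly:
$P = 1.5\times10^{-6}$ puts the sleep/wake boundary (a weighted-window
activity of $1/P$) between the sleep range and the wake range. The margins
are deliberate: sustained wake at ~8000 units trips the 7-epoch window
($301 \times 8000 \times P \approx 3.6$), while a 1–2-minute burst at up to
3200 units does not ($149 \times 3200 \times P \approx 0.7$ at the burst
centre). A burst instead lands in the $\ge 600$ score bin, scores LIGHT (or
is absorbed by accumulated score), and rule 3 merges it back into REM —
which is the mechanism that lets the index count it.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: PPG artifacts and missing heart rate, sensor
drift, apnea-related patterns, periodic limb movements, inter-night
within-subject correlation, circadian variation in heart rate, and any
dependence between activity and heart rate within a stage. Parameter
recovery on this generator demonstrates internal consistency of the
pipeline, not clinical validity.

## Problem sizes and runtime choices

The bundled studies are sized for interactive use: the cohort study stages
38 nights of 960 epochs (it runs in a few seconds), the clustering oracle
check uses 200 instances of at most 12 points, exact rank-test enumeration
covers all group sizes up to 8, and the idempotence property uses 1000
random 160-epoch hypnograms. The staging-recovery regression uses three
nights from a sharply separated profile (tight stage distributions, no
bursts, few arousals) and asks for at least 90% four-way epoch agreement
with the ground truth; on the default, noisier profiles agreement is around
86–91%.

## Known limitations

* The score-to-stage rule (cumulative, clamp, strict-zero threshold) is a
  documented convention, not a published constant; conclusions sensitive to
  the light/deep boundary should vary `deep_score_threshold`.
* The k-means REM split needs heart-rate contrast between deep and REM
  sleep within the night; nights with flat heart rate are flagged, not
  split.
* $P$ must be calibrated per device family; the published default is not
  transferable across unit scales, and the package makes that calibration
  explicit rather than hiding it.
* A minute is an epoch pair, so a single suprathreshold epoch makes its
  whole minute abnormal under the `max` aggregate; `mean` is stricter.
* The two-group test treats subjects as independent; repeated nights from
  one subject must be summarised before testing.
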
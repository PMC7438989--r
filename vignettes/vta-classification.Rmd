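---
title: "Classifying VTA neurons from extracellular recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying VTA neurons from extracellular recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtaclust)
```

## The problem

The ventral tegmental area (VTA) mixes dopaminergic (DA), GABAergic and
glutamatergic neurons. During in vivo extracellular single-unit recordings in
anesthetized rats, experimenters traditionally sort units by eye using a
handful of electrophysiological conventions: DA neurons fire slowly
(~2–4 Hz) with broad, often notched action potentials (APs) and irregular,
bursty discharge; GABAergic units fire fast (>10 Hz) with narrow APs.
These criteria overlap, and ad hoc combinations invite bias. `vtaclust`
implements an objective alternative: compute a small set of standard
features per unit, remove the unambiguous high-firing group, and let
unsupervised hierarchical clustering decide how the remaining, presumably
dopaminergic, population splits.

## The six features

For each unit the package computes, from the spike timestamps and the mean
AP waveform:

1. **Firing rate** (Hz): spike count over the observation window. Windows of
   at least 5 min of stable firing are expected; shorter epochs are
   rejected (`min_duration_s`, default 60 s as a hard floor).
2. **Firing-rate CV** (dimensionless): SD/mean of spike counts in
   consecutive 10 s bins (trailing partial bin discarded). The recording
   convention ("CV of the firing rates") does not pin down the estimator;
   binned rates rather than interspike intervals (ISIs) are the default
   here, with `bin_width` exposed. A perfectly regular train gives 0; a
   Poisson train tends to `1/sqrt(rate * bin_width)`.
3. **Percentage of spikes in bursts** (%SIB): the classical 80/160 ms rule.
   A burst opens at an ISI ≤ 80 ms, extends while ISIs stay < 160 ms, and
   is closed by a silence ≥ 160 ms; both boundaries are inclusive.
4. **Total AP duration** (ms) and
5. **Δt₁** (ms), the time from initiation of depolarization to the end of
   repolarization. Landmarks are threshold crossings at `noise_k` (default
   3) pre-trigger noise SDs around baseline: onset is the last sample at
   baseline before the principal peak, Δt₁ ends at the first return to
   baseline after the trough, the AP ends at the last *sustained*
   (≥ 0.05 ms) supra-threshold excursion, which includes the
   after-potential. All measures are invariant to amplitude scale, offset
   and polarity.
6. **Notch** (0/1): presence of a counter-movement (local extremum pair) on
   the rising or falling phase with prominence of at least 5% of the
   peak-to-trough amplitude.

### The terminal-silence reading of the burst rule

The quoted rule requires at least two spikes within 80 ms *followed by a
silence of at least 160 ms*. Treating the end of the recording as an
implicit burst close leads to an absurdity for fast pacemaker units: a
19 Hz regular train (mean ISI ~51 ms) would count as one train-long burst,
100% SIB — yet such units are reported with essentially zero bursting.
Under the reading implemented here (default
`require_terminal_silence = TRUE`) the closing silence must actually occur,
so a fast regular train that never pauses for 160 ms has 0% SIB, matching
how these units are characterized in practice. The alternative reading is
available as a flag. For ordinary DA-like trains, which pause often, the
two readings differ at most in the final spike run.

## Pre-filter and clustering

Units firing strictly above 10 Hz are split off first as putatively
GABAergic and summarized as their own group ("cluster 1"); a unit at
exactly 10 Hz stays. The remaining feature matrix is min–max scaled to
[0, 1] per column, PCA by singular value decomposition is reported (as a
variance-capture diagnostic; clustering uses the scaled features, not the
scores), and Ward agglomerative clustering is run on Euclidean distances in
the `ward.D2` dialect (squared distances inside the minimum-variance
criterion, merge heights on the distance scale — the modern convention; the
older `ward.D` dialect differs and is not used).

The number of clusters is chosen by a majority vote of four internal
validity indices evaluated on Ward cuts for k = 2..10: mean silhouette
width, Calinski–Harabasz, Davies–Bouldin and the Dunn index. Ties are
broken by the silhouette (then the smaller k), which is also the index
given interpretive priority. A 30-index battery would add breadth, not
depth: the indices here cover the three main families (cohesion/separation
ratios, variance ratios, diameter ratios), the per-index votes are
reported, and the set is extensible.

### Why the notch is excluded from the distance metric

After min–max scaling a binary 0/1 column spans the entire unit interval;
with ~50% prevalence its variance (0.25) dominates every continuous
column's, and Ward's criterion then partitions by notch before anything
else. Simulated cohorts show this plainly: with the notch at full weight
the two-cluster cut is the notch partition (adjusted Rand index ≈ 0
against the generating populations), while the published reference
clusters are demonstrably *not* notch-partitioned (roughly half of each
cluster is notched). The default is therefore `feature_weights =
c(notch = 0)`: the notch is computed, reported, and tested for association
with the clusters (chi-square), but does not enter the Euclidean metric.
Any other weight can be set in the pipeline config. Mixed-type metrics
(e.g. Gower) were deliberately not introduced, to stay with a single scaled
matrix.

## Cluster characterization

The final grouping (high-firing group first, clustered groups in ascending
mean %SIB) is summarized as mean ± SEM (SD/√n) for rate, %SIB, AP and Δt₁
durations, plus counts of bursting and notched units. Group differences
are tested with Kruskal–Wallis (tie-corrected) followed by Dunn's pairwise
z tests on mean ranks, Bonferroni-adjusted — the uncorrected Pearson
chi-square is used for notch contingencies. The Bonferroni family is the
default because it reproduces the conventional behavior of the commercial
statistics software typically used with these data; the adjustment method
is a parameter. Log-normality of rates and (non-zero) bursting percentages
is checked by Shapiro–Wilk on log₁₀ values.

The chi-square default deserves a note: on the reference notch table
(102/205 vs 34/64 notched) the uncorrected statistic gives p ≈ 0.64,
matching the published analysis; the Yates-corrected one does not. Yates
correction is available as a flag.

## The synthetic cohort generator

Real recordings of this kind are rarely deposited, so the package ships a
generator that produces cohorts with *exactly known* ground truth, making
every pipeline stage testable offline.

**Spike trains** are built from events: with probability `p_b` an event is
a burst of k spikes (k from a configurable distribution over 2..6,
intra-burst ISIs uniform on 30–70 ms), otherwise a single spike.
Inter-event gaps are 170 ms plus a gamma variate, so every gap exceeds the
160 ms closing silence and *every constructed burst, and nothing else,*
satisfies the detector's rule — the detector provably reproduces the
constructed labels spike-for-spike, which the test suite asserts. `p_b`
solves `pct_sib = 100·p_b·E[k] / (p_b·E[k] + 1 − p_b)` and the gap mean is
solved from the target rate. The 170 ms floor (not 160) leaves a margin so
floating-point timestamp arithmetic can never blur the rule boundary.
Non-bursting units whose rate is too high for such gaps (>~5.9 Hz) are
generated in a *pacemaker regime* instead — gamma ISIs (CV 0.1) truncated
below 160 ms, so no closing silence ever occurs and ground-truth %SIB is
exactly 0; this is the firing pattern of the fast regular, putatively
GABAergic population. Rates in the narrow infeasible window between the
two regimes raise an error stating the bound.

**Waveforms** are a canonical biphasic template (sine-lobe depolarization,
cosine descent through a negative trough, quarter-cosine repolarization,
small decaying after-potential), time-calibrated against
`waveform_metrics()` on the noiseless trace until the requested AP and Δt₁
durations are recovered within 1% (or one sample), then an optional notch
lobe is calibrated by bisection to the requested prominence (default 10%
of peak-to-trough), and Gaussian noise (default SD 1% of peak amplitude)
is added last. Δt₁ is drawn as a ratio of the AP duration, which produces
the linear AP–Δt₁ relationship seen across real cohorts (r² ≥ 0.8 in the
test suite).

### The bundled reference presets

`vta_presets()` describes three populations of the reference cohort
(n = 22 high-firing, 205 low-bursting, 64 high-bursting; 600 s per unit):
group means for rate (19.47 / 2.10 / 3.32 Hz), bursting (0 / 3.29 / 37.97%,
with 124/205 low-bursting units not bursting at all and the burster/
non-burster boundary at 17.5% SIB), AP duration (1.54 / 2.79 / 3.00 ms),
Δt₁ (0.60 / 1.01 / 1.11 ms) and notch prevalence (1/22, 102/205, 34/64)
follow the published characterization of that cohort.

Two generator design choices matter for interpretation:

* **Sample means are calibrated.** Within each population the drawn
  parameters are rescaled (clamped to the preset range, iterated) so the
  cohort's sample mean equals the preset target exactly. Without this,
  √n sampling noise alone (e.g. ~9% SD on the 22-unit group's mean rate)
  would dominate any comparison between recovered summaries and the
  reference values; with it, such comparisons measure pipeline fidelity.
* **Dispersions are chosen, not derived.** The reference characterization
  reports means ± SEM, which bounds but does not determine population
  spread. The preset SDs (log-scale rate SDs 0.285/0.50/0.36, AP SDs
  0.15/0.29/0.32 ms, bursting log-SDs 0.28/0.19, high-bursting SIB starting
  at 21%) were chosen once so that the three populations form the
  distinguishable rate-vs-bursting groups the reference cohort displays.
  Larger, SEM-derived SDs (SD = SEM·√n) produce heavier overlap, under
  which the two-cluster structure is not reliably recoverable by any
  configuration of this pipeline — that regime is a documented limitation,
  not a supported operating point. Consequently, passing tests demonstrate
  that the pipeline recovers populations *of the depicted separability*;
  they say nothing about cohorts whose groups genuinely overlap.
* The high-firing preset sets bursting to exactly 0 (the reference value,
  0.07%, is one bursting unit in 22); a >10 Hz unit with a tiny nonzero
  SIB is not representable under the burst rule (see above), and none of
  the recovered quantities depend on it.

What the generator does **not** emulate: electrode drift and sorting
errors, rate nonstationarity, correlated bursting across units,
waveform-shape families beyond the single biphasic template, and any
pharmacological modulation. Conclusions about real data should rest on the
feature definitions and the clustering procedure, not on the synthetic
cohorts' tidiness.

## Numerical choices and degenerate inputs

* ISI comparisons against the 80/160 ms boundaries use a 1e-6 ms
  tolerance, so timestamps stored in seconds hit the boundaries exactly.
* Constant feature columns scale to 0 with a warning; all-identical rows
  are rejected for cluster-number selection.
* Waveform onset/return landmarks use one-sided threshold crossings (a
  steep trace can jump the noise band between two samples); the AP end
  requires a sustained supra-threshold run so isolated noise samples
  cannot extend the AP.
* Silent trains have no CV (error); trains with fewer than 2 spikes or
  windows under 60 s are rejected for feature extraction.
* A cohort in which fewer than 3 units survive the pre-filter skips the
  clustering stages and reports the high-firing group alone.
* Everything downstream of generation is deterministic; generation is a
  pure function of the seed, and pipeline reruns with the same config and
  seed produce byte-identical reports.

## Problem sizes used in the tests

The suite validates the burst detector against an independent segment-based
oracle on 10⁴ random small trains and on every generated train; Ward
merges against an exhaustive minimum-variance oracle for n ≤ 8; clustering
recovery on 50 seeded replicates of the 269-unit non-high-firing cohort
(adjusted Rand index ≥ 0.9 required in ≥ 90% of them); and the full
291-unit pipeline against the reference group characteristics at 10%
relative tolerance. These sizes keep the default test run within a few
minutes while leaving the statistical assertions well-powered.

## A worked example

```{r example, eval = FALSE}
library(vtaclust)
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> <vta_report>
#>   units: 291 (22 high-firing, 269 clustered)
#>   PCA: first two components explain 76% of variance
#>   selected k = 2
#> <vta_cluster_summary>
#>  group             label   n    firing_rate        pct_sib n_bursting
#>      1       high-firing  22 19.47 +/- 0.82  0.00 +/- 0.00          0
#>      2 non-high-firing 1 207  2.10 +/- 0.07  3.20 +/- 0.33         78
#>      3 non-high-firing 2  62  3.36 +/- 0.13 38.61 +/- 0.95         62
#>         ap_dur           dt1 n_notch
#>  1.46 +/- 0.03 0.60 +/- 0.01       1
#>  2.64 +/- 0.02 1.00 +/- 0.01      95
#>  2.83 +/- 0.04 1.10 +/- 0.02      29
```

The high-firing group reproduces its 19.47 Hz target; the two recovered
clusters sit at 2.10 and 3.36 Hz with 3.2% and 38.6% of spikes in bursts —
the low-bursting/high-bursting split at the 17.5% boundary.

## Known limitations

* The CV estimator interpretation (binned rates vs ISIs) is a convention
  choice; both are defensible and the bin width materially affects the
  value.
* The Δt₁ "end of repolarization" landmark is taken at the baseline
  re-crossing after the trough; an alternative (trough time itself) would
  shorten Δt₁ systematically.
* Measured AP durations shrink by a few percent as waveform noise grows
  (the threshold at 3 noise SDs eats into the small after-potential); at
  the default noise level the bias is ≲ 4% and uniform across groups.
* The index vote can be unstable on data without clear cluster structure;
  inspect `k_report$index_table` rather than trusting `selected_k` blindly.
* Euclidean-with-weights is the only metric; for data where binary
  features must drive the clustering, this package is the wrong tool.
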
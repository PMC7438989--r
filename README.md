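# vtaclust

Unsupervised classification of ventral tegmental area (VTA) neurons from in
vivo extracellular recordings.

Electrophysiologists recording single units in the VTA of anesthetized
rodents classically label neurons by eye: putative GABAergic units fire fast
(>10 Hz) with narrow action potentials (APs); putative dopaminergic (DA)
units fire slowly with broad, often notched APs and variable bursting. These
criteria overlap and invite bias. `vtaclust` implements an objective
pipeline instead, for anyone who has sorted spike timestamps and an averaged
AP waveform per unit:

1. **Six features per unit** — firing rate (Hz); firing-rate coefficient of
   variation CV = SD/mean of 10 s binned rates; percentage of spikes in
   bursts (%SIB) under the classical 80/160 ms rule (burst opens at an
   interspike interval ≤ 80 ms, closes at a silence ≥ 160 ms); total AP
   duration; Δt₁ (depolarization onset to end of repolarization); notch
   presence (prominence ≥ 5% of peak-to-trough).
2. **Pre-filter** — units firing > 10 Hz are set aside as their own group.
3. **Clustering** — min–max scaling to [0, 1], PCA by singular value
   decomposition (variance-capture diagnostic), Ward agglomerative
   clustering (`ward.D2`, Euclidean) with the number of clusters *k* chosen
   by a silhouette-led majority vote of four internal validity indices
   (silhouette, Calinski–Harabasz, Davies–Bouldin, Dunn) over k = 2..10.
4. **Characterization** — mean ± SEM summaries per group, Kruskal–Wallis +
   Dunn post hoc tests, uncorrected Pearson chi-square for notch
   contingencies, Shapiro–Wilk log-normality checks.

Because cohorts of this kind are rarely deposited, the package also ships a
seeded synthetic-population generator (`generate_population()`,
`vta_presets()`) whose burst structure is known *exactly* by construction —
the burst detector provably reproduces the generated labels spike-for-spike
— so the entire pipeline is testable offline. See the vignette
(`vignettes/vta-classification.Rmd`) for the model, the generator design
and its limitations.

## A worked example

```r
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

This generates the bundled 291-unit reference cohort (22 high-firing + 205
low-bursting + 64 high-bursting units), extracts the six features, selects
k = 2 for the 269 non-high-firing units, and recovers the three groups: the
high-firing group at its 19.47 Hz target with short APs (Δt₁ 0.60 ms), and
two DA-like clusters separated by bursting (3.2% vs 38.6% of spikes in
bursts, boundary at 17.5%) but not by AP shape — the structure the method
is designed to expose. `report$tests` holds the Kruskal–Wallis/Dunn and
chi-square results; with `out_dir` set, the run writes the feature table,
assignments, dendrogram (Newick + JSON) and a report (JSON + Markdown).

Units on disk use plain formats: one timestamp (s) per line, a `t_ms,v`
waveform CSV and a JSON metadata sidecar per unit (`read_recording()`,
`write_cohort()`). A thin command-line wrapper lives at
`inst/cli/vtaclust.R` (subcommands `generate`, `features`, `run`).

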
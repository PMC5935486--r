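# gastrosync

Phase synchrony between the stomach's electrical rhythm and
resting-state brain activity.

The stomach is paced by a slow gastric rhythm (~0.05 Hz, three cycles
per minute) that can be recorded non-invasively at the abdomen as the
electrogastrogram (EGG). `gastrosync` quantifies, voxel by voxel,
whether BOLD fMRI fluctuations keep a consistent phase relation with
that rhythm, and characterises the resulting network: phase delays
between regions, shared variance with the EGG, delay-tolerant versus
instantaneous functional connectivity, and the slow dynamics of
coupling. It is written for researchers analysing simultaneous
EGG–fMRI recordings, and for anyone who wants a fully testable
reference implementation of this family of brain–body coupling
statistics.

## The statistic at its core

For each voxel the phase-locking value between the gastric-band EGG
phase φ_y and the voxel's gastric-band BOLD phase φ_x,

    PLV = | (1/T) Σ_t exp(i (φ_x(t) − φ_y(t))) |,

is compared with its chance level, the **median** PLV over all circular
time shifts of the EGG by at least 60 s (≈ 3 gastric cycles; 360
admissible shifts for 420 samples at TR 2 s). Group inference is a
voxelwise paired t test of empirical vs chance PLV across participants
with cluster-based permutation correction (supra-threshold clusters at
voxel p < 0.01 two-sided, scored by summed t, referred to the
max-statistic null from within-participant label exchanges; clusters
with Monte-Carlo p < α/2 per tail are significant).

The pipeline: gastric peak detection (Welch spectra, 15 µV² peak
criterion) → zero-phase ±0.015 Hz gastric filter → BOLD conditioning
(quadratic detrend, 0.01–0.1 Hz Butterworth, nuisance regression) →
analytic phases → 30 s trimming per end → PLV and surrogate chance →
cluster inference → node-level phase angles (Watson–Williams circular
ANOVA), coherence-based shared variance, sliding-window PLV, and
robustness controls (frequency-offset specificity, group time-shift
null, EGG-swap chance, confound correlations).

A synthetic-data module (`simulate_egg()`, `simulate_bold()`,
`make_cohort()`) generates cohorts with a drifting gastric oscillator
and BOLD clusters planted at known phase delays in 1/f noise, so every
stage is verifiable against ground truth without any data download.

## Worked example

```r
library(gastrosync)

truth  <- synthetic_truth(grid_dim = c(10, 10, 10),
                          cluster_centers = rbind(c(3, 3, 5), c(8, 8, 5)),
                          planted_delay = c(0, pi / 2), snr = 3)
cohort <- make_cohort(6, truth, seed = 101)

egg_peak(cohort$participants[[1]]$egg)
#> Gastric peak: 0.0500 Hz (3484.7 uV^2) on chan1 [auto]

analysis <- analyze_cohort(cohort, run_config(n_perm = 1000), seed = 1)
analysis$result
#> Cluster inference: 3 candidate(s), 2 significant at 0.05
#>   positive cluster: 16 voxels, sum(t) = 196.6, p = 0.01798 *
#>   positive cluster: 17 voxels, sum(t) = 194.6, p = 0.01798 *
#>   negative cluster: 1 voxels, sum(t) = -4.3, p = 0.6923

nodes <- node_summaries(analysis, cohort)
#> node 1: 16 voxels, relative angle -0.78 rad, consistency 1.00, shared variance 0.99
#> node 2: 17 voxels, relative angle +0.78 rad, consistency 1.00, shared variance 0.99
#> Watson-Williams: F(1, 10) = 34278.1, p = 5.2e-19
```

The two planted clusters are recovered as significant positive
clusters; their relative phase-locking angles (−0.78 and +0.78 rad,
i.e. ±π/4 around the network mean) reproduce the planted quarter-cycle
delay separation; phase-delay consistency across participants is at
ceiling, and the Watson–Williams test confirms distinct mean
directions. `run_pipeline(out_dir, ...)` performs the same analysis
end to end and writes t-map and cluster-label NIfTI volumes, cluster
and manifest JSON, and a per-node CSV.

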
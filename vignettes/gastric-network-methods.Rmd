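---
title: "Quantifying gastric-BOLD phase synchrony: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gastric-BOLD phase synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastrosync)
```

## The problem

The stomach's smooth muscle is paced by a slow electrical rhythm at
roughly three cycles per minute (0.05 Hz), measurable at the abdominal
skin as the electrogastrogram (EGG). `gastrosync` asks, voxel by voxel,
whether resting-state BOLD fMRI fluctuations keep a *consistent phase
relation* with that rhythm — whether parts of the brain speed up and
slow down with the stomach — and, if so, with what temporal delays, how
much shared variance, and how stably over time.

The measure of coupling is the phase-locking value between the
gastric-band EGG phase $\phi_y(t)$ and a voxel's gastric-band BOLD
phase $\phi_x(t)$:

$$\mathrm{PLV}_{x,y} = \left| \frac{1}{T} \sum_{t=1}^{T}
e^{i(\phi_x(t) - \phi_y(t))} \right|.$$

PLV is 1 when the phase difference is constant (at *any* lag), near 0
when it is unrelated; it is invariant to amplitudes and to constant
phase offsets. Because any finite-sample PLV is positive, raw values
are meaningless without a matched chance level: the package recomputes
each voxel's PLV with the EGG circularly time-shifted by every
admissible offset of at least 60 s (about three gastric cycles) and
takes the **median** of that surrogate distribution as the chance PLV.
Coupling strength is empirical minus chance. Group inference is a
voxelwise paired $t$ test of empirical versus chance across
participants, corrected by cluster-based permutation: candidate
clusters of $|t|$ above the $p<0.01$ two-sided threshold, scored by
their summed $t$, referred to the max-statistic null from 10,000
within-participant label exchanges (sign flips of difference maps).

## Processing chain and its fixed constants

1. **Gastric peak**: Welch spectra (200 s Hann windows, 150 s overlap,
   per-segment linear detrend) per EGG channel; the largest in-band
   (0.033–0.066 Hz) local maximum must exceed 15 µV² or the recording
   is rejected. Channel choice prefers power, overridden by a channel
   whose peak is more than twice as *sharp* (peak prominence over
   median in-band power); a manual override mirrors visual selection.
   Sharpness had no quantitative published definition, so the
   prominence ratio is this package's operationalisation.
2. **Gastric filter**: linear-phase FIR, passband peak ± 0.015 Hz,
   applied zero-phase. A literal low "filter order" cannot realise a
   ±0.015 Hz band, so the order is derived from the Hamming
   transition-width rule to meet the band: flat (< 1 dB) in the
   passband, ≥ 40 dB down at ±3 half-widths. Near the lower edge of
   the broadband range the transition narrows (and the order grows) so
   the design stays feasible for low gastric peaks.
3. **BOLD conditioning**, fixed order: quadratic detrend → 0.01–0.1 Hz
   4th-order Butterworth (applied forward–backward; zero phase keeps
   delay estimates interpretable) → optional nuisance regression
   (e.g. a CSF sphere mean) → the *same* gastric-band filter → analytic
   signal → trim.
4. **Trimming**: 15 volumes (30 s) per end are discarded *after* phase
   extraction, so Hilbert/filter edge effects fall in discarded
   samples. A 450-volume scan at TR 2 s leaves 420 samples = 840 s.
5. **Surrogates**: circular shifts $s \in [m, T-m-1]$, $m = 60/\mathrm{TR}$
   — 360 offsets at $T=420$. The symmetric closed interval would give
   361; the half-open convention is a bookkeeping choice, not physics.
6. **Clusters**: 26-connectivity by default (6/18 configurable);
   positive and negative families tested each at $\alpha/2$ against
   their own one-tailed max-statistic null, Monte-Carlo $p$ with the
   +1 correction.

Node-level follow-ups: per-cluster mean series; lock angle
$\Phi_k = \arg \frac{1}{T}\sum_t e^{i(\phi_x - \phi_y)}$; angles are
reported *relative* to the circular mean across nodes (computed on unit
vectors — an arithmetic mean of angles is ill-defined near ±π), because
the EGG-to-pacemaker delay is unknown but common to all nodes.
Between-participant consistency is the resultant length of the
participants' unit vectors. Equality of mean directions across nodes is
tested with the Watson–Williams circular ANOVA (F approximation with
the $1 + 3/(8\hat\kappa)$ correction; flagged when the mean resultant
drops below 0.45, where the approximation degrades). Shared variance
with the EGG is squared magnitude coherence from 120 s windows with
20 s overlap at the bin nearest the gastric peak; "36 windows" cannot
be realised on an 840 s series with that geometry, so the window count
is derived from the data (8) and reported. Delayed functional
connectivity (squared coherence) is contrasted with instantaneous
connectivity (squared Pearson on gastric-band series); a pure delay
moves variance from the second to the first. Sliding-window PLV uses
60 s windows every 10 s (79 windows on 840 s); window amplitude is the
mean Hilbert envelope (RMS available).

## The synthetic cohort: what it emulates, and what it does not

Every stage is validated against a generator with known ground truth:

* **EGG**: an oscillator whose instantaneous frequency performs a
  *mean-reverting* Gaussian random walk (innovation 7×10⁻⁴ Hz·s^(-1/2),
  reversion time 100 s), reflected into 0.033–0.066 Hz, observed on
  several channels with gains 1–0.35, amplitude 100 µV, white noise
  20 µV at 10 Hz — a realistic cutaneous EGG scale whose Welch peak
  clears 15 µV² by two orders of magnitude. Mean reversion matters: a
  pure random walk either stays so regular that a 60 s-shifted copy of
  the rhythm remains phase-locked to itself (chance PLV ≈ 0.8, which
  would defeat the surrogate logic) or, if made irregular enough to
  decorrelate, wanders so far that the realised spectral peak no longer
  sits at the intended frequency. The calibrated OU drift gives
  a chance level around 0.2 for a self-locked voxel and keeps 95% of
  realised peaks within one Welch bin of the planted frequency.
* **BOLD**: 450 volumes at TR 2 s on a 20×20×20 grid (spherical mask,
  ~2100 voxels) — the temporal structure of a real acquisition at a
  desk-scale spatial size. Coupled clusters follow
  $A\,g(t)\cos(\phi_{\mathrm{EGG}} + \delta_k)$ with per-cluster delays
  $\delta_k \in \{0, \pi/2, \pi\}$ by default; background is 1/f-shaped
  noise (spectrally shaped white noise, exponent 1), with no published
  generative model to imitate — it is a plausible stand-in, not an
  inference about real data. $A$ is expressed as a signal-to-noise
  ratio against the noise SD *inside the gastric band* (default 2), so
  detectability does not depend on the broadband noise scale. $g(t)$
  is an optional slow coupling gain used to study co-fluctuation of
  coupling and amplitude.
* **Cohorts** draw per-participant gastric frequencies uniformly from
  0.041–0.053 Hz (the spread observed across healthy adults) with
  per-participant seeds derived from one master seed.

Not emulated: hemodynamic convolution, head motion, physiological
confounds other than the planted rhythm, spatial autocorrelation of
noise, vascular geometry. Passing tests therefore demonstrate that the
*statistics* do what they claim on data obeying the model — not that
real gastric-BOLD coupling looks like this.

## Numerical choices and degenerate inputs

* Phases are always manipulated through complex exponentials; nothing
  unwraps angles. Wrapping maps to $(-\pi, \pi]$.
* The analytic signal is computed by FFT on the padded series; the
  0.05 Hz × 420-sample × TR 2 s combination places the gastric
  frequency exactly on a DFT bin, which is why two pure sinusoids
  yield PLV = 1 to machine precision.
* Chance maps for all shifts are computed at once via FFT circular
  cross-correlation of unit phasors, verified in tests against the
  direct per-shift computation.
* Because chance is the *median* of a right-skewed surrogate
  distribution, the coupling strength of a genuinely uncoupled voxel
  has median exactly zero but a small positive mean (the mean-minus-
  median gap of the PLV null, ~0.005 at these conditions). The
  calibration tests check the median-zero property and bound the mean;
  group-level validity is checked directly by the time-shifted-cohort
  null.
* Zero-variance voxels get $t = 0$ with a warning; constant series are
  rejected where a correlation is required; collinear nuisance columns
  are dropped with a warning; an all-zero series has no phase and says
  so.
* Exchangeability checks use exhaustive sign-flip enumeration
  (feasible up to ~20 participants) against the sampled permutation
  null.

## Scale of the validation runs

Test-suite simulations use the generator's full temporal structure
(450 volumes, 960 s EGG) with cohorts of 12 for power checks
(20 replicates, 1000 permutations), 6 for calibration replicates, and
small grids (5³–10³) where spatial extent is irrelevant. These sizes
were chosen to estimate each property with useful precision on a single
CPU; all thresholds (sensitivity ≥ 0.9, binomial false-positive bands,
±π/12 delay tolerance) are stated in the tests themselves.

## Known limitations

* The frequency-specificity control decays only once the offset band
  *excludes* the oscillator: PLV's amplitude invariance makes the curve
  flat for offsets smaller than the filter half-width. Real data, with
  far lower coupling SNR, can show earlier decay.
* The Watson–Williams approximation needs concentrated angles; at low
  consistency the test flags itself rather than pretending precision.
* The EGG-swap chance level resamples nothing: recordings must share a
  common trimmed length (they are truncated to the minimum with a
  warning otherwise).
* No directed measures: a phase lead does not imply causation, and the
  package deliberately offers nothing that suggests otherwise.
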
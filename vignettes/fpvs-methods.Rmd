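---
title: "Frequency-tagged categorisation responses: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged categorisation responses: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpvseeg)
```

## The paradigm and its spectral signature

Fast periodic visual stimulation (FPVS) presents stimuli at a fixed base
rate — here written words at 4 Hz — with every fourth item drawn from a
different semantic category, so category changes occur periodically at
1 Hz. Because the EEG response to a periodic stimulus is itself periodic,
any neural process that treats the alternate category differently from the
base category produces energy at exactly 1 Hz and its harmonics in the
amplitude spectrum, while general visual processing of the 4 Hz stream
appears at 4 Hz and its harmonics. The approach needs no task on the
stimuli themselves: participants monitor a fixation-cross colour change
(8 changes of 500 ms per 70 s sequence), which only anchors attention.

Each sequence runs 2 s fade-in, 70 s core stimulation, 2 s fade-out, with
a trigger at the fade-in onset and 2 s of pre-trigger padding retained at
segmentation. Tokens are drawn uniformly within category with no immediate
repetition. Four base/alternate contrasts (animals/cities both ways,
vegetables/countries both ways) are each repeated three times, giving 12
sequences and 840 category-change trials per subject.

## From raw recording to one epoch per condition

The preprocessing chain is: zero-phase band-pass 0.1–100 Hz and 50 Hz
notch (0.5 Hz width), downsampling 512 to 256 Hz, segmentation on the
stimulation start triggers, blink removal, interpolation of bad channels
(at most 5% per subject), common-average re-referencing, re-segmentation
to an integer number of 1 Hz cycles, and time-domain averaging of the
epochs per condition before the FFT (averaging coherent signal while
noise cancels, which lowers the spectral noise floor as $1/\sqrt{n}$).

Numerical choices worth stating explicitly:

- **Filters.** All filters are zero phase, so the relative phases of
  response harmonics — and therefore their time-domain summation — are
  untouched. The default backend applies the squared magnitude response of
  4th-order Butterworth designs in the frequency domain with reflection
  padding; this is the response a forward-backward (`filtfilt`) pass
  realises, without edge transients, and it is exact at every FFT bin. A
  `filtfilt` backend over `signal::butter` designs is provided and the two
  agree away from the band edges (cross-checked in the tests).
- **Epoch start.** The first alternate onset inside the core window falls
  0.75 s after fade-in (alternates occupy every 4th position of the whole
  stream, fades included). Epochs therefore start at
  trigger + fade-in + 0.75 s and hold the largest whole number of 1 Hz
  cycles that fits before the fade-out: 69 cycles, i.e. 17,664 samples at
  256 Hz, for the 70 s core. Aligning to an oddball-cycle boundary puts
  the category-change response exactly on the 1 Hz bin.
- **Blink removal.** A single blink source is removed by deterministic
  regression: every scalp channel is orthogonalised against a
  low-pass-filtered (16 Hz) vertical-EOG reference (below-eye minus
  above-eye). This is the classical regression equivalent of removing one
  ocular component, and unlike ICA with manual component selection it is
  exactly reproducible. The slope comes from the centred regression but
  the uncentred reference is subtracted, so the blink train's mean offset
  leaves the scalp as well. Signals uncorrelated with the reference pass
  through up to sampling covariance.
- **Interpolation.** "Linear" interpolation on a scalp is under-determined;
  bad channels are rebuilt as the inverse-distance-weighted mean of their
  4 nearest good channels.
- **Reference.** The common average is a linear spatial projection: an
  injected topography $w$ becomes $w - \bar{w}$. All ground-truth
  comparisons in the tests use this projected topography, which is the
  exact expectation for a linear pipeline.

## Quantifying tagged responses

With integer-cycle epochs no taper is needed: each tagged frequency
occupies a single bin and windowing would only smear it. Three neighbour-bin
transforms quantify a bin of interest against its local noise floor:

- **Baseline-subtracted amplitude** (µV): centre amplitude minus the mean
  of 20 surrounding bins (10 per side), skipping the immediately adjacent
  bin on each side against residual leakage and dropping the local maximum
  and minimum amplitude bins (18 bins averaged).
- **SNR**: centre divided by the same mean; $(\mathrm{SNR}-1)\times 100$
  is the percent signal increase over noise.
- **z-score**: centre standardised by the mean and sample SD ($n-1$) of 22
  surrounding bins (11 per side, no exclusions), with a one-tailed
  upper-tail p (tagged responses are amplitude increases).

Harmonics are selected once, on the grand average across participants and
electrodes, walking up from the fundamental and stopping at the first
non-significant harmonic ($z > 1.65$ for the oddball response, $z > 3.1$
for the much larger base response). Oddball harmonics that coincide with
base-rate multiples are never tested — they reflect the 4 Hz stream, not
categorisation — and skipping them does not break the run. The canonical
outcome is six oddball harmonics (1, 2, 3, 5, 6, 7 Hz) and sixteen base
harmonics (4–64 Hz). Responses are then summed chunk-wise: 25-bin slices
centred on each harmonic (centre at position 13) are added element-wise;
25 bins is exactly wide enough to hold both neighbour rules around the
centre, which is presumably why that width is conventional.

## Group statistics

Per-electrode z-scores on the grand-average summed response are corrected
across the 128-electrode family by Benjamini–Hochberg FDR (q = 0.05;
boundary cases within floating-point tolerance of q count as discoveries).
The data-driven ROI keeps significant electrodes that have another
significant electrode within 0.5 chord units (~29° of arc — two electrode
spacings; isolated electrodes drop out), removes midline electrodes, and
mirrors the left-hemisphere survivors to their right homologues by label
parity. Hemispheric contrasts are paired two-tailed t-tests on per-subject
ROI means. The living/non-living split averages epochs of the contrasts
sharing an alternate-category domain *before* the FFT, compares whole-scalp
means, subtracts the two grand-average spectra (quantified with the same
neighbour rules on the signed difference), and runs a 2 × 10
repeated-measures ANOVA (Contrasts × Electrodes) implemented as the
balanced within-subject decomposition with Greenhouse–Geisser epsilon
estimated per effect from the covariance of orthonormal contrast
variables; both uncorrected and corrected p-values are reported, since
sphericity over 10 electrodes is implausible but the correction is
undefined in published work that reports only one convention.

One subtlety: the ANOVA and ROI analyses need more subjects than
within-factor levels for a full-rank covariance estimate; with fewer, the
epsilon estimate degrades gracefully (it is clamped to 1 when undefined),
which standard multivariate implementations refuse outright.

## The synthetic-recording generator

The generator exists so that every downstream stage can be validated
against known ground truth. It emulates a 128-channel, 512 Hz acquisition
(extended 10-5 labels with unit-sphere positions, plus 4 EOG channels):

- **Responses** are sums of sinusoids at the harmonics of a fundamental,
  weighted by a scalp topography, present only during stimulation with
  linear contrast ramps over the fades. Defaults: a bilateral
  occipito-temporal base topography (Gaussians at PO7 and PO8, peak at
  PO8) whose harmonic ladder sums to ~4.5 µV, and a left
  occipito-temporal oddball topography (Gaussian at PO9) summing to
  0.25 µV over harmonics 1–7 Hz (4 Hz excluded). The sinusoid model makes
  every expected bin amplitude analytic; a periodic-transient mode exists
  for waveform realism, at the cost of analytic amplitudes.
- **Noise** is $1/f^{\alpha}$-shaped Gaussian noise ($\alpha = 1$) plus
  white Gaussian noise, independent per channel. The default scales
  (25 µV at 1 Hz pre-shaping, 12 µV white) were set from the per-bin
  floor formula $1.25\,\sigma_t\sqrt{2/N}/\sqrt{n_{\mathrm{epochs}}}$ so
  that the full protocol's summed-harmonic oddball SNR at the peak channel
  lands around 1.3–1.5, the magnitude seen in word-categorisation FPVS
  data. Note that amplitude-spectrum averaging preserves the *mean* noise
  floor (only its variance shrinks), so the floor is set by the
  single-subject epoch, not by cohort size.
- **Blinks** are Poisson-timed double-exponential transients (~400 ms) on
  anterior channels, mirrored with opposite signs on the above/below-eye
  EOG pair so the regression stage has a usable reference.

What the generator does not emulate: non-stationary alpha rhythms,
correlated noise fields across channels, biophysical volume conduction
(topographies are free weight maps, not dipole projections), eye movements
other than blinks, and real word stimuli (tokens are opaque ids). Passing
tests therefore demonstrate correctness of the *analysis* under the stated
signal model, not robustness to every property of real EEG.

## Validation design and problem sizes

The test suite validates at three levels, with sizes chosen to keep the
full run in minutes while preserving the protocol's bin arithmetic
(epochs always hold an integer number of 1 Hz cycles, so shortened
sequences change resolution but not alignment):

- **Worked numbers**: 280 items / 70 alternates per sequence, 840 trials
  across 12 sequences, 0.362 Hz chunk width, 6 + 16 harmonics, 11/128 =
  8.6%, SNR 1.35 ↔ 35% increase.
- **Oracle equivalence**: the neighbour-bin transforms and BH-FDR against
  naive brute-force reimplementations on 1,000 random spectra and
  p-vectors; the rmANOVA against both a hand-expanded 2×2×3 decomposition
  and `car::Anova` (n = 12); the EDF codec against `python-mne`.
- **Monte-Carlo properties** (20 seeds, 34-channel montage, 20–70 s
  sequences):
  - *Amplitude recovery*: 0.1–1.0 µV injected at 1 Hz on four separate
    channels, recovered within 5% of the reference-projected truth and
    monotone in every seed. The noise level (0.4/0.3 µV) is set so the
    known negative offset of floor subtraction ($\approx 1.25\sigma_{bin}$)
    stays inside the band — this block validates calibration and
    linearity; detection power is exercised separately.
  - *Peak-channel recovery*: with a focal left-OT topography
    (σ = 0.1 chord) at summed SNR well above 2, the grand-average (n = 6)
    argmax lands on the injected peak channel. A broad topography makes
    argmax identity ill-posed at low SNR — its immediate neighbour carries
    ≥ 0.98 of the peak weight — so focality, not extra SNR, is what makes
    this test meaningful.
  - *Null calibration*: noise-only cohorts of n = 14 (the protocol's
    grand-average regime, where amplitude bins are near-Gaussian by
    averaging; raw single-subject bins are Rayleigh and exceed z = 1.65
    at ~7.8% rather than 5%); the grand-average exceedance rate is checked
    against 5% ± 2%, and the FDR map flags ≤ 5% of electrodes.
  - *Interaction recovery*: dorsal (PO7) vs ventral (P9) group
    topographies in a 12-subject cohort drive the Contrasts × Electrodes
    interaction (GG-corrected p < 0.05) in ≥ 90% of seeds; identical
    topographies in ≤ 10%.

The acceptance script (`scripts/acceptance.R`) recomputes the worked
numbers and runs an 8-subject synthetic cohort (34 channels, 20 s
sequences, 2 repetitions, oddball amplitudes at three times the default so
the scaled-down recording matches the full protocol's detectability) end
to end, reporting peak amplitudes, SNRs, the ROI lateralisation t-test and
the ANOVA interaction.

## Known limitations

- The amplitude-domain baseline subtraction is biased low by the noise
  floor's sampling mean when signal and per-bin noise are comparable
  (Rician amplitude statistics); the bias is $O(1.25\sigma_{bin})$ and
  vanishes as epochs accumulate. This is a property of the method, not of
  the implementation.
- Harmonic selection on the grand average across all electrodes dilutes a
  focal response by the spatial mean of its (reference-projected) absolute
  topography; with few subjects the selection can return fewer harmonics
  than the canonical six, which is why fixed a priori harmonic sets are
  supported (`config$harmonics$fixed_oddball`).
- The published epoch length of "17,666 bins" is not an integer multiple
  of 256 samples per 1 Hz cycle; the implementation uses exact integer
  cycles (17,664 samples) and documents the 2-sample discrepancy rather
  than reproducing it.
- EDF output quantises to 16 bits per channel over the per-channel range;
  the binary+YAML sidecar format round-trips exactly and is the working
  format.
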
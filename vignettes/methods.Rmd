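---
title: "Methods: band-power comparison of guided and self-produced imagery EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-power comparison of guided and self-produced imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegimagery)
```

## The analysis problem

A single multi-channel EEG session records a subject alternating between two
imagery conditions over six sport-related scenes. In each scene the subject
first listens to a recorded script (*guided imagery*, 33–47 s), pauses for a
2-s wash-out break, then imagines the scene unaided for 60 s (*self-produced
imagery*). The scientific question is whether oscillatory band power —
specifically low alpha (8–10 Hz), high alpha (10–12 Hz) and the sensorimotor
rhythm (SMR, 12–15 Hz) — differs systematically between the two instruction
modalities, per scene and per scalp region.

The package implements the full chain from raw channels-by-samples
matrices to condition comparison tables and topographic map data, plus a
synthetic-session generator with closed-form expected band powers, so that
every stage is testable end to end without any recorded data.

## Processing model

### Preprocessing

Stages run in a fixed order, each recorded in the output's provenance:

1. **Channel QC** (report only). Automated heuristics replace visual
   inspection: a run of more than `max_constant_run` identical samples
   (default 125, i.e. 0.5 s at 250 Hz) flags a constant region; any sample
   beyond `amp_limit_uV` (default 500 µV) flags an amplitude excursion; and
   a log-variance z-score across channels beyond `var_z` (default 3.5)
   flags a variance outlier. Flagged channels are reported, never silently
   dropped — posterior channels legitimately carry several times the alpha
   power of frontal ones, which is why the variance screen uses the plain
   (not robust) z-score: with a robust scale estimate the physiological
   posterior group itself would be flagged.
2. **Butterworth bandpass**, order 5, 1–40 Hz. Butterworth designs are IIR;
   the filter is applied forward–backward (zero phase, squared magnitude
   response) so that filter phase cannot distort band-power estimates, with
   odd-reflection padding at the edges. The 1–40 Hz band excludes mains
   interference, so no notch filter is needed.
3. **Small-Laplacian (Hjorth) spatial filter.** Each channel's output is its
   potential minus the mean potential of its montage neighbors, computed
   simultaneously as a single matrix product `L X` with `L = I − A`,
   `A` row-normalised adjacency. Neighbor sets derive from 2-D montage
   positions (up to 4 nearest channels within a radius of 0.5 head units,
   symmetrised; boundary electrodes keep however many neighbors exist, with
   a minimum of two), and can be overridden by an explicit adjacency file.
4. **Per-channel demeaning.** "Removing the mean of every channel" is read
   as temporal demeaning (it supports stationarity); common-average
   referencing is not applied — the Laplacian already removes spatially
   common activity.
5. **ICA stage.** A seeded symmetric FastICA (tanh contrast) yields as many
   components as channels. The unmixing rotation is estimated on an evenly
   decimated subset of at most 40 000 samples — ample for a 30 × 30
   rotation — while component time courses and the reconstruction use the
   full recording. Component order and sign are canonicalised so the
   decomposition is deterministic for a given seed. Rejection is either an
   explicit index list or automatic by correlation with a supplied artifact
   reference; the default rejects nothing, in which case the stage is an
   identity map up to numerical precision (verified to 1e-6 relative). The
   Laplacian leaves one near-null variance direction, so whitening floors
   eigenvalues at 1e-10 of the largest; convergence tolerance is the
   customary 1e-4 and non-convergence is reported, never hidden.

### Band decomposition and power

Band extraction is an exact spectral mask: FFT of the segment, zero every
coefficient whose bin frequency lies outside the band, inverse FFT. No
window is applied here — windowing would destroy invertibility, and the
chain reconstructs time-domain band-limited signals. A Kaiser window is
used only in the diagnostic `psd_estimate()` (shape parameter 0 gives the
plain periodogram; the window's power gain is divided out so a sinusoid's
integrated spectrum recovers A²/2).

Band edges are half-open `[fmin, fmax)`: printed band tables use closed
brackets on both ends, which would double-count the shared edges (low/high
alpha meet at 10 Hz); half-open masks make alpha power *exactly* the sum of
its halves. Segments are processed at their native length without
zero-padding — 30–60-s segments give at worst 0.03 Hz bin resolution,
ample for 2-Hz-wide bands. Mean power is `(1/T) Σ x²(t)`; the power table
computes it in the frequency domain (Parseval sum over masked bins), which
equals decompose-then-average to machine precision. Guided and
self-produced powers are computed over their full, unequal segment
lengths; a common-truncation option was considered and rejected because
mean power is duration-normalised already.

### Maps and normalisation

For each band and scene the package produces a guided map, a self-produced
map, and a difference map (self-produced minus guided; the sign convention
follows the subtraction order of the study design). MinMax normalisation
`(v − min)/(max − min)` is applied **per map** — each panel spans the full
[0, 1] range — with a `0.5` constant for degenerate all-equal maps (a
neutral midpoint avoids implying structure). Differences are computed on
raw powers and then normalised; normalising before subtracting would
discard the bands' absolute scales. Rendering uses inverse-distance
interpolation on the unit head disc and is decorative; the tested product
is the exported per-electrode JSON.

### Statistics

The Wilcoxon signed-rank test uses the classical conventions: zero
differences dropped, midranks for tied magnitudes, statistic
`min(W+, W−)`, normal approximation `z = |W+ − n(n+1)/4| / σ` with the tie
correction in `σ²` and **no continuity correction on the reported Z**, and
an exact null by full enumeration of the `2^n` sign assignments for
`n ≤ 12` (the `auto` method switches to the normal approximation above
that). The uncorrected Z is what makes the saturated all-one-sign cases
land exactly on the boundary values `z_max(6) = 2.20`, `z_max(7) = 2.37`,
`z_max(14) = 3.30` familiar from small-sample paired designs. The
normal-approximation *p*, however, applies the standard continuity
correction (as `stats::wilcox.test` does by default): without it the
approximation deviates from the exact null by up to 0.13 at n = 5 and by
more than 0.05 through n = 10, while the corrected form stays within
0.04 everywhere — the uncorrected convention is a statement about the
printed statistic, not a good tail approximation. Two-sided p throughout;
direction is reported separately. Raw p values carry conventional stars; a Benjamini–Hochberg
column is emitted alongside for transparency but no family-wise correction
alters the primary columns.

Scene-level rows pair the two conditions over an *analysis set* of
electrodes; region-level rows pair them over scenes. Both paired-unit
choices are configuration, not claims: the default analysis set holds 14
electrodes (Fp1, Fp2, FC5, FC6, C1, C2, T7, T8, CP5, CP6, CPz, Pz, O1,
O2). Besides covering prefrontal to occipital sites in both hemispheres,
this set is as close to pairwise non-adjacent on the default montage as
the coverage allows (the montage graph's maximum independent set has 11
electrodes; the set adds T7, T8 and CPz with five adjacent pairs in
total). Adjacency matters because the Laplacian writes each channel's
activity into its neighbors' filtered signals: paired differences of
adjacent electrodes are strongly dependent, which would distort the
signed-rank test's size.

## The synthetic-session generator

`generate_session()` emulates the protocol: 30 channels at 250 Hz, six
scenes, guided durations drawn uniformly from 33–47 s, the 2-s break, 60 s
of imagery, and a 5-s rest between scenes. Each channel is the sum of

* **1/f background noise** — spectral shaping of white noise with exponent
  1 (configurable), clamped below 1 Hz, rescaled to a 5 µV standard
  deviation; and
* **one narrowband oscillator per primitive band** (theta 3 µV, low alpha
  4 µV, high alpha 3 µV, SMR 2 µV, low beta 1.5 µV, high beta 1 µV
  baseline amplitudes) — a sinusoid with a random phase and a slow
  (0.1 Hz) random-phase sinusoidal amplitude modulation, normalised so the
  expected mean power of an amplitude-A oscillator is exactly A²/2
  regardless of modulation depth (default 0.3).

Condition effects multiply oscillator amplitudes inside the marked
windows: low alpha × 1.3 in self-produced imagery, high alpha and SMR
× 1.3 in guided imagery — the qualitative pattern of the study design,
with the multiplier chosen for statistical testability rather than
fidelity to any subject. Parieto-occipital channels get a × 2 alpha
amplitude boost (eyes-closed posterior alpha dominance). An optional
shared low-frequency transient source can be mixed into Fp1/Fp2 with
fixed weights to exercise the ICA stage; the clean data ride along in the
recording's metadata for recovery scoring.

Two deliberate numerical choices keep the generator's ground truth exact:

* marker resolution is 2 s (guided durations are even whole seconds), and
* every oscillator's carrier lies on the 0.5-Hz grid strictly inside its
  band, drawn per channel.

Whole-even-second segments put half-Hz carriers exactly on FFT bins of
every condition segment, so band masks capture oscillators with zero
spectral leakage — with noise and modulation off, the power table matches
A²/2 to machine precision, giving the test suite an exact oracle.
Per-channel carriers are also physiological (peak frequencies vary across
the scalp) and have a second purpose: distinct carriers occupy orthogonal
FFT bins, so when the Laplacian mixes neighboring channels their band
powers add without coherent cross terms, keeping paired differences from
neighboring sites close to independent under the null.

What the generator does **not** emulate: volume conduction / a forward
head model beyond the posterior boost, event-related
(de)synchronisation dynamics within a segment, non-stationary artifacts
other than the optional frontal transients, and inter-channel noise
correlation. Tests passing on this material therefore certify the
*pipeline arithmetic and statistics*, not claims about any real dataset.

## Verification at a glance

The test suite covers each stage against independent oracles: dense-matrix
hand computation for the Laplacian, analytic responses for the Butterworth
filter, brute-force `2^n` enumeration and `stats::wilcox.test` for the
signed-rank test, the closed-form A²/2 law for the generator, and Parseval
identities for the band masks. Pipeline-level checks verify determinism
(two seeded runs are byte-identical), recovery of injected effects
(50 seeds, every scene row rejecting in the injected direction at
α = 0.05), and test size under null effects (200 seeds, per-row rejection
near the nominal 5%). The simulation sizes — 50 effect and 200 null
sessions at the full protocol length — were chosen to estimate those rates
with standard errors comfortably below the margins being asserted.

## Known limitations

* The paired-unit sets for both table styles are design choices exposed as
  configuration; nothing in a session file dictates them.
* The exact signed-rank method is capped at n = 20 (enumeration growth);
  the `auto` switch at n = 12 keeps exact inference for the small designs
  this package targets.
* The ICA stage is a generic FastICA with correlation-based rejection; it
  is not an artifact classifier, and with the default empty rejection list
  it intentionally changes nothing.
* CSV recordings carry no units; values are assumed to be microvolts.
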
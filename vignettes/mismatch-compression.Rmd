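---
title: "Simulating and mitigating mismatch compression in differential LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and mitigating mismatch compression in differential LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mclfp)
```

## The problem

Differential LFP (∂LFP) channels on sensing DBS devices subtract two
electrodes placed around the stimulating contact, so that the stimulation
waveform — volts, against microvolt-scale neural oscillations — enters the
amplifier as common mode and cancels. Cancellation is only as good as the
symmetry of the two electrodes: when their impedances differ, a residual
artifact leaks through, and because the leak can be orders of magnitude
larger than neural signal it pushes the amplifier into gain compression.
The recorded spectrum is then distorted twice over: the compressive
nonlinearity redistributes artifact power into new narrowband components,
and the effective gain seen by every other signal drops. We refer to the
whole process as mismatch compression (MC).

This package provides a phenomenological, layer-by-layer simulator of the
process, an analytic forecast of where artifacts land, and the mitigation
and diagnostic tools needed to measure oscillatory band power reliably in
its presence.

## Model structure and assumptions

The simulator mirrors the recording chain. All amplitudes are
dimensionless model units; every quantity the package reports (band
powers in dB, log-ratios, peak frequencies) depends only on amplitude
*ratios*, so no absolute voltage calibration is needed.

**Brain layer.** Signals are generated at `fs_hi = 4220` Hz for
`duration = 20` s (84,400 samples). Source `x1` holds a stationary
15 Hz sinusoid of amplitude `2e-3` plus a 1/f background; `x3` is an
independent 1/f background only. The 1/f noise is synthesised exactly in
the frequency domain: independent complex-Gaussian coefficients with
expected one-sided density `strength² / f` (`strength = 1e-3`), inverse
transformed. The synthesis is deterministic given a seed; `x3` uses
`seed + 1`. Whether the two backgrounds should share a strength is not
empirically constrained; we default to equal strengths.

**Stimulation.** The therapeutic waveform is a truncated Fourier series:
`n_harmonics = 6` sinusoids at multiples of `f_T = 130` Hz. Harmonic
weights default to the Fourier magnitudes of a 90 µs-per-phase biphasic
rectangular pulse, `|c_k| ∝ sin²(π k f_T w)/k`, normalised so harmonic 1
carries the configured stimulation amplitude. Note these weights *rise*
roughly linearly over k = 1..6 — a biphasic pulse pair acts as a doublet
whose spectrum grows before rolling off near `1/(2w)` ≈ 5.6 kHz — which
matches the observation that the strongest aliased artifacts come from
the higher harmonics. A simpler `1/k` decay is available
(`harmonic_decay = "inv_k"`), but with it the dominant compression-only
peak moves away from 66 Hz, so the pulse weighting is the default.

**Lead and leakage.** Electrodes are purely resistive (`Z1`, `Z3`); the
device's behavior is calibrated by a single point — roughly 10%
of the stimulation voltage leaks at a "typical" mismatch — so the leak
amplitude follows the simplest law through that point,
`A_d = V · min(1, |Z1 − Z3| / Z_b)` with `Z_b = 1e4` Ω. The leaked
waveform is the stimulation series rescaled so its *peak* equals `A_d`;
with matched electrodes nothing leaks. Electrode capacitance and finite
common-mode rejection are deliberately out of scope.

**Amplifier.** Three saturation models: `linear`, `hard_clip`
(`g2·clamp(g1 v, ±clip_level)`, `clip_level` default 1), and the default
`soft_clip` (`g2·tanh(g1 v)`, `g1 = g2 = 1`). Soft clipping is the
realistic model: compression appears gradually and may be invisible in
the time domain while already distorting the spectrum. For inputs below
`|g1 v| < 0.01` the tanh stage matches the linear amplifier to within
0.01%, so a stimulation-free simulation is effectively linear.

**ADC.** Output is produced by keeping every 10th sample (422 Hz), with
*no* anti-alias filter: the device undersamples the residual artifact,
and that aliasing is precisely the phenomenon of interest. An optional
first-order 100 Hz low-pass (the hardware filter) can be enabled ahead of
the decimator; lengths not divisible by the factor are truncated.

**Over-range marker (ORM).** A constant 105.5 Hz tone injected *after*
the differential stage — it is a device-side marker, not tissue signal,
so it must never be differenced away — but *before* the amplifier, so
compression shows up as a drop in its measured power and saturation as
the loss of its peak. Its amplitude is not documented anywhere we know
of; we default to `5e-3`, 2.5× the oscillation, placing the tone ~20 dB
above the simulated noise floor so that it is plainly visible in every
recording, as it is on the hardware. On the 422 Hz / 1024-bin Welch grid
the tone falls exactly on bin 256 (105.5 Hz), which makes its power a
clean scalar diagnostic.

## Artifact taxonomy

With `fs = 422` Hz (Nyquist 211 Hz) and 130 Hz stimulation:

* **SSH** (stimulation shaping harmonics): retained harmonics below
  Nyquist — 130 Hz.
* **ASH** (aliased shaping harmonics): retained harmonics folded by the
  undersampling — 162, 32, 98, 194, 64 Hz. Present for *any* amplifier.
* **IMH** (intermodulation harmonics): harmonics beyond the 6-term
  truncation, re-created by the nonlinearity and then folded — 66 Hz
  (7th), 196 Hz (8th), and weaker lines at higher orders (e.g. the 13th
  harmonic folds to 2 Hz, inside the delta band). Their presence is
  evidence of compression; the 6-harmonic truncation is chosen exactly so
  that the 66 Hz line is compression-specific.

`predict_artifacts()` computes these sets for any configuration;
`alias_frequency()` is the underlying folding rule.

## Analysis conventions and numerical choices

* **Welch estimate**: non-overlapping 844-sample segments (10 segments of
  a 20 s recording), 4-term Blackman–Harris window, zero-padded to 1024
  FFT bins (grid spacing 0.4121 Hz), one-sided density scaling with
  window-power correction, no per-segment detrending. In dB
  (`10·log10`). The −92 dB window sidelobes keep the enormous artifact
  peaks from drowning neighbouring bins, at the price of a wide (±2 Hz)
  main lobe — which is why 64 Hz and 66 Hz artifacts merge into a
  "multipeak" complex rather than two clean spikes.
* **Band powers**: half-open windows `[f_lo, f_hi)` so adjacent bands
  never share a bin; the DC bin is always excluded (the hardware
  high-pass makes it meaningless). Aggregation over dB values, mean or
  median.
* **Peak detection** (`find_peaks()`): the peak bin is the highest local
  maximum within ±1 bin of the candidate (falling back to the nearest bin
  when the peak is a shoulder on a louder neighbour's leakage skirt, as
  66 Hz is next to 64 Hz); prominence is measured against the *quieter*
  of the two flanking medians (2 bins to ±2 Hz away), so one contaminated
  flank cannot fake or bury a detection; threshold 6 dB, far below the
  ≥ 20 dB excursions the model produces at default settings.
* **Baseline removal** (`fit_baseline()`): least-squares polynomial of
  order 4 in frequency (Hz, linear axis; a log-frequency axis is a config
  switch) over 1–105 Hz. The upper edge sits just below the ORM so the
  constant marker tone cannot steer the baseline; a full-range fit is
  available. The fit runs on a centred/scaled basis internally (the raw
  Vandermonde in Hz⁴ is too ill-conditioned for exact recovery) and
  reports plain-power coefficients. Artifact bins are *not* masked — the
  adjusted windows and the median are the narrowband defences.
* **Degenerate inputs**: zero amplitudes yield exact zero signals; a
  recording shorter than one segment, an empty band, an underdetermined
  fit, or out-of-grid target frequencies raise informative errors rather
  than returning NA.

## Study protocols

`run_sweep()` emulates the acute voltage-sweep experiment (0, 2–8 V, one
20 s recording per condition; the clinical protocol uses 60 s, which is a
config field). By default the same noise seed is used at every voltage —
a paired design in which across-voltage differences are purely
stimulation effects. `gen_chronic_series()` emulates the post-implant
impedance dynamics: a bounded random walk with week-to-week steps of
sd 150 Ω before the phase change (default week 10) and 20 Ω after,
clamped to the observed 0–600 Ω range, with one recording per week.

## What the simulator does and does not emulate

It reproduces the *structure* of mismatch-compressed recordings: the
artifact taxonomy and exact peak frequencies, their growth with
stimulation voltage and mismatch, the suppression of genuine oscillations
and of the ORM under compression, and the greater voltage-sensitivity of
high-mismatch recordings that the GCr diagnostic picks up.

It does not attempt biophysical realism: no volume conduction or dipole
geometry, no electrode capacitance, no phase-spectrum distortion, no
device-specific artifacts unrelated to MC (e.g. mains hum), and no
amplifier input noise. One consequence matters for interpreting the
test suite: because the stimulation waveform is truncated at six
harmonics, the simulated artifact spectrum is *discrete*. Real recordings
under compression show broadband floor shifts at all frequencies, so the
mitigation pipeline stabilises every band; in the simulator, bands that
contain no artifact line (θ, α, β*) barely move with voltage in the first
place, and for them the polynomial baseline — fit through the unmasked
artifact peaks, exactly as prescribed — adds more across-voltage
variability than it removes. The across-sweep convergence tests therefore
show the pipeline's advantage where an artifact line sits inside the band
(δ with the 2 Hz line, γ with the 32 Hz line), and show the reverse in
artifact-free bands. Passing them says the pipeline behaves as designed
on this model, not that every band of real data improves by the same
margin — nor the converse.

## Problem sizes

Defaults reproduce the study conditions: 20 s at 4220 Hz (84,400
samples) decimated to 8,440; ten Welch segments; sweeps of eight
voltages; chronic series of 28 weeks. These sizes are what the reported
behaviors were developed at; every generator takes `duration`, and the
test suite uses shorter runs where length is irrelevant to the property
under test.
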
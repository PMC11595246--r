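---
title: "Time-wrapped hyperspectral acquisition and processing for time-domain coherent Raman imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-wrapped hyperspectral acquisition and processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdraman)
```

## The measurement this package models

In impulsive stimulated Raman microscopy a short pump pulse phase-locks the
low-frequency vibrations of the molecules in the focal volume. The vibrating
sample imposes a decaying oscillatory modulation on its refractive index,

$$\delta n(\tau) \;=\; \sum_i A_i\, e^{-\tau/T_{2,i}}\, \sin(2\pi\nu_i \tau + \phi_i),
\qquad \tau \ge 0,$$

where $\nu_i$ is the optical frequency of line $i$ (its Raman shift
$\Omega_i$ in cm$^{-1}$ times $100c$), $T_{2,i}$ its dephasing time and
$A_i$ its modulation depth. A delayed probe pulse experiences a red or blue
spectral shift proportional to $\mathrm{d}\,\delta n/\mathrm{d}\tau$, read
out as an intensity through an edge filter. Sweeping the pump-probe delay
$\tau$ and Fourier-transforming the trace yields the vibrational spectrum.

The delay is swept by an acousto-optic programmable dispersive filter
(an ultra-fast delay line) that covers `delay_span` = 4.5 ps of optical
delay in `window_duration` = 25 µs of laboratory time. The scan software
can only record plain 2D frames, so the instrument *time-wraps* the delay
dimension into the slow scan axis: the X galvo is slowed so that one full
delay scan happens while the beam crosses one **macro-pixel**, and the DAQ
keeps sampling at full rate. A raw frame is therefore an
$N_y \times (N_x \cdot N_\tau)$ record per channel, with $N_\tau = 270$
delay samples per macro-pixel, together with a trigger channel (one pulse
per delay scan) and a transmission channel (the delay line's
delay-dependent diffraction efficiency times the sample transmission).

This package simulates those raw records, registers them into
$(N_y, N_x, N_\tau)$ cubes using the trigger edges, and processes them into
per-pixel vibrational spectra and chemical images. The processing chain and
the acquisition-physics calculators are the contribution; everything is
testable without hardware because the simulator is a first-class, tested
module.

## Acquisition physics and the two calibration constants

Two timing constants describe the delay line and are deliberately carried
as *independent* configuration fields, because the instrument quotes them
independently and they are mutually inconsistent at the percent level:

* `delay_span / n_delay_samples` (4.5 ps / 270 ≈ 16.7 fs) defines the delay
  axis used to build and analyse traces;
* `delay_scaling` $\alpha_t$ = 161 fs/µs maps vibration frequencies to
  electronic frequencies: a vibration at $\Omega$ cm$^{-1}$ appears on the
  photodiode at $\Omega \cdot 100c \cdot \alpha_t \cdot 10^{-9}$ MHz.

Reconciling them (161 fs/µs × 25 µs = 4.025 ps ≠ 4.5 ps) would require
knowing which one reflects the true calibration, which is not stated; each
printed quantity is reproduced in its own context instead. The calculators
expose the resulting limits:

```{r physics}
electronic_frequency(160, 161)      # MHz at which a 160 cm^-1 line appears
max_shift_for_filter(1, 161)        # cm^-1 ceiling of a 1 MHz low-pass
nyquist_max_shift(delay_step(acquisition_config()))  # sampling ceiling
macro_pixel_length(500, 64)         # um swept during one delay scan
```

## What the simulator emulates — and what it does not

`simulate_acquisition()` writes, for every line, macro-pixel and window:
a trigger pulse, then $N_\tau$ samples of
`envelope × transmission × trace` into the Raman channel and
`envelope × transmission` into the transmission channel. Its stated world:

* **Detected trace**: the analytic first derivative of $\delta n$, plus a
  Gaussian pump-probe overlap spike at $\tau = 0$ (default FWHM 170 fs, the
  pulse duration; default amplitude 10× the largest line's derivative
  amplitude, as the overlap artifact dominates real traces). The spike is
  emitted only where the phantom contains material — an empty (void)
  species has no nonlinearity to produce it.
* **Envelope**: the delay line's per-window transmission is modelled as
  raised-cosine ramps (default `edge_fraction` 0.2) flanking a flat top;
  the real shape is bell-like but unspecified, so it is parameterised and
  nothing downstream depends on its exact form.
* **Jitter**: the DAQ clock is not synchronous with the line flyback, so
  each line starts with an unknown offset; modelled as one uniform integer
  circular shift per line, bounded by `jitter_max` (default 5 samples,
  required < $N_\tau/2$). Registration must remove it exactly.
* **Noise**: additive Gaussian noise per channel (defaults
  `raman_sigma` = 5e-4 and `transmission_sigma` = 1e-3, a few percent of a
  unit-amplitude line's derivative signal — representative of a shot-noise
  limited lock-in measurement).
* **Truncation**: an optional zeroed tail of the final line emulates
  imperfect trigger synchronization.

Not emulated: the RF detection chain (the 12 MHz modulation and lock-in
demodulation are treated as producing the baseband trace directly), pump
spectral bandwidth roll-off of the excitation efficiency, scanner
distortion, and sample motion. A green end-to-end test therefore
establishes that the *processing* is faithful, not that the instrument
model is complete.

## Registration

`reshape_to_cubes()` finds the rising edges of the trigger channel
(threshold at 50% of each line's dynamic range, debounced at half the
inter-edge period) and assigns the $N_\tau$ samples following each edge
(plus the configured `trigger_lead`) to consecutive macro-pixels and
windows. Because the simulator's jitter is a circular shift, full lines are
extracted with modulo indexing, which makes jitter removal exact — the
registered cubes are bit-identical whatever the jitter realization. A line
with fewer edges than expected is flagged truncated: present windows are
filled, missing or partially zeroed trailing macro-pixels are zero-filled
and masked invalid, and the cube stays rectangular. A line whose edge train
has a gap exceeding the window period is a structured error — the
instrument gives no precedent for repairing a malformed train, so the
package refuses to guess.

## Spectral processing

Per pixel, `process_cube()` applies:

1. **Normalization** (`normalize_by_transmission`): the Raman trace is
   divided by the transmission trace where the latter exceeds
   `floor_fraction` (default 0.05) of its maximum; edge samples below the
   floor are marked invalid instead of divided, so no non-finite value can
   enter the cube.
2. **Stitching** (`stitch_windows`): successive windows are offset by the
   3 ps mechanical step and overlap by 1.5 ps. For each adjacent pair the
   crossing of the falling and rising transmission envelopes is located;
   window $n$ contributes samples before the crossing, window $n+1$ after.
   A guard of `guard` valid samples on each side of the junction is
   re-generated from a modified-Akima (makima) interpolant fitted to the
   flanking retained samples — the makima slope weighting
   $w = |\delta_{i+1}-\delta_i| + |\delta_{i+1}+\delta_i|/2$ keeps the
   signal and its first derivative continuous without overshoot. The
   result is resampled onto a uniform axis at the native 16.7 fs spacing.

   The guard default is 2 samples. A wider guard was considered and
   rejected by measurement: bridging a 7-sample gap (guard 3) of a
   90 cm$^{-1}$ cosine sampled at 16.7 fs leaves 1.4% RMS reconstruction
   error, while guard 2 leaves 0.5% and guard 1 leaves 0.1%. Guard 2 is
   the widest setting that keeps clean-data reconstruction error well
   below 1% of the trace amplitude across the accessible band.
3. **Overlap masking** (`mask_overlap`): samples earlier than `cut_delay`
   (default 300 fs, comfortably past the 170 fs overlap spike) are zeroed;
   the retained region is mean-subtracted (the derivative signal is
   zero-mean in theory; any residual baseline would otherwise leak into
   the 10-150 cm$^{-1}$ band) and tapered with a Tukey window
   (`tukey_alpha` = 0.1 — a strong slope that preserves >90% of the
   trace).
4. **Spectrum** (`compute_spectrum`): magnitude of the FFT of the trace
   zero-padded to `pad_factor` (default 8) times the next power of two;
   the axis is converted to cm$^{-1}$ through the optical-delay sampling
   step. Eight-fold padding makes sub-bin peak positions and a 2 cm$^{-1}$
   FWHM measurable by interpolation.

`frequency_slice()` and `roi_spectrum()` produce the chemical images
(optional 2×2 Gaussian smoothing with $\sigma$ = 0.8 px — the instrument
states the kernel size but not its width — and image-max or cube-max
normalization) and region-averaged spectra.

## Magnitude versus power, and the FWHM convention

Whether displayed spectra are magnitude or power is not stated by the
instrument's description; the package stores **magnitude** by default
(which keeps the spectral chain exactly linear in the line amplitudes, a
tested invariant) and records the mode in the spectrum metadata.

The quoted *spectral resolutions*, however, pin down a convention: a
rectangular window of duration $T$ has a magnitude-FWHM of $1.2067/T$ —
2.24 cm$^{-1}$ even for an 18 ps trace — but a power-FWHM of $0.886/T$,
1.6 cm$^{-1}$ at 18 ps and 7 cm$^{-1}$ at 4.2 ps. Only the power (intensity)
convention is jointly consistent with the quoted 10 cm$^{-1}$
(single 4.5 ps window) and 2 cm$^{-1}$ (stitched multi-window) figures.
The resolution benchmarks therefore measure FWHM on power-mode spectra
(`mode = "power"`), while `peak_stats()` itself is convention-neutral: it
measures the values it is given.

## Numerical choices and degenerate inputs

* Trigger threshold 0.5 of the per-line dynamic range; robust to baseline
  drift. A flat trigger line is an error naming the line.
* Edge debounce at half the median inter-edge spacing rejects
  noise-induced double edges without losing true windows.
* Envelope-crossing search uses linear interpolation on a 256-point grid
  over the overlap; adjacent windows that do not overlap, or whose
  envelopes never cross, are errors.
* `makima` and `tukey_window` are implemented in-package (no
  signal-processing package is available in the target environment) and
  are tested against frozen reference values from an independent
  implementation.
* Delay-axis convention: sample $k$ (0-based) of window $w$ sits at
  $w \cdot \text{mechanical\_step} + k \cdot \text{delay\_span}/N_\tau$ —
  left-aligned, the trigger marking the scan start.
* All randomness flows through the `noise_model` seed; identical inputs
  give bit-identical records, cubes and spectra.

## The bundled phantoms

`phantom_bgo()` is a calibration phantom: a transparent crystal with a
single narrow resonance at 90 cm$^{-1}$ (default $T_2$ = 10 ps) occupying
one corner of a 64 × 63 frame, as used to calibrate the trigger lead.
`phantom_two_species()` is a chemical-contrast phantom on the 64 × 64,
500 µm field: an acetaminophen-like species (strongest low-frequency line
at 56 cm$^{-1}$), an anthracene-like species (37 cm$^{-1}$), and void.
Geometry and line parameters are synthetic stand-ins chosen once —
rectangular crystal blocks, $T_2$ = 5 ps, unit amplitudes, 0.85
transmission — not measured data.

```{r phantom-demo}
ph <- phantom_two_species()
ph
```

## Known limitations

* Registration is integer-sample; no fractional-delay interpolation of the
  trigger position (the instrument does the same).
* The simulator's jitter is circular, which real hardware is not; the
  registration consequently supports modulo extraction, and its exactness
  claims are with respect to this model.
* No lineshape fitting, baseline correction beyond mean subtraction, or
  denoising beyond the stated 2×2 Gaussian slice filter.
* The frame-rate and hardware-timing figures of the real instrument
  (130 ms/frame, 7.5 Hz) concern hardware and are out of scope; nothing in
  the package asserts them.
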
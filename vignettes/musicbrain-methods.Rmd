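---
title: "From sound to brain network dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sound to brain network dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musicbrain)
```

# Overview

`musicbrain` implements a complete modelling chain from an acoustic stimulus
to large-scale brain network dynamics, together with the matching analysis
pipeline for multichannel EEG recordings:

1. **Cochlea** — a finite-difference model of the basilar membrane converts a
   sound pressure signal into tonotopic neural spikes grouped into 24
   critical bands, summed into a single input signal $I(t)$.
2. **Network** — 90 FitzHugh–Nagumo (FHN) oscillators, one per region of the
   AAL-90 parcellation, coupled through a weighted two-hemisphere connectome;
   $I(t)$ drives the two auditory-cortex nodes (Temporal Sup L/R, nodes 41
   and 86).
3. **Measures** — mean phase velocities, a dynamical-phase Kuramoto order
   parameter $R(t)$, and a stimulus-coherence measure
   $\gamma = \frac{1}{\Delta T}\int_0^{\Delta T} R(t)\,I(t)\,dt$.
4. **EEG pipeline** — Mexican-hat wavelet decomposition into nine octave
   bands, windowed electrode-pair correlations, block averaging, top-25
   selection, and a band-wise correlation profile against the stimulus
   amplitude.

Synthetic generators (tone complexes, a song-like amplitude-modulated test
signal, a surrogate connectome, stimulus-locked synthetic EEG) make every
stage testable without external data.

# The cochlea model

## Equation of motion

The basilar membrane is a narrow trapezoidal plate, here reduced to a
one-dimensional rod of length $l = 3.5$ cm with position-dependent stiffness
$K(x) = 2\times 10^9 e^{-3.4x}$ dyn/cm$^3$ and cross section
$A(x) = 0.1\,\mathrm{cm}\,\times b(x)$, $b(x) = 0.1 + 0.02\,x/l$ cm, giving a
linear density $\mu(x) = m/A(x)$ for a model mass constant $m$. The
displacement $u(x,t)$ obeys

$$
\frac{\partial^2 u}{\partial t^2}
  = \frac{K(x)}{\mu(x)}\left(\frac{\partial^2 u}{\partial x^2}
    - \left(\frac{\pi}{b(x)}\right)^2 u\right)
  - d\,\frac{\partial u}{\partial t} - f(t),
$$

with homogeneous Dirichlet boundaries and the driving force $f(t)$ — the
audio samples, interpreted as sound pressure — applied instantaneously and
uniformly along $x$ (the long-wave approximation, valid below roughly
4 kHz: the sound speed in the cochlear lymph far exceeds the basilar-membrane
wave speed).

A word on the $\left(\pi/b\right)^2 u$ term. $K$ is a *per-volume*
(foundation) stiffness — its units, dyn/cm$^3$, make $K u / \mu$ an
acceleration, whereas a pure second-derivative term would not balance
dimensionally. Physically the membrane is clamped along its long edges, and
its dominant deflection across the narrow width $b(x)$ is the clamped
fundamental mode; eliminating the width coordinate by that mode converts the
transverse part of the membrane Laplacian into the local term
$-(\pi/b)^2 u$. The result is the standard cochlear picture: every position
carries a local resonance $\omega_0(x) = \sqrt{K/\mu}\,\pi/b(x)$, decreasing
from base to apex, and the longitudinal coupling term carries travelling
waves whose turning point sits where $\omega_0(x)$ matches the stimulus
frequency. We verified empirically that dropping the local term (taking the
printed one-dimensional Laplacian alone) destroys tonotopy altogether: the
steady-state response peak is then frequency-independent. A one-dimensional
rod model with the width-mode term behaves indistinguishably from a full 2-D
membrane for this purpose, which is why the rod reduction is used.

## Numerical scheme and calibration

The equation is integrated with explicit central differences in space and
time (second order). At the default grid of $n_\mathrm{grid} = 240$ points
(10 per critical band) and the audio time step $\Delta t = 1/192000$ s the
stability number $\max_x K A/(m)\,\Delta t^2/\Delta x^2$ is 0.84 for the
default mass $m = 3$; the constructor refuses configurations that violate
the bound. Input audio below 192 kHz is upsampled (Fourier zero-padding,
exact for band-limited signals).

Two parameters have no published values and are calibration choices,
reported by `calibrate_best_frequency_map()`:

* **mass constant** `mass = 3` — sets the overall best-frequency scale. With
  the default the map spans roughly 13 kHz at the base to 30 Hz at the apex,
  i.e. the audible range, and respects the stability bound with margin.
* **damping** `damping = 1000` s$^{-1}$ — sets the resonance width (about
  one critical band) and a transient decay time of a few milliseconds,
  matching the 5 ms spike transient that is discarded by `sound_to_input()`.

```{r tonotopy}
calibrate_best_frequency_map(freqs = c(200, 950, 4000), tone_duration = 0.08)
```

## Spikes

A neural spike is emitted at grid point $X$ and time $\tau$ when
$u(X,\tau)$ is a strict spatial maximum (maximal shearing of neighbouring
stereocilia), a strict temporal maximum, and positive (the cilia separate
only on positive deflection; `allow_negative_peaks` disables the sign
requirement). The spike weight is the displacement value — the natural
"strength" available in the model. Weights are summed per time bin across
all bands and the resulting $I(t)$ is max-normalized to 1. The binning rate
is a choice: for network experiments we bin at 50 Hz (20 ms), consistent
with the ~50 ms perceptual integration time of hearing — at audio-rate
binning the normalizing maximum is set by a single extreme bin and typical
loud-passage values become very small.

# The FHN network

Each region $k$ obeys

$$
\varepsilon \dot u_k = u_k - \tfrac{1}{3}u_k^3 - v_k
 + \sigma\!\!\sum_{j \in N_H}\!\! A_{kj}\,[B_{uu}(u_j{-}u_k) + B_{uv}(v_j{-}v_k)]
 + \varsigma\!\!\sum_{j \notin N_H}\!\! A_{kj}\,[\cdots] + C_k I(t),
$$
$$
\dot v_k = u_k + a
 + \sigma\!\!\sum_{j \in N_H}\!\! A_{kj}\,[B_{vu}(u_j{-}u_k) + B_{vv}(v_j{-}v_k)]
 + \varsigma\!\!\sum_{j \notin N_H}\!\! A_{kj}\,[\cdots],
$$

with $\varepsilon = 0.05$, threshold $a = 0.5$ (oscillatory regime),
intra-/inter-hemispheric coupling $\sigma = 0.7$, $\varsigma = 0.15$, and the
rotational coupling matrix $B$ with phase $\phi = \pi/2 - 0.1$ — an almost
pure activator–inhibitor cross-coupling that destabilizes full synchrony and
favours partial synchronization. $C_k = 1$ at the auditory nodes 41 and 86,
else 0.

## Time conversion

The FHN model is dimensionless. Its intrinsic period, measured by
`natural_frequency()` from the limit cycle (150 cycles after a transient),
is $T = 2.6659$, i.e. $\omega_\mathrm{FHN} = 2\pi/T = 2.3569$ and
$f_\mathrm{FHN} = 0.375$. A frequency-band parameter $n_b$ (Hz) ties the
model to physical time: 1 s of signal corresponds to $T \cdot n_b$
dimensionless units, equivalently the simulated brain frequency is
$f_b = n_b/f_\mathrm{FHN}$. The conversion always uses the *measured* $T$,
never a hard-coded constant. (Rounding $f_\mathrm{FHN}$ to 0.4 — as is
sometimes done — would give the familiar $T \approx 2.5$,
$\omega \approx 2.51$; the package reports the values its own integration
produces.)

## Integration

A Dormand–Prince 5(4) adaptive Runge–Kutta integrator (compiled, with the
network right-hand side evaluated through two 90×90 mat-vec products) with
default tolerances rtol $10^{-7}$/atol $10^{-9}$; ensemble scans use
$10^{-6}$/$10^{-8}$, where the single-oscillator frequency is stable to well
under 0.5%. Initial conditions are drawn per seed uniformly on the circle
$u^2 + v^2 = 4$. A transient (reference value 10 000 units; desk-scale
experiments use 500, long after the collective state settles) is integrated
before the input is switched on. The input enters unscaled (max 1) as a
zero-order hold over samples mean-pooled to 10 per FHN period — the audio
rate lies far below the integrator's step scale; pooling is the documented
decimation. Trajectories are stored on a uniform grid of 20 samples per
period.

# Synchrony measures

* **Mean phase velocity** $\omega_k = 2\pi M_k/\Delta T$, with $M_k$ the
  number of *complete* rotations of the unwrapped geometric phase
  $\tilde\phi_k = \mathrm{atan2}(v_k, u_k)$ (the quadrant-aware angle; the
  plain arctangent of $v/u$ is quadrant-ambiguous). The fractional remainder
  is discarded, so $\omega_k$ is quantized at $2\pi/\Delta T$.
* **Dynamical phase** $\theta_k$: the slow–fast FHN cycle sweeps the
  geometric phase non-uniformly, which would imprint spurious fluctuations
  on any phase-based order parameter. `dynamical_phase_map()` tabulates the
  time-of-arrival $t(\tilde\phi)$ along one unperturbed limit cycle (4096
  grid points, linear interpolation) and rescales
  $\theta = 2\pi\,t(\tilde\phi)/T$, which advances uniformly on the cycle.
* **Kuramoto order parameter**
  $R(t) = \lvert \frac{1}{N}\sum_k e^{i\theta_k(t)}\rvert \in [0, 1]$.
* **Coherence** $\gamma = \frac{1}{\Delta T}\int R\,I\,dt$ (trapezoidal
  quadrature after linear interpolation of $R$ and $I$ onto the coarser of
  the two physical-time grids): large exactly when synchronization episodes
  coincide with loud stimulus episodes.
* **Pearson correlation** through `stats::cor()` after validation, with
  errors that distinguish a constant first argument from a constant second.

# The surrogate connectome

The empirical DTI matrix behind the reference study is not publicly
deposited, so `generate_synthetic_connectome()` builds a surrogate with the
features that matter dynamically, and `load_adjacency()` accepts a measured
90×90 matrix whenever one is available. The surrogate is symmetric,
non-negative, zero-diagonal and max-normalized, with

* denser and stronger edges inside each 45-node hemisphere block than
  between blocks (`intra_density = 0.35` vs `inter_density = 0.12`,
  mean-weight ratio 2),
* heavy-tailed log-normal weights (`weight_sdlog = 1.5`) — empirical
  streamline-count matrices span orders of magnitude, and this heterogeneity
  is what keeps the network in the *partially* synchronized regime
  (time-averaged $R \approx 0.5$ with excursions between ~0 and ~0.9 at the
  reference coupling) instead of locking completely,
* elevated homologous-pair weights $(k, k+45)$, the callosal anti-diagonal,
* auditory hub structure: the rows of nodes 41/86 are scaled up
  (`auditory_hub = 2`), reflecting the high connectivity of the superior
  temporal region in tractography atlases and giving the stimulus its
  leverage over the collective dynamics.

These defaults were calibrated once against the qualitative regime reported
for the empirical matrix (partial synchronization; sensitivity of $R$ to
sustained auditory drive) and then frozen.

# Desk-scale experiments

`coherence_scan()` and `scenario_run()` drive ensembles over a grid of
$n_b$. The shipped study conditions are desk scale: a 30 s synthetic song
(10 alternating loud/quiet sections of 3 s, contrast 20:1, raised-cosine
ramps, plus the percussive beat layer — rhythm is the one stimulus feature
whose dimensionless rate crosses the FHN-responsive band as $n_b$ varies),
the surrogate connectome, 10 seeds, transient 500, and
$n_b \in \{5, 15, 30, 60, 90\}$ Hz. A reference-scale run (270 s song,
hundreds of seeds, transient 10 000) is the same function call with larger
arguments. With sizes this small the ensemble standard deviation of
$\gamma$ is comparable to parts of the structure of the $\gamma(n_b)$ curve
itself, and not every qualitative feature of the reference profile is
resolvable or even present with a surrogate connectome: the scan tests
assert the reference features (bounds, bookkeeping, a non-monotone
$\gamma(n_b)$ with an interior maximum, the decline of mean $R$ with
$n_b$) as stated, and a failing clause there reflects a genuine limit of
the desk-scale surrogate conditions rather than a tolerance choice.

# The EEG pipeline

All channels are decomposed with a Mexican-hat continuous wavelet transform,

$$
w(u, s) = \frac{1}{\sqrt{s}} \sum_k x_k\,
          \psi\!\left(\frac{(k-u)\,\Delta t}{s}\right),\qquad
\psi(x) = -\frac{2}{\pi^{1/4}\sqrt{3w}}
          \left(\frac{x^2}{w^2} - 1\right) e^{-x^2/2w^2},
$$

at nine octave scales $s_\mathrm{oct} = \alpha\,2^{\mathrm{oct}-1}$. The
width $w = 1$ and $\alpha$ are not published; we set $\alpha$ analytically
so the scale-1 peak response ($f^\ast = \sqrt{2}/(2\pi s)$ for a unit-width
Mexican hat) falls at the geometric mean $\sqrt{125 \cdot 250}$ Hz of the
highest band, which places the nine bands at 125–250 Hz (FB1) down to
0.49–0.98 Hz (FB9). The transform is computed by FFT convolution with zero
padding; the truncated kernel (support $\pm 5$ widths) is re-centred to zero
mean so constants map to zero exactly, and samples whose kernel overlaps the
padding are flagged valid/invalid rather than dropped.

The synchronization dynamics are windowed Pearson correlations over
successive non-overlapping 1 s windows (n = 500 samples at 500 Hz) for all
496 electrode pairs in each of the 9 bands — 4 464 series, one value per
second. Zero-variance windows yield r = 0 with a flag (a silent NaN would
poison every later average). Both the correlation series and the rectified,
1-s-averaged stimulus amplitude are then averaged in non-overlapping 4 s
blocks (about two musical bars — the scale of musical form). Per band the
25 series most correlated with the stimulus blocks are selected (ties broken
by pair index), averaged, and correlated with the stimulus; the across-band
mean of those selected averages gives the "whole brain" correlation.

The synthetic EEG generator reverses this logic: per band a shared
band-limited source enters every channel with a mixing weight modulated by
the stimulus envelope (depth `band_gain[b]`), the remainder of each
channel's band activity is independent, and a pink-noise background is
added. Windowed inter-channel correlation in band $b$ then tracks the
envelope with strength increasing in `band_gain[b]`, so band-specific
stimulus locking planted in bands 2–3 must be recovered as the profile's
maximum there. What the generator does *not* emulate: volume conduction,
electrode geometry, artifacts, non-stationary backgrounds, or any cortical
physiology — recovery tests validate the pipeline's selectivity, not any
claim about real EEG.

# Numerical and design notes

* Spike detection requires *strict* maxima; plateau points never spike.
  Equality ties in the top-25 ranking are broken lexicographically.
* `spikes_to_input()` errors when spikes fall outside the stated duration;
  an empty spike train yields an all-zero signal with a warning.
* The membrane energy used in the damping tests is the mixed two-slice form
  (kinetic + elastic + local potential evaluated on consecutive time
  slices), the discrete invariant of the leapfrog scheme; it is
  non-increasing under free damped evolution whenever the stability bound
  holds.
* The geometric phase of the FHN limit cycle is monotone about the origin
  (checked at map construction; a non-oscillatory parameter regime raises an
  error rather than returning a broken map).
* WAV I/O is a minimal RIFF PCM codec (16/24-bit integer, 32-bit float);
  there is no compressed-audio support.
* The ~50 ms perceptual integration window motivates the default 20 ms
  input binning but enters the numerics nowhere else.

# Known limitations

* The cochlea model has no middle-ear transfer function, hair-cell
  adaptation, refractoriness, or efferent feedback; spike "strength" is raw
  displacement.
* The network carries no propagation delays and models the oscillatory
  (a < 1) regime only.
* The surrogate connectome reproduces block structure and heterogeneity,
  not the true anatomy; quantitative coherence values therefore have no
  empirical counterpart, and only qualitative features of the
  $\gamma(n_b)$ profile are meaningful at desk scale.
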
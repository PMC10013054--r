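# musicbrain

Modelling how music drives large-scale brain network dynamics — and the
matching EEG analysis pipeline.

Listening to music modulates synchronization between brain regions, with the
strength of that modulation depending on the frequency band. `musicbrain`
implements a complete, testable chain for studying this numerically:

1. **Cochlea.** A finite-difference model of the basilar membrane (length
   3.5 cm, stiffness K(x) = 2×10⁹·e^(−3.4x) dyn/cm³, long-wave uniform
   forcing, Dirichlet boundaries) turns a sound pressure signal into neural
   spikes at strict positive spatio-temporal displacement maxima. Spikes are
   tonotopic — position encodes frequency — and are grouped into 24 critical
   bands, then summed per time bin into a max-normalized input signal I(t).
2. **Brain network.** 90 FitzHugh–Nagumo oscillators (ε = 0.05, a = 0.5,
   oscillatory regime), one per AAL-90 region, coupled through a weighted
   two-hemisphere connectome with rotational coupling
   B = [[cos φ, sin φ], [−sin φ, cos φ]], φ = π/2 − 0.1, intra-/
   inter-hemispheric strengths σ = 0.7 / ς = 0.15. I(t) is injected at the
   auditory cortices (Temporal Sup L/R, nodes 41 and 86). A frequency-band
   parameter n_b (Hz) ties the dimensionless model to physical time:
   1 s = T·n_b time units, with T the measured single-oscillator period.
3. **Measures.** Mean phase velocities ω_k = 2πM_k/ΔT, the Kuramoto order
   parameter R(t) = |N⁻¹Σ e^(iθ_k)| on a dynamical phase that uniformizes
   the slow–fast limit cycle, and the stimulus coherence
   γ = ΔT⁻¹∫R(t)·I(t)dt.
4. **EEG pipeline.** Mexican-hat wavelet decomposition of 32-channel
   recordings into nine octave bands (125–250 Hz down to 0.49–0.98 Hz),
   Pearson correlations of all 496 electrode pairs in successive 1-s windows
   (4,464 series), 4-s block averaging, selection of the 25 most
   stimulus-correlated series per band, and a band-wise correlation profile
   against the stimulus amplitude.

Synthetic generators for every input — tone complexes, a song-like
amplitude-modulated and rhythmic test signal, a two-hemisphere surrogate
connectome, stimulus-locked synthetic EEG — make the whole chain run and
test without any external data. Measured data (WAV audio, a 90×90 DTI
adjacency CSV, multichannel EEG CSV) drop into the same functions.

## Worked example

```r
library(musicbrain)

# intrinsic rhythm of one uncoupled oscillator
nf <- natural_frequency(fhn_parameters())
round(c(omega = nf$omega, period = nf$period, f = nf$f), 4)
#>  omega period      f
#> 2.3569 2.6659 0.3751

# a 475 Hz tone complex with ten 1/m partials through the cochlea
wave <- generate_tone_complex(475, 10, duration = 0.06, sample_rate = 192000)
res <- sound_to_input(wave)
nrow(res$spikes); sort(unique(res$spikes$band))
#> [1] 1989
#> [1]  5  6  7  8  9 10 11 14 16 17 19 20 24
# partial-related bands dominate: basal (low index) = high best frequency

# drive the network with a 30 s synthetic song and scan frequency bands
song <- generate_song_envelope(10, 3, seed = 42)
inp <- sound_to_input(song, output_rate = 50)$input
net <- generate_synthetic_connectome(seed = 1)
scan <- coherence_scan(inp, net, n_b_grid = c(5, 30, 90), seeds = 1:3)
scan$summary
#>   n_b mean_gamma   sd_gamma    mean_R n_runs
#> 1   5  0.1608241 0.014197568 0.5338425      3
#> 2  30  0.1745237 0.007931918 0.5626888      3
#> 3  90  0.1737239 0.008768354 0.5416288      3
```

`mean_gamma` is the coherence between the synchronization dynamics and the
stimulus — here lowest at n_b = 5 and maximal at an interior frequency-band
parameter; `mean_R` is the time-averaged Kuramoto order parameter. (A full
scan at the desk-scale defaults — 5 grid values, 10 seeds, short transient —
runs in roughly ten minutes on one core. Exact values depend on seeds.)

For the EEG side:

```r
env <- rep(rep(c(1, 0), each = 2000), length.out = 30000)  # 60 s at 500 Hz
recs <- generate_synthetic_eeg(env, band_gain = c(0, .9, .9, rep(0, 6)),
                               seed = 1)
prof <- band_correlation_profile(recs[[1]], env, stimulus_rate = 500)
prof$profile$band[which.max(prof$profile$r)]
#> [1] 2   # the injected gamma-band locking is recovered
```

A thin command-line front end wraps the same functions:

```sh
exec/musicbrain audio song --sections 10 --seed 42 --out song.wav
exec/musicbrain cochlea --in song.wav --input-signal I.csv
exec/musicbrain connectome --seed 1 --out A.csv
exec/musicbrain scan --input I.csv --connectome A.csv --out scan.csv
```

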
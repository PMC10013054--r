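Package: musicbrain
Title: Sound-Driven Brain Network Dynamics and EEG Synchronization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the path from an acoustic stimulus to large-scale brain
    network dynamics. A finite-difference basilar-membrane model converts
    audio into tonotopic neural spike trains grouped into 24 critical bands;
    the summed spike signal drives the auditory-cortex nodes of a network of
    90 FitzHugh-Nagumo oscillators coupled through a weighted two-hemisphere
    connectome. Synchrony is quantified by the Kuramoto order parameter on a
    dynamical phase, and a coherence measure relates synchronization episodes
    to the stimulus envelope across frequency-band scalings. A companion EEG
    pipeline decomposes multichannel recordings into nine octave bands with a
    Mexican-hat wavelet, computes windowed electrode-pair correlations, and
    profiles their band-wise correlation with the stimulus amplitude.
    Synthetic generators for stimuli, connectomes, and EEG recordings make
    the whole chain testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
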
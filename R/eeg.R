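#' Standard 32-channel electrode names (10-20 placement)
#'
#' @return Character vector of 32 electrode labels.
#' @export
electrode_names_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FT9", "FC5", "FC1",
    "FC2", "FC6", "FT10", "T7", "C3", "Cz", "C4", "T8", "TP9", "CP5",
    "CP1", "CP2", "CP6", "TP10", "P7", "P3", "Pz", "P4", "P8", "O1",
    "Oz", "O2")
}

#' Multichannel EEG recording
#'
#' @param data Numeric matrix, rows = samples, columns = channels.
#' @param sample_rate Sampling rate in Hz (default 500).
#' @param channels Channel names (default the 32-electrode 10-20 set).
#' @param subject,trial Optional identifiers.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, sample_rate = 500,
                          channels = electrode_names_32(),
                          subject = NA, trial = NA) {
  stopifnot(is.matrix(data))
  if (ncol(data) != length(channels))
    stop("`data` must have one column per channel name")
  colnames(data) <- channels
  structure(list(data = data, sample_rate = sample_rate,
                 channels = channels, subject = subject, trial = trial),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.4g s)\n",
              ncol(x$data), nrow(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate))
  invisible(x)
}

#' Grand average over recordings
#'
#' Per-channel arithmetic mean across subjects and trials; enhances evoked
#' (stimulus-locked) potentials against background activity.
#'
#' @param recordings List of [eeg_recording] objects with identical channels
#'   and lengths.
#' @return The averaged `eeg_recording`.
#' @export
grand_average <- function(recordings) {
  stopifnot(length(recordings) >= 1)
  ref <- recordings[[1]]
  for (r in recordings) {
    if (!identical(dim(r$data), dim(ref$data)) ||
        !identical(r$channels, ref$channels) ||
        r$sample_rate != ref$sample_rate)
      stop("all recordings must share channels, length and sample rate")
  }
  acc <- Reduce(`+`, lapply(recordings, `[[`, "data"))
  eeg_recording(acc / length(recordings), ref$sample_rate, ref$channels,
                subject = "grand_average", trial = length(recordings))
}

#' Mexican-hat (Ricker) wavelet
#'
#' psi(x) = -(2 / (pi^(1/4) sqrt(3 w))) (x^2/w^2 - 1) exp(-x^2 / (2 w^2)),
#' the normalized negative second derivative of a Gaussian of width `w`:
#' zero mean, unit L2 norm, zero crossings at x = +/- w.
#'
#' @param x Evaluation points.
#' @param width Wavelet width w (> 0).
#' @return psi(x).
#' @export
mexican_hat <- function(x, width = 1) {
  if (width <= 0) stop("`width` must be positive")
  -(2 / (pi^0.25 * sqrt(3 * width))) * (x^2 / width^2 - 1) *
    exp(-x^2 / (2 * width^2))
}

#' Octave-spaced wavelet scales
#'
#' s_oct = alpha * 2^(oct - 1) for oct = 1..`n_octaves`. With the default
#' `alpha` the Mexican-hat response of the first scale peaks at the geometric
#' mean of the 125-250 Hz band, so the nine scales cover the nine octave
#' bands FB1 (125-250 Hz) down to FB9 (0.49-0.98 Hz).
#'
#' @param alpha Smallest scale in seconds. The default places the scale-1
#'   peak response (sqrt(2)/(2 pi s) for a unit-width Mexican hat) at
#'   sqrt(125 * 250) Hz.
#' @param n_octaves Number of scales.
#' @return Numeric vector of scales in seconds.
#' @export
octave_scales <- function(alpha = NULL, n_octaves = 9) {
  if (is.null(alpha)) alpha <- sqrt(2) / (2 * pi * sqrt(125 * 250))
  alpha * 2^(seq_len(n_octaves) - 1)
}

#' Octave frequency-band edges
#'
#' @param n_bands Number of bands.
#' @return Data frame with `band`, `f_lo`, `f_hi` in Hz: FB1 = 125-250 Hz,
#'   each following band one octave lower.
#' @export
band_edges <- function(n_bands = 9) {
  data.frame(band = seq_len(n_bands),
             f_lo = 125 / 2^(seq_len(n_bands) - 1),
             f_hi = 250 / 2^(seq_len(n_bands) - 1))
}

#' Continuous wavelet transform at one scale
#'
#' w(u, s) = (1/sqrt(s)) sum_k x_k psi((k - u) dt / s), computed by FFT
#' convolution with zero padding. Samples whose wavelet support overlaps the
#' padded edges are flagged in the `"valid"` attribute rather than dropped.
#'
#' @param x Uniformly sampled series.
#' @param scale Wavelet scale s in the units of `dt` (> 0).
#' @param dt Sample interval.
#' @param width Mexican-hat width in wavelet-native units.
#' @param support Kernel half-width in multiples of `width * scale`.
#' @return Coefficient series of `length(x)` with attribute `"valid"`.
#' @export
cwt_band <- function(x, scale, dt, width = 1, support = 5) {
  if (scale <= 0) stop("`scale` must be positive")
  n <- length(x)
  half <- ceiling(support * width * scale / dt)
  if (2 * half + 1 > n)
    stop(sprintf(paste0("scale %.4g is too large for a series of %d ",
                        "samples (kernel needs %d)"), scale, n,
                 2 * half + 1))
  kern <- mexican_hat(((-half):half) * dt / scale, width) / sqrt(scale)
  kern <- kern - mean(kern)  # enforce zero mean on the truncated kernel

  # symmetric kernel: correlation == convolution
  L <- stats::nextn(n + 2 * half, 2)
  xf <- fft(c(x, numeric(L - n)))
  kf <- fft(c(kern[(half + 1):(2 * half + 1)],
              numeric(L - (2 * half + 1)), kern[1:half]))
  w <- Re(fft(xf * kf, inverse = TRUE))[1:n] / L
  valid <- rep(TRUE, n)
  if (half >= 1) {
    valid[1:min(half, n)] <- FALSE
    valid[max(1, n - half + 1):n] <- FALSE
  }
  attr(w, "valid") <- valid
  w
}

#' Decompose a recording into octave frequency bands
#'
#' Applies [cwt_band()] at each of the octave scales to every channel.
#'
#' @param eeg An [eeg_recording].
#' @param scales Wavelet scales in seconds (default [octave_scales()]).
#' @param width Mexican-hat width.
#' @return A `band_decomposition`: list with `bands` (list of coefficient
#'   matrices, one per band, same shape as the data), `scales`, `edges`.
#' @export
decompose_bands <- function(eeg, scales = octave_scales(), width = 1) {
  stopifnot(inherits(eeg, "eeg_recording"))
  dt <- 1 / eeg$sample_rate
  bands <- lapply(scales, function(s) {
    apply(eeg$data, 2, function(ch) as.numeric(cwt_band(ch, s, dt, width)))
  })
  structure(list(bands = bands, scales = scales,
                 edges = band_edges(length(scales)),
                 sample_rate = eeg$sample_rate, channels = eeg$channels,
                 width = width),
            class = "band_decomposition")
}

#' Windowed Pearson correlation of two series
#'
#' Pearson r over successive non-overlapping windows (1 s of samples by
#' default). Windows in which either series has zero variance yield r = 0 and
#' are flagged.
#'
#' @param a,b Equal-length numeric series.
#' @param window_samples Window length in samples.
#' @return Numeric vector (one r per window) with attribute `"flagged"`
#'   marking zero-variance windows.
#' @export
windowed_correlation <- function(a, b, window_samples = 500) {
  if (length(a) != length(b)) stop("series must have equal length")
  n_win <- length(a) %/% window_samples
  if (n_win < 1) stop("series shorter than one window")
  r <- numeric(n_win)
  flagged <- logical(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * window_samples + 1):(w * window_samples)
    sa <- sd(a[idx]); sb <- sd(b[idx])
    if (sa == 0 || sb == 0) {
      r[w] <- 0
      flagged[w] <- TRUE
    } else {
      r[w] <- cor(a[idx], b[idx])
    }
  }
  attr(r, "flagged") <- flagged
  r
}

# all electrode-pair windowed correlations of one band matrix
# (samples x channels) -> windows x n_pairs, pairs in combn order
.windowed_pair_correlations <- function(band, window_samples) {
  n_ch <- ncol(band)
  n_win <- nrow(band) %/% window_samples
  pairs <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  ord <- order(pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  out <- matrix(0, n_win, nrow(pairs))
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * window_samples + 1):(w * window_samples)
    cc <- suppressWarnings(cor(band[idx, , drop = FALSE]))
    cc[!is.finite(cc)] <- 0   # zero-variance channels
    out[w, ] <- cc[pairs]
  }
  out
}

#' Electrode-pair correlation dynamics
#'
#' The synchronization dynamics stage: per frequency band, Pearson r between
#' every electrode pair over successive 1-s windows, yielding
#' n_pairs x n_bands correlation time series at 1 value/s (4,464 series for
#' 32 channels and 9 bands).
#'
#' @param decomp A [decompose_bands()] result.
#' @param window_s Window length in seconds.
#' @return A `correlation_dynamics`: list with `bands` (list of
#'   windows x n_pairs matrices), `pair_labels`, `n_series`.
#' @export
correlation_dynamics <- function(decomp, window_s = 1) {
  stopifnot(inherits(decomp, "band_decomposition"))
  win <- round(window_s * decomp$sample_rate)
  n_ch <- length(decomp$channels)
  pairs <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  ord <- order(pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  bands <- lapply(decomp$bands, .windowed_pair_correlations,
                  window_samples = win)
  structure(list(bands = bands,
                 pair_labels = paste(decomp$channels[pairs[, 1]],
                                     decomp$channels[pairs[, 2]],
                                     sep = "-"),
                 pair_index = pairs,
                 n_series = length(bands) * nrow(pairs),
                 edges = decomp$edges),
            class = "correlation_dynamics")
}

#' Non-overlapping block average
#'
#' Means over successive blocks of `block` values (4-s blocks of 1-s values
#' by default); a trailing partial block is dropped.
#'
#' @param series Numeric vector or matrix (matrices are averaged along rows).
#' @param block Block length.
#' @return The block-averaged vector or matrix.
#' @export
block_average <- function(series, block = 4) {
  if (is.matrix(series)) {
    n_blk <- nrow(series) %/% block
    if (n_blk < 1) stop("series shorter than one block")
    idx <- rep(seq_len(n_blk), each = block)
    out <- rowsum(series[seq_len(n_blk * block), , drop = FALSE], idx) / block
    rownames(out) <- NULL
    return(out)
  }
  n_blk <- length(series) %/% block
  if (n_blk < 1) stop("series shorter than one block")
  colMeans(matrix(series[seq_len(n_blk * block)], nrow = block))
}

#' Select the most stimulus-correlated pair series per band
#'
#' Ranks, per frequency band, all electrode-pair correlation series by their
#' Pearson correlation with the block-averaged stimulus amplitude and keeps
#' the top `k`; ties are broken by pair index for determinism.
#'
#' @param corr_blocks List (one element per band) of blocks x n_pairs
#'   matrices of block-averaged correlation dynamics.
#' @param stimulus_blocks Block-averaged stimulus amplitude (same block
#'   count).
#' @param k Number of series kept per band.
#' @return List per band with `indices`, `r` (their correlations, ranked) and
#'   `mean_series` (mean of the selected series).
#' @export
select_top_k <- function(corr_blocks, stimulus_blocks, k = 25) {
  lapply(corr_blocks, function(B) {
    n_blk <- min(nrow(B), length(stimulus_blocks))
    if (k > ncol(B)) stop("`k` exceeds the number of pair series")
    s <- stimulus_blocks[seq_len(n_blk)]
    r <- apply(B[seq_len(n_blk), , drop = FALSE], 2, function(col) {
      if (sd(col) == 0 || sd(s) == 0) return(NA_real_)
      cor(col, s)
    })
    ord <- order(-r, seq_along(r), na.last = TRUE)
    sel <- ord[seq_len(k)]
    list(indices = sel, r = r[sel],
         mean_series = rowMeans(B[seq_len(n_blk), sel, drop = FALSE]))
  })
}

#' Stimulus amplitude in analysis blocks
#'
#' Rectifies the stimulus, averages it over 1-s windows, then over 4-s
#' blocks — the representation of the musical large-scale form used
#' throughout the pipeline.
#'
#' @param stimulus Numeric samples or an [input_signal] / [sound_wave].
#' @param sample_rate Sampling rate (taken from the object if available).
#' @param window_s,block 1-s window and block size.
#' @return Block-averaged amplitude vector.
#' @export
stimulus_blocks <- function(stimulus, sample_rate = NULL, window_s = 1,
                            block = 4) {
  if (inherits(stimulus, "input_signal") || inherits(stimulus, "sound_wave")) {
    sample_rate <- stimulus$sample_rate
    stimulus <- if (!is.null(stimulus$values)) stimulus$values
                else stimulus$samples
  }
  if (is.null(sample_rate)) stop("`sample_rate` is required for raw samples")
  win <- round(window_s * sample_rate)
  n_win <- length(stimulus) %/% win
  if (n_win < block) stop("stimulus shorter than one block")
  per_s <- colMeans(matrix(abs(stimulus[seq_len(n_win * win)]), nrow = win))
  block_average(per_s, block)
}

#' Band-wise stimulus-correlation profile
#'
#' The full experimental analysis chain: octave-band wavelet decomposition,
#' windowed electrode-pair correlations, 4-s block averaging, top-k selection
#' per band against the stimulus amplitude, and the final Pearson correlation
#' of each band's selected-mean synchronization dynamics with the stimulus —
#' plus the all-band average ("whole brain") correlation.
#'
#' @param eeg An [eeg_recording] (typically a grand average).
#' @param stimulus Stimulus samples, [input_signal] or [sound_wave].
#' @param stimulus_rate Sampling rate of raw stimulus samples.
#' @param k Series kept per band.
#' @param scales Wavelet scales.
#' @param width Mexican-hat width.
#' @param block Block size in 1-s windows.
#' @return A `band_correlation_profile`: data frame `profile` (band, f_lo,
#'   f_hi, r), `overall_r` (r of the across-band mean), `selection`,
#'   `stimulus_blocks`, `n_series`.
#' @export
band_correlation_profile <- function(eeg, stimulus, stimulus_rate = NULL,
                                     k = 25, scales = octave_scales(),
                                     width = 1, block = 4) {
  stim_blk <- stimulus_blocks(stimulus, stimulus_rate, block = block)
  if (sd(stim_blk) == 0)
    stop("`stimulus` has zero variance at the block scale; ",
         "the correlation is undefined")
  decomp <- decompose_bands(eeg, scales, width)
  cd <- correlation_dynamics(decomp)
  corr_blocks <- lapply(cd$bands, block_average, block = block)
  n_blk <- min(vapply(corr_blocks, nrow, 1L), length(stim_blk))
  stim_blk <- stim_blk[seq_len(n_blk)]
  sel <- select_top_k(corr_blocks, stim_blk, k)
  r_band <- vapply(sel, function(s)
    pearson_r(s$mean_series[seq_len(n_blk)], stim_blk), numeric(1))
  mean_all <- rowMeans(vapply(sel, function(s) s$mean_series[seq_len(n_blk)],
                              numeric(n_blk)))
  prof <- cbind(band_edges(length(scales)), r = r_band)
  structure(list(profile = prof,
                 overall_r = pearson_r(mean_all, stim_blk),
                 selection = sel, stimulus_blocks = stim_blk,
                 n_series = cd$n_series),
            class = "band_correlation_profile")
}

#' @export
print.band_correlation_profile <- function(x, ...) {
  cat("<band_correlation_profile>\n")
  print(x$profile, row.names = FALSE)
  cat(sprintf("all-band average: r = %.3f (%d pair series analyzed)\n",
              x$overall_r, x$n_series))
  invisible(x)
}

# 1/f (pink) background noise via spectral shaping, unit sd
.pink_noise <- function(n) {
  L <- stats::nextn(n, 2)
  X <- fft(rnorm(L))
  f <- c(1, seq_len(L - 1))
  X <- X / sqrt(pmin(f, L - f + 1))
  x <- Re(fft(X, inverse = TRUE))[1:n]
  (x - mean(x)) / sd(x)
}

#' Generate synthetic stimulus-locked EEG recordings
#'
#' Emulates the structure the analysis pipeline is designed to detect: per
#' octave band, all channels share a band-limited source whose share of each
#' channel's band activity is modulated by the stimulus envelope with depth
#' `band_gain[b]`; the remainder is independent band-limited activity, plus a
#' pink-noise background per channel. Windowed inter-channel correlation in
#' band b therefore tracks the envelope with strength increasing in
#' `band_gain[b]`. The shared sources are identical across subjects and
#' trials (evoked, stimulus-locked), the rest is independent.
#'
#' @param stimulus_envelope Envelope in \[0, 1\] sampled at `sample_rate`
#'   (its length sets the recording length).
#' @param band_gain Modulation depth per band (length = number of scales).
#' @param n_subjects,n_trials Recordings generated = subjects x trials.
#' @param seed Integer seed (same seed, same recordings).
#' @param sample_rate Sampling rate in Hz.
#' @param scales Wavelet scales defining the bands.
#' @param noise_sd Pink-noise background level relative to the band sources.
#' @param n_channels Number of electrodes.
#' @return List of [eeg_recording] objects.
#' @export
generate_synthetic_eeg <- function(stimulus_envelope, band_gain,
                                   n_subjects = 1, n_trials = 1, seed = 1,
                                   sample_rate = 500,
                                   scales = octave_scales(),
                                   noise_sd = 0.5, n_channels = 32) {
  n <- length(stimulus_envelope)
  if (any(stimulus_envelope < 0)) stop("envelope must be non-negative")
  if (length(band_gain) != length(scales))
    stop("`band_gain` must have one entry per scale")
  set.seed(as.integer(seed))
  dt <- 1 / sample_rate
  std <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x
  # shared (evoked) band-limited sources, one per band
  g <- lapply(scales, function(s) std(as.numeric(cwt_band(rnorm(n), s, dt))))
  lam <- lapply(seq_along(scales), function(b)
    pmin(1, pmax(0, band_gain[b] * stimulus_envelope)))
  channels <- electrode_names_32()[seq_len(n_channels)]
  recs <- list()
  for (subj in seq_len(n_subjects)) {
    for (trial in seq_len(n_trials)) {
      X <- matrix(0, n, n_channels)
      for (b in seq_along(scales)) {
        shared <- sqrt(lam[[b]]) * g[[b]]
        for (ch in seq_len(n_channels)) {
          own <- std(as.numeric(cwt_band(rnorm(n), scales[b], dt)))
          X[, ch] <- X[, ch] + shared + sqrt(1 - lam[[b]]) * own
        }
      }
      for (ch in seq_len(n_channels))
        X[, ch] <- X[, ch] + noise_sd * .pink_noise(n)
      recs[[length(recs) + 1]] <-
        eeg_recording(X, sample_rate, channels, subject = subj, trial = trial)
    }
  }
  recs
}
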
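#' Generate a harmonic tone complex
#'
#' Builds the classic test stimulus y(t) = sum_{m=1..M} (1/m) sin(2 pi m f0 t):
#' a fundamental plus harmonics with amplitudes falling off as 1/m.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param n_partials Number of partial tones (>= 1), fundamental included.
#' @param duration Signal length in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param normalize If `TRUE`, rescale so the peak amplitude is 1 (default
#'   `FALSE`, leaving the analytic 1/m amplitudes untouched).
#' @return A [sound_wave].
#' @examples
#' w <- generate_tone_complex(475, 10, duration = 0.05, sample_rate = 192000)
#' @export
generate_tone_complex <- function(f0, n_partials, duration,
                                  sample_rate = 192000, normalize = FALSE) {
  if (f0 <= 0) stop("`f0` must be positive")
  if (n_partials < 1) stop("`n_partials` must be at least 1")
  if (duration <= 0) stop("`duration` must be positive")
  nyquist <- sample_rate / 2
  if (f0 * n_partials >= nyquist)
    stop(sprintf(paste0("partial %d at %g Hz violates the Nyquist limit ",
                        "(%g Hz at sample rate %g Hz)"),
                 n_partials, f0 * n_partials, nyquist, sample_rate))
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  y <- numeric(n)
  for (m in seq_len(n_partials)) {
    y <- y + sin(2 * pi * m * f0 * t) / m
  }
  if (normalize) y <- y / max(abs(y))
  sound_wave(y, sample_rate)
}

#' Generate a song-like amplitude-modulated test signal
#'
#' Synthetic stand-in for a real piece of music at desk scale: a harmonic
#' carrier amplitude-modulated by a piecewise section envelope that alternates
#' loud and quiet sections (verse/chorus-like large-scale form) with smooth
#' raised-cosine ramps, plus a percussive layer — short broadband noise
#' bursts on a regular beat grid, scaled by the section envelope — standing
#' in for the rhythmic transients of real music. Reproducible from `seed`.
#'
#' @param n_sections Number of alternating sections (>= 2).
#' @param section_length Length of one section in seconds.
#' @param seed Integer seed; the same seed always yields the same samples.
#' @param sample_rate Sampling rate in Hz.
#' @param f0 Carrier fundamental in Hz.
#' @param n_partials Carrier partial count.
#' @param quiet_level Amplitude of the quiet sections relative to the loud
#'   sections (loud = 1).
#' @param ramp_fraction Fraction of a section spent ramping between levels.
#' @param level_jitter Relative uniform jitter applied to each section level
#'   (seeded); 0 gives the exact programmed pattern.
#' @param carrier_level Carrier amplitude relative to the beat bursts.
#' @param beat_interval Beat spacing in seconds (100 bpm by default).
#' @param beat_length Length of one percussive burst in seconds.
#' @param beat_level Burst amplitude; 0 disables the percussive layer.
#' @return A [sound_wave] (peak-normalized to 1) with attribute
#'   `"section_envelope"` (per-sample programmed envelope) and
#'   `"section_levels"`.
#' @examples
#' s <- generate_song_envelope(4, 0.5, seed = 1, sample_rate = 8000)
#' @export
generate_song_envelope <- function(n_sections, section_length, seed,
                                   sample_rate = 192000, f0 = 220,
                                   n_partials = 5, quiet_level = 0.05,
                                   ramp_fraction = 0.1, level_jitter = 0.05,
                                   carrier_level = 1, beat_interval = 0.6,
                                   beat_length = 0.03, beat_level = 1) {
  if (n_sections < 2) stop("`n_sections` must be at least 2")
  if (quiet_level < 0 || quiet_level > 1)
    stop("`quiet_level` must be in [0, 1]")
  if (ramp_fraction < 0 || ramp_fraction > 0.5)
    stop("`ramp_fraction` must be in [0, 0.5]")

  n_sec_samp <- round(section_length * sample_rate)
  n <- n_sections * n_sec_samp
  set.seed(as.integer(seed))
  levels <- rep(c(1, quiet_level), length.out = n_sections)
  if (level_jitter > 0)
    levels <- levels * runif(n_sections, 1 - level_jitter, 1 + level_jitter)

  env <- rep(levels, each = n_sec_samp)
  # smooth section transitions with a raised-cosine ramp
  n_ramp <- max(1L, round(ramp_fraction * n_sec_samp))
  if (n_ramp > 1L) {
    for (s in seq_len(n_sections - 1)) {
      j <- s * n_sec_samp
      lo <- levels[s]; hi <- levels[s + 1]
      idx <- (j - n_ramp + 1):(j + n_ramp)
      w <- (1 - cos(pi * seq(0, 1, length.out = length(idx)))) / 2
      env[idx] <- lo + (hi - lo) * w
    }
  }

  carrier <- generate_tone_complex(f0, n_partials, n / sample_rate,
                                   sample_rate, normalize = TRUE)
  y <- carrier_level * carrier$samples * env

  if (beat_level > 0) {
    n_burst <- max(1L, round(beat_length * sample_rate))
    decay <- exp(-seq(0, 5, length.out = n_burst))
    starts <- seq(1, n - n_burst, by = round(beat_interval * sample_rate))
    for (t0 in starts) {
      idx <- t0:(t0 + n_burst - 1)
      y[idx] <- y[idx] + beat_level * rnorm(n_burst) * decay * env[t0]
    }
  }

  wave <- sound_wave(y / max(abs(y)), sample_rate)
  attr(wave, "section_envelope") <- env
  attr(wave, "section_levels") <- levels
  wave
}
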
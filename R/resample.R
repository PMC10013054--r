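#' Band-limited upsampling
#'
#' Raises the sampling rate of a [sound_wave] by Fourier-domain zero padding:
#' the spectrum is kept unchanged below the original Nyquist frequency and the
#' inverse transform is evaluated on the denser grid. Exact for band-limited
#' (periodic) signals; the cochlea model needs 192 kHz input to satisfy the
#' FDTD stability bound.
#'
#' @param wave A [sound_wave].
#' @param target_rate Target sampling rate in Hz (>= `wave$sample_rate`).
#' @return A [sound_wave] at `target_rate`; the duration is preserved to
#'   within one sample period.
#' @examples
#' w <- generate_tone_complex(440, 1, 0.1, 8000)
#' up <- upsample(w, 48000)
#' @export
upsample <- function(wave, target_rate) {
  stopifnot(inherits(wave, "sound_wave"))
  if (target_rate < wave$sample_rate)
    stop("`target_rate` (", target_rate, " Hz) is below the current rate (",
         wave$sample_rate, " Hz); downsampling is not supported")
  if (target_rate == wave$sample_rate) return(wave)

  x <- wave$samples
  n <- length(x)
  n_out <- round(n * target_rate / wave$sample_rate)
  if (n_out == n) return(sound_wave(x, target_rate))

  X <- fft(x)
  Y <- complex(n_out)
  half <- floor(n / 2)
  if (n %% 2 == 0) {
    # split the Nyquist bin symmetrically to keep the signal real
    Y[1:half] <- X[1:half]
    Y[half + 1] <- X[half + 1] / 2
    Y[n_out - half + 1] <- Conj(X[half + 1]) / 2
    if (half > 1) Y[(n_out - half + 2):n_out] <- X[(half + 2):n]
  } else {
    Y[1:(half + 1)] <- X[1:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(half + 2):n]
  }
  y <- Re(fft(Y, inverse = TRUE)) / n
  sound_wave(y, target_rate)
}
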
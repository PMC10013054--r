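#' Sampled sound pressure signal
#'
#' Container for a uniformly sampled, dimensionless sound pressure signal.
#' Amplitudes are conventionally kept in \[-1, 1\]; the cochlea model's force
#' scale absorbs any physical calibration.
#'
#' @param samples Numeric vector of pressure samples.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return An object of class `sound_wave` with fields `samples` and
#'   `sample_rate`.
#' @examples
#' w <- sound_wave(sin(2 * pi * 440 * seq(0, 0.01, by = 1 / 48000)), 48000)
#' duration(w)
#' @export
sound_wave <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  if (anyNA(samples)) stop("`samples` contains missing values")
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate)),
            class = "sound_wave")
}

#' Duration of a sampled signal
#'
#' @param x A `sound_wave` or `input_signal` object.
#' @return Duration in seconds (`n_samples / sample_rate`).
#' @export
duration <- function(x) {
  UseMethod("duration")
}

#' @export
duration.sound_wave <- function(x) length(x$samples) / x$sample_rate

#' @export
print.sound_wave <- function(x, ...) {
  cat(sprintf("<sound_wave> %d samples @ %g Hz (%.4g s), range [%.3g, %.3g]\n",
              length(x$samples), x$sample_rate, duration(x),
              min(x$samples), max(x$samples)))
  invisible(x)
}
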
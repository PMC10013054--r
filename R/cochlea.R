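#' Basilar-membrane model parameters
#'
#' Physical and numerical parameters of the finite-difference basilar-membrane
#' model. The membrane (length `l` = 3.5 cm, a narrow rod) carries a stiffness
#' profile K(x) = 2e9 * exp(-3.4 x) dyn/cm^3 and a cross section
#' A(x) = 0.1 cm * b(x) with width b(x) = 0.1 cm + 0.02 cm * x/l, so the linear
#' density is mu(x) = mass / A(x). The displacement obeys
#'
#'   u_tt = (K/mu) (u_xx - (pi/b)^2 u) - d u_t - f(t)
#'
#' with homogeneous Dirichlet boundaries and the driving force f(t) acting
#' instantaneously and uniformly along x (long-wave approximation). The
#' (pi/b)^2 term is the clamped fundamental mode of the narrow width: it gives
#' every position a local resonance omega_0(x) = sqrt(K/mu) * pi/b, which is
#' what makes the membrane a tonotopic frequency analyzer (best frequencies
#' run from roughly 13 kHz at the base, x = 0, to 30 Hz at the apex with the
#' default mass).
#'
#' @param n_grid Number of spatial grid points (divisible by `n_bands`).
#' @param dt Time step in seconds; 1/192000 s keeps the explicit scheme below
#'   its stability bound at the default grid.
#' @param mass Model mass constant (sets the overall best-frequency scale;
#'   calibrated so the map spans the audible range, see
#'   [calibrate_best_frequency_map()]).
#' @param damping Damping rate d in 1/s (sets resonance width and the ~5 ms
#'   transient decay).
#' @param length Membrane length in cm.
#' @param n_bands Number of critical bands the grid is partitioned into.
#' @return A `membrane_parameters` object with the grid, the coupling
#'   coefficient `cx` = K/mu, the local resonance rates `w2`, and the
#'   stability number `cfl` (checked < 1 at construction).
#' @export
membrane_parameters <- function(n_grid = 240, dt = 1 / 192000, mass = 3,
                                damping = 1000, length = 3.5, n_bands = 24) {
  if (n_grid %% n_bands != 0)
    stop("`n_grid` must be divisible by `n_bands`")
  if (n_grid < 3) stop("`n_grid` must be at least 3")
  if (mass <= 0 || damping < 0 || dt <= 0) stop("invalid parameter values")
  x <- seq(0, length, length.out = n_grid)
  dx <- length / (n_grid - 1)
  K <- stiffness_profile(x, length)
  A <- 0.1 * (0.1 + 0.02 * x / length)
  b <- A / 0.1
  cx <- K * A / mass            # K/mu with mu = mass/A
  w2 <- cx * (pi / b)^2         # local resonance rate^2
  cfl <- max(cx) * dt^2 / dx^2
  if (cfl >= 1)
    stop(sprintf(paste0("explicit FDTD stability bound violated (CFL = %.3f",
                        " >= 1); increase `mass`, reduce `n_grid`, or use a",
                        " smaller `dt`"), cfl))
  structure(list(n_grid = n_grid, dt = dt, mass = mass, damping = damping,
                 length = length, n_bands = n_bands, x = x, dx = dx,
                 stiffness = K, cross_section = A, width = b, cx = cx,
                 w2 = w2, cfl = cfl),
            class = "membrane_parameters")
}

#' @export
print.membrane_parameters <- function(x, ...) {
  cat(sprintf(paste0("<membrane_parameters> %d grid points on %.2f cm, ",
                     "dt = 1/%g s, mass = %g, damping = %g /s, CFL = %.2f\n"),
              x$n_grid, x$length, round(1 / x$dt), x$mass, x$damping, x$cfl))
  invisible(x)
}

#' Basilar-membrane stiffness profile
#'
#' K(x) = 2e9 * exp(-3.4 x) dyn/cm^3, strictly decreasing from base (x = 0)
#' to apex.
#'
#' @param x Position(s) along the membrane in cm.
#' @param length Membrane length in cm (upper bound for `x`).
#' @return Stiffness in dyn/cm^3.
#' @examples
#' stiffness_profile(0)    # 2e9
#' @export
stiffness_profile <- function(x, length = 3.5) {
  if (any(x < 0 | x > length))
    stop("`x` must lie within [0, ", length, "] cm")
  2e9 * exp(-3.4 * x)
}

#' Initial membrane state
#'
#' @param params A [membrane_parameters] object.
#' @param u Current displacement (defaults to rest).
#' @param u_prev Displacement one step earlier (defaults to `u`, i.e. zero
#'   initial velocity).
#' @param time Current time in seconds.
#' @return A `membrane_state` object.
#' @export
membrane_state <- function(params, u = NULL, u_prev = NULL, time = 0) {
  n <- params$n_grid
  if (is.null(u)) u <- numeric(n)
  if (is.null(u_prev)) u_prev <- u
  stopifnot(length(u) == n, length(u_prev) == n)
  u[c(1, n)] <- 0
  u_prev[c(1, n)] <- 0
  structure(list(u = u, u_prev = u_prev, time = time),
            class = "membrane_state")
}

#' Advance the membrane by one explicit FDTD step
#'
#' One central-difference update of the damped membrane equation with the
#' same force value applied at every interior grid point and the boundaries
#' clamped to zero.
#'
#' @param state A [membrane_state].
#' @param force Driving force sample f(t) (scalar).
#' @param params A [membrane_parameters] object.
#' @return The updated `membrane_state`.
#' @export
step_membrane <- function(state, force, params) {
  u <- state$u
  up <- state$u_prev
  n <- params$n_grid
  i <- 2:(n - 1)
  dt <- params$dt
  lap <- u[i + 1] - 2 * u[i] + u[i - 1]
  un <- numeric(n)
  un[i] <- 2 * u[i] - up[i] + params$cx[i] * dt^2 / params$dx^2 * lap -
    params$w2[i] * dt^2 * u[i] - dt^2 * force -
    params$damping * dt * (u[i] - up[i])
  if (any(!is.finite(un)) || max(abs(un)) > 1e12)
    stop("membrane update became unstable; use a smaller dt or more damping")
  membrane_state(params, u = un, u_prev = u, time = state$time + dt)
}

#' Discrete membrane energy
#'
#' Mixed-form discrete energy of the explicit scheme (kinetic + elastic +
#' local-resonance potential, with the elastic and potential parts evaluated
#' as products of consecutive time slices). Non-increasing under free damped
#' evolution when the stability bound holds.
#'
#' @param state A [membrane_state].
#' @param params A [membrane_parameters] object.
#' @return Scalar energy (model units).
#' @export
membrane_energy <- function(state, params) {
  u <- state$u
  up <- state$u_prev
  dt <- params$dt
  dx <- params$dx
  kin <- 0.5 * sum(((u - up) / dt)^2)
  du <- diff(u) / dx
  dup <- diff(up) / dx
  c_half <- (params$cx[-1] + params$cx[-params$n_grid]) / 2
  ela <- 0.5 * sum(c_half * du * dup)
  pot <- 0.5 * sum(params$w2 * u * up)
  kin + ela + pot
}

#' Detect neural spikes in a displacement field
#'
#' A spike is emitted at grid point X and time index tau when the displacement
#' is a strict spatial maximum (larger than both spatial neighbours, maximum
#' shearing of adjacent nerve fibres) and a strict temporal maximum (larger
#' than the previous and next sample), and positive (stereocilia are driven
#' apart only on positive deflection; set `allow_negative_peaks = TRUE` to
#' drop the sign requirement).
#'
#' @param u_field Displacement matrix, rows = grid points, columns = time
#'   samples (at least 3 x 3).
#' @param allow_negative_peaks If `TRUE`, negative local maxima also count.
#' @return A data frame with columns `t_idx` (column index), `x_idx` (row
#'   index) and `weight` (the displacement value), ordered by time then
#'   position.
#' @export
detect_spikes <- function(u_field, allow_negative_peaks = FALSE) {
  stopifnot(is.matrix(u_field), nrow(u_field) >= 3, ncol(u_field) >= 3)
  n <- nrow(u_field)
  nt <- ncol(u_field)
  i <- 2:(n - 1)
  j <- 2:(nt - 1)
  u <- u_field[i, j, drop = FALSE]
  ok <- u > u_field[i - 1, j, drop = FALSE] &
        u > u_field[i + 1, j, drop = FALSE] &
        u > u_field[i, j - 1, drop = FALSE] &
        u > u_field[i, j + 1, drop = FALSE]
  if (!allow_negative_peaks) ok <- ok & (u > 0)
  w <- which(ok, arr.ind = TRUE)
  out <- data.frame(t_idx = w[, 2] + 1L, x_idx = w[, 1] + 1L,
                    weight = u[w])
  out[order(out$t_idx, out$x_idx), , drop = FALSE]
}

#' Map a grid index to its critical band
#'
#' The spatial grid is partitioned into `n_bands` equal contiguous segments;
#' because the stiffness decays exponentially this partition is approximately
#' logarithmic in best frequency. Band 1 is the basal end (highest best
#' frequency), band `n_bands` the apical end.
#'
#' @param grid_index 1-based grid index (vectorized).
#' @param n_grid Number of grid points.
#' @param n_bands Number of bands.
#' @return Integer band label(s) in `1..n_bands`.
#' @examples
#' assign_critical_band(c(1, 240))   # bands 1 and 24
#' @export
assign_critical_band <- function(grid_index, n_grid = 240, n_bands = 24) {
  if (any(grid_index < 1 | grid_index > n_grid))
    stop("grid index out of range 1..", n_grid)
  as.integer((grid_index - 1) %/% (n_grid / n_bands) + 1)
}

#' Tonotopic spike train
#'
#' @param time Spike times in seconds (non-decreasing after ordering).
#' @param band Critical-band labels (1..`n_bands`).
#' @param weight Positive spike weights (displacement magnitudes).
#' @param n_bands Number of critical bands.
#' @return A `spike_train` object (a data frame with attribute `n_bands`).
#' @export
spike_train <- function(time, band, weight, n_bands = 24) {
  stopifnot(length(time) == length(band), length(band) == length(weight))
  if (length(band) && (any(band < 1) || any(band > n_bands)))
    stop("band labels must lie in 1..", n_bands)
  if (any(weight <= 0)) stop("spike weights must be positive")
  ord <- order(time, band)
  out <- data.frame(time = time[ord], band = as.integer(band[ord]),
                    weight = weight[ord])
  attr(out, "n_bands") <- n_bands
  class(out) <- c("spike_train", "data.frame")
  out
}

#' Network input signal I(t)
#'
#' Non-negative, uniformly sampled sum of spike weights per time bin,
#' max-normalized to 1.
#'
#' @param values Non-negative samples.
#' @param sample_rate Sampling rate in Hz.
#' @param normalized Whether `values` are already max-normalized.
#' @return An `input_signal` object.
#' @export
input_signal <- function(values, sample_rate, normalized = TRUE) {
  if (any(values < 0)) stop("input signal values must be non-negative")
  structure(list(values = as.numeric(values),
                 sample_rate = as.numeric(sample_rate),
                 normalized = normalized),
            class = "input_signal")
}

#' @export
duration.input_signal <- function(x) length(x$values) / x$sample_rate

#' @export
print.input_signal <- function(x, ...) {
  cat(sprintf("<input_signal> %d samples @ %g Hz (%.4g s), max %.3g\n",
              length(x$values), x$sample_rate, duration(x), max(x$values)))
  invisible(x)
}

#' Sum a spike train into the network input signal
#'
#' Per output sample, I is the sum of the weights of all spikes (all bands)
#' falling into that sample bin; the result is then normalized so that
#' max I = 1 (when any spike exists).
#'
#' @param spikes A [spike_train].
#' @param duration Output signal length in seconds (all spikes must fall
#'   before it).
#' @param sample_rate Output sampling rate in Hz.
#' @return An [input_signal] with attribute `"total_weight"` (the
#'   pre-normalization mass).
#' @export
spikes_to_input <- function(spikes, duration, sample_rate) {
  n <- round(duration * sample_rate)
  if (nrow(spikes) == 0) {
    warning("empty spike train; returning an all-zero input signal")
    out <- input_signal(numeric(n), sample_rate)
    attr(out, "total_weight") <- 0
    return(out)
  }
  if (any(spikes$time >= duration))
    stop("all spike times must be smaller than `duration`")
  idx <- floor(spikes$time * sample_rate) + 1
  vals <- numeric(n)
  agg <- tapply(spikes$weight, idx, sum)
  vals[as.integer(names(agg))] <- agg
  total <- sum(spikes$weight)
  out <- input_signal(vals / max(vals), sample_rate)
  attr(out, "total_weight") <- total
  out
}

#' Run the full cochlea stage: sound in, spikes and I(t) out
#'
#' Feeds a sound wave through the basilar-membrane FDTD model, detects
#' tonotopic spikes, discards an initial transient, and sums the spike
#' weights into the network input signal.
#'
#' @param wave A [sound_wave]; upsampled automatically if its rate is below
#'   the model rate `1/params$dt`.
#' @param params A [membrane_parameters] object.
#' @param transient Initial interval in seconds whose spikes are discarded
#'   (membrane settling; default 5 ms).
#' @param output_rate Sampling rate of the returned I(t); defaults to the
#'   model rate.
#' @param allow_negative_peaks Passed to the spike detector.
#' @return A list with `spikes` (a [spike_train] carrying also the grid index
#'   `x_idx`), `input` (an [input_signal]) and `params`.
#' @export
sound_to_input <- function(wave, params = membrane_parameters(),
                           transient = 0.005, output_rate = NULL,
                           allow_negative_peaks = FALSE) {
  stopifnot(inherits(wave, "sound_wave"))
  model_rate <- 1 / params$dt
  if (wave$sample_rate < model_rate) wave <- upsample(wave, model_rate)
  if (wave$sample_rate > model_rate)
    stop("wave sample rate exceeds the model rate 1/dt; choose a smaller dt")
  res <- .cochlea_fdtd(wave$samples, params$cx, params$w2, params$damping,
                       params$dx, params$dt, FALSE, allow_negative_peaks)
  t_s <- res$t_idx * params$dt
  keep <- t_s >= transient
  x_idx <- res$x_idx[keep] + 1L  # 0-based C++ grid index -> 1-based
  spikes <- spike_train(t_s[keep],
                        assign_critical_band(x_idx, params$n_grid,
                                             params$n_bands),
                        res$weight[keep], params$n_bands)
  spikes$x_idx <- x_idx[order(t_s[keep])]
  if (is.null(output_rate)) output_rate <- model_rate
  inp <- if (nrow(spikes) == 0) {
    warning("no spikes detected; input signal is all zero")
    input_signal(numeric(round(duration(wave) * output_rate)), output_rate)
  } else {
    spikes_to_input(spikes, duration(wave), output_rate)
  }
  list(spikes = spikes, input = inp, params = params)
}

#' Measure the best-frequency map of the membrane model
#'
#' Drives the model with sustained pure tones and reports, per frequency, the
#' grid position and critical band of the maximal steady-state displacement
#' envelope. This is the calibration report for the `mass` and `damping`
#' defaults.
#'
#' @param params A [membrane_parameters] object.
#' @param freqs Tone frequencies in Hz.
#' @param tone_duration Tone length in seconds (steady state is read from the
#'   final third).
#' @return A data frame with `freq`, `peak_x` (cm), `peak_index`, `band`.
#' @export
calibrate_best_frequency_map <- function(params = membrane_parameters(),
                                         freqs = c(100, 200, 475, 950, 2000,
                                                   4000, 8000),
                                         tone_duration = 0.2) {
  rows <- lapply(freqs, function(f) {
    wave <- generate_tone_complex(f, 1, tone_duration, 1 / params$dt)
    res <- .cochlea_fdtd(wave$samples, params$cx, params$w2, params$damping,
                         params$dx, params$dt, FALSE, TRUE)
    steady <- res$t_idx * params$dt >= 2 / 3 * tone_duration
    if (!any(steady)) return(data.frame(freq = f, peak_x = NA_real_,
                                        peak_index = NA_integer_,
                                        band = NA_integer_))
    env <- tapply(abs(res$weight[steady]), res$x_idx[steady] + 1L, max)
    peak <- as.integer(names(env)[which.max(env)])
    data.frame(freq = f, peak_x = params$x[peak], peak_index = peak,
               band = assign_critical_band(peak, params$n_grid,
                                           params$n_bands))
  })
  do.call(rbind, rows)
}

#' Write a spike train to CSV
#'
#' @param spikes A [spike_train].
#' @param path Output path (columns `time_s`, `band`, `weight`).
#' @return `path`, invisibly.
#' @export
write_spike_train <- function(spikes, path) {
  df <- data.frame(time_s = spikes$time, band = spikes$band,
                   weight = spikes$weight)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an input signal to CSV
#'
#' @param input An [input_signal].
#' @param path Output path (columns `time_s`, `value`).
#' @return `path`, invisibly.
#' @export
write_input_signal <- function(input, path) {
  n <- length(input$values)
  df <- data.frame(time_s = (seq_len(n) - 1) / input$sample_rate,
                   value = input$values)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
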
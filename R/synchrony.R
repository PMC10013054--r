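# unwrap a phase sequence: remove 2*pi jumps so consecutive differences lie
# in (-pi, pi]
#' @noRd
.unwrap <- function(phase) {
  if (length(phase) < 2) return(phase)
  d <- diff(phase)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phase[1], d))
}

#' Geometric phase of a trajectory
#'
#' Quadrant-aware angle atan2(v, u) per node, unwrapped along time.
#'
#' @param traj A `trajectory` from [simulate_network()].
#' @param unwrap Return unwrapped phases (default) or raw angles in
#'   (-pi, pi].
#' @return Matrix (time x node) of phases in radians.
#' @export
geometric_phase <- function(traj, unwrap = TRUE) {
  ph <- atan2(traj$v, traj$u)
  if (unwrap) ph <- apply(ph, 2, .unwrap)
  ph
}

#' Build a phase-uniformizing map from a sampled cycle
#'
#' Given one full revolution of a closed orbit (u(t), v(t)), tabulates the
#' time of arrival t(phi) at each geometric phase and returns the dynamical
#' phase theta(phi) = 2*pi*t(phi)/T, a monotone map on \[0, 2*pi) under which
#' the cycle advances at constant rate.
#'
#' @param times Sample times covering at least one full revolution.
#' @param u,v State samples.
#' @param resolution Number of grid points of the tabulated map.
#' @return A `phase_map` object; call it via [apply_phase_map()].
#' @export
phase_map_from_cycle <- function(times, u, v, resolution = 4096) {
  ph <- .unwrap(atan2(v, u))
  if (any(diff(ph) <= 0))
    stop(paste0("geometric phase is not monotone along the cycle; ",
                "the orbit does not wind simply about the origin"))
  # one full revolution starting at the first multiple of 2*pi
  p0 <- 2 * pi * ceiling(ph[1] / (2 * pi))
  p1 <- p0 + 2 * pi
  if (ph[length(ph)] < p1)
    stop("cycle samples must cover at least one full revolution")
  t0 <- approx(ph, times, xout = p0, ties = "ordered")$y
  t1 <- approx(ph, times, xout = p1, ties = "ordered")$y
  period <- t1 - t0
  grid <- seq(0, 2 * pi, length.out = resolution + 1)
  t_of_phi <- approx(ph - p0, times - t0, xout = grid, ties = "ordered")$y
  theta <- 2 * pi * t_of_phi / period
  theta[resolution + 1] <- 2 * pi
  structure(list(phi = grid, theta = theta, period = period),
            class = "phase_map")
}

#' Dynamical-phase map of the uncoupled FHN oscillator
#'
#' Integrates a single uncoupled node, extracts one limit-cycle revolution,
#' and tabulates the transformation from geometric phase to the dynamical
#' phase theta = 2*pi*t(phi)/T under which the unperturbed oscillator rotates
#' uniformly. This suppresses the apparent order-parameter fluctuations that
#' the FHN slow-fast time scales would otherwise imprint on the Kuramoto
#' order parameter. Memoized per parameter set within a session.
#'
#' @param params An [fhn_parameters] object.
#' @param resolution Grid points of the tabulated map.
#' @return A `phase_map`.
#' @export
dynamical_phase_map <- function(params = fhn_parameters(),
                                resolution = 4096) {
  if (params$a >= 1) stop("a >= 1: excitable regime, no limit cycle")
  key <- paste("map", params$epsilon, params$a, resolution, sep = "_")
  if (!is.null(.musicbrain_cache[[key]])) return(.musicbrain_cache[[key]])
  nf <- natural_frequency(params)
  t0 <- 200
  times <- seq(t0, t0 + 2.5 * nf$period, by = nf$period / 20000)
  res <- .fhn_integrate(c(1, 0), 0, times, matrix(0, 1, 1), 1, 0, 0, 1,
                        params$epsilon, params$a, 0, numeric(0), 1, 0,
                        1e-9, 1e-11, 1e-4, 0.02, 1e9)
  map <- phase_map_from_cycle(times, res$states[, 1], res$states[, 2],
                              resolution)
  .musicbrain_cache[[key]] <- map
  map
}

#' Apply a phase map
#'
#' Maps geometric phases (wrapped or unwrapped) through a [phase_map]; the
#' winding number is preserved, the within-cycle position is uniformized.
#'
#' @param map A `phase_map`.
#' @param phase Numeric vector or matrix of geometric phases in radians.
#' @return Dynamical phases of the same shape.
#' @export
apply_phase_map <- function(map, phase) {
  wrap <- phase %% (2 * pi)
  th <- approx(map$phi, map$theta, xout = as.vector(wrap),
               ties = "ordered")$y
  out <- 2 * pi * ((as.vector(phase) - wrap) / (2 * pi)) + th
  if (is.matrix(phase)) out <- matrix(out, nrow(phase), ncol(phase))
  out
}

#' Mean phase velocity per node
#'
#' omega_k = 2*pi*M_k / DeltaT, where M_k is the number of complete 2*pi
#' windings of the unwrapped geometric phase of node k over the measurement
#' window DeltaT (same time units as the trajectory).
#'
#' @param traj A `trajectory`.
#' @return Numeric vector omega_k (one per node); their plain average is the
#'   spatially averaged mean phase velocity.
#' @export
mean_phase_velocity <- function(traj) {
  ph <- geometric_phase(traj)
  dT <- traj$times[length(traj$times)] - traj$times[1]
  gain <- ph[nrow(ph), ] - ph[1, ]
  if (any(gain < 2 * pi))
    stop("trajectory covers fewer than one full rotation for some node")
  2 * pi * floor(gain / (2 * pi)) / dT
}

#' Kuramoto order parameter series
#'
#' R(t) = |(1/N) sum_k exp(i theta_k(t))|: 1 for complete phase
#' synchronization, near 0 for incoherence.
#'
#' @param phases Matrix (time x node) of phases in radians.
#' @param times Optional time stamps (dimensionless).
#' @param times_s Optional physical time stamps in seconds.
#' @return An `order_parameter_series` with `R`, `times`, `times_s` and
#'   `mean_R`.
#' @export
kuramoto_order <- function(phases, times = NULL, times_s = NULL) {
  stopifnot(is.matrix(phases))
  R <- Mod(rowMeans(exp(1i * phases)))
  structure(list(R = R, times = times, times_s = times_s, mean_R = mean(R)),
            class = "order_parameter_series")
}

#' @export
print.order_parameter_series <- function(x, ...) {
  cat(sprintf("<order_parameter_series> %d samples, mean R = %.3f\n",
              length(x$R), x$mean_R))
  invisible(x)
}

#' Order parameter of a simulated trajectory
#'
#' Convenience chain: geometric phase, dynamical-phase transformation,
#' Kuramoto order parameter. Physical time stamps are attached when the
#' trajectory was driven by a rescaled input.
#'
#' @param traj A `trajectory`.
#' @param map Optional pre-computed [dynamical_phase_map()].
#' @return An `order_parameter_series`.
#' @export
order_parameter <- function(traj, map = NULL) {
  if (is.null(map)) map <- dynamical_phase_map(traj$params)
  theta <- apply_phase_map(map, geometric_phase(traj))
  times_s <- if (!is.na(traj$n_b))
    traj$times / (traj$period * traj$n_b) else NULL
  kuramoto_order(theta, times = traj$times, times_s = times_s)
}

#' Stimulus-coherence measure gamma
#'
#' Time average of the Kuramoto order parameter weighted with the normalized
#' input signal, gamma = (1/DeltaT) integral R(t) I(t) dt over the common
#' physical support: large when episodes of high synchronization coincide
#' with loud stimulus episodes, 0 when they never overlap.
#'
#' @param R An `order_parameter_series` carrying physical time stamps
#'   `times_s` (as produced by [order_parameter()] for a driven run).
#' @param input The [input_signal] the run was driven with.
#' @param tol Relative mismatch of the two supports tolerated before an
#'   alignment error is raised.
#' @return gamma in \[0, 1\] (given R <= 1 and I <= 1).
#' @export
coherence_gamma <- function(R, input, tol = 0.05) {
  stopifnot(inherits(R, "order_parameter_series"),
            inherits(input, "input_signal"))
  if (is.null(R$times_s))
    stop("order parameter series carries no physical time axis")
  dT <- duration(input)
  t_R <- R$times_s
  if (abs(t_R[length(t_R)] - dT) > tol * dT)
    stop(sprintf(paste0("misaligned supports: R covers %.4g s but the ",
                        "input lasts %.4g s"), t_R[length(t_R)], dT))
  # interpolate both onto the coarser of the two grids
  dt_R <- if (length(t_R) > 1) t_R[2] - t_R[1] else dT
  dt_I <- 1 / input$sample_rate
  dt <- max(dt_R, dt_I)
  t_end <- min(t_R[length(t_R)], dT)
  grid <- seq(0, t_end, by = dt)
  Rg <- approx(t_R, R$R, xout = grid, rule = 2, ties = "ordered")$y
  t_I <- (seq_along(input$values) - 1) / input$sample_rate
  Ig <- approx(t_I, input$values, xout = grid, rule = 2, ties = "ordered")$y
  sum(diff(grid) * (Rg[-1] * Ig[-1] + Rg[-length(Rg)] * Ig[-length(Ig)]) / 2) /
    dT
}

#' Pearson correlation coefficient
#'
#' Centered, normalized linear cross-correlation of two equal-length
#' sequences (no time delay).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return r in \[-1, 1\].
#' @examples
#' pearson_r(1:4, c(2, 1, 4, 3))   # 0.6
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (sd(x) == 0) stop("`x` has zero variance; the correlation is undefined")
  if (sd(y) == 0) stop("`y` has zero variance; the correlation is undefined")
  cor(x, y)
}
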
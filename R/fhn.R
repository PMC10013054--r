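#' FitzHugh-Nagumo network parameters
#'
#' Parameters of the 90-node FHN network. Each node follows the slow-fast FHN
#' dynamics (activator u, inhibitor v, timescale separation `epsilon`,
#' threshold `a`; oscillatory for a < 1). Nodes are diffusively coupled through
#' the rotational scheme of [coupling_matrix()]: strength `sigma` inside a
#' hemisphere, `varsigma` between hemispheres. The external input enters the
#' activator equation of the nodes flagged by the input mask (the auditory
#' cortices by default).
#'
#' @param epsilon Timescale separation (> 0).
#' @param a Threshold parameter; a < 1 gives self-sustained oscillations
#'   (a warning is issued otherwise).
#' @param sigma Intra-hemispheric coupling strength.
#' @param varsigma Inter-hemispheric coupling strength.
#' @param phi Coupling phase in radians (default pi/2 - 0.1, predominantly
#'   activator-inhibitor cross-coupling).
#' @return An `fhn_parameters` object.
#' @export
fhn_parameters <- function(epsilon = 0.05, a = 0.5, sigma = 0.7,
                           varsigma = 0.15, phi = pi / 2 - 0.1) {
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (a >= 1)
    warning("a >= 1: the FHN node is excitable, not oscillatory")
  structure(list(epsilon = epsilon, a = a, sigma = sigma,
                 varsigma = varsigma, phi = phi),
            class = "fhn_parameters")
}

#' @export
print.fhn_parameters <- function(x, ...) {
  cat(sprintf(paste0("<fhn_parameters> epsilon = %g, a = %g, sigma = %g, ",
                     "varsigma = %g, phi = %g\n"),
              x$epsilon, x$a, x$sigma, x$varsigma, x$phi))
  invisible(x)
}

#' Rotational coupling matrix
#'
#' The 2 x 2 rotation B = \[\[cos phi, sin phi\], \[-sin phi, cos phi\]\]
#' mixing activator and inhibitor differences in the coupling term. Near
#' phi = pi/2 the coupling is almost a pure activator-inhibitor
#' cross-coupling, the regime favouring partial synchronization.
#'
#' @param phi Coupling phase in radians.
#' @return A `coupling_scheme` object with components `buu`, `buv`, `bvu`,
#'   `bvv` and the matrix `B`.
#' @examples
#' coupling_matrix(0)$B         # identity
#' @export
coupling_matrix <- function(phi) {
  B <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
  dimnames(B) <- list(c("u", "v"), c("u", "v"))
  structure(list(buu = B[1, 1], buv = B[1, 2], bvu = B[2, 1], bvv = B[2, 2],
                 B = B, phi = phi),
            class = "coupling_scheme")
}

# combined coupling-weight matrix: sigma on intra-, varsigma on
# inter-hemispheric edges
.coupling_weights <- function(network, params) {
  A <- network$adjacency
  intra <- outer(network$hemisphere, network$hemisphere, "==")
  params$sigma * A * intra + params$varsigma * A * !intra
}

.input_mask <- function(network) {
  ck <- numeric(length(network$hemisphere))
  ck[network$auditory_nodes] <- 1
  ck
}

#' FHN network vector field
#'
#' Right-hand side of the coupled FHN equations: for node k with hemisphere
#' set N_H,
#' \deqn{\epsilon \dot u_k = u_k - u_k^3/3 - v_k
#'   + \sigma \sum_{j \in N_H} A_{kj} [B_{uu}(u_j-u_k) + B_{uv}(v_j-v_k)]
#'   + \varsigma \sum_{j \notin N_H} A_{kj} [\cdots] + C_k I(t)}
#' \deqn{\dot v_k = u_k + a + \sigma \sum_{j \in N_H} A_{kj}
#'   [B_{vu}(u_j-u_k) + B_{vv}(v_j-v_k)] + \varsigma \sum_{j \notin N_H}
#'   [\cdots]}
#' This is the reference (vectorized R) implementation; the integrator uses an
#' equivalent compiled version.
#'
#' @param t Time (only used to evaluate `input`).
#' @param state Numeric vector of length 180: `c(u, v)`.
#' @param network A `brain_network`.
#' @param params An [fhn_parameters] object.
#' @param scheme A [coupling_matrix()] result (defaults to `params$phi`).
#' @param input A function of time returning the scalar stimulus I(t), or
#'   `NULL` for no input.
#' @return The derivative vector `c(du, dv)` of length 180.
#' @export
fhn_rhs <- function(t, state, network, params,
                    scheme = coupling_matrix(params$phi), input = NULL) {
  n <- length(network$hemisphere)
  if (length(state) != 2 * n)
    stop("state must have length ", 2 * n)
  if (any(!is.finite(state))) stop("non-finite state")
  u <- state[1:n]
  v <- state[(n + 1):(2 * n)]
  M <- .coupling_weights(network, params)
  deg <- rowSums(M)
  su <- as.vector(M %*% u) - deg * u
  sv <- as.vector(M %*% v) - deg * v
  I <- if (is.null(input)) 0 else input(t)
  ck <- .input_mask(network)
  du <- (u - u^3 / 3 - v + scheme$buu * su + scheme$buv * sv + ck * I) /
    params$epsilon
  dv <- u + params$a + scheme$bvu * su + scheme$bvv * sv
  c(du, dv)
}

#' Natural frequency of a single uncoupled FHN oscillator
#'
#' Integrates one uncoupled node past a transient and measures the limit
#' cycle: the period T as the mean interval between successive 2*pi windings
#' of the unwrapped geometric phase (at least `n_cycles` cycles), and the
#' angular frequency omega = 2*pi/T. The result is memoized per
#' (epsilon, a, rtol) within a session.
#'
#' @param params An [fhn_parameters] object (coupling is ignored).
#' @param t_transient Transient discarded before measuring.
#' @param n_cycles Number of full cycles measured (>= 100 recommended).
#' @param rtol,atol Integrator tolerances.
#' @return A list with `omega`, `period` (T), and `f` (= 1/T), all in
#'   dimensionless units.
#' @examples
#' \donttest{natural_frequency(fhn_parameters())}
#' @export
natural_frequency <- function(params = fhn_parameters(), t_transient = 200,
                              n_cycles = 150, rtol = 1e-8, atol = 1e-10) {
  if (params$a >= 1)
    stop("a >= 1: excitable regime, no limit cycle")
  key <- paste("nf", params$epsilon, params$a, rtol, atol, t_transient,
               n_cycles, sep = "_")
  if (!is.null(.musicbrain_cache[[key]])) return(.musicbrain_cache[[key]])

  t_end <- t_transient + n_cycles * 3.2  # generous upper bound on T
  out_dt <- 0.005
  times <- seq(t_transient, t_end, by = out_dt)
  res <- .fhn_integrate(c(1, 0), 0, times, matrix(0, 1, 1), 1, 0, 0, 1,
                        params$epsilon, params$a, 0, numeric(0), 1, 0,
                        rtol, atol, 1e-4, 0.05, 1e9)
  u <- res$states[, 1]
  v <- res$states[, 2]
  ph <- .unwrap(atan2(v, u))
  # times at which the phase completes each winding
  k_first <- ceiling(ph[1] / (2 * pi)) + 1
  targets <- (k_first + 0:(n_cycles - 1)) * 2 * pi
  targets <- targets[targets <= ph[length(ph)]]
  if (length(targets) < 2)
    stop("trajectory too short to measure the period")
  tc <- approx(ph, times, xout = targets, ties = "ordered")$y
  period <- mean(diff(tc))
  out <- list(omega = 2 * pi / period, period = period, f = 1 / period)
  .musicbrain_cache[[key]] <- out
  out
}

#' Map a physical input signal onto dimensionless FHN time
#'
#' The dimensionless FHN model carries no time scale; it is tied to physical
#' time by identifying the oscillator's intrinsic rhythm with a frequency-band
#' parameter `n_b` (Hz): 1 s of signal corresponds to T * n_b dimensionless
#' time units, where T is the measured single-oscillator period. Equivalently
#' the simulated brain frequency is f_b = n_b / f_FHN. For the integrator the
#' signal is decimated by mean pooling to `samples_per_period` samples per FHN
#' period (full audio resolution lies far below the integrator's step scale)
#' and evaluated by zero-order hold.
#'
#' @param input An [input_signal].
#' @param n_b Frequency-band parameter in Hz (> 0).
#' @param params An [fhn_parameters] object (used to measure T).
#' @param samples_per_period Input samples per FHN period after decimation.
#' @return A list with the pooled `values`, their spacing `dt_sim` in
#'   dimensionless time, `t_total_sim`, the conversion factor
#'   `sim_units_per_second` (= T * n_b), `f_b`, and an evaluator
#'   `at(t_sim)` returning I at dimensionless time (0 outside support).
#' @export
rescale_input <- function(input, n_b, params = fhn_parameters(),
                          samples_per_period = 10) {
  stopifnot(inherits(input, "input_signal"))
  if (n_b <= 0) stop("`n_b` must be positive")
  nf <- natural_frequency(params)
  sim_per_s <- nf$period * n_b
  dur <- duration(input)
  # pool to samples_per_period samples per period T: physical pooling window
  pool <- max(1L, round(input$sample_rate / (samples_per_period * n_b)))
  n_full <- (length(input$values) %/% pool) * pool
  pooled <- colMeans(matrix(input$values[1:n_full], nrow = pool))
  tail_n <- length(input$values) - n_full
  if (tail_n > 0)
    pooled <- c(pooled, mean(input$values[(n_full + 1):length(input$values)]))
  dt_sim <- (pool / input$sample_rate) * sim_per_s
  list(values = pooled, dt_sim = dt_sim,
       t_total_sim = dur * sim_per_s,
       sim_units_per_second = sim_per_s,
       f_b = n_b / nf$f, n_b = n_b, period = nf$period,
       at = function(t_sim) {
         idx <- floor(t_sim / dt_sim) + 1
         out <- numeric(length(t_sim))
         ok <- idx >= 1 & idx <= length(pooled) & t_sim >= 0
         out[ok] <- pooled[idx[ok]]
         out
       })
}

#' Simulate the stimulus-driven FHN brain network
#'
#' Draws initial conditions uniformly on the circle u^2 + v^2 = 4, integrates
#' the network with an adaptive Runge-Kutta (Dormand-Prince 5(4)) scheme for
#' `t_transient` dimensionless units without input, then for the rescaled
#' input's full length with the stimulus injected at the auditory nodes, and
#' records the state on a uniform output grid.
#'
#' @param network A `brain_network`.
#' @param params An [fhn_parameters] object.
#' @param input An [input_signal], or `NULL` for a free run.
#' @param n_b Frequency-band parameter in Hz (required with `input`).
#' @param seed Integer seed for the initial conditions.
#' @param t_transient Transient time before the input starts (the reference
#'   study conditions use 10000; desk-scale experiments use less).
#' @param duration Free-run measurement length in dimensionless units (used
#'   only when `input` is `NULL`).
#' @param samples_per_period Output samples per FHN period.
#' @param rtol,atol Integrator tolerances.
#' @return A `trajectory` object: `times` (dimensionless, 0 = input onset),
#'   matrices `u`, `v` (time x node), `n_b`, `duration_s`, the measured
#'   `period`, `params`, `network`, integrator statistics, and `seed`.
#' @export
simulate_network <- function(network, params = fhn_parameters(), input = NULL,
                             n_b = NULL, seed = 1, t_transient = 10000,
                             duration = NULL, samples_per_period = 20,
                             rtol = 1e-7, atol = 1e-9) {
  n <- length(network$hemisphere)
  nf <- natural_frequency(params)
  set.seed(as.integer(seed))
  ang <- runif(n, 0, 2 * pi)
  y0 <- c(2 * cos(ang), 2 * sin(ang))

  if (!is.null(input)) {
    if (is.null(n_b)) stop("`n_b` is required when an input is supplied")
    rs <- rescale_input(input, n_b, params)
    t_meas <- rs$t_total_sim
    inp_values <- rs$values
    inp_dt <- rs$dt_sim
    duration_s <- duration(input)
  } else {
    if (is.null(duration))
      stop("supply `duration` (dimensionless) for a free run")
    t_meas <- duration
    inp_values <- numeric(0)
    inp_dt <- 1
    duration_s <- NA_real_
    rs <- NULL
  }

  out_dt <- nf$period / samples_per_period
  out_times <- seq(t_transient, t_transient + t_meas, by = out_dt)
  M <- .coupling_weights(network, params)
  sch <- coupling_matrix(params$phi)
  res <- .fhn_integrate(y0, 0, out_times, M, sch$buu, sch$buv, sch$bvu,
                        sch$bvv, params$epsilon, params$a,
                        .input_mask(network), inp_values, inp_dt,
                        t_transient, rtol, atol, 1e-4, out_dt, 1e10)
  states <- res$states
  if (any(!is.finite(states)))
    stop("integration produced non-finite states")
  structure(list(times = out_times - t_transient,
                 u = states[, 1:n, drop = FALSE],
                 v = states[, (n + 1):(2 * n), drop = FALSE],
                 n_b = if (is.null(n_b)) NA_real_ else n_b,
                 duration_s = duration_s,
                 period = nf$period, f_fhn = nf$f, omega_fhn = nf$omega,
                 params = params, network = network, seed = seed,
                 t_transient = t_transient,
                 rescaled_input = rs,
                 n_accepted = res$n_accepted, n_rejected = res$n_rejected),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(paste0("<trajectory> %d nodes, %d samples over %.4g ",
                     "dimensionless units (n_b = %s, seed = %s)\n"),
              ncol(x$u), length(x$times), max(x$times),
              format(x$n_b), format(x$seed)))
  invisible(x)
}
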
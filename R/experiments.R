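#' Coherence scan over frequency-band parameters
#'
#' For every combination of `n_b` and seed: simulate the driven network,
#' compute the dynamical-phase Kuramoto order parameter R(t), and the
#' stimulus-coherence gamma. Desk-scale defaults (short transient, modest
#' tolerances) keep an ensemble scan tractable; the reference study
#' conditions (t_transient = 10000, hundreds of seeds, a full song) are a
#' matter of arguments, not code.
#'
#' @param input An [input_signal] (the cochlea output for the stimulus).
#' @param network A `brain_network`.
#' @param n_b_grid Frequency-band parameters in Hz.
#' @param seeds Integer seeds (the ensemble).
#' @param params An [fhn_parameters] object.
#' @param t_transient Transient before input onset (dimensionless).
#' @param rtol,atol Integrator tolerances.
#' @param verbose Print per-run progress.
#' @return A `coherence_scan` object: `results` (tidy data frame n_b, seed,
#'   gamma, mean_R) and `summary` (per n_b: mean/sd gamma, mean mean_R).
#' @export
coherence_scan <- function(input, network, n_b_grid = c(5, 15, 30, 60, 90),
                           seeds = 1:10, params = fhn_parameters(),
                           t_transient = 500, rtol = 1e-6, atol = 1e-8,
                           verbose = FALSE) {
  map <- dynamical_phase_map(params)
  rows <- list()
  for (n_b in n_b_grid) {
    for (seed in seeds) {
      t0 <- proc.time()[["elapsed"]]
      traj <- simulate_network(network, params, input, n_b = n_b,
                               seed = seed, t_transient = t_transient,
                               rtol = rtol, atol = atol)
      R <- order_parameter(traj, map)
      g <- coherence_gamma(R, input)
      rows[[length(rows) + 1]] <-
        data.frame(n_b = n_b, seed = seed, gamma = g, mean_R = R$mean_R)
      if (verbose)
        message(sprintf("n_b = %g, seed = %d: gamma = %.4f, mean R = %.3f (%.1f s)",
                        n_b, seed, g, R$mean_R,
                        proc.time()[["elapsed"]] - t0))
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$n_b), function(d)
    data.frame(n_b = d$n_b[1], mean_gamma = mean(d$gamma),
               sd_gamma = sd(d$gamma), mean_R = mean(d$mean_R),
               n_runs = nrow(d))))
  summary <- summary[order(summary$n_b), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 n_b_grid = n_b_grid, seeds = seeds,
                 t_transient = t_transient),
            class = "coherence_scan")
}

#' @export
print.coherence_scan <- function(x, ...) {
  cat("<coherence_scan>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Single dynamical-scenario run
#'
#' Simulates one driven run and emits the standard diagnostic quantities: the
#' order parameter time series R(t), the per-node mean phase velocities
#' omega_k (with hemisphere labels and the auditory nodes marked), their
#' spatial average, and the temporal mean of R.
#'
#' @param network A `brain_network`.
#' @param input An [input_signal] or `NULL` for a free run.
#' @param n_b Frequency-band parameter in Hz.
#' @param seed Integer seed.
#' @param params An [fhn_parameters] object.
#' @param t_transient Transient before input onset.
#' @param duration Free-run length (dimensionless) when `input` is `NULL`.
#' @param rtol,atol Integrator tolerances.
#' @return A `scenario_run` object: `R` (order-parameter series), `omega`
#'   (data frame node, omega, hemisphere, auditory), `omega_bar`, `mean_R`,
#'   `gamma` (NA for free runs), `n_b`, `traj`.
#' @export
scenario_run <- function(network, input = NULL, n_b = NULL, seed = 1,
                         params = fhn_parameters(), t_transient = 500,
                         duration = NULL, rtol = 1e-6, atol = 1e-8) {
  traj <- simulate_network(network, params, input, n_b = n_b, seed = seed,
                           t_transient = t_transient, duration = duration,
                           rtol = rtol, atol = atol)
  R <- order_parameter(traj)
  omega_k <- mean_phase_velocity(traj)
  nodes <- seq_along(omega_k)
  omega <- data.frame(node = nodes, omega = omega_k,
                      hemisphere = network$hemisphere,
                      auditory = nodes %in% network$auditory_nodes)
  g <- if (!is.null(input)) coherence_gamma(R, input) else NA_real_
  structure(list(R = R, omega = omega, omega_bar = mean(omega_k),
                 mean_R = R$mean_R, gamma = g, n_b = traj$n_b,
                 seed = seed, traj = traj),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf(paste0("<scenario_run> n_b = %s, seed = %d: mean R = %.3f, ",
                     "omega_bar = %.3f, gamma = %s\n"),
              format(x$n_b), x$seed, x$mean_R, x$omega_bar,
              format(x$gamma, digits = 3)))
  invisible(x)
}

#' Savitzky-Golay smoothing (plot helper)
#'
#' Thin wrapper over [signal::sgolayfilt()] for presentation of scan curves;
#' never part of any measure.
#'
#' @param y Numeric series.
#' @param p Polynomial order.
#' @param n Window length (odd).
#' @return The smoothed series.
#' @export
smooth_savitzky_golay <- function(y, p = 3, n = 5) {
  signal::sgolayfilt(y, p = p, n = n)
}

#' Write scan results as tidy CSV
#'
#' @param scan A [coherence_scan()] result.
#' @param path Output path (columns n_b, seed, gamma, mean_R).
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(scan, path) {
  write.table(scan$results, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
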
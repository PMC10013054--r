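# shared fixtures, built in code

# small membrane for fast FDTD tests
small_membrane <- function(n_grid = 48, ...) {
  membrane_parameters(n_grid = n_grid, ...)
}

# brute-force spike detector: the independent oracle for detect_spikes
brute_force_spikes <- function(u, allow_negative_peaks = FALSE) {
  out <- data.frame(t_idx = integer(), x_idx = integer(), weight = numeric())
  for (j in 2:(ncol(u) - 1)) {
    for (i in 2:(nrow(u) - 1)) {
      val <- u[i, j]
      if (!allow_negative_peaks && val <= 0) next
      if (val > u[i - 1, j] && val > u[i + 1, j] &&
          val > u[i, j - 1] && val > u[i, j + 1]) {
        out <- rbind(out, data.frame(t_idx = j, x_idx = i, weight = val))
      }
    }
  }
  out
}

# two-pass Pearson correlation: the independent oracle for pearson_r
two_pass_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my)) / length(x)
  den <- sqrt(sum((x - mx)^2) / length(x)) * sqrt(sum((y - my)^2) / length(y))
  num / den
}

# triple-loop FHN right-hand side: the independent oracle for fhn_rhs
triple_loop_rhs <- function(t, state, network, params, scheme, I = 0) {
  n <- length(network$hemisphere)
  u <- state[1:n]
  v <- state[(n + 1):(2 * n)]
  A <- network$adjacency
  ck <- numeric(n)
  ck[network$auditory_nodes] <- 1
  du <- numeric(n)
  dv <- numeric(n)
  for (k in 1:n) {
    su_in <- 0; sv_in <- 0; su_out <- 0; sv_out <- 0
    for (j in 1:n) {
      cu <- scheme$buu * (u[j] - u[k]) + scheme$buv * (v[j] - v[k])
      cv <- scheme$bvu * (u[j] - u[k]) + scheme$bvv * (v[j] - v[k])
      if (network$hemisphere[j] == network$hemisphere[k]) {
        su_in <- su_in + A[k, j] * cu
        sv_in <- sv_in + A[k, j] * cv
      } else {
        su_out <- su_out + A[k, j] * cu
        sv_out <- sv_out + A[k, j] * cv
      }
    }
    du[k] <- (u[k] - u[k]^3 / 3 - v[k] + params$sigma * su_in +
              params$varsigma * su_out + ck[k] * I) / params$epsilon
    dv[k] <- u[k] + params$a + params$sigma * sv_in + params$varsigma * sv_out
  }
  c(du, dv)
}

# small driven network run shared across tests (memoized)
cached_small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- generate_synthetic_connectome(seed = 7)
      inp <- input_signal(rep(c(0.8, 0.1), each = 25), 10)  # 5 s, on/off
      cache <<- list(net = net,
                     inp = inp,
                     traj = simulate_network(net, fhn_parameters(), inp,
                                             n_b = 10, seed = 1,
                                             t_transient = 100,
                                             rtol = 1e-6, atol = 1e-8))
    }
    cache
  }
})
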
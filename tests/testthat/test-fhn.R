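test_that("coupling matrix is the stated rotation", {
  expect_equal(coupling_matrix(0)$B, diag(2), ignore_attr = TRUE)
  B <- coupling_matrix(pi / 2)$B
  expect_equal(B, matrix(c(0, -1, 1, 0), 2, 2), ignore_attr = TRUE)
  s <- coupling_matrix(pi / 2 - 0.1)
  expect_equal(s$buu, sin(0.1))
  expect_equal(det(s$B), 1)
  expect_equal(s$B %*% t(s$B), diag(2), ignore_attr = TRUE)
})

test_that("the network vector field matches the triple-loop oracle", {
  params <- fhn_parameters()
  scheme <- coupling_matrix(params$phi)
  for (seed in 1:4) {
    set.seed(seed)
    net <- generate_synthetic_connectome(seed = seed + 50)
    state <- rnorm(180)
    got <- fhn_rhs(0, state, net, params)
    want <- triple_loop_rhs(0, state, net, params, scheme)
    expect_equal(got, want, tolerance = 1e-12)

    # compiled right-hand side agrees with the R reference
    M <- musicbrain:::.coupling_weights(net, params)
    ck <- musicbrain:::.input_mask(net)
    got_cpp <- musicbrain:::.fhn_rhs_eval(0, state, M, scheme$buu,
                                          scheme$buv, scheme$bvu, scheme$bvv,
                                          params$epsilon, params$a, ck,
                                          numeric(0), 1, 0)
    expect_equal(got_cpp, want, tolerance = 1e-12)
  }
})

test_that("decoupled and synchronized-manifold limits reduce correctly", {
  net <- generate_synthetic_connectome(seed = 1)
  p0 <- fhn_parameters(sigma = 0, varsigma = 0)
  set.seed(1)
  state <- rnorm(180)
  got <- fhn_rhs(0, state, net, p0)
  u <- state[1:90]; v <- state[91:180]
  expect_equal(got, c((u - u^3 / 3 - v) / p0$epsilon, u + p0$a),
               tolerance = 1e-14)

  # identical node states: diffusive coupling vanishes
  p <- fhn_parameters()
  state_sync <- c(rep(0.7, 90), rep(-0.2, 90))
  got2 <- fhn_rhs(0, state_sync, net, p)
  single <- c((0.7 - 0.7^3 / 3 + 0.2) / p$epsilon, 0.7 + p$a)
  expect_equal(got2, rep(single, each = 90), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the uncoupled oscillator's limit cycle calibration is stable", {
  nf <- natural_frequency(fhn_parameters())
  expect_equal(nf$omega, 2 * pi / nf$period, tolerance = 1e-12)
  # tolerance robustness: < 0.5% drift between loose and tight integration
  loose <- natural_frequency(fhn_parameters(), rtol = 1e-6, atol = 1e-8)
  tight <- natural_frequency(fhn_parameters(), rtol = 1e-9, atol = 1e-11)
  expect_equal(loose$omega, tight$omega, tolerance = 5e-3)
  excitable <- suppressWarnings(fhn_parameters(a = 1.5))
  expect_error(natural_frequency(excitable), "excitable")
})

test_that("input rescaling implements the time conversion", {
  p <- fhn_parameters()
  nf <- natural_frequency(p)
  inp <- input_signal(rep(c(1, 0), each = 50), 100)  # 1 s
  rs <- rescale_input(inp, n_b = 30, p)
  expect_equal(rs$sim_units_per_second, nf$period * 30)
  expect_equal(rs$t_total_sim, nf$period * 30, tolerance = 1e-12)
  expect_equal(rs$f_b, 30 / nf$f)
  # n_b equal to the intrinsic frequency is the identity point f_b = 1
  rs1 <- rescale_input(inp, n_b = nf$f, p)
  expect_equal(rs1$f_b, 1)
  # evaluator: first half on, second half off, zero outside support
  expect_equal(rs$at(0.1 * rs$t_total_sim), 1)
  expect_equal(rs$at(0.9 * rs$t_total_sim), 0)
  expect_equal(rs$at(2 * rs$t_total_sim), 0)
  expect_error(rescale_input(inp, n_b = -1), "positive")
})

test_that("simulation is deterministic, bounded, and coupling raises coherence", {
  run <- cached_small_run()
  traj <- run$traj
  expect_true(all(abs(traj$u) < 5) && all(abs(traj$v) < 5))
  expect_true(all(diff(traj$times) > 0))

  # exact reproducibility under the same seed
  traj2 <- simulate_network(run$net, fhn_parameters(), run$inp, n_b = 10,
                            seed = 1, t_transient = 100,
                            rtol = 1e-6, atol = 1e-8)
  expect_identical(traj$u, traj2$u)

  # uncoupled free run: every node at the natural frequency
  p0 <- fhn_parameters(sigma = 0, varsigma = 0)
  free <- simulate_network(run$net, p0, seed = 2, t_transient = 100,
                           duration = 150, rtol = 1e-6, atol = 1e-8)
  w <- mean_phase_velocity(free)
  nf <- natural_frequency(p0)
  # omega = 2*pi*M/DeltaT is floor-quantized at 2*pi/DeltaT
  expect_true(all(abs(w - nf$omega) <= 2 * pi / 150 + 1e-9))

  # coupled free run is more coherent than the uncoupled one (paired
  # initial conditions; a homogeneous network, where diffusive coupling
  # synchronizes unambiguously — the heavy-tailed default regime sits at
  # partial synchronization by design)
  homog <- generate_synthetic_connectome(seed = 7, intra_strength = 4,
                                         weight_sdlog = 0.8,
                                         auditory_hub = 1)
  free_h <- simulate_network(homog, p0, seed = 2, t_transient = 100,
                             duration = 150, rtol = 1e-6, atol = 1e-8)
  coup_h <- simulate_network(homog, fhn_parameters(), seed = 2,
                             t_transient = 100, duration = 150,
                             rtol = 1e-6, atol = 1e-8)
  expect_gt(order_parameter(coup_h)$mean_R, order_parameter(free_h)$mean_R)
})
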
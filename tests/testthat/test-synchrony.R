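test_that("kuramoto order parameter hits its exact identities", {
  n <- 90
  # identical phases -> R = 1
  th <- matrix(1.3, 5, n)
  expect_equal(kuramoto_order(th)$R, rep(1, 5))
  # uniform phase fan (roots of unity) -> R = 0
  th <- matrix(2 * pi * (1:n) / n, 1, n)
  expect_equal(kuramoto_order(th)$R, 0, tolerance = 1e-14)
  # antiphase halves cancel
  th <- matrix(rep(c(0, pi), each = 45), 1, n)
  expect_equal(kuramoto_order(th)$R, 0, tolerance = 1e-14)
  # bounds on random phases
  set.seed(2)
  th <- matrix(runif(50 * n, 0, 2 * pi), 50, n)
  R <- kuramoto_order(th)$R
  expect_true(all(R >= 0 & R <= 1))
})

test_that("coherence gamma satisfies its exact identities and bilinearity", {
  mk_R <- function(vals, t_end = 1) {
    structure(list(R = vals,
                   times_s = seq(0, t_end, length.out = length(vals)),
                   mean_R = mean(vals)),
              class = "order_parameter_series")
  }
  I1 <- input_signal(rep(1, 100), 100)
  expect_equal(coherence_gamma(mk_R(rep(1, 101)), I1), 1, tolerance = 1e-12)

  # disjoint supports -> gamma = 0 (gap between R's and I's support)
  Ioff <- input_signal(c(rep(0, 60), rep(1, 40)), 100)
  Ron <- mk_R(c(rep(1, 40), rep(0, 61)))
  expect_equal(coherence_gamma(Ron, Ioff), 0, tolerance = 1e-12)

  # R == 1 -> gamma = time mean of I
  set.seed(4)
  Iv <- runif(100)
  Ir <- input_signal(Iv, 100)
  g <- coherence_gamma(mk_R(rep(1, 101)), Ir)
  expect_equal(g, mean(Iv), tolerance = 0.02)

  # scaling I by c scales gamma by c
  Ir2 <- input_signal(Iv * 0.3, 100, normalized = FALSE)
  expect_equal(coherence_gamma(mk_R(rep(1, 101)), Ir2) / g, 0.3,
               tolerance = 1e-10)
  # gamma <= mean I whenever R <= 1
  expect_lte(coherence_gamma(mk_R(runif(101)), Ir), mean(Iv))

  # misaligned supports error
  Ishort <- input_signal(rep(1, 30), 100)
  expect_error(coherence_gamma(mk_R(rep(1, 101)), Ishort), "misaligned")
})

test_that("pearson_r matches the two-pass oracle and its exact cases", {
  expect_equal(pearson_r(1:4, c(2, 1, 4, 3)), 0.6)
  x <- rnorm(20)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  for (seed in 1:5) {
    set.seed(seed)
    a <- rnorm(100)
    b <- rnorm(100) + 0.5 * a
    expect_equal(pearson_r(a, b), two_pass_pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "`x` has zero variance")
  expect_error(pearson_r(rnorm(5), rep(2, 5)), "`y` has zero variance")
  expect_error(pearson_r(1:3, 1:4), "equal length")
})

test_that("the dynamical phase map uniformizes the FHN limit cycle", {
  params <- fhn_parameters()
  map <- dynamical_phase_map(params)
  expect_equal(range(map$theta), c(0, 2 * pi), tolerance = 1e-10)
  expect_true(all(diff(map$theta) >= 0))

  # applying the map to a fresh limit-cycle trajectory linearizes the phase
  nf <- natural_frequency(params)
  times <- seq(300, 300 + 3 * nf$period, by = nf$period / 500)
  res <- musicbrain:::.fhn_integrate(c(1, 0), 0, times, matrix(0, 1, 1),
                                     1, 0, 0, 1, params$epsilon, params$a,
                                     0, numeric(0), 1, 0, 1e-9, 1e-11,
                                     1e-4, 0.02, 1e9)
  phi <- musicbrain:::.unwrap(atan2(res$states[, 2], res$states[, 1]))
  theta <- apply_phase_map(map, phi)
  tt <- times - times[1]
  resid <- (theta - theta[1]) - 2 * pi * tt / nf$period
  expect_lt(max(abs(resid)), 0.01)

  # variance of the dynamical phase velocity is suppressed >= 10x
  v_geo <- var(diff(phi))
  v_dyn <- var(diff(theta))
  expect_lt(v_dyn * 10, v_geo)

  # a perfect circle already has uniform phase: the map is the identity
  tc <- seq(0, 2.6, by = 0.001)
  circ <- phase_map_from_cycle(tc, 2 * cos(2 * pi * tc / 1.3),
                               2 * sin(2 * pi * tc / 1.3))
  expect_equal(circ$theta, circ$phi, tolerance = 1e-6)
})

test_that("mean phase velocity counts complete windings", {
  # synthetic trajectory advancing exactly 3 cycles over 3 time units
  t <- seq(0, 3, by = 0.001)
  traj <- structure(list(times = t,
                         u = cbind(cos(2 * pi * t), cos(2 * pi * t)),
                         v = cbind(sin(2 * pi * t), sin(2 * pi * t))),
                    class = "trajectory")
  w <- mean_phase_velocity(traj)
  expect_equal(w, rep(2 * pi, 2))
  # spatial average consistency
  expect_equal(mean(w), 2 * pi)

  short <- structure(list(times = t[1:100], u = traj$u[1:100, , drop = FALSE],
                          v = traj$v[1:100, , drop = FALSE]),
                     class = "trajectory")
  expect_error(mean_phase_velocity(short), "rotation")
})
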
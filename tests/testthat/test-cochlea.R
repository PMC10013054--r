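test_that("stiffness profile matches the exponential law", {
  expect_equal(stiffness_profile(0), 2e9)
  expect_equal(stiffness_profile(3.5), 2e9 * exp(-11.9))
  x <- seq(0, 3.5, length.out = 50)
  expect_true(all(diff(stiffness_profile(x)) < 0))
  expect_error(stiffness_profile(4), "within")
})

test_that("membrane parameters enforce the stability bound and monotone profiles", {
  p <- membrane_parameters()
  expect_lt(p$cfl, 1)
  expect_true(all(diff(p$stiffness) < 0))
  expect_true(all(diff(p$cross_section) > 0))
  # destabilizing configuration is rejected at construction
  expect_error(membrane_parameters(mass = 0.2), "stability")
})

test_that("zero state with zero force is a fixed point; boundaries stay clamped", {
  p <- small_membrane()
  st <- membrane_state(p)
  st2 <- step_membrane(st, 0, p)
  expect_equal(st2$u, numeric(p$n_grid))

  set.seed(1)
  u0 <- c(0, rnorm(p$n_grid - 2), 0) * 1e-3
  st <- membrane_state(p, u = u0)
  for (i in 1:50) {
    st <- step_membrane(st, sin(i / 5), p)
    expect_identical(st$u[c(1, p$n_grid)], c(0, 0))
  }
})

test_that("free damped evolution has non-increasing discrete energy", {
  p <- small_membrane()
  for (seed in 1:3) {
    set.seed(seed)
    # smooth random initial displacement, zero initial velocity
    u0 <- c(0, cumsum(rnorm(p$n_grid - 2)), 0)
    u0 <- u0 - seq(0, u0[p$n_grid - 1], length.out = p$n_grid)
    u0[c(1, p$n_grid)] <- 0
    st <- membrane_state(p, u = u0 * 1e-4)
    e <- membrane_energy(st, p)
    for (i in 1:100) {
      st <- step_membrane(st, 0, p)
      e_new <- membrane_energy(st, p)
      expect_lte(e_new, e * (1 + 1e-12))
      e <- e_new
    }
  }
})

test_that("spike detection equals brute-force enumeration on random fields", {
  for (seed in 1:6) {
    set.seed(seed)
    nr <- sample(5:50, 1)
    nc <- sample(5:50, 1)
    u <- matrix(rnorm(nr * nc), nr, nc)
    for (neg in c(FALSE, TRUE)) {
      got <- detect_spikes(u, allow_negative_peaks = neg)
      want <- brute_force_spikes(u, allow_negative_peaks = neg)
      want <- want[order(want$t_idx, want$x_idx), ]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
    }
  }

  # single constructed positive peak
  u <- matrix(-1, 7, 7)
  u[4, 4] <- 1
  sp <- detect_spikes(u)
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$t_idx, sp$x_idx, sp$weight), c(4, 4, 1))

  # monotone field has no interior maxima
  u <- outer(1:10, 1:10, `+`)
  expect_equal(nrow(detect_spikes(u * 1.0)), 0)
})

test_that("on-line FDTD spike detection equals detect_spikes on the stored field", {
  p <- small_membrane()
  set.seed(3)
  force <- rnorm(400)
  res <- musicbrain:::.cochlea_fdtd(force, p$cx, p$w2, p$damping, p$dx, p$dt,
                                    TRUE, FALSE)
  ref <- detect_spikes(res$field)
  expect_equal(res$t_idx + 0L, ref$t_idx - 0L, ignore_attr = TRUE)
  expect_equal(res$x_idx + 1L, ref$x_idx, ignore_attr = TRUE)
  expect_equal(res$weight, ref$weight, ignore_attr = TRUE)
})

test_that("critical bands partition the grid with basal band 1", {
  b <- assign_critical_band(1:240)
  expect_equal(sort(unique(b)), 1:24)
  expect_equal(b[1], 1L)
  expect_equal(b[240], 24L)
  expect_equal(as.vector(table(b)), rep(10L, 24))
  expect_true(all(diff(b) >= 0))
  expect_error(assign_critical_band(0), "out of range")
})

test_that("spikes_to_input conserves mass, normalizes, and handles empties", {
  sp <- spike_train(time = c(0.1, 0.1, 0.3), band = c(2, 5, 9),
                    weight = c(0.2, 0.3, 0.1))
  inp <- spikes_to_input(sp, duration = 0.5, sample_rate = 10)
  expect_equal(max(inp$values), 1)
  expect_equal(inp$values[2], 1)          # 0.2 + 0.3 in one bin -> max
  expect_equal(inp$values[4], 0.1 / 0.5)
  # pre-normalization mass equals total spike weight (max raw bin = 0.5)
  expect_equal(sum(inp$values) * 0.5, sum(sp$weight))
  expect_equal(attr(inp, "total_weight"), 0.6)

  # conservation on a random spike set
  set.seed(9)
  sp2 <- spike_train(time = runif(200, 0, 0.9), band = sample(1:24, 200, TRUE),
                     weight = runif(200))
  inp2 <- spikes_to_input(sp2, 1, 50)
  expect_equal(sum(inp2$values) * max(tapply(sp2$weight,
               floor(sp2$time * 50), sum)), sum(sp2$weight))

  empty <- spike_train(numeric(0), integer(0), numeric(0))
  expect_warning(z <- spikes_to_input(empty, 1, 100), "empty")
  expect_equal(z$values, numeric(100))

  expect_error(spikes_to_input(sp, duration = 0.05, sample_rate = 10),
               "smaller than")
})

test_that("tone complexes produce tonotopic band-clustered spikes", {
  p <- membrane_parameters()
  w475 <- generate_tone_complex(475, 1, 0.06, 192000)
  w950 <- generate_tone_complex(950, 1, 0.06, 192000)
  r475 <- sound_to_input(w475, p)
  r950 <- sound_to_input(w950, p)
  # lower tone sits more apically (larger band index)
  expect_gt(mean(r475$spikes$band), mean(r950$spikes$band))

  # transient removal: no spikes before 5 ms
  expect_true(all(r475$spikes$time >= 0.005))

  # silent input yields a zero signal
  silent <- sound_wave(numeric(1920), 192000)
  expect_warning(rs <- sound_to_input(silent, p), "no spikes")
  expect_true(all(rs$input$values == 0))
})

test_that("best-frequency position is monotone in stimulus frequency", {
  map <- calibrate_best_frequency_map(freqs = c(200, 950, 4000),
                                      tone_duration = 0.08)
  expect_true(all(diff(map$peak_index) < 0))  # higher f -> more basal
  expect_true(all(diff(map$band) <= 0))
})
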
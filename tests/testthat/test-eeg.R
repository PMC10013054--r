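test_that("grand averaging behaves like an arithmetic mean", {
  set.seed(1)
  x <- eeg_recording(matrix(rnorm(500 * 32), 500, 32))
  expect_equal(grand_average(rep(list(x), 75))$data, x$data)

  neg <- x
  neg$data <- -x$data
  expect_equal(grand_average(list(x, neg))$data, matrix(0, 500, 32),
               ignore_attr = TRUE)

  # averaging N i.i.d. noise recordings shrinks the sd by ~ 1/sqrt(N)
  set.seed(2)
  recs <- lapply(1:75, function(i)
    eeg_recording(matrix(rnorm(400 * 32), 400, 32)))
  ga <- grand_average(recs)
  ratio <- sd(ga$data) / mean(vapply(recs, function(r) sd(r$data), 1))
  expect_equal(ratio, 1 / sqrt(75), tolerance = 0.1)

  bad <- eeg_recording(matrix(0, 300, 32))
  expect_error(grand_average(list(x, bad)), "share")
})

test_that("the Mexican hat wavelet has its analytic shape", {
  for (w in c(0.5, 1, 2)) {
    expect_equal(mexican_hat(0, w), 2 / (pi^0.25 * sqrt(3 * w)))
    expect_equal(mexican_hat(c(-w, w), w), c(0, 0))
  }
  # zero mean (admissibility)
  x <- seq(-40, 40, by = 0.01)
  expect_lt(abs(sum(mexican_hat(x, 1)) * 0.01), 1e-8)
  expect_error(mexican_hat(0, -1), "positive")
})

test_that("octave scales double and target the printed band edges", {
  s <- octave_scales()
  expect_length(s, 9)
  expect_equal(s[-1] / s[-9], rep(2, 8))
  # scale-1 peak response sits at the geometric centre of 125-250 Hz
  f_peak <- sqrt(2) / (2 * pi * s[1])
  expect_equal(f_peak, sqrt(125 * 250), tolerance = 1e-12)
  e <- band_edges()
  expect_equal(e$f_hi[1], 250)
  expect_equal(e$f_lo[9], 125 / 256)
})

test_that("the wavelet transform is linear, kills constants, and is band selective", {
  dt <- 1 / 500
  s <- octave_scales()
  expect_equal(as.numeric(cwt_band(numeric(600), s[3], dt)), numeric(600))

  set.seed(3)
  x <- rnorm(600)
  y <- rnorm(600)
  lin <- cwt_band(2 * x - 3 * y, s[3], dt)
  expect_equal(as.numeric(lin),
               as.numeric(2 * cwt_band(x, s[3], dt) - 3 * cwt_band(y, s[3], dt)),
               tolerance = 1e-10)

  const <- cwt_band(rep(5, 600), s[2], dt)
  expect_lt(max(abs(const[attr(const, "valid")])), 1e-8)

  # a tone at FB3's centre frequency concentrates its energy in band 3
  f3 <- sqrt(31.25 * 62.5)
  t <- seq(0, 4, by = dt)
  tone <- sin(2 * pi * f3 * t)
  energy <- vapply(s, function(sc) {
    w <- cwt_band(tone, sc, dt)
    sum(w[attr(w, "valid")]^2)
  }, 1)
  expect_equal(which.max(energy), 3)

  expect_error(cwt_band(rnorm(50), s[9], dt), "too large")
})

test_that("windowed correlation has the stated resolution and null level", {
  set.seed(4)
  a <- rnorm(270 * 500)
  r_self <- windowed_correlation(a, a)
  expect_length(r_self, 270)
  expect_equal(as.numeric(r_self), rep(1, 270), tolerance = 1e-12)

  b <- rnorm(270 * 500)
  r_null <- windowed_correlation(a, b)
  expect_lt(abs(mean(r_null)), 3 * 2 / sqrt(500))

  # zero-variance window flagged as r = 0
  az <- a
  az[1:500] <- 7
  rz <- windowed_correlation(az, b)
  expect_equal(rz[1], 0)
  expect_true(attr(rz, "flagged")[1])
  expect_error(windowed_correlation(a, b[-1]), "equal length")
})

test_that("block averaging drops the trailing partial block", {
  expect_equal(block_average(c(1, 2, 3, 4)), 2.5)
  expect_equal(block_average(rep(7, 12)), rep(7, 3))
  expect_length(block_average(rnorm(270)), 67)
  m <- matrix(1:16, 8, 2)
  expect_equal(dim(block_average(m)), c(2L, 2L))
  expect_equal(block_average(m)[, 1], c(2.5, 6.5))
})

test_that("top-k selection equals a brute-force ranking oracle", {
  set.seed(5)
  n_blk <- 30
  stim <- runif(n_blk)
  B <- matrix(rnorm(n_blk * 40), n_blk, 40)
  B[, 17] <- stim                       # plant an exact copy
  sel <- select_top_k(list(B), stim, k = 5)[[1]]
  expect_equal(sel$indices[1], 17)
  expect_equal(sel$r[[1]], 1)

  # oracle: full sort of all (pair, r) tuples
  r_all <- apply(B, 2, function(col) cor(col, stim))
  oracle <- order(-r_all, seq_along(r_all))[1:5]
  expect_equal(sel$indices, oracle)
  expect_equal(sel$mean_series, rowMeans(B[, oracle]))

  # degenerate selection: k = n_pairs averages everything
  all_sel <- select_top_k(list(B), stim, k = 40)[[1]]
  expect_equal(all_sel$mean_series, rowMeans(B))
  expect_error(select_top_k(list(B), stim, k = 41), "exceeds")
})

test_that("the pipeline produces exactly 32*31/2*9 = 4464 series", {
  set.seed(6)
  eeg <- eeg_recording(matrix(rnorm(20 * 500 * 32), ncol = 32))
  cd <- correlation_dynamics(decompose_bands(eeg))
  expect_equal(cd$n_series, 4464)
  expect_length(cd$bands, 9)
  expect_equal(dim(cd$bands[[1]]), c(20L, 496L))
})

test_that("synthetic EEG is deterministic and band injection is recovered", {
  dur_s <- 40
  n <- dur_s * 500
  env <- rep(rep(c(1, 0), each = 4 * 500), length.out = n)
  gain <- c(0, 0.9, 0.9, rep(0, 6))

  r1 <- generate_synthetic_eeg(env, gain, seed = 9)
  r2 <- generate_synthetic_eeg(env, gain, seed = 9)
  expect_identical(r1[[1]]$data, r2[[1]]$data)

  prof <- band_correlation_profile(r1[[1]], env, stimulus_rate = 500)
  expect_equal(prof$n_series, 4464)
  expect_true(all(abs(prof$profile$r) <= 1))
  top2 <- order(-prof$profile$r)[1:2]
  expect_setequal(top2, c(2, 3))

  # zero-variance stimulus errors out of pearson
  expect_error(band_correlation_profile(r1[[1]], rep(1, n),
                                        stimulus_rate = 500),
               "zero variance")
})
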
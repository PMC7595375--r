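test_that("zero-phase Butterworth low-pass has the designed response", {
  fs <- 1000
  t <- (0:19999) / fs
  mid <- 5000:15000
  # DC gain 1
  expect_equal(lowpass(rep(2.5, 3000), 2, 5, fs), rep(2.5, 3000),
               tolerance = 1e-9)
  # passband: 0.1 Hz attenuated < 1 %
  y <- lowpass(sin(2 * pi * 0.1 * t), 2, 5, fs)
  expect_gt(max(abs(y[mid])), 0.99)
  # stopband: 50 Hz (10x cutoff) attenuated > 99 %
  y50 <- lowpass(sin(2 * pi * 50 * t), 2, 5, fs)
  expect_lt(max(abs(y50[mid])), 0.01)
  # zero phase: slow sinusoid peak is not shifted
  x2 <- sin(2 * pi * 1 * t)
  y2 <- lowpass(x2, 2, 5, fs)
  expect_lt(abs(which.max(y2[1:1000]) - which.max(x2[1:1000])), 3)
  expect_error(lowpass(x2, 2, 600, fs), "Nyquist")
})

test_that("sway velocity matches closed forms", {
  fs <- 1000
  expect_equal(sway_velocity(rep(1, 10 * fs), fs, discard = 2, window = 5)$sway_velocity_s, 0)
  # linear ramp of slope v: telescoping sum gives exactly v
  v <- 0.7
  ramp <- v * (0:(10 * fs - 1)) / fs
  # exact up to the (n-1)/n edge of the telescoping sum
  expect_equal(sway_velocity(ramp, fs, discard = 2, window = 5)$sway_velocity_s,
               v, tolerance = 1e-3)
  # sinusoid total variation: 4 * A * f
  A <- 2; f <- 1.3
  x <- A * sin(2 * pi * f * (0:(45 * fs - 1)) / fs)
  s <- sway_velocity(x, fs, discard = 15, window = 30)$sway_velocity_s
  expect_equal(s, 4 * A * f, tolerance = 1e-3)
  # scale equivariance
  expect_equal(sway_velocity(3 * x, fs)$sway_velocity_s,
               3 * sway_velocity(x, fs)$sway_velocity_s)
  expect_error(sway_velocity(x[1:1000], fs), "need >=")
})

test_that("sway_velocity defaults implement the 15 s discard / 30 s window", {
  fs <- 200
  x <- rnorm(46 * fs)
  res <- sway_velocity(x, fs)
  expect_equal(res$window_start, 15)
  expect_equal(res$window_length, 30)
  # half-open window: manual recomputation over samples (15*fs, 45*fs]
  idx <- (15 * fs + 1):(45 * fs)
  expect_equal(res$sway_velocity_s, sum(abs(diff(x[idx]))) / 30)
})

test_that("cycle decomposition separates periodic and random parts", {
  fs <- 100
  cyc <- sin(2 * pi * (0:(2 * fs - 1)) / (2 * fs)) + 5   # mean-offset cycle
  trace <- rep(cyc, 13)
  dec <- cycle_decompose(trace, 2, 13, fs)
  expect_equal(dec$n_cycles_used, 12)
  expect_equal(dec$random_sd, rep(0, 2 * fs))
  expect_equal(dec$periodic, cyc - mean(cyc))            # per-cycle centering
  expect_equal(dec$random_power, 0)
  expect_error(cycle_decompose(trace[-1], 2, 13, fs), "length")
  expect_error(cycle_decompose(rep(cyc, 2), 2, 2, fs, discard_first = 1),
               "at least 2")
})

test_that("decomposition identity: residual SS equals (n-1) x SD^2 sum", {
  set.seed(3)
  fs <- 50
  for (rep_i in 1:5) {
    trace <- rnorm(13 * 2 * fs) + rep(sin(2 * pi * (0:(2 * fs - 1)) / fs), 13)
    dec <- cycle_decompose(trace, 2, 13, fs)
    cycles <- matrix(trace, ncol = 13)[, -1]
    cycles <- sweep(cycles, 2, colMeans(cycles))
    lhs <- sum((cycles - dec$periodic)^2)
    rhs <- (dec$n_cycles_used - 1) * sum(dec$random_sd^2)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("adding a fixed cycle moves only the periodic component", {
  set.seed(4)
  fs <- 50
  trace <- rnorm(13 * fs)
  extra <- cos(2 * pi * (0:(fs - 1)) / fs)
  d0 <- cycle_decompose(trace, 1, 13, fs)
  d1 <- cycle_decompose(trace + rep(extra, 13), 1, 13, fs)
  expect_equal(d1$random_sd, d0$random_sd, tolerance = 1e-10)
  expect_equal(d1$periodic, d0$periodic + (extra - mean(extra)),
               tolerance = 1e-10)
})

test_that("periodic power of pure noise is 1/12 of per-cycle power", {
  # Monte-Carlo oracle: for i.i.d. noise the across-cycle mean of 12
  # centred cycles has 1/12 the expected power of one centred cycle
  set.seed(5)
  n_rep <- 500; spc <- 40
  p_periodic <- p_cycle <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    trace <- rnorm(13 * spc)
    dec <- cycle_decompose(trace, cycle_duration = 1, n_cycles = 13,
                           sample_rate = spc)
    p_periodic[i] <- dec$periodic_power
    cyc1 <- trace[(spc + 1):(2 * spc)]
    p_cycle[i] <- sum((cyc1 - mean(cyc1))^2)
  }
  expect_equal(mean(p_periodic) / mean(p_cycle), 1 / 12, tolerance = 0.1)
})

test_that("sway power is the unnormalised sum of squares", {
  expect_equal(sway_power(rep(0, 7)), 0)
  expect_equal(sway_power(rep(3, 11)), 11 * 9)
  x <- rnorm(100)
  expect_equal(sway_power(x), length(x) * mean(x^2))
  expect_error(sway_power(numeric(0)), "empty")
})
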
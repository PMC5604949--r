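test_that("Brockway conversion matches hand arithmetic and rejects bad input", {
  expect_identical(brockway_power(0, 0), 0)
  expect_equal(brockway_power(300, 240), (16.58 * 300 + 4.51 * 240) / 60)
  expect_equal(brockway_power(60, 0), 16.58)
  expect_equal(brockway_power(c(0, 300), c(0, 240)), c(0, 100.94))
  expect_error(brockway_power(-1, 0), "non-negative")
})

test_that("dynamics inversion is the exact inverse of the forward response", {
  # constant response is a fixed point
  s <- breath_series(breath_times(10), power = 100)
  expect_equal(invert_dynamics(s, 42)$c, rep(100, 9))

  # constant drive, regular breaths
  fs <- forward_response(150, tau = 42, breath_times(60, 4), r0 = 0)
  expect_equal(invert_dynamics(fs, 42)$c, rep(150, 59), tolerance = 1e-12)

  # arbitrary per-breath drive, irregular schedule: machine-precision round trip
  withr::with_seed(7, {
    t <- cumsum(runif(40, 2, 6))
    cs <- runif(39, 80, 400)
    fs <- forward_response(cs, tau = 42, t, r0 = 120)
    expect_equal(invert_dynamics(fs, 42)$c, cs, tolerance = 1e-12)
  })

  # two-breath hand computation: c = r0 + (tau/h) (r1 - r0)
  s2 <- breath_series(c(0, 4), power = c(100, 110))
  expect_equal(invert_dynamics(s2, 42)$c, 100 + 42 / 4 * 10)

  expect_error(invert_dynamics(breath_series(1, power = 100), 42), "at least 2")
  expect_error(invert_dynamics(s2, tau = -1), "tau")
  expect_error(breath_series(c(0, 4), power = c(1, 2), h = c(4, 0)), "positive")
})

test_that("forward response has the right fixed point, first step and decay", {
  expect_equal(forward_response(100, 42, breath_times(5), r0 = 100)$power,
               rep(100, 5))
  fs <- forward_response(100, 42, cumsum(rep(4.2, 2)), r0 = 0)
  expect_equal(fs$power[2], 10) # (h / tau) * c
  # after 3 tau of constant drive the gap has shrunk by ~ e^-3
  t3 <- breath_times(ceiling(3 * 42 / 4), 4)
  fs3 <- forward_response(100, 42, t3, r0 = 0)
  ratio <- abs(fs3$power[length(t3)] - 100) / 100
  expect_equal(ratio, exp(-3), tolerance = 0.2)
  expect_error(forward_response(100, 42, c(1, 1, 2)), "increasing")
})

test_that("zero-order estimate averages inverted samples and is consistent", {
  fs <- forward_response(150, tau = 42, breath_times(50), r0 = 0)
  expect_equal(estimate_cost_zero_order(fs, 42), 150, tolerance = 1e-12)

  # alternating per-breath drive averages to the midpoint
  fs2 <- forward_response(rep(c(100, 200), 20), 42, breath_times(41), r0 = 150)
  expect_equal(estimate_cost_zero_order(fs2, 42), 150, tolerance = 1e-9)

  # i.i.d. noise on r: estimate converges to the true drive (1e4 breaths)
  withr::with_seed(11, {
    t <- breath_times(1e4)
    fs <- forward_response(150, 42, t, r0 = 150)
    noisy <- breath_series(t, power = fs$power + rnorm(1e4, 0, 5))
    est <- estimate_cost_zero_order(noisy, 42)
    # SD of the mean of inverted samples ~ 5 * sqrt((1-k)^2 + k^2) / sqrt(n)
    expect_equal(est, 150, tolerance = 3 * 5 * sqrt(2) * (42 / 4) / sqrt(1e4) / 150)
  })
})

test_that("zero-order estimate is invariant to time shifts and equivariant in units", {
  withr::with_seed(3, {
    t <- cumsum(runif(30, 3, 5))
    fs <- forward_response(runif(29, 100, 300), 42, t, r0 = 200)
    base <- estimate_cost_zero_order(fs, 42)
    shifted <- breath_series(fs$t + 1000, power = fs$power, h = fs$h)
    expect_equal(estimate_cost_zero_order(shifted, 42), base)
    scaled <- breath_series(fs$t, power = fs$power / 65.8, h = fs$h)
    expect_equal(estimate_cost_zero_order(scaled, 42), base / 65.8)
  })
})

test_that("linear cost fit recovers slope and intercept from noiseless data", {
  withr::with_seed(5, {
    t <- breath_times(80)
    x <- rep(c(1.6, 1.7, 1.9, 2.0), 20)
    cs <- 80 * x[-1] + 10
    fs <- forward_response(cs, 42, t, r0 = 80 * x[1] + 10)
    s <- breath_series(t, power = fs$power, x_meas = x, h = fs$h)
    m <- estimate_cost_linear(s, 42)
    expect_equal(m$lambda1, 80, tolerance = 1e-9)
    expect_equal(m$lambda0, 10, tolerance = 1e-9)

    # forward-model route agrees exactly on noiseless data
    mf <- estimate_cost_linear(s, 42, method = "forward")
    expect_equal(mf$lambda1, 80, tolerance = 1e-9)
    expect_equal(mf$lambda0, 10, tolerance = 1e-9)

    # degenerate slope
    fs0 <- forward_response(rep(120, 79), 42, t, r0 = 120)
    s0 <- breath_series(t, power = fs0$power, x_meas = x, h = fs0$h)
    expect_equal(estimate_cost_linear(s0, 42)$lambda1, 0, tolerance = 1e-9)

    # identical x on every breath is rank deficient
    sr <- breath_series(t, power = fs0$power, x_meas = 1.8, h = fs0$h)
    expect_error(estimate_cost_linear(sr, 42), "rank")
  })
})

test_that("two-level design reduces OLS slope to the group-mean difference", {
  withr::with_seed(9, {
    a <- 1.7; b <- 1.9
    t <- breath_times(60)
    x <- rep(c(a, b), 30)
    fs <- forward_response(100 * x[-1], 42, t, r0 = 100 * x[1])
    noisy <- fs$power + rnorm(60, 0, 3)
    s <- breath_series(t, power = noisy, x_meas = x, h = fs$h)
    m <- estimate_cost_linear(s, 42)
    inv <- invert_dynamics(s, 42)
    slope <- (mean(inv$c[inv$x_meas == b]) - mean(inv$c[inv$x_meas == a])) / (b - a)
    expect_equal(m$lambda1, slope, tolerance = 1e-9)
  })
})

test_that("inversion noise amplification matches the closed form", {
  # c_i = (1 - k) r_{i-1} + k r_i with k = tau/h: SD is s * sqrt((1-k)^2 + k^2)
  withr::with_seed(21, {
    s_noise <- 2
    k <- 42 / 4
    t <- breath_times(1e4)
    base <- forward_response(200, 42, t, r0 = 200)
    noisy <- breath_series(t, power = base$power + rnorm(1e4, 0, s_noise))
    inv <- invert_dynamics(noisy, 42)
    expect_equal(sd(inv$c), s_noise * sqrt((1 - k)^2 + k^2), tolerance = 0.05)
  })
})

test_that("step frequency is recovered from thigh-angle maxima", {
  subj <- noiseless_subject()
  fs <- 100
  # pure sinusoid: stride period = signal period
  a <- simulate_thigh_angle(subj, 1.8, duration = 10, fs = fs)
  expect_equal(estimate_step_frequency(a$angle, fs), 1.8, tolerance = 1.5 / fs)

  # noisy sinusoid at SNR ~ 10
  withr::with_seed(13, {
    amp_rms <- 25 / sqrt(2)
    an <- simulate_thigh_angle(subj, 1.8, 10, fs, noise_sd = amp_rms / sqrt(10))
    expect_equal(estimate_step_frequency(an$angle, fs), 1.8, tolerance = 0.02 * 1.8)
  })

  # only the most recent four steps count: chirp ending at 1.0 Hz strides
  t1 <- seq(0, 6, by = 1 / fs)                     # 0.7 Hz strides
  t2 <- seq(0, 4, by = 1 / fs)                     # 1.0 Hz strides
  chirp <- c(25 * sin(2 * pi * 0.7 * t1), 25 * sin(2 * pi * 1.0 * t2))
  expect_equal(estimate_step_frequency(chirp, fs), 2.0, tolerance = 0.02)

  expect_error(estimate_step_frequency(25 * sin(2 * pi * 0.5 * seq(0, 2, 0.01)), 100),
               "maxima")
})

test_that("periodic signals of period T give step frequency 2/T", {
  fs <- 200
  for (f_stride in c(0.6, 0.8, 1.1)) {
    t <- seq(0, 8, by = 1 / fs)
    # non-sinusoidal but strictly periodic waveform
    sig <- 20 * sin(2 * pi * f_stride * t) + 5 * sin(4 * pi * f_stride * t - 1)
    expect_equal(estimate_step_frequency(sig, fs), 2 * f_stride,
                 tolerance = 2 * f_stride^2 / fs * 2 + 1e-6)
  }
})
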
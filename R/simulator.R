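#' Synthetic treadmill subject
#'
#' Ground truth for simulation studies: a smooth single-minimum net
#' metabolic landscape over step frequency, a first-order respiratory lag,
#' irregular breath timing, additive breath noise, and imperfect metronome
#' tracking.
#'
#' Default magnitudes are chosen to be physiologically plausible for
#' treadmill walking: a net cost of 3 W/kg at the optimum rising by 1 W/kg
#' at a 25% frequency deviation (curvature 16 W/kg per squared relative
#' deviation), standing cost 1.5 W/kg, respiratory time constant 42 s, and
#' a breath rate of 0.3 breaths/s (within the physiologic 0.2-0.3 range).
#' The per-breath noise SD is calibrated so that a 40-breath zero-order net
#' cost estimate has an SD of about 0.2 W/kg.
#'
#' @param x_pref Preferred step frequency (Hz).
#' @param mass Body mass (kg).
#' @param x_opt Landscape argmin (Hz); defaults to `x_pref`.
#' @param c_min Net cost at the argmin (W/kg).
#' @param curvature Landscape curvature (W/kg per squared relative
#'   frequency deviation).
#' @param asym Optional cubic asymmetry term (W/kg per cubed relative
#'   deviation); 0 for a symmetric bowl.
#' @param standing_cost Standing metabolic cost (W/kg).
#' @param tau Respiratory time constant (s).
#' @param breath_rate_mean Mean breath rate (breaths/s), in `[0.2, 0.3]`.
#' @param breath_interval_sd SD of the inter-breath interval (s); intervals
#'   are truncated-normal with a 1 s floor.
#' @param breath_noise_sd SD of additive noise on each breath's observed
#'   power (W/kg; scaled by mass internally).
#' @param tracking_sd SD of the fractional step-frequency tracking error.
#' @param seed Per-subject seed (informational; runs set their own seeds).
#' @return A `subject_profile` list.
#' @export
subject_profile <- function(x_pref = 1.85, mass = 65.8, x_opt = x_pref,
                            c_min = 3.0, curvature = 16, asym = 0,
                            standing_cost = 1.5, tau = 42,
                            breath_rate_mean = 0.3, breath_interval_sd = 0.5,
                            breath_noise_sd = 0.31, tracking_sd = 0.02,
                            seed = NULL) {
  stopifnot(
    x_pref > 0, mass > 0, tau > 0,
    breath_rate_mean >= 0.2, breath_rate_mean <= 0.3,
    breath_interval_sd > 0, breath_noise_sd >= 0, tracking_sd >= 0,
    x_opt >= 0.75 * x_pref, x_opt <= 1.25 * x_pref
  )
  structure(
    list(x_pref = x_pref, mass = mass, x_opt = x_opt, c_min = c_min,
         curvature = curvature, asym = asym, standing_cost = standing_cost,
         tau = tau, breath_rate_mean = breath_rate_mean,
         breath_interval_sd = breath_interval_sd,
         breath_noise_sd = breath_noise_sd, tracking_sd = tracking_sd,
         seed = seed),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> x_pref = %.3f Hz, mass = %.1f kg, x_opt = %.3f Hz\n",
    x$x_pref, x$mass, x$x_opt
  ))
  invisible(x)
}

#' True net metabolic landscape of a synthetic subject
#'
#' `c_min + curvature * d^2 + asym * d^3` with `d = (x - x_opt) / x_pref`:
#' smooth with a single minimum at `x_opt`.
#'
#' @param subj A [subject_profile()].
#' @param x Step frequencies (Hz), positive.
#' @return Net mass-normalized cost (W/kg).
#' @export
true_cost <- function(subj, x) {
  stopifnot(all(x > 0))
  d <- (x - subj$x_opt) / subj$x_pref
  subj$c_min + subj$curvature * d^2 + subj$asym * d^3
}

#' Gross steady-state respiratory level at a frequency
#'
#' Walking: `(true_cost(x) + standing_cost) * mass`; standing (`x = NA`):
#' `standing_cost * mass`. Watts.
#'
#' @inheritParams true_cost
#' @return Steady-state gross power (W).
#' @export
subject_steady_state <- function(subj, x) {
  ifelse(is.na(x),
    subj$standing_cost * subj$mass,
    (true_cost(subj, ifelse(is.na(x), subj$x_pref, x)) + subj$standing_cost) *
      subj$mass
  )
}

# truncated-normal inter-breath intervals with a hard 1 s floor
rtrunc_interval <- function(n, mu, sd, lower = 1) {
  p0 <- stats::pnorm(lower, mu, sd)
  stats::qnorm(stats::runif(n, p0, 1), mu, sd)
}

#' Simulate one walking (or standing) bout
#'
#' Generates `n_breaths` breaths at the commanded frequency: irregular
#' breath intervals, per-breath measured frequency `x_cmd * (1 + e)` with
#' Gaussian tracking error, a latent respiratory response following the
#' first-order lag driven by the gross cost at the measured frequency, and
#' additive Gaussian observation noise on power. `x_cmd = NA` simulates
#' quiet standing.
#'
#' The respiratory state carries across consecutive bouts via the `state`
#' argument; `state = NULL` starts at the steady state for the subject's
#' preferred frequency (i.e. after a warm-up walk). After a rest of five
#' minutes or more the state should be reset by passing `state = NULL`.
#'
#' @param subj A [subject_profile()].
#' @param x_cmd Commanded step frequency (Hz), or `NA` for standing.
#' @param n_breaths Number of breaths (`>= 2`).
#' @param state Carry-over state from a previous bout (`$r`, W), or `NULL`.
#' @return A list: `series` (a [breath_series()] with `x_meas`), `state`
#'   (to pass to the next bout) and `duration_s`.
#' @export
simulate_bout <- function(subj, x_cmd, n_breaths, state = NULL) {
  stopifnot(n_breaths >= 2)
  h <- rtrunc_interval(n_breaths, 1 / subj$breath_rate_mean,
                       subj$breath_interval_sd)
  t <- cumsum(h)
  if (is.na(x_cmd)) {
    x_meas <- rep(NA_real_, n_breaths)
    drive <- rep(subj$standing_cost * subj$mass, n_breaths)
  } else {
    x_meas <- x_cmd * (1 + stats::rnorm(n_breaths, 0, subj$tracking_sd))
    drive <- (true_cost(subj, x_meas) + subj$standing_cost) * subj$mass
  }
  r0 <- if (is.null(state)) subject_steady_state(subj, subj$x_pref) else state$r
  r <- numeric(n_breaths)
  prev <- r0
  for (i in seq_len(n_breaths)) {
    w <- h[i] / subj$tau
    prev <- (1 - w) * prev + w * drive[i]
    r[i] <- prev
  }
  power <- r + stats::rnorm(n_breaths, 0, subj$breath_noise_sd * subj$mass)
  series <- breath_series(t = t, power = power, x_meas = x_meas, h = h,
                          mass = subj$mass)
  list(series = series, state = list(r = prev), duration_s = sum(h))
}

#' Simulate a thigh flexion-angle signal
#'
#' A sinusoid at the stride frequency (`x / 2`, assuming step symmetry)
#' with 25 degree amplitude, slow phase wander and optional additive
#' Gaussian noise: the fixture for the step-frequency detector.
#'
#' @param subj A [subject_profile()] (unused fields tolerated; kept for a
#'   uniform interface).
#' @param x Step frequency (Hz).
#' @param duration Signal length (s); must cover at least 3 strides.
#' @param fs Sampling rate (Hz).
#' @param noise_sd Additive noise SD (deg).
#' @param phase_noise_sd Per-sample phase random-walk SD (rad).
#' @return A data frame with columns `t` and `angle` (deg) and attribute
#'   `fs`.
#' @export
simulate_thigh_angle <- function(subj, x, duration, fs = 100, noise_sd = 0,
                                 phase_noise_sd = 0) {
  stride_f <- x / 2
  if (duration * stride_f < 3) stop("duration must cover at least 3 strides")
  t <- seq(0, duration, by = 1 / fs)
  phase <- cumsum(stats::rnorm(length(t), 0, phase_noise_sd))
  angle <- 25 * sin(2 * pi * stride_f * t + phase) +
    stats::rnorm(length(t), 0, noise_sd)
  out <- data.frame(t = t, angle = angle)
  attr(out, "fs") <- fs
  out
}

#' Generate a cohort of synthetic subjects
#'
#' Preferred frequencies are uniform on 1.7-2.0 Hz; masses are normal with
#' mean 65.8 kg and SD 9.7 kg (truncated positive), matching a typical
#' young healthy cohort; the landscape argmin coincides with the preferred
#' frequency (grid-fit baselines cluster near preferred). Per-subject seeds
#' are derived deterministically from `seed`.
#'
#' @param n Number of subjects.
#' @param seed Cohort seed.
#' @param ... Overrides passed to every [subject_profile()].
#' @return A list of `subject_profile`s.
#' @export
make_cohort <- function(n, seed, ...) {
  stopifnot(n >= 1)
  set.seed(seed)
  x_pref <- stats::runif(n, 1.7, 2.0)
  mass <- stats::qnorm(stats::runif(n, stats::pnorm(0, 65.8, 9.7), 1), 65.8, 9.7)
  seeds <- sample.int(2^31 - 2, n)
  lapply(seq_len(n), function(i) {
    subject_profile(x_pref = x_pref[i], mass = mass[i], seed = seeds[i], ...)
  })
}

#' Simulator-backed evaluator for Bayesian optimization
#'
#' Returns a closure suitable for [run_bayes_opt()]: each call simulates a
#' bout at the commanded frequency (respiratory state carried across
#' calls), inverts the dynamics and returns the zero-order gross cost
#' estimate normalized by body mass (W/kg).
#'
#' @param subj A [subject_profile()].
#' @param warm_start Start the respiratory state at the preferred-frequency
#'   steady state (post warm-up); `FALSE` starts cold at standing level.
#' @return A function `(x_cmd, n_breaths)` returning `cost`, `x_meas` and
#'   `duration_s`.
#' @export
bo_evaluator <- function(subj, warm_start = TRUE) {
  state <- if (warm_start) NULL else list(r = subj$standing_cost * subj$mass)
  function(x_cmd, n_breaths) {
    b <- simulate_bout(subj, x_cmd, n_breaths, state = state)
    state <<- b$state
    list(
      cost = estimate_cost_zero_order(b$series, subj$tau) / subj$mass,
      cost_units = "W_per_kg",
      x_meas = mean(b$series$x_meas),
      duration_s = b$duration_s
    )
  }
}

#' Simulator-backed evaluator for gradient descent
#'
#' Returns a closure suitable for [run_gradient_descent()]: each call
#' simulates 30-breath (by default) bouts at `x_cmd - delta` then
#' `x_cmd + delta` back to back, fits the linear instantaneous-cost model
#' across the combined 60 breaths, and reports the slope in the requested
#' cost units. Gross (non-normalized) cost is used, matching an online
#' pipeline working in raw calorimetry units.
#'
#' @inheritParams bo_evaluator
#' @param cost_units `"ml_o2_per_min"` (gross O2-equivalent rate; 20.1 J
#'   per mL O2) or `"W"`.
#' @return A function `(x_cmd, delta, breaths_per_side)` returning `model`
#'   (a [cost_model()]), `cost`, `x_meas` and `duration_s`.
#' @export
gd_evaluator <- function(subj, cost_units = "ml_o2_per_min",
                         warm_start = TRUE) {
  state <- if (warm_start) NULL else list(r = subj$standing_cost * subj$mass)
  w_per_ml_min <- brockway_coefficients$j_per_ml_o2_gross / 60
  scale <- if (cost_units == "ml_o2_per_min") 1 / w_per_ml_min else 1
  function(x_cmd, delta, breaths_per_side) {
    lo <- simulate_bout(subj, x_cmd - delta, breaths_per_side, state = state)
    hi <- simulate_bout(subj, x_cmd + delta, breaths_per_side, state = lo$state)
    state <<- hi$state
    series <- bind_breaths(lo$series, hi$series)
    m <- estimate_cost_linear(series, subj$tau)
    list(
      model = cost_model(m$lambda1 * scale, m$lambda0 * scale, tau = subj$tau,
                         units = cost_units),
      cost = predict(m, x_cmd) * scale,
      x_meas = mean(series$x_meas),
      duration_s = lo$duration_s + hi$duration_s
    )
  }
}
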
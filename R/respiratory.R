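#' Instantaneous-cost model coefficients
#'
#' The instantaneous energetic cost is modelled as a linear function of the
#' measured step frequency, `c(x) = lambda1 * x + lambda0`, driving a
#' first-order respiratory response with time constant `tau`. A zero-order
#' model has `lambda1 = 0` exactly.
#'
#' @param lambda1 Cost slope (cost units per Hz).
#' @param lambda0 Cost intercept (cost units).
#' @param tau Respiratory time constant (s); must be positive.
#' @param units Label for the cost units (informational).
#' @return A `cost_model` list.
#' @export
cost_model <- function(lambda1, lambda0, tau = 42, units = "W") {
  stopifnot(tau > 0)
  structure(
    list(lambda1 = lambda1, lambda0 = lambda0, tau = tau, units = units),
    class = "cost_model"
  )
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf(
    "<cost_model> c(x) = %.4g * x + %.4g [%s], tau = %.3g s\n",
    x$lambda1, x$lambda0, x$units, x$tau
  ))
  invisible(x)
}

#' Predict instantaneous cost from a cost model
#'
#' @param object A [cost_model()].
#' @param newdata Step frequencies (Hz).
#' @param ... Unused.
#' @return Instantaneous cost at each frequency.
#' @export
predict.cost_model <- function(object, newdata, ...) {
  object$lambda1 * newdata + object$lambda0
}

#' Invert first-order respiratory dynamics
#'
#' The respiratory response follows the one-step recursion
#' `r_i = (1 - h_i/tau) * r_{i-1} + (h_i/tau) * c_i`, where `h_i` is the time
#' since the previous breath. Solving for the driving cost gives
#' `c_i = r_{i-1} + (tau / h_i) * (r_i - r_{i-1})`. The first breath seeds the
#' dynamic state, so the output has one sample fewer than the input.
#'
#' This deconvolution removes the slow respiratory lag but amplifies
#' breath-to-breath noise by roughly `tau / h`, which is why downstream
#' estimators average many inverted samples.
#'
#' @param series A [breath_series()] with at least two breaths.
#' @param tau Respiratory time constant (s), default 42.
#' @return A data frame with one row per breath after the first: `t`, `c`
#'   (instantaneous cost, same units as `power`) and `x_meas`.
#' @export
invert_dynamics <- function(series, tau = 42) {
  stopifnot(inherits(series, "breath_series"))
  if (tau <= 0) stop("tau must be positive")
  n <- nrow(series)
  if (n < 2) stop("need at least 2 breaths to invert the dynamics")
  r <- series$power
  h <- series$h[-1]
  if (any(h <= 0)) stop("inter-breath intervals must be positive")
  ci <- r[-n] + (tau / h) * (r[-1] - r[-n])
  data.frame(t = series$t[-1], c = ci, x_meas = series$x_meas[-1])
}

#' Zero-order instantaneous-cost estimate
#'
#' Fits a constant to the inverted cost samples by ordinary least squares,
#' i.e. returns their mean. This is the per-evaluation cost estimate used by
#' the Bayesian optimizer (40 breaths per evaluation by default protocol).
#'
#' @inheritParams invert_dynamics
#' @param trim_sd Optional outlier trimming: drop inverted samples more than
#'   this many SDs from the mean before averaging. `NULL` (default) disables
#'   trimming.
#' @return Scalar cost estimate, same units as `series$power`.
#' @export
estimate_cost_zero_order <- function(series, tau = 42, trim_sd = NULL) {
  inv <- invert_dynamics(series, tau)
  ci <- inv$c
  if (!is.null(trim_sd)) {
    keep <- abs(ci - mean(ci)) <= trim_sd * stats::sd(ci)
    if (any(keep)) ci <- ci[keep]
  }
  mean(ci)
}

#' Linear instantaneous-cost estimate
#'
#' Regresses the inverted cost samples on the measured step frequency to
#' recover the slope and intercept of the linear cost model. The slope is the
#' quantity the gradient-descent comparator uses as its cost gradient: under
#' a linear model the symmetric finite difference across the two perturbed
#' frequencies equals `lambda1` exactly.
#'
#' Two fitting routes are provided. `method = "invert"` (the default) is OLS
#' of the inverted samples on frequency. `method = "forward"` instead fits
#' `(lambda1, lambda0)` by least squares on the raw response: it minimizes
#' `sum((r_i - rhat_i(lambda))^2)` where `rhat` is the forward-simulated
#' response driven by `lambda1 * x_i + lambda0` from the observed first
#' breath. Both agree exactly on noiseless data.
#'
#' @inheritParams invert_dynamics
#' @param method `"invert"` or `"forward"`; see Details.
#' @param trim_sd As in [estimate_cost_zero_order()] (invert method only).
#' @return A [cost_model()].
#' @export
estimate_cost_linear <- function(series, tau = 42, method = c("invert", "forward"),
                                 trim_sd = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(series, "breath_series"))
  x_all <- series$x_meas
  if (anyNA(x_all)) stop("x_meas must be present on every breath")
  if (length(unique(x_all)) < 2) {
    stop("all x_meas identical: the linear model is rank-deficient")
  }
  if (method == "invert") {
    inv <- invert_dynamics(series, tau)
    d <- inv
    if (!is.null(trim_sd)) {
      keep <- abs(d$c - mean(d$c)) <= trim_sd * stats::sd(d$c)
      if (any(keep)) d <- d[keep, ]
    }
    fit <- stats::lm(c ~ x_meas, data = d)
    co <- stats::coef(fit)
    cost_model(lambda1 = unname(co["x_meas"]), lambda0 = unname(co["(Intercept)"]),
               tau = tau)
  } else {
    # forward route: r is linear in (lambda1, lambda0) so the least-squares
    # problem is itself linear -- build the design by propagating the recursion
    n <- nrow(series)
    if (n < 2) stop("need at least 2 breaths")
    h <- series$h[-1]
    a <- 1 - h / tau
    b <- h / tau
    # r_i = prod(a) * r_1 + sum over j of weights * c_j; accumulate columns
    z1 <- z0 <- numeric(n - 1)  # coefficients on lambda1, lambda0
    base <- numeric(n - 1)      # contribution of the seed r_1
    c1 <- c0 <- 0
    seed <- series$power[1]
    for (i in seq_len(n - 1)) {
      c1 <- a[i] * c1 + b[i] * x_all[i + 1]
      c0 <- a[i] * c0 + b[i]
      seed_i <- if (i == 1) a[1] * seed else a[i] * base[i - 1]
      z1[i] <- c1; z0[i] <- c0; base[i] <- seed_i
    }
    y <- series$power[-1] - base
    fit <- stats::lm(y ~ 0 + z1 + z0)
    co <- stats::coef(fit)
    cost_model(lambda1 = unname(co["z1"]), lambda0 = unname(co["z0"]), tau = tau)
  }
}

#' Forward-simulate the respiratory response
#'
#' Generates the breath-level response `r_i` from a driving instantaneous
#' cost via the first-order recursion (see [invert_dynamics()]). Used by the
#' synthetic subject and as the round-trip oracle for the inversion.
#'
#' @param cost_fn Either a single cost value, a vector of per-breath costs
#'   (one per breath after the first), or a function of time `t` returning
#'   the cost driving the response at that breath.
#' @param tau Respiratory time constant (s).
#' @param breath_times Strictly increasing breath timestamps (s). The first
#'   breath carries the initial state `r0`.
#' @param r0 Initial response level (W).
#' @return A [breath_series()] whose `power` is the simulated response.
#' @export
forward_response <- function(cost_fn, tau = 42, breath_times, r0 = 0) {
  stopifnot(tau > 0)
  t <- as.numeric(breath_times)
  n <- length(t)
  if (n < 1) stop("need at least one breath time")
  if (n > 1 && any(diff(t) <= 0)) stop("breath times must be strictly increasing")
  h <- c(if (n > 1) diff(t)[1] else 1, diff(t))
  cvals <- if (is.function(cost_fn)) {
    cost_fn(t[-1])
  } else {
    rep_len(as.numeric(cost_fn), max(n - 1, 1))
  }
  r <- numeric(n)
  r[1] <- r0
  for (i in seq_len(n - 1)) {
    w <- h[i + 1] / tau
    r[i + 1] <- (1 - w) * r[i] + w * cvals[i]
  }
  breath_series(t = t, power = r, h = h)
}

#' Estimate step frequency from a thigh-angle signal
#'
#' Stride time is the interval between consecutive maxima of the thigh
#' flexion angle; stride frequency is its reciprocal and step frequency is
#' twice that, assuming left/right symmetry. The returned value averages the
#' step frequency over the most recent four steps (two strides), mirroring
#' online step-frequency feedback.
#'
#' The raw angle is first smoothed with a short moving average (default
#' 0.1 s) to suppress sensor noise; candidate maxima closer than a
#' refractory period are then rejected, as are peaks whose topographic
#' prominence is below a fraction of the signal range, to avoid
#' double-counting on noisy signals.
#'
#' @param angle Thigh flexion angle samples (deg).
#' @param fs Sampling rate (Hz).
#' @param refractory_s Minimum spacing between accepted maxima (s).
#' @param min_prominence Minimum peak prominence as a fraction of the signal
#'   range.
#' @param smooth_s Moving-average window (s); 0 disables smoothing.
#' @return Step frequency (Hz).
#' @export
estimate_step_frequency <- function(angle, fs, refractory_s = 0.3,
                                    min_prominence = 0.1, smooth_s = 0.1) {
  angle <- as.numeric(angle)
  if (length(angle) < 5) stop("signal too short for peak detection")
  w <- max(1L, as.integer(round(smooth_s * fs)))
  if (w %% 2 == 0) w <- w + 1L  # symmetric window: no peak-position shift
  if (w > 1) {
    sm <- stats::filter(angle, rep(1 / w, w), sides = 2)
    keep <- !is.na(sm)
    angle <- as.numeric(sm[keep])
  }
  rng <- diff(range(angle))
  if (rng <= 0) stop("flat signal: no detectable maxima")
  pk <- pracma::findpeaks(angle,
    minpeakdistance = max(1L, as.integer(round(refractory_s * fs)))
  )
  if (is.null(pk)) stop("no maxima detected")
  prom <- peak_prominence(angle, pk[, 2])
  pk <- pk[prom >= min_prominence * rng, , drop = FALSE]
  if (nrow(pk) < 3) stop("need at least 3 detectable flexion maxima")
  idx <- sort(pk[, 2])
  stride_t <- diff(idx) / fs
  step_f <- 2 / stride_t            # one value per stride interval
  k <- min(2, length(step_f))       # last two strides = last four steps
  mean(utils::tail(step_f, k))
}

# topographic prominence of local maxima: height above the deeper of the two
# key saddles toward higher ground (or the global min when none is higher)
peak_prominence <- function(x, idx) {
  vapply(idx, function(p) {
    hp <- x[p]
    left <- x[seq_len(p - 1)]
    right <- if (p < length(x)) x[(p + 1):length(x)] else numeric(0)
    lk <- {
      higher <- which(left > hp)
      if (length(higher) == 0) min(c(left, hp)) else min(left[(max(higher)):length(left)])
    }
    rk <- {
      higher <- which(right > hp)
      if (length(higher) == 0) min(c(right, hp)) else min(right[seq_len(min(higher))])
    }
    hp - max(lk, rk)
  }, numeric(1))
}
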
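# Shared fixtures built in code.

# regular breath schedule: n breaths h seconds apart, starting at t = h
breath_times <- function(n, h = 4) cumsum(rep(h, n))

# noiseless, perfectly tracking subject
noiseless_subject <- function(x_pref = 1.8, ...) {
  subject_profile(x_pref = x_pref, breath_noise_sd = 0, tracking_sd = 0, ...)
}

# hand-built trajectory for convergence-rule tests
fake_trajectory <- function(x_cmd, cost = NULL, method = "gd",
                            phase = NULL, duration_s = 60, x_pref = 1.8) {
  n <- length(x_cmd)
  if (is.null(cost)) cost <- rep(5, n)
  if (is.null(phase)) {
    phase <- if (method == "bo") c(rep("init", 3), rep("ei", n - 3)) else rep("gd", n)
  }
  tr <- data.frame(
    iter = seq_len(n), phase = phase, x_cmd = x_cmd, x_meas = x_cmd,
    cost = cost, cost_units = "W_per_kg",
    duration_s = rep_len(duration_s, n),
    hyp_sigma2 = NA_real_, hyp_l = NA_real_, hyp_noise2 = NA_real_
  )
  attr(tr, "method") <- method
  attr(tr, "x_pref") <- x_pref
  attr(tr, "status") <- "complete"
  class(tr) <- c("hil_trajectory", "data.frame")
  tr
}

# constant-mean landscape with a closed-form posterior, for energy arithmetic
flat_landscape <- function(level_wkg = 3, mass = 65.8, standing_wkg = 1.5,
                           freqs = seq(1.35, 2.25, length.out = 9)) {
  structure(
    list(
      freqs = freqs, costs = rep(level_wkg, length(freqs)),
      posterior = list(mean_fn = function(x) rep(level_wkg, length(x))),
      hp = NULL, argmin = freqs[1], standing_wkg = standing_wkg, mass = mass
    ),
    class = "hil_landscape"
  )
}

# dense explicit-inverse GP oracle (independent of the package's solver path)
gp_oracle <- function(X, y, hp, xs, center = FALSE) {
  mu0 <- if (center) mean(y) else 0
  n <- length(X)
  K <- hp$sigma2 * exp(-outer(X, X, "-")^2 / (2 * hp$length_scale^2)) +
    diag(hp$noise2 + 1e-10 * hp$sigma2, n)
  Ki <- solve(K)
  Ks <- hp$sigma2 * exp(-outer(xs, X, "-")^2 / (2 * hp$length_scale^2))
  list(
    mean = drop(Ks %*% Ki %*% (y - mu0)) + mu0,
    var = hp$sigma2 - diag(Ks %*% Ki %*% t(Ks)),
    lml = drop(-0.5 * t(y - mu0) %*% Ki %*% (y - mu0)) -
      0.5 * as.numeric(determinant(K)$modulus) - 0.5 * n * log(2 * pi)
  )
}
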
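#' Expected improvement under a Gaussian predictive distribution
#'
#' For a minimization problem with incumbent `mu_best`, the improvement of a
#' candidate with predictive distribution `N(mean, sd^2)` is
#' `max(mu_best - c, 0)`, whose expectation has the closed form
#' `EI = sd * (u * pnorm(u) + dnorm(u))` with `u = (mu_best - mean) / sd`.
#' When `sd = 0` the expected improvement is defined to be 0. The predictive
#' sd is the function-value (latent-cost) sd, without observation noise.
#'
#' @param mean Predictive mean(s).
#' @param sd Predictive standard deviation(s), `>= 0`.
#' @param mu_best Incumbent: minimum posterior mean over evaluated points.
#' @return Expected improvement, non-negative, in cost units.
#' @export
expected_improvement <- function(mean, sd, mu_best) {
  if (any(sd < 0)) stop("sd must be non-negative")
  out <- numeric(length(mean))
  pos <- sd > 0
  u <- (mu_best - mean[pos]) / sd[pos]
  out[pos] <- sd[pos] * (u * stats::pnorm(u) + stats::dnorm(u))
  pmax(out, 0)
}

#' Incumbent: minimum posterior mean over evaluated points
#'
#' The incumbent used by expected improvement is the minimum of the
#' *posterior mean* at the observed inputs, not the minimum raw observation:
#' with noisy cost estimates the raw minimum is biased low.
#'
#' @param post A [gp_posterior()].
#' @return A list with `value` (cost) and `x` (the evaluated frequency
#'   attaining it; lowest frequency on exact ties).
#' @export
mu_best <- function(post) {
  m <- post$mean_fn(post$X)
  i <- which(m == min(m))
  i <- i[which.min(post$X[i])]
  list(value = m[i], x = post$X[i])
}

#' Propose the next step frequency by maximizing expected improvement
#'
#' Maximizes EI over the closed search domain using multi-restart local
#' search: `restarts` random starts plus both domain endpoints and the best
#' point of a dense screening grid, each refined by bound-constrained
#' optimization. If EI is numerically zero everywhere (degenerate
#' posterior), the maximum-variance point is returned instead. Exact ties
#' break toward the lowest frequency.
#'
#' @param post A [gp_posterior()].
#' @param domain Numeric c(lower, upper) search interval (Hz).
#' @param restarts Number of random restarts (default 10).
#' @param grid_n Size of the screening grid.
#' @return The proposed frequency (Hz) with attribute `"ei"`.
#' @export
propose_next <- function(post, domain, restarts = 10, grid_n = 1001) {
  stopifnot(length(domain) == 2, domain[1] < domain[2])
  inc <- mu_best(post)$value
  ei_fn <- function(x) {
    expected_improvement(post$mean_fn(x), sqrt(post$var_fn(x)), inc)
  }
  grid <- seq(domain[1], domain[2], length.out = grid_n)
  ei_grid <- ei_fn(grid)
  if (max(ei_grid) <= .Machine$double.eps) {
    v <- post$var_fn(grid)
    i <- which(v == max(v))
    x <- grid[i[1]]
    attr(x, "ei") <- 0
    attr(x, "fallback") <- "max_variance"
    return(x)
  }
  starts <- c(
    stats::runif(restarts, domain[1], domain[2]),
    domain,
    grid[which.max(ei_grid)]
  )
  best_x <- grid[which.max(ei_grid)]
  best_ei <- max(ei_grid)
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, function(x) -ei_fn(x), method = "L-BFGS-B",
                   lower = domain[1], upper = domain[2]),
      error = function(e) NULL
    )
    if (is.null(res)) next
    val <- -res$value
    if (val > best_ei + 1e-15 ||
        (abs(val - best_ei) <= 1e-15 && res$par < best_x)) {
      best_ei <- val
      best_x <- res$par
    }
  }
  x <- unname(best_x)
  attr(x, "ei") <- best_ei
  x
}

#' Random three-point initial design
#'
#' One frequency is drawn uniformly from each of the three sub-intervals
#' 75-91.7%, 91.7-108.3% and 108.3-125% of the preferred step frequency,
#' and the three are presented in random order.
#'
#' @param x_pref Preferred step frequency (Hz).
#' @return Three frequencies (Hz).
#' @export
initial_design <- function(x_pref) {
  stopifnot(x_pref > 0)
  edges <- c(0.75, 11 / 12, 13 / 12, 1.25) * x_pref
  pts <- stats::runif(3, edges[1:3], edges[2:4])
  sample(pts)
}

#' Bayesian-optimization configuration
#'
#' Defaults follow the step-frequency protocol: a 3-point random initial
#' design, 17 EI-driven iterations (20 evaluations in total), 40 breaths per
#' cost estimate, a search domain of 75-125% of preferred frequency, and 10
#' restarts for both the acquisition and the hyperparameter fits.
#'
#' @param x_pref Preferred step frequency (Hz).
#' @param n_init Initial design size.
#' @param n_iterations Number of EI-driven evaluations.
#' @param breaths_per_eval Breaths per cost estimate.
#' @param domain Search interval (Hz); default `c(0.75, 1.25) * x_pref`.
#' @param ei_restarts,hp_restarts Restart counts for acquisition and
#'   hyperparameter optimization.
#' @param seed Optional integer seed applied at the start of a run.
#' @return A `bo_config` list.
#' @export
bo_config <- function(x_pref, n_init = 3, n_iterations = 17,
                      breaths_per_eval = 40, domain = c(0.75, 1.25) * x_pref,
                      ei_restarts = 10, hp_restarts = 10, seed = NULL) {
  stopifnot(n_init >= 1, breaths_per_eval >= 2, domain[1] < domain[2])
  structure(
    list(x_pref = x_pref, n_init = n_init, n_iterations = n_iterations,
         breaths_per_eval = breaths_per_eval, domain = domain,
         ei_restarts = ei_restarts, hp_restarts = hp_restarts, seed = seed),
    class = "bo_config"
  )
}

#' Gradient-descent configuration
#'
#' Defaults follow the published schedule: `alpha_n = A0 * alpha0 /
#' (A0 + n * gamma)` with `A0 = 3`, `alpha0 = 4e-4` Hz per (mL/min) and
#' `gamma = 1`; +/-5% of preferred frequency perturbations with 30 breaths
#' per side; 15 iterations; initialization at 20% above or below preferred
#' frequency with random sign. `alpha0`'s units imply costs expressed as an
#' O2-rate equivalent (mL/min), the default `cost_units`.
#'
#' @param x_pref Preferred step frequency (Hz).
#' @param A0,alpha0,gamma Step-size schedule constants.
#' @param delta_frac Perturbation size as a fraction of `x_pref`.
#' @param n_iterations Number of gradient iterations.
#' @param breaths_per_side Breaths collected at each perturbed frequency.
#' @param init_offset Initialization offset fraction (sign randomized).
#' @param domain Clipping interval (Hz).
#' @param cost_units `"ml_o2_per_min"` (default, matches `alpha0`) or `"W"`.
#' @param seed Optional integer seed applied at the start of a run.
#' @return A `gd_config` list.
#' @export
gd_config <- function(x_pref, A0 = 3, alpha0 = 4e-4, gamma = 1,
                      delta_frac = 0.05, n_iterations = 15,
                      breaths_per_side = 30, init_offset = 0.20,
                      domain = c(0.75, 1.25) * x_pref,
                      cost_units = c("ml_o2_per_min", "W"), seed = NULL) {
  stopifnot(alpha0 > 0, delta_frac > 0, n_iterations >= 1)
  structure(
    list(x_pref = x_pref, A0 = A0, alpha0 = alpha0, gamma = gamma,
         delta_frac = delta_frac, n_iterations = n_iterations,
         breaths_per_side = breaths_per_side, init_offset = init_offset,
         domain = domain, cost_units = match.arg(cost_units), seed = seed),
    class = "gd_config"
  )
}

#' Gradient-descent step size schedule
#'
#' `alpha_n = A0 * alpha0 / (A0 + n * gamma)` for iteration `n >= 0`;
#' monotone decreasing toward zero.
#'
#' @param n Iteration index (0-based); vectorized.
#' @param cfg A [gd_config()] (only the schedule constants are used).
#' @return Step size(s) `alpha_n`.
#' @export
gd_step_size <- function(n, cfg) {
  stopifnot(all(n >= 0))
  cfg$A0 * cfg$alpha0 / (cfg$A0 + n * cfg$gamma)
}

new_trajectory <- function(rows, method, x_pref, seed = NULL,
                           status = "complete") {
  tr <- do.call(rbind, rows)
  rownames(tr) <- NULL
  attr(tr, "method") <- method
  attr(tr, "x_pref") <- x_pref
  attr(tr, "seed") <- seed
  attr(tr, "status") <- status
  class(tr) <- c("hil_trajectory", "data.frame")
  tr
}

#' @export
print.hil_trajectory <- function(x, ...) {
  cat(sprintf(
    "<hil_trajectory> method = %s, %d evaluations, x_pref = %.3g Hz (%s)\n",
    attr(x, "method"), nrow(x), attr(x, "x_pref"), attr(x, "status")
  ))
  print(as.data.frame(x))
  invisible(x)
}

traj_row <- function(iter, phase, x_cmd, x_meas, cost, cost_units,
                     duration_s, hp = NULL) {
  data.frame(
    iter = iter, phase = phase, x_cmd = x_cmd,
    x_meas = if (is.null(x_meas)) NA_real_ else x_meas,
    cost = cost, cost_units = cost_units,
    duration_s = if (is.null(duration_s)) NA_real_ else duration_s,
    hyp_sigma2 = if (is.null(hp)) NA_real_ else hp$sigma2,
    hyp_l = if (is.null(hp)) NA_real_ else hp$length_scale,
    hyp_noise2 = if (is.null(hp)) NA_real_ else hp$noise2
  )
}

#' Run expected-improvement Bayesian optimization
#'
#' Executes the random initial design, then `n_iterations` EI-driven
#' evaluations. Hyperparameters are refit by marginal likelihood after every
#' evaluation once at least two observations exist (including during the
#' completion of the initial design), and each proposal maximizes EI over
#' the configured domain.
#'
#' The `evaluator` abstracts the subject: called as `evaluator(x_cmd,
#' n_breaths)` it must return a list with elements `cost` (scalar estimate),
#' and optionally `x_meas` (mean measured frequency, Hz) and `duration_s`.
#' An evaluator error truncates the trajectory with status `"truncated"`.
#'
#' @param evaluator Cost-evaluation closure; see Details.
#' @param config A [bo_config()].
#' @return A `hil_trajectory` data frame, one row per evaluation, with
#'   columns `iter`, `phase` (`"init"`/`"ei"`), `x_cmd`, `x_meas`, `cost`,
#'   `cost_units`, `duration_s` and the fitted hyperparameters.
#' @export
run_bayes_opt <- function(evaluator, config) {
  stopifnot(inherits(config, "bo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  xs <- ys <- numeric(0)
  rows <- list()
  status <- "complete"
  hp <- NULL

  eval_one <- function(x_cmd) {
    r <- evaluator(x_cmd, config$breaths_per_eval)
    if (is.numeric(r) && length(r) == 1) r <- list(cost = r)
    r
  }
  refit <- function() {
    if (length(xs) < 2) return(NULL)
    gp_fit_hyperparameters(xs, ys, n_restarts = config$hp_restarts,
                           domain = config$domain)
  }
  step <- function(iter, phase, x_cmd) {
    r <- tryCatch(eval_one(x_cmd), error = function(e) e)
    if (inherits(r, "error")) return(FALSE)
    xs <<- c(xs, x_cmd)
    ys <<- c(ys, r$cost)
    hp <<- refit()   # refit after every evaluation, first once n >= 2
    rows[[length(rows) + 1]] <<- traj_row(
      iter, phase, x_cmd, r$x_meas, r$cost,
      if (is.null(r$cost_units)) "W_per_kg" else r$cost_units,
      r$duration_s, hp
    )
    TRUE
  }

  design <- initial_design(config$x_pref)
  design <- pmin(pmax(design, config$domain[1]), config$domain[2])
  iter <- 0L
  for (x_cmd in design) {
    iter <- iter + 1L
    if (!step(iter, "init", x_cmd)) {
      return(new_trajectory(rows, "bo", config$x_pref, config$seed, "truncated"))
    }
  }
  for (k in seq_len(config$n_iterations)) {
    iter <- iter + 1L
    post <- gp_posterior(xs, ys, hp)
    x_cmd <- as.numeric(propose_next(post, config$domain,
                                     restarts = config$ei_restarts))
    if (!step(iter, "ei", x_cmd)) {
      status <- "truncated"
      break
    }
  }
  new_trajectory(rows, "bo", config$x_pref, config$seed, status)
}

#' Run finite-difference gradient descent on instantaneous cost
#'
#' Starts from 20% above or below the preferred frequency (random sign) and
#' iterates `x_{n+1} = clip(x_n - alpha_n * J_n)`, where `J_n` is the slope
#' `lambda1` of the linear instantaneous-cost model fitted across paired
#' evaluations at `x_n +/- delta_n`. Under the linear model this slope
#' equals the symmetric finite difference `(c(x_n + delta) - c(x_n -
#' delta)) / (2 delta)` exactly, so no separate differencing is performed.
#'
#' The `evaluator` is called as `evaluator(x_cmd, delta, breaths_per_side)`
#' and must return a list with `model` (a [cost_model()] whose `lambda1` is
#' in the configured cost units per Hz), and optionally `cost` (cost at
#' `x_cmd` for bookkeeping), `x_meas` and `duration_s`.
#'
#' @param evaluator Paired-perturbation evaluation closure; see Details.
#' @param config A [gd_config()].
#' @return A `hil_trajectory` with one row per iteration (phase `"gd"`);
#'   attribute `"x_final"` holds the post-update command after the last
#'   iteration.
#' @export
run_gradient_descent <- function(evaluator, config) {
  stopifnot(inherits(config, "gd_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sgn <- if (stats::runif(1) < 0.5) -1 else 1
  x <- config$x_pref * (1 + sgn * config$init_offset)
  x <- min(max(x, config$domain[1]), config$domain[2])
  delta <- config$delta_frac * config$x_pref
  rows <- list()
  status <- "complete"
  for (n in seq_len(config$n_iterations) - 1L) {
    r <- tryCatch(evaluator(x, delta, config$breaths_per_side),
                  error = function(e) e)
    if (inherits(r, "error")) {
      status <- "truncated"
      break
    }
    J <- r$model$lambda1
    cost_at_x <- if (!is.null(r$cost)) r$cost else predict(r$model, x)
    rows[[length(rows) + 1]] <- traj_row(
      n + 1L, "gd", x, r$x_meas, cost_at_x, config$cost_units, r$duration_s
    )
    x <- x - gd_step_size(n, config) * J
    x <- min(max(x, config$domain[1]), config$domain[2])
  }
  tr <- new_trajectory(rows, "gd", config$x_pref, config$seed, status)
  attr(tr, "x_final") <- x
  tr
}
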
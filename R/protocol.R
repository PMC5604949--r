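#' Grid frequencies for the discrete parameter sweep
#'
#' The nine sweep conditions: preferred step frequency and 5, 10, 15 and
#' 25% below and above it.
#'
#' @param x_pref Preferred step frequency (Hz).
#' @return Nine frequencies (Hz), increasing.
#' @export
grid_frequencies <- function(x_pref) {
  x_pref * (1 + c(-0.25, -0.15, -0.10, -0.05, 0, 0.05, 0.10, 0.15, 0.25))
}

#' Build the metabolic-landscape baseline from a discrete grid search
#'
#' For each grid condition the metabolic power is averaged over the final
#' two minutes of the bout, the standing mean (same windowing) is
#' subtracted, and the result is normalized by body mass. A GP is fit to
#' the nine net costs and the frequency minimizing the posterior mean —
#' located by a dense grid plus local refinement — is the baseline
#' minimum-energy solution.
#'
#' @param grid_results A named list mapping step frequency (as names, or
#'   via the `freqs` argument) to [breath_series()] objects, one per grid
#'   condition.
#' @param standing_series A [breath_series()] recorded during quiet
#'   standing.
#' @param mass Body mass (kg).
#' @param freqs Grid frequencies (Hz); defaults to `as.numeric(names(...))`.
#' @param window_s Averaging window at the end of each bout (s).
#' @param hp_restarts Restarts for the GP hyperparameter fit.
#' @param argmin_tol Refinement tolerance for the argmin (Hz).
#' @return A `hil_landscape`: grid frequencies and net costs (W/kg), the
#'   fitted posterior and hyperparameters, the argmin, the standing cost
#'   (W/kg) and the mass.
#' @export
build_landscape <- function(grid_results, standing_series, mass,
                            freqs = NULL, window_s = 120, hp_restarts = 10,
                            argmin_tol = 1e-4) {
  if (is.null(freqs)) freqs <- as.numeric(names(grid_results))
  stopifnot(length(freqs) == length(grid_results), !anyNA(freqs), mass > 0)
  window_mean <- function(series) {
    t_end <- series$t[nrow(series)]
    if (t_end - series$t[1] < window_s) {
      stop(sprintf("bout too short: need at least %g s of breaths", window_s))
    }
    mean(series$power[series$t > t_end - window_s])
  }
  standing_w <- window_mean(standing_series)
  y <- vapply(grid_results, function(s) (window_mean(s) - standing_w) / mass,
              numeric(1))
  ord <- order(freqs)
  freqs <- freqs[ord]; y <- unname(y[ord])
  hp <- gp_fit_hyperparameters(freqs, y, n_restarts = hp_restarts,
                               domain = range(freqs))
  post <- gp_posterior(freqs, y, hp)
  hull <- range(freqs)
  grid <- seq(hull[1], hull[2], length.out = 2001)
  mg <- post$mean_fn(grid)
  i <- which(mg == min(mg))[1]         # lowest frequency on exact ties
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  argmin <- if (lo < hi) {
    stats::optimize(post$mean_fn, c(lo, hi), tol = argmin_tol)$minimum
  } else grid[i]
  if (post$mean_fn(argmin) > mg[i]) argmin <- grid[i]
  structure(
    list(freqs = freqs, costs = y, posterior = post, hp = hp,
         argmin = argmin, standing_wkg = standing_w / mass, mass = mass),
    class = "hil_landscape"
  )
}

#' @export
print.hil_landscape <- function(x, ...) {
  cat(sprintf(
    "<hil_landscape> %d conditions over %.2f-%.2f Hz, argmin %.3f Hz (%.2f W/kg net)\n",
    length(x$freqs), min(x$freqs), max(x$freqs), x$argmin,
    x$posterior$mean_fn(x$argmin)
  ))
  invisible(x)
}

#' Evaluate the landscape posterior mean at frequencies
#'
#' Queries outside the grid hull are clipped to it.
#'
#' @param landscape A `hil_landscape`.
#' @param x Step frequencies (Hz).
#' @param gross Add the standing cost back (gross W/kg).
#' @return Net (or gross) mass-normalized cost (W/kg).
#' @export
landscape_cost <- function(landscape, x, gross = FALSE) {
  x <- pmin(pmax(x, min(landscape$freqs)), max(landscape$freqs))
  landscape$posterior$mean_fn(x) + if (gross) landscape$standing_wkg else 0
}

traj_active_rows <- function(traj, include_init = FALSE) {
  if (attr(traj, "method") == "bo" && !include_init) {
    traj[traj$phase == "ei", , drop = FALSE]
  } else {
    traj
  }
}

#' Detect convergence of an optimization trajectory
#'
#' Applies an iteration-to-iteration termination criterion post hoc: the
#' run is deemed converged at the first iteration `j >= 2` (within the
#' method's own iteration sequence) whose change falls below the threshold.
#' For the step-frequency criterion the change is
#' `|x_j - x_{j-1}| / x_pref`; for the metabolic-cost criterion it is
#' `|c_j - c_{j-1}| / |c_{j-1}|`. Thresholds are percentages: the defaults
#' used in analysis are 1 (BO) and 0.41 (GD) for step frequency, and 2 for
#' metabolic cost.
#'
#' For Bayesian optimization only EI-driven evaluations count as
#' iterations; the initial design is excluded (its duration can be added to
#' the reported time via `include_init_time`).
#'
#' @param traj A `hil_trajectory`.
#' @param criterion `"step_frequency"` or `"metabolic_cost"`.
#' @param epsilon Threshold in percent; defaults to 1 (BO) / 0.41 (GD) for
#'   step frequency and 2 for metabolic cost.
#' @param x_pref Preferred frequency (Hz); defaults to the trajectory
#'   attribute.
#' @param include_init_time Also report time including the initial design.
#' @return A `convergence_report` list: `converged`, `iteration` (count of
#'   method iterations through detection), `iter_abs` (trajectory `iter`
#'   at detection), `time_min`, `time_incl_init_min`, `x_conv`, `cost_conv`
#'   and the criterion settings. When the criterion never fires,
#'   `converged = FALSE` and full-trajectory totals are reported.
#' @export
detect_convergence <- function(traj,
                               criterion = c("step_frequency", "metabolic_cost"),
                               epsilon = NULL, x_pref = NULL,
                               include_init_time = TRUE) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(traj, "hil_trajectory"))
  method <- attr(traj, "method")
  if (is.null(x_pref)) x_pref <- attr(traj, "x_pref")
  if (is.null(epsilon)) {
    epsilon <- if (criterion == "metabolic_cost") 2 else if (method == "bo") 1 else 0.41
  }
  stopifnot(epsilon > 0)
  rows <- traj_active_rows(traj)
  init_time <- sum(traj$duration_s[traj$phase == "init"], na.rm = TRUE)
  m <- nrow(rows)
  if (m < 2) stop("need at least 2 post-initialization iterations")
  change <- if (criterion == "step_frequency") {
    100 * abs(diff(rows$x_cmd)) / x_pref
  } else {
    100 * abs(diff(rows$cost)) / abs(rows$cost[-m])
  }
  hit <- which(change < epsilon)
  converged <- length(hit) > 0
  j <- if (converged) hit[1] + 1L else m
  time_s <- sum(rows$duration_s[seq_len(j)], na.rm = FALSE)
  structure(
    list(
      criterion = criterion, epsilon = epsilon, method = method,
      converged = converged, iteration = j, iter_abs = rows$iter[j],
      time_min = time_s / 60,
      time_incl_init_min = if (include_init_time) (time_s + init_time) / 60 else NA_real_,
      x_conv = rows$x_cmd[j], cost_conv = rows$cost[j], x_pref = x_pref
    ),
    class = "convergence_report"
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "<convergence_report> %s / %s eps = %.3g%%: %s at iteration %d (%.1f min), x = %.3f Hz\n",
    x$method, x$criterion, x$epsilon,
    if (x$converged) "converged" else "not converged",
    x$iteration, x$time_min, x$x_conv
  ))
  invisible(x)
}

#' Step-frequency error at convergence
#'
#' Percent error of the converged frequency against the sweep-fit argmin
#' and against the preferred frequency. Both are expressed relative to the
#' preferred frequency by default (`denominator = "preferred"`), keeping
#' the two columns on a common dimensionless scale; set `denominator =
#' "reference"` to divide by each reference frequency itself.
#'
#' @param x_conv Frequency at convergence (Hz).
#' @param landscape A `hil_landscape` (its `argmin` is the sweep-fit
#'   reference).
#' @param x_pref Preferred step frequency (Hz).
#' @param denominator `"preferred"` or `"reference"`.
#' @return A list with `vs_sweep_fit` and `vs_preferred`, in percent.
#' @export
error_metrics <- function(x_conv, landscape, x_pref,
                          denominator = c("preferred", "reference")) {
  denominator <- match.arg(denominator)
  x_ref <- landscape$argmin
  den <- function(ref) if (denominator == "preferred") x_pref else ref
  list(
    vs_sweep_fit = 100 * abs(x_conv - x_ref) / den(x_ref),
    vs_preferred = 100 * abs(x_conv - x_pref) / den(x_pref)
  )
}

#' Energy expended during an optimization run
#'
#' Integrates the landscape's constant cost at each visited frequency over
#' the iteration durations: `sum(cost(x_cmd) * mass * duration)` converted
#' from joules to kilocalories. The landscape cost is net
#' (standing-subtracted) by default; `gross = TRUE` adds the standing cost
#' back.
#'
#' @param traj A `hil_trajectory`.
#' @param landscape A `hil_landscape`.
#' @param mass Body mass (kg); defaults to the landscape's.
#' @param stop_at Integrate rows with `iter <= stop_at` (e.g. a
#'   convergence report's `iter_abs`); `NULL` integrates the whole run.
#' @param gross Use gross (standing-included) cost.
#' @return Energy (kcal).
#' @export
energy_expenditure <- function(traj, landscape, mass = NULL, stop_at = NULL,
                               gross = FALSE) {
  if (is.null(mass)) mass <- landscape$mass
  rows <- as.data.frame(traj)
  if (!is.null(stop_at)) rows <- rows[rows$iter <= stop_at, , drop = FALSE]
  if (nrow(rows) == 0) return(0)
  w_kg <- landscape_cost(landscape, rows$x_cmd, gross = gross)
  sum(w_kg * mass * rows$duration_s) / 4184
}

#' Run one experimental condition on a synthetic subject
#'
#' Executes the full bout structure of one protocol day against the
#' simulator: `"grid"` runs the nine randomized 6-minute sweep conditions
#' plus 6 minutes of standing and returns the landscape baseline; `"gd"`
#' runs 15 gradient-descent iterations; `"bo"` runs the 3-point initial
#' design plus EI-driven evaluations. For the optimizers both termination
#' criteria are evaluated post hoc.
#'
#' @param subj A [subject_profile()].
#' @param method `"grid"`, `"gd"` or `"bo"`.
#' @param seed Run seed.
#' @param config Optional [bo_config()] / [gd_config()] override.
#' @param landscape Optional precomputed `hil_landscape`; when supplied for
#'   the optimizer methods, error metrics and energy expenditure are added
#'   to each report.
#' @param bout_s Grid bout length (s).
#' @param standing_s Standing bout length (s).
#' @return For `"grid"`: a list with `landscape`. For the optimizers: a
#'   list with `trajectory` and `reports` (one `convergence_report` per
#'   criterion, augmented with error/energy when a landscape is given).
#' @export
run_condition <- function(subj, method = c("grid", "gd", "bo"), seed = NULL,
                          config = NULL, landscape = NULL, bout_s = 360,
                          standing_s = 360) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method == "grid") {
    n_breaths <- function(len_s) max(2L, ceiling(len_s * subj$breath_rate_mean * 1.25))
    trim_to <- function(series, len_s) {
      series[series$t <= len_s, , drop = FALSE]
    }
    standing <- simulate_bout(subj, NA, n_breaths(standing_s),
                              state = list(r = subj$standing_cost * subj$mass))
    freqs <- sample(grid_frequencies(subj$x_pref))   # randomized bout order
    state <- NULL
    results <- list()
    for (f in freqs) {
      b <- simulate_bout(subj, f, n_breaths(bout_s), state = state)
      state <- b$state
      results[[sprintf("%.6f", f)]] <- trim_to(b$series, bout_s)
    }
    ls <- build_landscape(results, trim_to(standing$series, standing_s),
                          mass = subj$mass,
                          freqs = as.numeric(names(results)))
    return(list(landscape = ls, method = method, seed = seed))
  }
  if (method == "bo") {
    if (is.null(config)) config <- bo_config(subj$x_pref)
    traj <- run_bayes_opt(bo_evaluator(subj), config)
  } else {
    if (is.null(config)) config <- gd_config(subj$x_pref)
    traj <- run_gradient_descent(gd_evaluator(subj, config$cost_units), config)
  }
  reports <- lapply(c("step_frequency", "metabolic_cost"), function(cr) {
    rep <- detect_convergence(traj, cr)
    if (!is.null(landscape)) {
      err <- error_metrics(rep$x_conv, landscape, subj$x_pref)
      rep$error_vs_sweep_fit <- err$vs_sweep_fit
      rep$error_vs_preferred <- err$vs_preferred
      rep$energy_kcal <- energy_expenditure(traj, landscape,
                                            mass = subj$mass,
                                            stop_at = rep$iter_abs)
    }
    rep
  })
  names(reports) <- c("step_frequency", "metabolic_cost")
  list(trajectory = traj, reports = reports, method = method, seed = seed)
}
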
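#' Replicated cohort benchmark of both optimizers
#'
#' The simulation-study counterpart of a multi-subject experiment: for each
#' of `n_seeds` replicate cohorts of `n_subjects` synthetic subjects, every
#' subject undergoes the discrete grid search (landscape baseline), the
#' Bayesian-optimization day and the gradient-descent day, and the
#' step-frequency termination criterion is applied post hoc at each
#' method's threshold (1% of preferred for BO, 0.41% for GD).
#'
#' Replicate cohort seeds and per-subject run seeds are derived
#' deterministically from `seed`.
#'
#' @param n_subjects Subjects per cohort (default 8).
#' @param n_seeds Number of replicate cohorts (default 25).
#' @param seed Master seed.
#' @param ... Overrides forwarded to [make_cohort()].
#' @return A data frame with one row per subject x replicate: convergence
#'   iteration, convergence flag, time and frequency at convergence for
#'   both methods, and the BO error against the sweep-fit argmin and the
#'   preferred frequency (percent of preferred).
#' @export
cohort_benchmark <- function(n_subjects = 8, n_seeds = 25, seed = 1, ...) {
  set.seed(seed)
  cohort_seeds <- sample.int(2^31 - 2, n_seeds)
  rows <- vector("list", n_subjects * n_seeds)
  k <- 0L
  for (r in seq_len(n_seeds)) {
    cohort <- make_cohort(n_subjects, cohort_seeds[r], ...)
    for (i in seq_along(cohort)) {
      subj <- cohort[[i]]
      grid <- run_condition(subj, "grid", seed = subj$seed)
      ls <- grid$landscape
      bo <- run_condition(subj, "bo", seed = subj$seed + 1L, landscape = ls)
      gd <- run_condition(subj, "gd", seed = subj$seed + 2L, landscape = ls)
      rb <- bo$reports$step_frequency
      rd <- gd$reports$step_frequency
      k <- k + 1L
      rows[[k]] <- data.frame(
        replicate = r, subject = i, x_pref = subj$x_pref,
        sweep_argmin = ls$argmin,
        bo_converged = rb$converged, bo_iterations = rb$iteration,
        bo_time_min = rb$time_min, bo_x_conv = rb$x_conv,
        bo_err_sweep = rb$error_vs_sweep_fit,
        bo_err_pref = rb$error_vs_preferred,
        gd_converged = rd$converged, gd_iterations = rd$iteration,
        gd_time_min = rd$time_min, gd_x_conv = rd$x_conv
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a cohort benchmark
#'
#' Means over converged runs of the convergence iteration for each method,
#' plus the mean BO error against the sweep-fit argmin; the quantities
#' reported by a multi-subject comparison study.
#'
#' @param bench Output of [cohort_benchmark()].
#' @return A list: `bo_mean_iterations`, `gd_mean_iterations`,
#'   `bo_mean_error_vs_sweep`, the convergence rates, and the SDs of the
#'   per-run convergence times for each method.
#' @export
summarize_benchmark <- function(bench) {
  list(
    bo_mean_iterations = mean(bench$bo_iterations[bench$bo_converged]),
    gd_mean_iterations = mean(bench$gd_iterations[bench$gd_converged]),
    bo_mean_error_vs_sweep = mean(bench$bo_err_sweep[bench$bo_converged]),
    bo_convergence_rate = mean(bench$bo_converged),
    gd_convergence_rate = mean(bench$gd_converged),
    bo_time_sd_min = stats::sd(bench$bo_time_min[bench$bo_converged]),
    gd_time_sd_min = stats::sd(bench$gd_time_min[bench$gd_converged]),
    n = nrow(bench)
  )
}
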
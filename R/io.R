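#' Read and write the breath CSV dialect
#'
#' Columns `t_s,h_s,vo2_ml_min,vco2_ml_min[,x_meas_hz]` (header required,
#' UTF-8, `.` decimal separator). When gas columns are all missing a
#' `power_w` column is accepted in their place. Round trips are lossless to
#' below 1e-9.
#'
#' @param path File path.
#' @param mass Optional body mass (kg) attached to the series.
#' @return [read_breath_csv()]: a [breath_series()].
#' @export
read_breath_csv <- function(path, mass = NA_real_) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  required <- c("t_s", "h_s")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("breath CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_gas <- all(c("vo2_ml_min", "vco2_ml_min") %in% names(df)) &&
    !all(is.na(df$vo2_ml_min))
  if (!has_gas && !"power_w" %in% names(df)) {
    stop("breath CSV missing column(s): vo2_ml_min, vco2_ml_min (or power_w)")
  }
  bad <- which(!stats::complete.cases(df[required]))
  if (length(bad) > 0) {
    stop(sprintf("malformed breath CSV row(s): %s",
                 paste(bad + 1L, collapse = ", ")))
  }
  x_meas <- if ("x_meas_hz" %in% names(df)) df$x_meas_hz else NA_real_
  if (has_gas) {
    breath_series(t = df$t_s, vo2 = df$vo2_ml_min, vco2 = df$vco2_ml_min,
                  x_meas = x_meas, h = df$h_s, mass = mass)
  } else {
    breath_series(t = df$t_s, power = df$power_w, x_meas = x_meas,
                  h = df$h_s, mass = mass)
  }
}

#' @rdname read_breath_csv
#' @param series A [breath_series()].
#' @export
write_breath_csv <- function(series, path) {
  stopifnot(inherits(series, "breath_series"))
  df <- data.frame(
    t_s = series$t, h_s = series$h,
    vo2_ml_min = series$vo2, vco2_ml_min = series$vco2,
    power_w = series$power, x_meas_hz = series$x_meas
  )
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write the trajectory CSV dialect
#'
#' Columns `iter,phase,method,x_cmd_hz,x_meas_hz,cost,cost_units,
#' duration_s,hyp_sigma2,hyp_l,hyp_noise2`, plus `x_pref_hz` carried on
#' every row for self-containment.
#'
#' @param path File path.
#' @return [read_trajectory_csv()]: a `hil_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("iter", "phase", "method", "x_cmd_hz", "cost", "x_pref_hz")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("trajectory CSV missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tr <- data.frame(
    iter = df$iter, phase = df$phase, x_cmd = df$x_cmd_hz,
    x_meas = if ("x_meas_hz" %in% names(df)) df$x_meas_hz else NA_real_,
    cost = df$cost,
    cost_units = if ("cost_units" %in% names(df)) df$cost_units else NA,
    duration_s = if ("duration_s" %in% names(df)) df$duration_s else NA_real_,
    hyp_sigma2 = if ("hyp_sigma2" %in% names(df)) df$hyp_sigma2 else NA_real_,
    hyp_l = if ("hyp_l" %in% names(df)) df$hyp_l else NA_real_,
    hyp_noise2 = if ("hyp_noise2" %in% names(df)) df$hyp_noise2 else NA_real_
  )
  attr(tr, "method") <- df$method[1]
  attr(tr, "x_pref") <- df$x_pref_hz[1]
  attr(tr, "status") <- if ("status" %in% names(df)) df$status[1] else "complete"
  class(tr) <- c("hil_trajectory", "data.frame")
  tr
}

#' @rdname read_trajectory_csv
#' @param traj A `hil_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "hil_trajectory"))
  df <- data.frame(
    iter = traj$iter, phase = traj$phase, method = attr(traj, "method"),
    x_cmd_hz = traj$x_cmd, x_meas_hz = traj$x_meas, cost = traj$cost,
    cost_units = traj$cost_units, duration_s = traj$duration_s,
    hyp_sigma2 = traj$hyp_sigma2, hyp_l = traj$hyp_l,
    hyp_noise2 = traj$hyp_noise2,
    x_pref_hz = attr(traj, "x_pref"), status = attr(traj, "status")
  )
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a subject profile from YAML
#'
#' Field names mirror [subject_profile()] arguments; every constant is
#' overridable and unknown fields are rejected.
#'
#' @param path YAML file path.
#' @return A [subject_profile()].
#' @export
read_subject_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(subject_profile))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown subject field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(subject_profile, cfg)
}

#' Write a subject profile to YAML
#'
#' @param subj A [subject_profile()].
#' @param path Destination path.
#' @export
write_subject_yaml <- function(subj, path) {
  yaml::write_yaml(unclass(subj)[!vapply(unclass(subj), is.null, logical(1))],
                   path)
  invisible(path)
}
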
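#' Energetic equivalents used to convert gas exchange to power
#'
#' Coefficients of the Brockway equation (J per mL of O2 consumed and CO2
#' produced) and the gross energetic equivalent of oxygen used when costs are
#' expressed as an O2-rate equivalent (mL O2/min). Kept in one place so they
#' can be overridden consistently.
#'
#' @format A named list with elements `j_per_ml_o2` (16.58), `j_per_ml_co2`
#'   (4.51) and `j_per_ml_o2_gross` (20.1).
#' @export
brockway_coefficients <- list(
  j_per_ml_o2 = 16.58,
  j_per_ml_co2 = 4.51,
  j_per_ml_o2_gross = 20.1
)

#' Convert breath-by-breath gas exchange to metabolic power
#'
#' Applies the Brockway equation: each mL of O2 uptake contributes 16.58 J
#' and each mL of CO2 production 4.51 J, so a per-minute exchange rate maps
#' to power as `(16.58 * vo2 + 4.51 * vco2) / 60` watts.
#'
#' @param vo2 Oxygen uptake rate (mL/min). Vectorized.
#' @param vco2 Carbon-dioxide production rate (mL/min). Vectorized.
#' @param coef Energetic coefficients; see [brockway_coefficients].
#' @return Metabolic power in watts.
#' @examples
#' brockway_power(300, 240) # about 100.9 W, typical quiet standing
#' @export
brockway_power <- function(vo2, vco2, coef = brockway_coefficients) {
  if (any(vo2 < 0, na.rm = TRUE) || any(vco2 < 0, na.rm = TRUE)) {
    stop("gas exchange rates must be non-negative")
  }
  (coef$j_per_ml_o2 * vo2 + coef$j_per_ml_co2 * vco2) / 60
}

#' Construct a breath series
#'
#' A breath series is the package's container for timestamped breath-by-breath
#' respiratory data: breath times, inter-breath intervals, metabolic power per
#' breath and (optionally) the measured step frequency at each breath. Power
#' can be supplied directly or derived from VO2/VCO2 via [brockway_power()].
#'
#' @param t Breath timestamps (s since bout start), strictly increasing.
#' @param power Metabolic power per breath (W). Omit to derive from gas rates.
#' @param vo2,vco2 Gas exchange rates (mL/min), used when `power` is missing.
#' @param x_meas Measured step frequency at each breath (Hz), or `NA`.
#' @param h Elapsed time since the previous breath (s). Defaults to
#'   `diff(t)` with the first interval copied; must be consistent with `t`.
#' @param mass Subject body mass (kg), optional, carried for normalization.
#' @return A `breath_series`: a data frame with columns `t`, `h`, `vo2`,
#'   `vco2`, `power`, `x_meas` and attribute `mass`.
#' @export
breath_series <- function(t, power = NULL, vo2 = NA_real_, vco2 = NA_real_,
                          x_meas = NA_real_, h = NULL, mass = NA_real_) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < 1) stop("breath series needs at least one breath")
  if (n > 1 && any(diff(t) <= 0)) stop("breath timestamps must be strictly increasing")
  if (is.null(h)) {
    h <- if (n > 1) c(diff(t)[1], diff(t)) else 1
  }
  h <- rep_len(as.numeric(h), n)
  if (any(h <= 0)) stop("inter-breath intervals h must be positive")
  if (n > 1) {
    dh <- abs(diff(t) - h[-1])
    if (any(dh > 1e-3)) {
      warning(sprintf("h inconsistent with t by up to %.4g s", max(dh)))
    }
  }
  vo2 <- rep_len(as.numeric(vo2), n)
  vco2 <- rep_len(as.numeric(vco2), n)
  if (is.null(power)) {
    power <- brockway_power(vo2, vco2)
  }
  power <- rep_len(as.numeric(power), n)
  out <- data.frame(
    t = t, h = h, vo2 = vo2, vco2 = vco2, power = power,
    x_meas = rep_len(as.numeric(x_meas), n)
  )
  attr(out, "mass") <- mass
  class(out) <- c("breath_series", "data.frame")
  out
}

#' @export
print.breath_series <- function(x, ...) {
  m <- attr(x, "mass")
  cat(sprintf(
    "<breath_series> %d breaths over %.1f s%s\n", nrow(x),
    if (nrow(x) > 1) x$t[nrow(x)] - x$t[1] else 0,
    if (is.finite(m)) sprintf(", mass %.1f kg", m) else ""
  ))
  print(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("... %d more breaths\n", nrow(x) - 4))
  invisible(x)
}

#' Concatenate breath series
#'
#' Joins bouts recorded back-to-back; timestamps of later series are shifted
#' so that the combined time axis is strictly increasing with the stated gap.
#'
#' @param ... `breath_series` objects in chronological order.
#' @param gap_s Gap inserted between consecutive series (s).
#' @return A single `breath_series`.
#' @export
bind_breaths <- function(..., gap_s = NULL) {
  pieces <- list(...)
  stopifnot(length(pieces) >= 1)
  out <- pieces[[1]]
  for (p in pieces[-1]) {
    gap <- if (is.null(gap_s)) p$h[1] else gap_s
    offset <- out$t[nrow(out)] + gap - p$t[1]
    p$t <- p$t + offset
    p$h[1] <- gap
    df <- rbind(as.data.frame(out), as.data.frame(p))
    attr(df, "mass") <- attr(out, "mass")
    class(df) <- class(out)
    out <- df
  }
  out
}
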
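#' Gaussian-process hyperparameters
#'
#' Squared-exponential hyperparameters for the 1-D cost surrogate: signal
#' variance `sigma2`, length scale `l` (Hz) and observation-noise variance
#' `noise2`. All must be strictly positive.
#'
#' @param sigma2 Signal variance (cost units squared).
#' @param length_scale Kernel length scale (Hz).
#' @param noise2 i.i.d. observation-noise variance (cost units squared).
#' @return A `gp_hyperparameters` list.
#' @export
gp_hyperparameters <- function(sigma2, length_scale, noise2) {
  stopifnot(sigma2 > 0, length_scale > 0, noise2 > 0)
  structure(
    list(sigma2 = unname(sigma2), length_scale = unname(length_scale),
         noise2 = unname(noise2)),
    class = "gp_hyperparameters"
  )
}

#' @export
print.gp_hyperparameters <- function(x, ...) {
  cat(sprintf(
    "<gp_hyperparameters> sigma2 = %.4g, l = %.4g Hz, noise2 = %.4g\n",
    x$sigma2, x$length_scale, x$noise2
  ))
  invisible(x)
}

#' Squared-exponential covariance
#'
#' `k(x, x') = sigma2 * exp(-(x - x')^2 / (2 l^2))`. The observation-noise
#' variance is *not* part of the covariance function itself: it enters only
#' on the diagonal of the Gram matrix of observed points (`same_point =
#' TRUE`), so that noise is counted once, consistent with the posterior
#' equations.
#'
#' @param x,x2 Step frequencies (Hz); recycled against each other.
#' @param hp A [gp_hyperparameters()].
#' @param same_point If `TRUE`, add `noise2` (diagonal convention).
#' @return Covariance values.
#' @export
gp_kernel <- function(x, x2, hp, same_point = FALSE) {
  k <- hp$sigma2 * exp(-(x - x2)^2 / (2 * hp$length_scale^2))
  if (same_point) k <- k + hp$noise2
  k
}

# Gram matrix over observed inputs with noise on the diagonal plus a small
# jitter for factorization stability.
gp_gram <- function(X, hp, jitter_rel = 1e-10) {
  D2 <- outer(X, X, "-")^2
  K <- hp$sigma2 * exp(-D2 / (2 * hp$length_scale^2))
  jitter <- jitter_rel * sum(diag(K)) / length(X)
  K + diag(hp$noise2 + jitter, length(X))
}

#' Gaussian-process posterior over step frequency
#'
#' Conditions a zero-mean GP prior on observations `(X, y)` with i.i.d.
#' Gaussian noise. Because metabolic costs are far from zero, `y` is centered
#' by its sample mean before conditioning and the offset is restored in
#' predictions (`center = TRUE`, the default); the prior is zero-mean on the
#' centered scale. The predictive variance is the function-value
#' (latent-cost) variance, without the observation-noise term.
#'
#' Predictions use a Cholesky factorization of `K + noise2 * I`:
#' `E[c*] = k*' (K + noise2 I)^-1 y` and
#' `s*^2 = k(x*, x*) - k*' (K + noise2 I)^-1 k*`.
#'
#' @param X Observed step frequencies (Hz).
#' @param y Observed cost estimates (same length as `X`).
#' @param hp A [gp_hyperparameters()].
#' @param center Center `y` by its mean before conditioning.
#' @return A `gp_posterior` with closures `mean_fn(x)` and `var_fn(x)`, the
#'   cached Cholesky factor, and the training data.
#' @export
gp_posterior <- function(X, y, hp, center = TRUE) {
  stopifnot(length(X) == length(y), length(X) >= 1)
  X <- as.numeric(X); y <- as.numeric(y)
  mu0 <- if (center) mean(y) else 0
  yc <- y - mu0
  K <- gp_gram(X, hp)
  L <- tryCatch(chol(K), error = function(e) {
    stop("Gram matrix not positive definite after jitter: ", conditionMessage(e))
  })
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  mean_fn <- function(xs) {
    Ks <- hp$sigma2 * exp(-outer(xs, X, "-")^2 / (2 * hp$length_scale^2))
    drop(Ks %*% alpha) + mu0
  }
  var_fn <- function(xs) {
    Ks <- hp$sigma2 * exp(-outer(xs, X, "-")^2 / (2 * hp$length_scale^2))
    v <- forwardsolve(t(L), t(Ks))
    pmax(hp$sigma2 - colSums(v^2), 0)
  }
  structure(
    list(mean_fn = mean_fn, var_fn = var_fn, chol = L, alpha = alpha,
         X = X, y = y, hp = hp, mu0 = mu0),
    class = "gp_posterior"
  )
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior> n = %d observations, ", length(x$X)))
  print(x$hp)
  invisible(x)
}

#' Log marginal likelihood of a GP dataset
#'
#' `-(1/2) y' (K + noise2 I)^-1 y - (1/2) log det(K + noise2 I) -
#' (n/2) log(2 pi)`, evaluated via Cholesky factorization. `y` is centered
#' as in [gp_posterior()] when `center = TRUE`.
#'
#' @inheritParams gp_posterior
#' @param grad If `TRUE`, attach the gradient with respect to
#'   `log(sigma2, l, noise2)` as attribute `"gradient"`.
#' @return Log density (nats).
#' @export
gp_log_marginal_likelihood <- function(X, y, hp, center = TRUE, grad = FALSE) {
  stopifnot(length(X) == length(y))
  n <- length(X)
  yc <- y - if (center) mean(y) else 0
  K <- gp_gram(X, hp)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  ll <- -0.5 * sum(yc * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
  if (grad) {
    Kinv <- chol2inv(L)
    A <- tcrossprod(alpha) - Kinv
    D2 <- outer(X, X, "-")^2
    Kf <- hp$sigma2 * exp(-D2 / (2 * hp$length_scale^2))
    # derivatives of K wrt log-parameters: Kf, Kf * D2 / l^2, noise2 * I
    g <- 0.5 * c(
      sum(A * Kf),
      sum(A * Kf * D2 / hp$length_scale^2),
      sum(diag(A)) * hp$noise2
    )
    attr(ll, "gradient") <- g
  }
  ll
}

#' Default hyperparameter bounds
#'
#' Bounds scale with the data: the length scale spans 2%-200% of the input
#' range (or the supplied domain width), the signal variance 1e-4 to 1e2
#' times the sample variance of `y`, and the noise variance 1e-6 to 1 times
#' it. Degenerate `var(y)` falls back to 1.
#'
#' @param X,y Training data.
#' @param domain Optional c(lower, upper) search domain whose width anchors
#'   the length-scale bounds; defaults to the range of `X`.
#' @return A list with elements `lower` and `upper`, each a named vector
#'   over `(sigma2, length_scale, noise2)`.
#' @export
gp_default_bounds <- function(X, y, domain = NULL) {
  width <- if (!is.null(domain)) diff(range(domain)) else diff(range(X))
  if (!is.finite(width) || width <= 0) width <- max(abs(X), 1)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  list(
    lower = c(sigma2 = 1e-4 * vy, length_scale = 0.02 * width, noise2 = 1e-6 * vy),
    upper = c(sigma2 = 1e2 * vy, length_scale = 2.0 * width, noise2 = 1 * vy)
  )
}

#' Fit GP hyperparameters by maximizing the log marginal likelihood
#'
#' Bound-constrained L-BFGS-B search over log-parameters, restarted from
#' `n_restarts` initializations drawn log-uniformly within the bounds (the
#' first start is the geometric mid-point of the bounds). The restart with
#' the highest marginal likelihood wins. Randomness is consumed from R's
#' global generator, so results are reproducible under `set.seed()`.
#'
#' @inheritParams gp_posterior
#' @param bounds As returned by [gp_default_bounds()].
#' @param n_restarts Number of random restarts (default 10).
#' @param domain Passed to [gp_default_bounds()] when `bounds` is `NULL`.
#' @return A [gp_hyperparameters()] with attribute `"logLik"`.
#' @export
gp_fit_hyperparameters <- function(X, y, bounds = NULL, n_restarts = 10,
                                   domain = NULL, center = TRUE) {
  stopifnot(length(X) == length(y), length(X) >= 2)
  if (is.null(bounds)) bounds <- gp_default_bounds(X, y, domain)
  lo <- log(bounds$lower); hi <- log(bounds$upper)
  obj <- function(lp) {
    hp <- gp_hyperparameters(exp(lp[1]), exp(lp[2]), exp(lp[3]))
    ll <- tryCatch(
      gp_log_marginal_likelihood(X, y, hp, center = center, grad = TRUE),
      error = function(e) NULL
    )
    if (is.null(ll)) return(list(value = 1e10, grad = c(0, 0, 0)))
    list(value = -as.numeric(ll), grad = -attr(ll, "gradient"))
  }
  last <- new.env()
  fn <- function(lp) { r <- obj(lp); assign("g", r$grad, envir = last); r$value }
  gr <- function(lp) get("g", envir = last)

  starts <- rbind(
    (lo + hi) / 2,
    matrix(stats::runif(3 * max(n_restarts - 1, 0), rep(lo, each = max(n_restarts - 1, 0)),
                        rep(hi, each = max(n_restarts - 1, 0))),
           ncol = 3, byrow = FALSE)
  )
  best <- NULL
  diagnostics <- character(0)
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B",
                   lower = lo, upper = hi, control = list(maxit = 200)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(res))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all hyperparameter restarts failed: ", paste(diagnostics, collapse = "; "))
  }
  hp <- gp_hyperparameters(exp(best$par[1]), exp(best$par[2]), exp(best$par[3]))
  attr(hp, "logLik") <- -best$value
  hp
}
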
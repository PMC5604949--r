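# analytic evaluators over a noiseless quadratic cost, used as optimizer
# fixtures: cost(x) = a (x - x_opt)^2 + c0
quad_bo_evaluator <- function(a, x_opt, c0 = 4) {
  function(x_cmd, n_breaths) list(cost = a * (x_cmd - x_opt)^2 + c0)
}
quad_gd_evaluator <- function(a, x_opt, c0 = 4) {
  function(x_cmd, delta, breaths_per_side) {
    # exact linear fit across the two perturbed points: the chord slope of a
    # quadratic centered at x_cmd equals its derivative there
    lo <- a * (x_cmd - delta - x_opt)^2 + c0
    hi <- a * (x_cmd + delta - x_opt)^2 + c0
    l1 <- (hi - lo) / (2 * delta)
    list(model = cost_model(l1, lo - l1 * (x_cmd - delta), units = "W"),
         cost = a * (x_cmd - x_opt)^2 + c0)
  }
}

test_that("expected improvement matches its closed form and conventions", {
  expect_identical(expected_improvement(3, 0, 5), 0)
  expect_identical(expected_improvement(10, 0, 5), 0)
  expect_equal(expected_improvement(4, 1, 4), dnorm(0))
  expect_true(all(expected_improvement(rnorm(50), abs(rnorm(50)), 0) >= 0))
  expect_error(expected_improvement(0, -1, 0), "non-negative")
})

test_that("expected improvement agrees with a Monte-Carlo oracle", {
  withr::with_seed(43, {
    draws <- rnorm(2e5)
    for (case in list(c(4, 1, 4.5), c(5, 0.3, 4.5), c(3, 2, 4.5))) {
      m <- case[1]; s <- case[2]; mb <- case[3]
      imp <- pmax(mb - (m + s * draws), 0)
      mc_se <- sd(imp) / sqrt(length(draws))
      expect_equal(expected_improvement(m, s, mb), mean(imp),
                   tolerance = max(3 * mc_se / max(mean(imp), 1e-12), 1e-8))
    }
  })
})

test_that("EI is translation invariant and scale equivariant", {
  withr::with_seed(47, {
    m <- rnorm(20); s <- abs(rnorm(20)); mb <- 0.3
    expect_equal(expected_improvement(m + 7, s, mb + 7),
                 expected_improvement(m, s, mb))
    expect_equal(expected_improvement(5 * m, 5 * s, 5 * mb),
                 5 * expected_improvement(m, s, mb))
  })
})

test_that("the incumbent is the minimum posterior mean, not the raw minimum", {
  # single datum
  hp <- gp_hyperparameters(1, 0.3, 0.2)
  p1 <- gp_posterior(1.8, 4.2, hp)
  expect_equal(mu_best(p1)$value, p1$mean_fn(1.8))

  # vanishing noise: interpolation makes it min(y)
  hp0 <- gp_hyperparameters(1, 0.3, 1e-10)
  X <- c(1.6, 1.8, 2.0); y <- c(4.5, 4.0, 4.3)
  expect_equal(mu_best(gp_posterior(X, y, hp0))$value, 4.0, tolerance = 1e-6)

  # noisy duplicates at one x shrink toward each other
  pd <- gp_posterior(c(1.8, 1.8), c(3.5, 4.5), hp)
  mb <- mu_best(pd)$value
  expect_gt(mb, 3.5)
  expect_lt(mb, 4.5)
})

test_that("EI proposals dominate a dense grid and stay in the domain", {
  withr::with_seed(53, {
    hp <- gp_hyperparameters(0.5, 0.2, 0.05)
    domain <- c(1.35, 2.25)
    for (rep in 1:8) {
      X <- runif(sample(2:8, 1), domain[1], domain[2])
      y <- rnorm(length(X), 4.5, 0.5)
      post <- gp_posterior(X, y, hp)
      x_star <- propose_next(post, domain)
      expect_gte(x_star, domain[1]); expect_lte(x_star, domain[2])
      grid <- seq(domain[1], domain[2], length.out = 1000)
      inc <- mu_best(post)$value
      ei_grid <- expected_improvement(post$mean_fn(grid),
                                      sqrt(post$var_fn(grid)), inc)
      ei_star <- expected_improvement(post$mean_fn(x_star),
                                      sqrt(post$var_fn(x_star)), inc)
      expect_gte(ei_star, max(ei_grid) - 1e-9)
    }
  })
})

test_that("with equal observations the proposal explores away from the data", {
  withr::with_seed(59, {
    hp <- gp_hyperparameters(0.5, 0.1, 1e-6)
    domain <- c(1.35, 2.25)
    post <- gp_posterior(c(1.6, 1.7), c(4, 4), hp)
    x_star <- propose_next(post, domain)
    expect_gt(min(abs(x_star - c(1.6, 1.7))), 0.05)
  })
})

test_that("initial design draws one point per interval, in random order", {
  withr::with_seed(61, {
    for (i in 1:50) {
      d <- sort(initial_design(2.0))
      expect_gte(d[1], 1.5); expect_lte(d[1], 2 * 11 / 12)
      expect_gte(d[2], 2 * 11 / 12); expect_lte(d[2], 2 * 13 / 12)
      expect_gte(d[3], 2 * 13 / 12); expect_lte(d[3], 2.5)
    }
  })
  withr::with_seed(5, a <- initial_design(1.8))
  withr::with_seed(5, b <- initial_design(1.8))
  expect_identical(a, b)
  # per-interval uniformity: empirical means at interval midpoints
  withr::with_seed(67, {
    draws <- t(replicate(1e4, sort(initial_design(1.0))))
    mids <- c((0.75 + 11 / 12) / 2, 1, (13 / 12 + 1.25) / 2)
    se <- (11 / 12 - 0.75) / sqrt(12) / sqrt(1e4)
    for (k in 1:3) {
      expect_lt(abs(mean(draws[, k]) - mids[k]), 3 * se)
    }
  })
})

test_that("the gradient-descent step-size schedule is the stated hyperbola", {
  cfg <- gd_config(1.8)
  expect_equal(gd_step_size(0, cfg), 4e-4)
  expect_equal(gd_step_size(3, cfg), 4e-4 / 2)
  a <- gd_step_size(0:100, cfg)
  expect_true(all(diff(a) < 0))
  expect_lt(a[101], 4e-4 * 3 / 100)
})

test_that("gradient descent reproduces the analytic recursion on a quadratic", {
  a <- 30; x_opt <- 1.8
  cfg <- gd_config(1.8, cost_units = "W", seed = 71)
  tr <- run_gradient_descent(quad_gd_evaluator(a, x_opt), cfg)
  # closed-form recursion with the same initialization sign
  x <- tr$x_cmd[1]
  expected <- numeric(15)
  for (n in 0:14) {
    expected[n + 1] <- x
    x <- x - gd_step_size(n, cfg) * 2 * a * (x - x_opt)
    x <- min(max(x, cfg$domain[1]), cfg$domain[2])
  }
  expect_equal(tr$x_cmd, expected, tolerance = 1e-12)
  expect_equal(attr(tr, "x_final"), x, tolerance = 1e-12)

  # once the contraction factor is < 1, |x_n - x_opt| decreases monotonically
  dev <- abs(tr$x_cmd - x_opt)
  contracting <- which(gd_step_size(0:14, cfg) * 2 * a < 1)
  expect_true(all(diff(dev[contracting]) <= 1e-12))
})

test_that("gradient descent is stationary at the optimum and on linear costs", {
  cfg0 <- gd_config(1.8, init_offset = 0, seed = 73)
  tr0 <- run_gradient_descent(quad_gd_evaluator(30, 1.8), cfg0)
  expect_equal(tr0$x_cmd, rep(1.8, 15), tolerance = 1e-12)

  lin_eval <- function(x_cmd, delta, breaths_per_side) {
    list(model = cost_model(50, 0, units = "W"))
  }
  trl <- run_gradient_descent(lin_eval, gd_config(1.8, seed = 79))
  # constant slope: every update shrinks by alpha_n * 50 until clipped
  steps <- -diff(trl$x_cmd)
  unclipped <- trl$x_cmd[-1] > gd_config(1.8)$domain[1] + 1e-12
  expect_equal(steps[unclipped],
               (gd_step_size(0:13, gd_config(1.8)) * 50)[unclipped])
})

test_that("Bayesian optimization recovers the argmin of a noiseless quadratic", {
  cfg <- bo_config(1.8, n_iterations = 8, seed = 83)
  tr <- run_bayes_opt(quad_bo_evaluator(10, 1.87), cfg)
  expect_equal(nrow(tr), 11)
  expect_equal(tr$phase, c(rep("init", 3), rep("ei", 8)))
  ei_x <- tr$x_cmd[tr$phase == "ei"]
  expect_lt(min(abs(ei_x - 1.87)), 0.01 * 1.87)
  # all proposals respect the domain
  expect_true(all(tr$x_cmd >= cfg$domain[1] & tr$x_cmd <= cfg$domain[2]))
})

test_that("a flat landscape neither crashes nor escapes the domain", {
  cfg <- bo_config(1.8, n_iterations = 4, seed = 89)
  tr <- run_bayes_opt(function(x, n) list(cost = 5), cfg)
  expect_equal(nrow(tr), 7)
  expect_true(all(tr$x_cmd >= cfg$domain[1] & tr$x_cmd <= cfg$domain[2]))
})

test_that("BO runs are deterministic given the seed and record hyperparameters", {
  cfg <- bo_config(1.8, n_iterations = 3, seed = 97)
  t1 <- run_bayes_opt(quad_bo_evaluator(12, 1.75), cfg)
  t2 <- run_bayes_opt(quad_bo_evaluator(12, 1.75), cfg)
  expect_identical(t1, t2)
  expect_true(all(is.finite(t1$hyp_sigma2[-1])))
  expect_true(all(is.finite(t1$hyp_l[-1])))
})

test_that("the noiseless incumbent is monotone in true cost across iterations", {
  withr::with_seed(101, seeds <- sample.int(1e6, 20))
  for (s in seeds) {
    subj <- noiseless_subject(x_pref = 1.8)
    cfg <- bo_config(1.8, n_iterations = 4, seed = s)
    tr <- run_bayes_opt(bo_evaluator(subj), cfg)
    # incumbent = best cost observed so far (exact costs when noiseless)
    inc <- cummin(tr$cost)
    expect_true(all(diff(true_cost(subj, tr$x_cmd[match(inc, tr$cost)])) <= 1e-9))
  }
})
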
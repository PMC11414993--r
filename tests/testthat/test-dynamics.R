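test_that("finite-difference derivative estimates have the expected accuracy", {
  t <- seq(0, 2, length.out = 41)
  lin <- tibble::tibble(t = t, x = 3 * t)
  d <- estimate_derivatives(lin, "x", scheme = "central")
  expect_equal(d$dx[2:40], rep(3, 39))
  # quadratic is exact at interior points for the central scheme
  quad <- tibble::tibble(t = t, x = t^2)
  dq <- estimate_derivatives(quad, "x", scheme = "central")
  expect_equal(dq$dx[2:40], 2 * t[2:40], tolerance = 1e-12)
  # second-order convergence on sin(t): halving the step quarters the error
  err <- vapply(c(41, 81), function(n) {
    tt <- seq(0, 2, length.out = n)
    s <- tibble::tibble(t = tt, x = sin(tt))
    ds <- estimate_derivatives(s, "x", scheme = "central")
    max(abs(ds$dx[2:(n - 1)] - cos(tt[2:(n - 1)])))
  }, numeric(1))
  expect_equal(err[1] / err[2], 4, tolerance = 0.15)
  # analytic scheme passes stored derivative columns through
  sim <- tibble::tibble(t = t, x = exp(t), dx = exp(t))
  expect_equal(estimate_derivatives(sim, "x", scheme = "analytic")$dx, exp(t))
  expect_error(estimate_derivatives(tibble::tibble(t = c(1, 0), x = 1:2), "x"),
               "strictly increasing")
})

test_that("one RK4 step of exponential decay matches the hand-worked value", {
  f <- function(t, Y) -Y
  arr <- klgp:::.rk4_integrate(f, matrix(1), c(0, 0.1))
  expect_equal(arr[2, 1, 1], 0.90483750, tolerance = 1e-9)
})

test_that("RK4 shows fourth-order global convergence", {
  f <- function(t, Y) -Y
  err <- vapply(c(0.1, 0.05), function(h) {
    arr <- klgp:::.rk4_integrate(f, matrix(1), seq(0, 1, by = h))
    abs(arr[dim(arr)[1], 1, 1] - exp(-1))
  }, numeric(1))
  expect_equal(err[1] / err[2], 16, tolerance = 1)
})

test_that("identified linear dynamics reproduce held-out trajectories", {
  dat <- make_decay_trajectories(n_curves = 5, n_points = 200)
  dm <- fit_dynamics(dat, states = c("x1", "x2"), curve = "curve",
                     scheme = "analytic", basis = basis12,
                     priors = prior_spec(n_draws = 800, burn_in = 400),
                     tol = 4, seed = 3)
  expect_s3_class(dm, "kl_dynamics")
  expect_named(dm$state_models, c("x1", "x2"))
  # derivative field: relative RMSE < 1% against the exact field dx1 = -x1
  grid <- tibble::tibble(x1 = seq(0.05, 1.8, length.out = 50),
                         x2 = seq(0.05, 1.8, length.out = 50))
  pd <- predict_derivative(dm, grid)
  # relative RMSE: error RMS over the RMS of the true derivative field
  expect_lt(sqrt(mean((pd$dx1 + grid$x1)^2) / mean(grid$x1^2)), 0.01)
  expect_lt(sqrt(mean((pd$dx2 + 0.5 * grid$x2)^2) / mean((0.5 * grid$x2)^2)),
            0.01)
  # posterior-mean prediction equals the mean of per-draw predictions
  r <- retained_draws(dm$state_models$x1$draws)
  per_draw <- vapply(seq_len(nrow(r$beta_draws)), function(i) {
    predict_derivative(dm, grid[1, ], coefficients = i)$dx1
  }, numeric(1))
  expect_equal(mean(per_draw), pd$dx1[1], tolerance = 1e-10)

  # held-out initial condition: forecast matches the closed-form solution
  t <- seq(0, 5, length.out = 150)
  fc <- integrate_dynamics(dm, c(x1 = 1.2, x2 = 1.2), t_grid = t,
                           n_ensemble = 40, seed = 5)
  expect_s3_class(fc, "kl_forecast")
  w <- forecast_means(fc)
  expect_lt(mean(abs(w$x1 - 1.2 * exp(-t))), 0.01)
  expect_lt(mean(abs(w$x2 - 1.2 * exp(-0.5 * t))), 0.01)
  # envelopes bracket the mean trajectory pointwise
  expect_true(all(fc$lower <= fc$mean + 1e-8))
  expect_true(all(fc$upper >= fc$mean - 1e-8))
  # default ensemble size of the uncertainty band
  expect_equal(dim(attr(fc, "draws"))[2], 40)
  expect_equal(formals(integrate_dynamics)$n_ensemble, 40L)
})

test_that("forcing channels enter the fitted field and the integrator", {
  # dx = -x + u with a known forcing; learn from several forced trajectories
  t <- seq(0, 4, length.out = 120)
  make_curve <- function(amp, i) {
    u <- amp * sin(t)
    # exact solution of dx = -x + amp sin t from x0 = 1
    x <- (1 + amp / 2) * exp(-t) + amp * (sin(t) - cos(t)) / 2
    tibble::tibble(curve = i, t = t, x = x, u = u, dx = -x + u)
  }
  dat <- dplyr::bind_rows(make_curve(0.5, 1), make_curve(1, 2),
                          make_curve(1.5, 3), make_curve(2, 4))
  dm <- fit_dynamics(dat, states = "x", forcing = "u", curve = "curve",
                     scheme = "analytic", basis = basis12,
                     priors = fast_prior(), tol = 3, seed = 6)
  fc <- integrate_dynamics(dm, c(x = 1), t_grid = t,
                           forcing = function(tt) c(u = 1.2 * sin(tt)),
                           n_ensemble = 20, seed = 2)
  w <- forecast_means(fc)
  truth <- (1 + 0.6) * exp(-t) + 1.2 * (sin(t) - cos(t)) / 2
  expect_lt(mean(abs(w$x - truth)), 0.02)
  # sampled forcing with linear interpolation gives the same field
  fc2 <- integrate_dynamics(dm, c(x = 1), t_grid = t,
                            forcing = tibble::tibble(t = t, u = 1.2 * sin(t)),
                            n_ensemble = 20, seed = 2)
  w2 <- forecast_means(fc2)
  expect_equal(w2$x, w$x, tolerance = 1e-3)
})

test_that("mean absolute error follows its definition", {
  a <- tibble::tibble(t = 1:3, x = c(1, 2, 3))
  expect_equal(mean_absolute_error(a, a, "x")$mae, 0)
  b <- dplyr::mutate(a, x = x + 2)
  expect_equal(mean_absolute_error(b, a, "x")$mae, 2)
  d <- tibble::tibble(t = 1:3, x = c(2, 2, 5))
  expect_equal(mean_absolute_error(d, a, "x")$mae, 1)
  misaligned <- tibble::tibble(t = c(1, 2, 3.5), x = 1:3)
  expect_error(mean_absolute_error(misaligned, a, "x"), "not aligned")
})
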
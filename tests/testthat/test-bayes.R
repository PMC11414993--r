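test_that("coefficient conditional matches hand substitution and limits", {
  # single observation, single intercept column
  out <- conditional_beta(matrix(1), 2, sigma2 = 1, tau2 = 1)
  expect_equal(out$mu, 1)
  expect_equal(out$Sigma, matrix(0.5))
  # linearity: zero target -> zero mean
  X <- matrix(rnorm(30), 10, 3)
  out0 <- conditional_beta(X, rep(0, 10), 1, 1)
  expect_equal(out0$mu, rep(0, 3))
  # ridge limit: huge tau2 approaches least squares
  set.seed(2)
  z <- rnorm(10)
  ls <- drop(solve(crossprod(X), crossprod(X, z)))
  out_inf <- conditional_beta(X, z, 1, 1e12)
  expect_equal(out_inf$mu, ls, tolerance = 1e-6)
  expect_true(isSymmetric(out_inf$Sigma))
})

test_that("inverse-gamma conditional parameters follow the closed forms", {
  p <- prior_spec(a = 4, b = 1, a_tau = 4, b_tau = 0.5)
  X <- matrix(rnorm(30), 10, 3)
  set.seed(3)
  z <- rnorm(10)
  s <- conditional_sigma2_params(X, z, beta = rep(0, 3), tau2 = 2, prior = p)
  expect_equal(s$a_star, 4 + 10 / 2 + 3 / 2)
  # beta at the conditional mean: quadratic form vanishes
  cb <- conditional_beta(X, z, 1, 2)
  s_mu <- conditional_sigma2_params(X, z, beta = cb$mu, tau2 = 2, prior = p)
  A <- crossprod(X) + diag(1 / 2, 3)
  expect_equal(s_mu$b_star,
               1 + 0.5 * (sum(z^2) - drop(crossprod(cb$mu, crossprod(X, z)))),
               tolerance = 1e-10)
  # ... and it equals the direct residual form b + RSS/2 + beta'beta/(2 tau2)
  beta <- rnorm(3)
  s_any <- conditional_sigma2_params(X, z, beta = beta, tau2 = 2, prior = p)
  expect_equal(s_any$b_star,
               1 + 0.5 * (sum((z - X %*% beta)^2) + sum(beta^2) / 2),
               tolerance = 1e-10)
  tt <- conditional_tau2_params(beta = c(1, 1), sigma2 = 1, prior = p)
  expect_equal(tt$a_star, 4 + 1)
  expect_equal(tt$b_star, 0.5 + 1)
  expect_equal(conditional_tau2_params(numeric(0), 1, p)$b_star, p$b_tau)
})

test_that("conditionals agree with brute-force dense-grid posterior evaluation", {
  # random small instances: evaluate the un-normalized joint posterior on a
  # dense grid and compare moments with the closed-form conditionals
  set.seed(11)
  for (rep in 1:3) {
    N <- sample(8:20, 1)
    X <- cbind(1, matrix(runif(N), N, 1))
    beta_true <- c(0.5, 1)
    z <- drop(X %*% beta_true) + rnorm(N, 0, 0.3)
    sigma2 <- 0.3^2; tau2 <- 4

    # beta | sigma2, tau2 on a 161x161 grid
    cb <- conditional_beta(X, z, sigma2, tau2)
    sd1 <- sqrt(cb$Sigma[1, 1]); sd2 <- sqrt(cb$Sigma[2, 2])
    g1 <- seq(cb$mu[1] - 6 * sd1, cb$mu[1] + 6 * sd1, length.out = 161)
    g2 <- seq(cb$mu[2] - 6 * sd2, cb$mu[2] + 6 * sd2, length.out = 161)
    gr <- expand.grid(b1 = g1, b2 = g2)
    logp <- apply(gr, 1, function(b) {
      -sum((z - X %*% b)^2) / (2 * sigma2) - sum(b^2) / (2 * sigma2 * tau2)
    })
    w <- exp(logp - max(logp)); w <- w / sum(w)
    mu_grid <- c(sum(w * gr$b1), sum(w * gr$b2))
    expect_equal(mu_grid, cb$mu, tolerance = 1e-3)
    var_grid <- c(sum(w * (gr$b1 - mu_grid[1])^2),
                  sum(w * (gr$b2 - mu_grid[2])^2))
    expect_equal(var_grid, diag(cb$Sigma), tolerance = 5e-3)

    # sigma2 | beta, tau2 against IG(a*, b*) moments on a dense grid
    pr <- prior_spec(a = 4, b = 1, a_tau = 4, b_tau = 1)
    beta <- beta_true + 0.1
    sp <- conditional_sigma2_params(X, z, beta, tau2, pr)
    s_grid <- seq(1e-4, 3, length.out = 20000)
    logd <- -(pr$a + N / 2 + ncol(X) / 2 + 1) * log(s_grid) -
      (pr$b + 0.5 * (sum((z - X %*% beta)^2) + sum(beta^2) / tau2)) / s_grid
    wd <- exp(logd - max(logd)); wd <- wd / sum(wd)
    m_grid <- sum(wd * s_grid)
    expect_equal(m_grid, sp$b_star / (sp$a_star - 1), tolerance = 1e-3)

    # tau2 | beta, sigma2 likewise
    tp <- conditional_tau2_params(beta, sigma2, pr)
    t_grid <- seq(1e-4, 50, length.out = 20000)
    logt <- -(pr$a_tau + length(beta) / 2 + 1) * log(t_grid) -
      (pr$b_tau + sum(beta^2) / (2 * sigma2)) / t_grid
    wt <- exp(logt - max(logt)); wt <- wt / sum(wt)
    expect_equal(sum(wt * t_grid), tp$b_star / (tp$a_star - 1),
                 tolerance = 5e-3)
  }
})

test_that("Gibbs draws are seeded, positive and stationary at the closed form", {
  set.seed(4)
  X <- cbind(1, matrix(runif(120), 60, 2))
  z <- drop(X %*% c(1, 2, -1)) + rnorm(60, 0, 0.2)
  pr <- prior_spec(n_draws = 1500, burn_in = 500)
  d1 <- gibbs_sample(X, z, pr, seed = 42)
  d2 <- gibbs_sample(X, z, pr, seed = 42)
  expect_identical(d1$beta_draws, d2$beta_draws)
  expect_identical(d1$sigma2_draws, d2$sigma2_draws)
  expect_true(all(d1$sigma2_draws > 0))
  expect_true(all(d1$tau2_draws > 0))
  # with fixed variances the beta draws average to the closed-form mean
  df <- gibbs_sample(X, z, prior_spec(n_draws = 4000, burn_in = 500),
                     seed = 9, fix_sigma2 = 0.04, fix_tau2 = 10)
  cb <- conditional_beta(X, z, 0.04, 10)
  bm <- colMeans(retained_draws(df)$beta_draws)
  mc_sd <- sqrt(diag(cb$Sigma) / 3500)
  expect_true(all(abs(bm - cb$mu) < 5 * mc_sd))
  expect_error(gibbs_sample(cbind(1, c(NA, 1)), c(1, 2)), "non-finite")
})

test_that("posterior recovers generating coefficients in a large sample", {
  set.seed(7)
  N <- 2000
  X <- cbind(1, matrix(runif(3 * N), N, 3))
  beta_true <- c(0.5, 2, -1.5, 0.8)
  z <- drop(X %*% beta_true) + rnorm(N, 0, 0.1)
  d <- retained_draws(gibbs_sample(X, z, prior_spec(), seed = 13))
  bm <- colMeans(d$beta_draws)
  bs <- apply(d$beta_draws, 2, sd)
  expect_true(all(abs(bm - beta_true) < 3 * bs))
  expect_equal(mean(d$sigma2_draws), 0.01, tolerance = 0.25)
})

test_that("information criteria follow their definitions", {
  set.seed(5)
  X <- cbind(1, runif(200))
  z <- drop(X %*% c(1, 2)) + rnorm(200, 0, 0.3)
  d <- gibbs_sample(X, z, fast_prior(), seed = 1)
  aic <- information_criterion(d, X, z, "aic")
  bic <- information_criterion(d, X, z, "bic")
  # BIC - AIC = P (ln N - 2) exactly, for any fit
  expect_equal(bic - aic, 2 * (log(200) - 2), tolerance = 1e-10)
  # a model containing the active term beats intercept-only on AIC
  X0 <- X[, 1, drop = FALSE]
  d0 <- gibbs_sample(X0, z, fast_prior(), seed = 1)
  expect_lt(aic, information_criterion(d0, X0, z, "aic"))
  # plug-in likelihood arithmetic: AIC = 2P - 2 lnL at the posterior means
  r <- retained_draws(d)
  lnL <- sum(dnorm(z, drop(X %*% colMeans(r$beta_draws)),
                   sqrt(mean(r$sigma2_draws)), log = TRUE))
  expect_equal(aic, 2 * 2 - 2 * lnL, tolerance = 1e-8)
})
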
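# Conjugate Gibbs sampler for the fixed-term linear model, plus BIC/AIC.

#' Prior and sampler settings for the linear Bayes model
#'
#' The model is `z = X beta + eps`, `eps ~ N(0, sigma^2)`, with conjugate
#' priors `beta ~ N(0, sigma^2 tau^2 I)`, `sigma^2 ~ IG(a, b)` and
#' `tau^2 ~ IG(a_tau, b_tau)`. A single `(sigma^2, tau^2)` pair scales all
#' coefficients, which is the common-scale assumption under which every
#' expansion coefficient has the same iid normal prior.
#'
#' @param a,b Shape and scale of the inverse-gamma prior on the observation
#'   variance `sigma^2` (scale `b` is in squared target units).
#' @param a_tau,b_tau Shape and scale of the inverse-gamma prior on the
#'   dimensionless coefficient-variance ratio `tau^2`.
#' @param n_draws Total Gibbs sweeps (default 2000).
#' @param burn_in Sweeps discarded from the front (default 1000).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(a = 4, b = 1, a_tau = 4, b_tau = 1,
                       n_draws = 2000, burn_in = 1000) {
  stopifnot(a > 0, b > 0, a_tau > 0, b_tau > 0,
            burn_in >= 0, burn_in < n_draws)
  structure(list(a = a, b = b, a_tau = a_tau, b_tau = b_tau,
                 n_draws = as.integer(n_draws), burn_in = as.integer(burn_in)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf(
    "<prior_spec> sigma2 ~ IG(%g, %g), tau2 ~ IG(%g, %g), %d draws (%d burn-in)\n",
    x$a, x$b, x$a_tau, x$b_tau, x$n_draws, x$burn_in))
  invisible(x)
}

#' Conditional posterior of the coefficients
#'
#' For fixed `(sigma^2, tau^2)` the coefficients are normal with
#' `mu = (X'X + I/tau^2)^{-1} X'z` and `Sigma = sigma^2 (X'X + I/tau^2)^{-1}`.
#'
#' @param X Design matrix (N x P).
#' @param z Target vector (length N).
#' @param sigma2,tau2 Positive variance parameters.
#' @return List with `mu` (length P) and `Sigma` (P x P).
#' @export
conditional_beta <- function(X, z, sigma2, tau2) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(z), sigma2 > 0, tau2 > 0)
  A <- crossprod(X) + diag(1 / tau2, ncol(X))
  R <- tryCatch(chol(A), error = function(e)
    stop("X'X + I/tau^2 is numerically singular (pathological tau^2?)",
         call. = FALSE))
  Ainv <- chol2inv(R)
  mu <- drop(Ainv %*% crossprod(X, z))
  list(mu = mu, Sigma = sigma2 * Ainv)
}

#' Conditional inverse-gamma parameters for the observation variance
#'
#' For fixed `(beta, tau^2)`: `a* = a + N/2 + P/2` and
#' `b* = b + [(mu - beta)'(X'X + I/tau^2)(mu - beta) + z'z - mu'X'z] / 2`.
#'
#' @inheritParams conditional_beta
#' @param beta Current coefficient vector.
#' @param prior A [prior_spec()].
#' @return List with `a_star`, `b_star`.
#' @export
conditional_sigma2_params <- function(X, z, beta, tau2, prior) {
  X <- as.matrix(X)
  N <- nrow(X); P <- ncol(X)
  stopifnot(length(z) == N, length(beta) == P)
  a_star <- prior$a + N / 2 + P / 2
  if (N == 0L && P == 0L) return(list(a_star = prior$a, b_star = prior$b))
  A <- crossprod(X) + diag(1 / tau2, P)
  Xtz <- crossprod(X, z)
  mu <- drop(solve(A, Xtz))
  d <- mu - beta
  b_star <- prior$b +
    0.5 * (drop(crossprod(d, A %*% d)) + sum(z^2) - drop(crossprod(mu, Xtz)))
  list(a_star = a_star, b_star = b_star)
}

#' Conditional inverse-gamma parameters for the prior-scale ratio
#'
#' For fixed `(beta, sigma^2)`: `a_tau* = a_tau + P/2` and
#' `b_tau* = b_tau + beta'beta / (2 sigma^2)`.
#'
#' @param beta Coefficient vector.
#' @param sigma2 Positive observation variance.
#' @param prior A [prior_spec()].
#' @return List with `a_star`, `b_star`.
#' @export
conditional_tau2_params <- function(beta, sigma2, prior) {
  stopifnot(sigma2 > 0)
  list(a_star = prior$a_tau + length(beta) / 2,
       b_star = prior$b_tau + sum(beta^2) / (2 * sigma2))
}

# draw from IG(shape, scale): 1 / rgamma(1, shape, rate = scale)
.rinvgamma <- function(shape, scale) 1 / stats::rgamma(1L, shape, rate = scale)

#' Gibbs sampler for the conjugate linear model
#'
#' Cycles the three closed-form conditionals (`beta`, then `sigma^2`, then
#' `tau^2`) starting from the prior means of the variances (or 1 where the
#' prior mean is undefined). Because `X'X + I/tau^2` shares eigenvectors with
#' `X'X` for every `tau^2`, the sampler eigendecomposes `X'X` once and then
#' draws `beta` in the eigenbasis, making each sweep O(P^2) instead of the
#' O(P^3) of a per-sweep factorization.
#'
#' @inheritParams conditional_beta
#' @param prior A [prior_spec()].
#' @param seed Integer seed; identical seeds give identical draws.
#' @param fix_sigma2,fix_tau2 Optional fixed values (the corresponding
#'   conditional update is skipped); used for validation against closed forms.
#' @return An object of class `kl_draws`: list with `beta_draws`
#'   (n_draws x P), `sigma2_draws`, `tau2_draws`, `burn_in`.
#' @export
gibbs_sample <- function(X, z, prior = prior_spec(), seed = 1L,
                         fix_sigma2 = NULL, fix_tau2 = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(z))) {
    stop("non-finite values in design matrix or target", call. = FALSE)
  }
  N <- nrow(X); P <- ncol(X)
  stopifnot(length(z) == N)

  XtX <- crossprod(X)
  Xtz <- drop(crossprod(X, z))
  ztz <- sum(z^2)

  sigma2 <- fix_sigma2 %||%
    (if (prior$a > 1) prior$b / (prior$a - 1) else 1)
  tau2 <- fix_tau2 %||%
    (if (prior$a_tau > 1) prior$b_tau / (prior$a_tau - 1) else 1)

  n_draws <- prior$n_draws
  beta_draws <- matrix(NA_real_, n_draws, P)
  sigma2_draws <- numeric(n_draws)
  tau2_draws <- numeric(n_draws)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  # spectral route: X'X = V diag(d) V', so (X'X + I/tau2)^{-1} = V diag(w) V'
  # with w = 1/(d + 1/tau2) for any tau2; one eigendecomposition serves all
  # sweeps.
  ed <- eigen(XtX, symmetric = TRUE)
  V <- ed$vectors
  d_eig <- pmax(ed$values, 0)
  c_vec <- drop(crossprod(V, Xtz))   # V'X'z

  for (s in seq_len(n_draws)) {
    w <- 1 / (d_eig + 1 / tau2)
    wc <- w * c_vec
    eta <- stats::rnorm(P)
    beta <- drop(V %*% (wc + sqrt(sigma2 * w) * eta))

    if (is.null(fix_sigma2)) {
      # (mu - beta)'A(mu - beta) = sigma2 * sum(eta^2);  mu'X'z = sum(w c^2)
      b_star <- prior$b +
        0.5 * (sigma2 * sum(eta^2) + ztz - sum(wc * c_vec))
      sigma2 <- .rinvgamma(prior$a + N / 2 + P / 2, b_star)
    }
    if (is.null(fix_tau2)) {
      tau2 <- .rinvgamma(prior$a_tau + P / 2,
                         prior$b_tau + sum(beta^2) / (2 * sigma2))
    }
    beta_draws[s, ] <- beta
    sigma2_draws[s] <- sigma2
    tau2_draws[s] <- tau2
  }

  structure(list(beta_draws = beta_draws, sigma2_draws = sigma2_draws,
                 tau2_draws = tau2_draws, burn_in = prior$burn_in),
            class = "kl_draws")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Retained (post-burn-in) draws
#'
#' @param draws A [gibbs_sample()] result.
#' @return `kl_draws` restricted to post-burn-in sweeps (burn_in reset to 0).
#' @export
retained_draws <- function(draws) {
  stopifnot(inherits(draws, "kl_draws"))
  keep <- seq.int(draws$burn_in + 1L, nrow(draws$beta_draws))
  structure(list(beta_draws = draws$beta_draws[keep, , drop = FALSE],
                 sigma2_draws = draws$sigma2_draws[keep],
                 tau2_draws = draws$tau2_draws[keep], burn_in = 0L),
            class = "kl_draws")
}

#' @export
print.kl_draws <- function(x, ...) {
  cat(sprintf("<kl_draws> %d sweeps (%d burn-in), %d coefficients\n",
              nrow(x$beta_draws), x$burn_in, ncol(x$beta_draws)))
  invisible(x)
}

#' Tidy summary of posterior draws
#'
#' @param x A `kl_draws` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: posterior mean, sd and a 95%
#'   credible interval from the retained draws.
#' @method tidy kl_draws
#' @export
tidy.kl_draws <- function(x, ...) {
  r <- retained_draws(x)
  B <- r$beta_draws
  tibble::tibble(
    coefficient = seq_len(ncol(B)),
    estimate = colMeans(B),
    std.error = apply(B, 2, stats::sd),
    conf.low = apply(B, 2, stats::quantile, 0.025),
    conf.high = apply(B, 2, stats::quantile, 0.975)
  )
}

#' Information criterion of a fitted term set
#'
#' `BIC = P log N - 2 log L` and `AIC = 2P - 2 log L`, where the likelihood is
#' the plug-in Gaussian likelihood evaluated at the posterior-mean
#' coefficients and posterior-mean observation variance over retained draws,
#' and `P` counts all coefficients including the intercept.
#'
#' @param draws A [gibbs_sample()] result.
#' @param X Design matrix used in the fit.
#' @param z Target vector.
#' @param which `"aic"` or `"bic"`.
#' @return Scalar criterion value.
#' @export
information_criterion <- function(draws, X, z, which = c("aic", "bic")) {
  which <- match.arg(tolower(which), c("aic", "bic"))
  X <- as.matrix(X)
  r <- retained_draws(draws)
  if (nrow(r$beta_draws) == 0L) stop("no retained draws", call. = FALSE)
  beta_hat <- colMeans(r$beta_draws)
  s2_hat <- mean(r$sigma2_draws)
  if (!is.finite(s2_hat) || s2_hat <= 0) {
    stop("degenerate likelihood: non-positive residual variance", call. = FALSE)
  }
  N <- nrow(X); P <- ncol(X)
  rss <- sum((z - drop(X %*% beta_hat))^2)
  loglik <- -N / 2 * log(2 * pi * s2_hat) - rss / (2 * s2_hat)
  if (which == "bic") P * log(N) - 2 * loglik else 2 * P - 2 * loglik
}
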
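# shared fixtures: small basis and synthetic regression/dynamics generators

basis12 <- kl_basis(12)

# z = sum_j coef_j * prod_k phi_{terms[j,k]}(x_k) + noise
make_expansion_data <- function(terms, coefs, n, noise_sd, seed,
                                basis = basis12) {
  set.seed(seed)
  x <- matrix(runif(n * ncol(terms)), n,
              dimnames = list(NULL, paste0("x", seq_len(ncol(terms)))))
  X <- build_design_matrix(terms, x, basis)
  z <- drop(X[, -1, drop = FALSE] %*% coefs) + rnorm(n, 0, noise_sd)
  list(x = x, z = z, signal_sd = stats::sd(drop(X[, -1, drop = FALSE] %*% coefs)))
}

# two-state linear decay system with exact derivatives, several curves
make_decay_trajectories <- function(n_curves = 4, n_points = 150, t_max = 5) {
  t <- seq(0, t_max, length.out = n_points)
  dplyr::bind_rows(lapply(seq_len(n_curves), function(i) {
    x0 <- i / 2
    tibble::tibble(curve = i, t = t,
                   x1 = x0 * exp(-t), x2 = x0 * exp(-0.5 * t),
                   dx1 = -x0 * exp(-t), dx2 = -0.5 * x0 * exp(-0.5 * t))
  }))
}

fast_prior <- function(...) prior_spec(..., n_draws = 500, burn_in = 250)
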
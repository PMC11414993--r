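# SIR epidemic benchmark: simulator and training/test set generators.

#' SIR model parameters
#'
#' @param gamma Recovery rate per unit time (default 0.5).
#' @param N_P Total (conserved) population size (default 1000).
#' @return An object of class `sir_params`.
#' @export
sir_params <- function(gamma = 0.5, N_P = 1000) {
  stopifnot(gamma > 0, N_P > 0)
  structure(list(gamma = gamma, N_P = N_P), class = "sir_params")
}

#' SIR right-hand side
#'
#' `dS = -B I S / N_P`, `dI = B I S / N_P - gamma I`, `dR = gamma I`.
#' The population is conserved (`dS + dI + dR = 0`), so only two of the three
#' states are independent.
#'
#' @param state Numeric vector `c(S, I, R)` (or matrix with those columns).
#' @param B Transmissibility (scalar, per unit time).
#' @param params An [sir_params()].
#' @return Derivatives in the same shape as `state`.
#' @export
sir_rhs <- function(state, B, params = sir_params()) {
  if (is.matrix(state)) {
    S <- state[, 1]; I <- state[, 2]; R <- state[, 3]
  } else {
    S <- state[1]; I <- state[2]; R <- state[3]
  }
  inf <- B * I * S / params$N_P
  rec <- params$gamma * I
  d <- unname(cbind(-inf, inf - rec, rec))
  if (is.matrix(state)) d else drop(d)
}

#' Simulate one SIR trajectory
#'
#' Fixed-step classical RK4 integration of the SIR equations under a constant
#' or time-varying transmissibility. Besides the states, the output carries
#' the sampled forcing `B(t)` and the exact (analytic) derivative channels,
#' which serve as noiseless regression targets for dynamics identification.
#'
#' @param x0 Numeric `c(S, I, R)` initial condition summing to `N_P`.
#' @param B Scalar transmissibility or a `function(t)` returning it.
#' @param params An [sir_params()].
#' @param t_grid Strictly increasing time grid.
#' @return Tibble with columns `t, S, I, R, B, dS, dI, dR`.
#' @export
simulate_sir <- function(x0, B, params = sir_params(),
                         t_grid = seq(0, 10, length.out = 345)) {
  stopifnot(length(x0) == 3L, all(x0 >= 0))
  if (abs(sum(x0) - params$N_P) > 1e-8 * params$N_P) {
    stop("initial condition must sum to N_P = ", params$N_P, call. = FALSE)
  }
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing",
                                   call. = FALSE)
  B_fn <- if (is.function(B)) B else function(t) B

  f <- function(t, Y) sir_rhs(Y, B_fn(t), params)
  arr <- .rk4_integrate(f, matrix(x0, 1L), t_grid)
  states <- arr[, 1L, ]
  if (min(states) < -1e-6 * params$N_P) {
    stop("SIR integration produced negative states beyond tolerance",
         call. = FALSE)
  }
  Bt <- vapply(t_grid, B_fn, numeric(1))
  d <- sir_rhs(states, Bt, params)
  tibble::tibble(t = t_grid, S = states[, 1], I = states[, 2], R = states[, 3],
                 B = Bt, dS = d[, 1], dI = d[, 2], dR = d[, 3])
}

# deterministic stratified initial-condition design over the feasible simplex
# {S0 + I0 + R0 = N_P, I0 > 0}: I0 in {10,50,100,200,400} crossed with
# R0 in {0,200,500}, truncated per-B to the counts below.
.sir_ic_design <- function() {
  g <- expand.grid(I0 = c(10, 50, 100, 200, 400), R0 = c(0, 200, 500))
  g$S0 <- 1000 - g$I0 - g$R0
  g
}

#' Generate the SIR training set
#'
#' 58 constant-transmissibility curves: `B` takes the six values 0.5 to 9.0 in
#' steps of 1.7, with (10, 10, 10, 10, 9, 9) initial conditions per value
#' drawn from a deterministic stratified coverage design on the state simplex.
#' Each curve is integrated on `t in [0, 10]` at 345 points, so the pooled set
#' holds roughly 20,000 training instances. Generation is fully deterministic;
#' `seed` is recorded in the metadata for provenance.
#'
#' @param seed Integer recorded in the curve metadata.
#' @param t_max,n_points Time horizon and samples per curve.
#' @param params An [sir_params()].
#' @return Tibble of stacked curves (`curve_id, t, S, I, R, B, dS, dI, dR`)
#'   with a `metadata` attribute (one row per curve: B, initial condition,
#'   seed) sufficient to regenerate each curve.
#' @export
sir_training_set <- function(seed = 1L, t_max = 10, n_points = 345,
                             params = sir_params()) {
  B_values <- seq(0.5, 9.0, by = 1.7)
  counts <- c(10L, 10L, 10L, 10L, 9L, 9L)
  ics <- .sir_ic_design()
  t_grid <- seq(0, t_max, length.out = n_points)

  meta <- list(); curves <- list(); id <- 0L
  for (j in seq_along(B_values)) {
    for (k in seq_len(counts[j])) {
      id <- id + 1L
      ic <- ics[k, ]
      sim <- simulate_sir(c(ic$S0, ic$I0, ic$R0), B_values[j], params, t_grid)
      curves[[id]] <- dplyr::mutate(sim, curve_id = id, .before = 1)
      meta[[id]] <- tibble::tibble(
        curve_id = id, B_type = "constant", B0 = B_values[j],
        B_param = NA_real_, S0 = ic$S0, I0 = ic$I0, R0 = ic$R0, seed = seed)
    }
  }
  out <- dplyr::bind_rows(curves)
  attr(out, "metadata") <- dplyr::bind_rows(meta)
  out
}

#' Reconstruct a transmissibility schedule from curve metadata
#'
#' Returns the `B(t)` function described by one metadata row of
#' [sir_training_set()] or [sir_test_set()], so every generated curve can be
#' regenerated (or re-integrated) from its metadata alone.
#'
#' @param type `"constant"`, `"ramp"` or `"sinusoid"`.
#' @param B0 Baseline transmissibility.
#' @param param Slope (ramp; levels off at t = 4) or amplitude (period-1
#'   sinusoid); ignored for `"constant"`.
#' @return A vectorized function of time.
#' @export
sir_forcing_fn <- function(type, B0, param = NA_real_) {
  switch(type,
    constant = function(t) rep(B0, length(t)),
    ramp = function(t) B0 + param * pmin(t, 4),
    sinusoid = function(t) B0 + param * sin(2 * pi * t),
    stop("unknown forcing type ", type, call. = FALSE)
  )
}

#' Generate the SIR test set
#'
#' 24 curves with time-varying transmissibility, eight per starting value
#' `B0 in {1.35, 4.75, 8.15}`: one ramp (slope +1 for the two lower `B0`,
#' -1 for 8.15, running from t = 0 to t = 4 and leveling off) and seven
#' period-1 sinusoids with amplitudes equally spaced on `[0.5, min(3, B0)]`
#' (the cap keeps `B(t) >= 0`). All curves start from the canonical epidemic
#' initial condition `(S, I, R) = (990, 10, 0)` and share the training grid.
#' Generation is fully deterministic; `seed` is recorded for provenance.
#'
#' @inheritParams sir_training_set
#' @return As [sir_training_set()], with metadata columns `B_type`
#'   (`"ramp"`/`"sinusoid"`), `B0` and `B_param` (slope or amplitude).
#' @export
sir_test_set <- function(seed = 1L, t_max = 10, n_points = 345,
                         params = sir_params()) {
  B0_values <- c(1.35, 4.75, 8.15)
  slopes <- c(1, 1, -1)
  x0 <- c(990, 10, 0)
  t_grid <- seq(0, t_max, length.out = n_points)

  meta <- list(); curves <- list(); id <- 0L
  for (j in seq_along(B0_values)) {
    B0 <- B0_values[j]
    specs <- dplyr::bind_rows(
      tibble::tibble(B_type = "ramp", B_param = slopes[j]),
      tibble::tibble(B_type = "sinusoid",
                     B_param = seq(0.5, min(3, B0), length.out = 7))
    )
    for (k in seq_len(nrow(specs))) {
      id <- id + 1L
      fn <- sir_forcing_fn(specs$B_type[k], B0, specs$B_param[k])
      sim <- simulate_sir(x0, fn, params, t_grid)
      curves[[id]] <- dplyr::mutate(sim, curve_id = id, .before = 1)
      meta[[id]] <- tibble::tibble(
        curve_id = id, B_type = specs$B_type[k], B0 = B0,
        B_param = specs$B_param[k], S0 = x0[1], I0 = x0[2], R0 = x0[3],
        seed = seed)
    }
  }
  out <- dplyr::bind_rows(curves)
  attr(out, "metadata") <- dplyr::bind_rows(meta)
  out
}

#' Min-max normalization of data channels
#'
#' Maps each requested channel to `[0, 1]` via `(x - min) / (max - min)` using
#' the pooled extremes of the supplied data; the returned spec supports
#' test-time reuse and inverse mapping. A degenerate (constant) channel maps
#' to 0.5 with a warning.
#'
#' @param data Data frame.
#' @param channels Character vector of columns to normalize.
#' @return List with `data` (tibble, requested channels normalized) and
#'   `spec` (tibble `channel, min, max`).
#' @export
minmax_normalize <- function(data, channels) {
  data <- tibble::as_tibble(data)
  stopifnot(all(channels %in% names(data)))
  spec <- tibble::tibble(
    channel = channels,
    min = vapply(channels, function(ch) min(data[[ch]]), numeric(1)),
    max = vapply(channels, function(ch) max(data[[ch]]), numeric(1))
  )
  if (!all(is.finite(spec$min)) || !all(is.finite(spec$max))) {
    stop("non-finite values in channels to normalize", call. = FALSE)
  }
  for (i in seq_along(channels)) {
    ch <- channels[i]
    if (spec$max[i] > spec$min[i]) {
      data[[ch]] <- (data[[ch]] - spec$min[i]) / (spec$max[i] - spec$min[i])
    } else {
      warning("channel '", ch, "' is constant; normalized to 0.5",
              call. = FALSE)
      data[[ch]] <- rep(0.5, nrow(data))
    }
  }
  list(data = data, spec = spec)
}

#' Invert a min-max normalization
#'
#' @param data Data frame with normalized channels.
#' @param spec Spec tibble from [minmax_normalize()].
#' @return Tibble with the spec's channels mapped back to original units.
#' @export
minmax_denormalize <- function(data, spec) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(spec))) {
    ch <- spec$channel[i]
    if (ch %in% names(data)) {
      data[[ch]] <- data[[ch]] * (spec$max[i] - spec$min[i]) + spec$min[i]
    }
  }
  data
}
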
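# Dynamic system identification: fit derivative models, integrate with RK4.

#' Estimate time derivatives of a timeseries
#'
#' The identification procedure is concurrent: time derivatives are modeled as
#' a static function of the concurrent states and forcing. This helper
#' produces the derivative targets. The `central` scheme uses second-order
#' central differences at interior points and first-order one-sided
#' differences at the endpoints (suited to measured data); the `analytic`
#' scheme passes through exact derivative columns already present in the data
#' (suited to simulator output).
#'
#' @param series Data frame with a time column and state columns.
#' @param states Character vector of state column names.
#' @param scheme `"central"` or `"analytic"`.
#' @param time Name of the time column (default `"t"`).
#' @param derivative_cols For `scheme = "analytic"`: named character vector
#'   mapping state name to its derivative column; defaults to `paste0("d", states)`.
#' @return Tibble with one derivative column per state, named `paste0("d", states)`,
#'   aligned row-for-row with `series`.
#' @export
estimate_derivatives <- function(series, states,
                                 scheme = c("central", "analytic"),
                                 time = "t", derivative_cols = NULL) {
  scheme <- match.arg(scheme)
  series <- tibble::as_tibble(series)
  t <- series[[time]]
  if (is.null(t)) stop("time column '", time, "' not found", call. = FALSE)
  if (any(diff(t) <= 0)) stop("time must be strictly increasing", call. = FALSE)

  if (scheme == "analytic") {
    derivative_cols <- derivative_cols %||% stats::setNames(paste0("d", states), states)
    missing <- setdiff(unname(derivative_cols), names(series))
    if (length(missing)) {
      stop("analytic scheme requires derivative columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out <- series[, unname(derivative_cols), drop = FALSE]
    names(out) <- paste0("d", states)
    return(tibble::as_tibble(out))
  }

  if (length(t) < 3L) stop("central differences need at least 3 time points",
                           call. = FALSE)
  d <- lapply(states, function(s) {
    x <- series[[s]]
    n <- length(x)
    dx <- numeric(n)
    dx[1] <- (x[2] - x[1]) / (t[2] - t[1])
    dx[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
    i <- 2:(n - 1)
    dx[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
    dx
  })
  names(d) <- paste0("d", states)
  tibble::as_tibble(d)
}

#' Fit a dynamics model by per-state forward selection
#'
#' Pools all time points of all trajectories into one static regression
#' problem per state: the target is that state's time derivative and the
#' inputs are the concurrent states and forcing channels, jointly min-max
#' normalized to `[0, 1]` using pooled training extremes. Each state gets its
#' own forward-selected BSS-ANOVA expansion.
#'
#' @param data Data frame of stacked trajectories (long over time), optionally
#'   grouped by a curve-identifier column.
#' @param states Character vector of state column names (each gets a model).
#' @param forcing Optional character vector of forcing column names.
#' @param time Time column name.
#' @param curve Optional curve-identifier column (needed for the central
#'   scheme so differences never straddle two trajectories).
#' @param scheme Derivative scheme passed to [estimate_derivatives()].
#' @param derivative_cols See [estimate_derivatives()].
#' @param basis A [kl_basis()].
#' @param priors A single [prior_spec()] applied to every state, or a named
#'   list of priors keyed by state name.
#' @param tol,criterion,seed,stage_cap Passed to [forward_select()]; each
#'   state's fit derives its own sub-seed from `seed`.
#' @param normalize_targets If `TRUE` (default) each state's derivative target
#'   is min-max normalized to `[0, 1]` with the same convention as the inputs,
#'   so the inverse-gamma prior scales refer to a unit-range target;
#'   predictions are mapped back to derivative units automatically.
#' @return An object of class `kl_dynamics`: per-state `kl_fit`s, the shared
#'   input layout, the pooled input normalization spec and the per-state
#'   target normalization spec.
#' @export
fit_dynamics <- function(data, states, forcing = NULL, time = "t",
                         curve = NULL, scheme = c("analytic", "central"),
                         derivative_cols = NULL, basis = kl_basis(),
                         priors = prior_spec(), tol = 3L,
                         criterion = "aic", seed = 1L, stage_cap = 20L,
                         normalize_targets = TRUE) {
  scheme <- match.arg(scheme)
  data <- tibble::as_tibble(data)
  inputs <- c(states, forcing)
  missing <- setdiff(c(time, inputs), names(data))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "),
                            call. = FALSE)

  pieces <- if (is.null(curve)) list(data) else split(data, data[[curve]])
  targets <- dplyr::bind_rows(lapply(pieces, estimate_derivatives,
                                     states = states, scheme = scheme,
                                     time = time,
                                     derivative_cols = derivative_cols))
  pooled <- dplyr::bind_rows(pieces)

  norm <- minmax_normalize(pooled, inputs)
  x_norm <- as.matrix(norm$data[, inputs, drop = FALSE])

  if (inherits(priors, "prior_spec")) {
    priors <- stats::setNames(rep(list(priors), length(states)), states)
  }
  stopifnot(all(states %in% names(priors)))

  target_spec <- tibble::tibble(
    state = states,
    min = vapply(states, function(s) {
      if (normalize_targets) min(targets[[paste0("d", s)]]) else 0
    }, numeric(1)),
    max = vapply(states, function(s) {
      if (normalize_targets) max(targets[[paste0("d", s)]]) else 1
    }, numeric(1))
  )

  state_models <- list()
  for (i in seq_along(states)) {
    s <- states[i]
    z <- targets[[paste0("d", s)]]
    if (normalize_targets) {
      if (target_spec$max[i] <= target_spec$min[i]) {
        stop("derivative target for state '", s, "' is constant; cannot ",
             "min-max normalize", call. = FALSE)
      }
      z <- (z - target_spec$min[i]) / (target_spec$max[i] - target_spec$min[i])
    }
    state_models[[s]] <- forward_select(
      x_norm, z, basis = basis, prior = priors[[s]],
      tol = tol, criterion = criterion, seed = as.integer(seed) + 7919L * i,
      stage_cap = stage_cap, normalization = norm$spec)
  }

  structure(list(state_models = state_models, states = states,
                 forcing = forcing, layout = inputs,
                 normalization = norm$spec, target_spec = target_spec,
                 time = time, seed = as.integer(seed)),
            class = "kl_dynamics")
}

#' @export
print.kl_dynamics <- function(x, ...) {
  cat("<kl_dynamics> learned dynamics for states:",
      paste(x$states, collapse = ", "),
      if (length(x$forcing)) paste0("(forcing: ",
                                    paste(x$forcing, collapse = ", "), ")"),
      "\n")
  for (s in x$states) {
    cat(sprintf("  d%s/dt: %d terms, %s = %.3f\n", s,
                nrow(x$state_models[[s]]$terms),
                toupper(x$state_models[[s]]$criterion),
                x$state_models[[s]]$best_criterion))
  }
  invisible(x)
}

#' Term-level summary of a dynamics model
#' @param x A `kl_dynamics`.
#' @param ... Unused.
#' @return Tibble of per-term coefficient summaries for every state model.
#' @method tidy kl_dynamics
#' @export
tidy.kl_dynamics <- function(x, ...) {
  dplyr::bind_rows(lapply(x$states, function(s) {
    dplyr::mutate(tidy(x$state_models[[s]]), state = s, .before = 1)
  }))
}

#' Per-state fit summaries of a dynamics model
#' @param x A `kl_dynamics`.
#' @param ... Unused.
#' @return One row per state model.
#' @method glance kl_dynamics
#' @export
glance.kl_dynamics <- function(x, ...) {
  dplyr::bind_rows(lapply(x$states, function(s) {
    dplyr::mutate(glance(x$state_models[[s]]), state = s, .before = 1)
  }))
}

#' Evaluate the learned derivative field
#'
#' @param model A `kl_dynamics`.
#' @param newdata Data frame with the model's state and forcing columns in
#'   original units.
#' @param coefficients `"mean"` or an integer retained-draw index.
#' @return Tibble with one column per state derivative (`dS`-style names).
#' @export
predict_derivative <- function(model, newdata, coefficients = "mean") {
  stopifnot(inherits(model, "kl_dynamics"))
  ts <- model$target_spec
  out <- lapply(seq_along(model$states), function(i) {
    s <- model$states[i]
    p <- as.numeric(predict(model$state_models[[s]], newdata,
                            coefficients = coefficients))
    p * (ts$max[i] - ts$min[i]) + ts$min[i]
  })
  names(out) <- paste0("d", model$states)
  tibble::as_tibble(out)
}

# classical RK4 step; f(t, Y) takes and returns a matrix (trajectories x states)
.rk4_step <- function(f, t, Y, h) {
  k1 <- f(t, Y)
  k2 <- f(t + h / 2, Y + h / 2 * k1)
  k3 <- f(t + h / 2, Y + h / 2 * k2)
  k4 <- f(t + h, Y + h * k3)
  Y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# generic fixed-grid RK4 over a matrix of trajectories; returns a
# (time x traj x state) array
.rk4_integrate <- function(f, Y0, t_grid) {
  n_t <- length(t_grid)
  out <- array(NA_real_, c(n_t, nrow(Y0), ncol(Y0)))
  out[1, , ] <- Y0
  Y <- Y0
  for (i in seq_len(n_t - 1L)) {
    Y <- .rk4_step(f, t_grid[i], Y, t_grid[i + 1L] - t_grid[i])
    out[i + 1L, , ] <- Y
  }
  out
}

# build a forcing evaluator u(t) -> named list of channel values from either
# a function or a sampled data frame (linear interpolation or zero-order hold)
.make_forcing_fn <- function(forcing, channels, time, hold = c("linear", "zoh")) {
  hold <- match.arg(hold)
  if (is.null(channels) || length(channels) == 0L) {
    return(function(t) NULL)
  }
  if (is.function(forcing)) {
    return(function(t) {
      v <- forcing(t)
      if (is.null(names(v))) names(v) <- channels
      v
    })
  }
  if (is.data.frame(forcing)) {
    tf <- forcing[[time]]
    fns <- lapply(channels, function(ch) {
      y <- forcing[[ch]]
      if (is.null(y)) stop("forcing column '", ch, "' not found", call. = FALSE)
      if (hold == "linear") {
        stats::approxfun(tf, y, rule = 2)
      } else {
        stats::approxfun(tf, y, method = "constant", rule = 2)
      }
    })
    names(fns) <- channels
    return(function(t) vapply(fns, function(f) f(t), numeric(1)))
  }
  stop("forcing must be a function of t or a sampled data frame", call. = FALSE)
}

#' Integrate learned dynamics with ensemble uncertainty
#'
#' Classical fourth-order Runge-Kutta on the supplied time grid (step = grid
#' spacing; forcing evaluated at half-steps, linearly interpolated when given
#' as samples). The mean trajectory uses posterior-mean coefficients; the
#' ensemble integrates `n_ensemble` trajectories under independently drawn
#' coefficient vectors from the retained Gibbs draws, and the 95% envelope is
#' the pointwise 2.5%/97.5% percentile band of the ensemble (no Gaussian
#' assumption). States are clamped to the normalized training box when the
#' integration wanders outside it; the number of clamped evaluations is
#' recorded. Trajectories that go non-finite are dropped from the envelope
#' with a warning.
#'
#' @param model A `kl_dynamics` from [fit_dynamics()].
#' @param x0 Named numeric vector of initial states (original units).
#' @param t_grid Strictly increasing time vector.
#' @param forcing Forcing as `function(t)` returning the forcing channel
#'   value(s), or a data frame with the time column and forcing columns.
#' @param n_ensemble Ensemble size for the uncertainty band (default 40).
#' @param seed Seed for the draw selection.
#' @param forcing_hold `"linear"` (default) or `"zoh"` interpolation for
#'   sampled forcing.
#' @return An object of class `kl_forecast`: tibble with columns `t`, `state`,
#'   `mean`, `lower`, `upper`; attributes `draws` (time x ensemble x state
#'   array), `n_failed`, `clamped`.
#' @export
integrate_dynamics <- function(model, x0, t_grid, forcing = NULL,
                               n_ensemble = 40L, seed = 1L,
                               forcing_hold = "linear") {
  stopifnot(inherits(model, "kl_dynamics"))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing",
                                   call. = FALSE)
  states <- model$states
  x0 <- x0[states]
  if (any(is.na(x0))) stop("x0 must name every model state", call. = FALSE)
  u_fn <- .make_forcing_fn(forcing, model$forcing, model$time, forcing_hold)

  # coefficient matrices: row 1 = posterior mean, rows 2.. = sampled draws
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  n_traj <- n_ensemble + 1L
  betas <- lapply(states, function(s) {
    r <- retained_draws(model$state_models[[s]]$draws)
    idx <- sample.int(nrow(r$beta_draws), n_ensemble, replace = TRUE)
    rbind(colMeans(r$beta_draws), r$beta_draws[idx, , drop = FALSE])
  })
  names(betas) <- states

  spec <- model$normalization
  clamped <- 0L
  rhs <- function(t, Y) {
    # Y: n_traj x n_states; assemble raw inputs (states + forcing at time t)
    alive <- rowSums(!is.finite(Y)) == 0L
    D <- matrix(NA_real_, nrow(Y), length(states))
    if (!any(alive)) return(D)
    inp <- Y[alive, , drop = FALSE]
    colnames(inp) <- states
    u <- u_fn(t)
    if (!is.null(u)) {
      for (ch in model$forcing) inp <- cbind(inp, rep(u[[ch]], nrow(inp)))
      colnames(inp) <- c(states, model$forcing)
    }
    nd <- .apply_norm(inp, spec)
    clamped <<- clamped + nd$clamped
    ts <- model$target_spec
    for (j in seq_along(states)) {
      s <- states[j]
      X <- build_design_matrix(model$state_models[[s]]$terms, nd$data,
                               model$state_models[[s]]$basis)
      D[alive, j] <- rowSums(X * betas[[s]][alive, , drop = FALSE]) *
        (ts$max[j] - ts$min[j]) + ts$min[j]
    }
    D
  }

  Y0 <- matrix(rep(as.numeric(x0), each = n_traj), n_traj, length(states))
  arr <- .rk4_integrate(rhs, Y0, t_grid)   # time x traj x state

  ens <- arr[, -1L, , drop = FALSE]
  ok <- apply(ens, 2L, function(m) all(is.finite(m)))
  n_failed <- sum(!ok)
  if (n_failed > 0) {
    warning(n_failed, " ensemble trajectories went non-finite and were ",
            "excluded from the envelopes", call. = FALSE)
    ens <- ens[, ok, , drop = FALSE]
  }

  qs <- apply(ens, c(1L, 3L), stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  fc <- tibble::tibble(
    t = rep(t_grid, times = length(states)),
    state = rep(states, each = length(t_grid)),
    mean = as.vector(arr[, 1L, ]),
    lower = as.vector(qs[1L, , ]),
    upper = as.vector(qs[2L, , ])
  )
  structure(fc, class = c("kl_forecast", class(fc)),
            draws = ens, n_failed = n_failed, clamped = clamped)
}

#' Plot an ensemble forecast
#'
#' @param object A `kl_forecast`.
#' @param observed Optional data frame with the time column `t` and observed
#'   state columns for overlay.
#' @param ... Unused.
#' @return A ggplot object: mean trajectory with 95% ensemble ribbon,
#'   facetted by state.
#' @method autoplot kl_forecast
#' @export
autoplot.kl_forecast <- function(object, observed = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$t, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(colour = "blue") +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time", y = "state") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    obs <- tidyr::pivot_longer(
      tibble::as_tibble(observed)[, c("t", unique(object$state))],
      -"t", names_to = "state", values_to = "value")
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(.data$t, .data$value),
                                 colour = "red", size = 0.6)
  }
  p
}

#' Mean absolute error between aligned trajectories
#'
#' @param predicted,observed Data frames sharing the time column and the state
#'   columns; time grids must be aligned.
#' @param states Character vector of state columns to score.
#' @param time Time column name.
#' @return Tibble with columns `state`, `mae`. Aggregation across curves is
#'   the unweighted mean of per-curve MAEs.
#' @export
mean_absolute_error <- function(predicted, observed, states, time = "t") {
  predicted <- tibble::as_tibble(predicted)
  observed <- tibble::as_tibble(observed)
  tp <- predicted[[time]]; to <- observed[[time]]
  if (length(tp) != length(to) || max(abs(tp - to)) > 1e-8 * max(1, max(abs(to)))) {
    stop("prediction and observation time grids are not aligned", call. = FALSE)
  }
  tibble::tibble(
    state = states,
    mae = vapply(states, function(s) {
      mean(abs(predicted[[s]] - observed[[s]]))
    }, numeric(1), USE.NAMES = FALSE)
  )
}

# wide view of a forecast (one column per state's mean), convenient for MAE
#' Convert a forecast to wide format
#'
#' @param forecast A `kl_forecast`.
#' @return Tibble with `t` and one column per state holding the mean forecast.
#' @export
forecast_means <- function(forecast) {
  tidyr::pivot_wider(tibble::as_tibble(forecast)[, c("t", "state", "mean")],
                     names_from = "state", values_from = "mean")
}
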
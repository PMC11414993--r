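# Forward variable selection over staged term sets.

#' Enumerate the substages of a selection stage
#'
#' Stage `I` introduces every term whose basis-function orders sum to `I`.
#' A substage is one multiset of orders (up to three factors, limited by the
#' number of inputs); substages run in order of ascending maximum order, so
#' terms built from lower-order basis functions enter first. Ties at equal
#' maximum are broken by ascending cardinality, then lexicographically.
#'
#' @param stage Positive integer stage index.
#' @param n_inputs Number of input features.
#' @return List of integer vectors (sorted multisets of basis orders).
#' @examples
#' enumerate_substage(2, 2) # list(c(1,1), 2)
#' @export
enumerate_substage <- function(stage, n_inputs) {
  stopifnot(stage >= 1, n_inputs >= 1)
  max_parts <- min(3L, n_inputs)
  parts <- .partitions(stage, max_parts)
  ord <- order(vapply(parts, max, 1L),
               lengths(parts),
               vapply(parts, function(p) paste(sprintf("%04d", p), collapse = ""),
                      ""))
  parts[ord]
}

# integer partitions of n into at most k parts, each part >= 1
.partitions <- function(n, k, max_part = n) {
  if (n == 0L) return(list(integer(0)))
  if (k == 0L) return(list())
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in .partitions(n - p, k - 1L, p)) {
      out[[length(out) + 1L]] <- c(rest, p)   # ascending order within multiset
    }
  }
  out
}

#' Expand an order-multiset into term-index rows
#'
#' Assigns the multiset's basis orders to distinct input columns in every
#' possible way: `choose(n_inputs, k)` input combinations times the distinct
#' permutations of the multiset. Rows are returned in a fixed deterministic
#' order.
#'
#' @param orders Integer vector of basis orders (a multiset, length <= 3).
#' @param n_inputs Number of input features.
#' @return Integer matrix, one row per term, `n_inputs` columns; entry = order
#'   of the basis function applied to that input (0 = input absent).
#' @examples
#' expand_terms(c(1, 2), 3) # 6 rows
#' @export
expand_terms <- function(orders, n_inputs) {
  k <- length(orders)
  if (k > n_inputs) {
    stop("multiset of ", k, " orders cannot be assigned to ", n_inputs,
         " inputs", call. = FALSE)
  }
  combos <- utils::combn(n_inputs, k, simplify = FALSE)
  perms <- unique(.permutations(orders))
  rows <- list()
  for (cb in combos) {
    for (pm in perms) {
      row <- integer(n_inputs)
      row[cb] <- pm
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Build the regression design matrix for a term set
#'
#' First column is the intercept (all ones); column `j + 1` is the product
#' over active inputs of the basis function of the indicated order evaluated
#' at that (normalized) input.
#'
#' @param terms Integer term-index matrix (rows = terms, cols = inputs);
#'   may have zero rows for an intercept-only design.
#' @param x Numeric matrix or data frame of inputs, all values in `[0, 1]`.
#' @param basis A [kl_basis()] object.
#' @return Numeric matrix with `nrow(x)` rows and `nrow(terms) + 1` columns.
#' @export
build_design_matrix <- function(terms, x, basis) {
  x <- as.matrix(x)
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("inputs must be normalized to [0,1] before building the design matrix",
         call. = FALSE)
  }
  n <- nrow(x)
  terms <- .as_term_matrix(terms, ncol(x))
  X <- matrix(1, n, nrow(terms) + 1L)
  if (nrow(terms) == 0L) return(X)
  # cache phi_k(x_j) for every (input, order) pair actually used
  cache <- new.env(parent = emptyenv())
  phi <- function(j, k) {
    key <- paste0(j, "_", k)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- eval_basis(basis, k, x[, j])
      cache[[key]] <- v
    }
    v
  }
  for (r in seq_len(nrow(terms))) {
    active <- which(terms[r, ] > 0L)
    col <- rep(1, n)
    for (j in active) col <- col * phi(j, terms[r, j])
    X[, r + 1L] <- col
  }
  X
}

.as_term_matrix <- function(terms, n_inputs) {
  if (is.null(terms)) return(matrix(integer(0), 0, n_inputs))
  terms <- as.matrix(terms)
  storage.mode(terms) <- "integer"
  if (nrow(terms) > 0L && ncol(terms) != n_inputs) {
    stop("term-index matrix has ", ncol(terms), " columns but there are ",
         n_inputs, " inputs", call. = FALSE)
  }
  terms
}

#' Forward variable selection for the KL-decomposed BSS-ANOVA GP
#'
#' Grows the expansion stage by stage. Stage `I` visits its substages in
#' [enumerate_substage()] order, appending all [expand_terms()] rows of the
#' substage to the cumulative term set, refitting by [gibbs_sample()] and
#' scoring with [information_criterion()]. A counter resets whenever a new
#' global minimum of the criterion is found and increments otherwise; the
#' search stops once the counter reaches `tol` (or at the stage cap) and the
#' model state at the global minimum is returned. The intercept-only model is
#' scored first so that pure-noise targets can select an empty term set.
#'
#' @param x Feature matrix or data frame, values normalized to `[0, 1]`.
#' @param z Numeric target vector.
#' @param basis A [kl_basis()] object; if a reached stage needs higher orders
#'   than the basis holds, the basis is extended transparently
#'   (`on_exhausted = "extend"`) or an error is raised (`"error"`).
#' @param prior A [prior_spec()].
#' @param tol Integer >= 1: number of consecutive non-improving substages
#'   tolerated before termination.
#' @param criterion `"aic"` (default, as used for the dynamic benchmarks) or
#'   `"bic"`.
#' @param seed Integer seed; each substage refit derives its own sub-seed.
#' @param stage_cap Hard upper bound on the stage index (termination guard).
#' @param on_exhausted `"extend"` or `"error"`.
#' @param normalization Optional per-feature `(min, max)` tibble recorded in
#'   the fitted model (used by the dynamics layer); defaults to the identity
#'   map on `[0, 1]`.
#' @return An object of class `kl_fit`: the selected term-index matrix,
#'   posterior draws at the optimum, the criterion trace, the per-feature
#'   normalization, and the basis.
#' @export
forward_select <- function(x, z, basis = kl_basis(), prior = prior_spec(),
                           tol = 3L, criterion = c("aic", "bic"), seed = 1L,
                           stage_cap = 20L, on_exhausted = c("extend", "error"),
                           normalization = NULL) {
  criterion <- match.arg(tolower(criterion), c("aic", "bic"))
  on_exhausted <- match.arg(on_exhausted)
  stopifnot(tol >= 1)
  x <- as.matrix(x)
  feature_names <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  colnames(x) <- feature_names
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("features must be normalized to [0,1] before forward_select",
         call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(z))) {
    stop("non-finite values in features or target", call. = FALSE)
  }
  n_inputs <- ncol(x)

  terms <- matrix(integer(0), 0, n_inputs, dimnames = list(NULL, feature_names))
  X <- matrix(1, nrow(x), 1L)
  trace <- list()
  best <- Inf
  best_state <- NULL
  counter <- 0L
  substage_id <- 0L

  score_state <- function(X, terms) {
    draws <- gibbs_sample(X, z, prior, seed = as.integer(seed) + substage_id)
    crit <- information_criterion(draws, X, z, which = criterion)
    list(draws = draws, crit = crit, terms = terms)
  }

  st <- score_state(X, terms)
  trace[[1L]] <- tibble::tibble(stage = 0L, substage = 0L, n_terms = 0L,
                                criterion = st$crit)
  best <- st$crit
  best_state <- st

  stage <- 1L
  repeat {
    if (stage > stage_cap) {
      warning("forward selection hit the stage cap (", stage_cap,
              ") before the tolerance criterion", call. = FALSE)
      break
    }
    if (stage > basis$n_basis) {
      if (on_exhausted == "error") {
        stop("stage ", stage, " requires basis order beyond n_basis = ",
             basis$n_basis, call. = FALSE)
      }
      basis <- kl_basis(max(stage, 2L * basis$n_basis), basis$grid_intervals)
    }
    done <- FALSE
    for (ms in enumerate_substage(stage, n_inputs)) {
      substage_id <- substage_id + 1L
      new_rows <- expand_terms(ms, n_inputs)
      colnames(new_rows) <- feature_names
      new_cols <- build_design_matrix(new_rows, x, basis)[, -1L, drop = FALSE]
      X <- cbind(X, new_cols)
      terms <- rbind(terms, new_rows)
      st <- score_state(X, terms)
      trace[[length(trace) + 1L]] <- tibble::tibble(
        stage = stage, substage = substage_id, n_terms = nrow(terms),
        criterion = st$crit)
      if (st$crit < best) {
        best <- st$crit
        best_state <- st
        counter <- 0L
      } else {
        counter <- counter + 1L
      }
      if (counter >= tol) { done <- TRUE; break }
    }
    if (done) break
    stage <- stage + 1L
  }

  norm_spec <- normalization %||% tibble::tibble(
    channel = feature_names, min = 0, max = 1)

  structure(list(
    terms = best_state$terms,
    draws = best_state$draws,
    criterion = criterion,
    criterion_trace = dplyr::bind_rows(trace),
    best_criterion = best,
    normalization = norm_spec,
    basis = basis,
    prior = prior,
    seed = as.integer(seed)
  ), class = "kl_fit")
}

#' Predict from a fitted expansion
#'
#' @param object A `kl_fit` from [forward_select()].
#' @param newdata Data frame or matrix of features in original units; the
#'   stored min-max normalization is applied and the result clamped to
#'   `[0, 1]` (the basis is only defined there); the number of clamped values
#'   is reported via the `"clamped"` attribute.
#' @param coefficients `"mean"` for the posterior-mean prediction, or an
#'   integer index of a retained draw.
#' @param ... Unused.
#' @return Numeric vector of predictions with attribute `clamped`.
#' @export
predict.kl_fit <- function(object, newdata, coefficients = "mean", ...) {
  x <- .apply_norm(newdata, object$normalization)
  X <- build_design_matrix(object$terms, x$data, object$basis)
  r <- retained_draws(object$draws)
  beta <- if (identical(coefficients, "mean")) {
    colMeans(r$beta_draws)
  } else {
    stopifnot(is.numeric(coefficients), length(coefficients) == 1L,
              coefficients >= 1, coefficients <= nrow(r$beta_draws))
    r$beta_draws[as.integer(coefficients), ]
  }
  out <- drop(X %*% beta)
  attr(out, "clamped") <- x$clamped
  out
}

# apply stored (min,max) spec; clamp to [0,1]; count clamps
.apply_norm <- function(newdata, spec) {
  x <- as.matrix(as.data.frame(newdata)[, spec$channel, drop = FALSE])
  if (!all(is.finite(x))) stop("non-finite prediction inputs", call. = FALSE)
  for (j in seq_len(ncol(x))) {
    lo <- spec$min[j]; hi <- spec$max[j]
    x[, j] <- if (hi > lo) (x[, j] - lo) / (hi - lo) else 0.5
  }
  clamped <- sum(x < 0 | x > 1)
  x[x < 0] <- 0
  x[x > 1] <- 1
  list(data = x, clamped = clamped)
}

#' @export
print.kl_fit <- function(x, ...) {
  cat(sprintf("<kl_fit> %d expansion terms (+ intercept), %s = %.4f\n",
              nrow(x$terms), toupper(x$criterion), x$best_criterion))
  invisible(x)
}

#' Tidy a fitted expansion
#'
#' @param x A `kl_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (intercept first): a readable
#'   term label, per-input basis orders, posterior mean, sd and 95% interval.
#' @method tidy kl_fit
#' @export
tidy.kl_fit <- function(x, ...) {
  co <- tidy(x$draws)
  labels <- c("(Intercept)", apply(x$terms, 1L, function(row) {
    active <- which(row > 0L)
    paste(sprintf("phi%d(%s)", row[active], colnames(x$terms)[active]),
          collapse = "*")
  }))
  dplyr::bind_cols(tibble::tibble(term = labels), co[, -1L])
}

#' One-line fit summary
#'
#' @param x A `kl_fit`.
#' @param ... Unused.
#' @return Tibble with term count, criterion, posterior-mean variances.
#' @method glance kl_fit
#' @export
glance.kl_fit <- function(x, ...) {
  r <- retained_draws(x$draws)
  tibble::tibble(
    n_terms = nrow(x$terms),
    criterion = x$criterion,
    best_criterion = x$best_criterion,
    sigma2 = mean(r$sigma2_draws),
    tau2 = mean(r$tau2_draws),
    n_draws_retained = nrow(r$beta_draws)
  )
}

#' Plot the criterion trace of a forward-selection run
#'
#' @param fit A `kl_fit`.
#' @return A ggplot object: criterion against cumulative term count, with the
#'   selected model marked.
#' @export
plot_criterion_trace <- function(fit) {
  stopifnot(inherits(fit, "kl_fit"))
  tr <- fit$criterion_trace
  ggplot2::ggplot(tr, ggplot2::aes(.data$n_terms, .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = tr[which.min(tr$criterion), ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "expansion terms", y = toupper(fit$criterion)) +
    ggplot2::theme_minimal()
}
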
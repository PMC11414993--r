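# Model archives and timeseries CSV input.

.klgp_format_version <- 1L

# read_json(simplifyVector = FALSE) returns data frames as lists of row
# records; rebuild a tibble from them
.rows_to_tibble <- function(rows) {
  dplyr::bind_rows(lapply(rows, function(r) tibble::as_tibble(r)))
}

.fit_to_archive <- function(fit) {
  list(
    terms = unname(fit$terms),
    feature_names = colnames(fit$terms) %||% fit$normalization$channel,
    criterion = fit$criterion,
    best_criterion = fit$best_criterion,
    criterion_trace = as.data.frame(fit$criterion_trace),
    beta_draws = unname(fit$draws$beta_draws),
    sigma2_draws = fit$draws$sigma2_draws,
    tau2_draws = fit$draws$tau2_draws,
    burn_in = fit$draws$burn_in,
    normalization = as.data.frame(fit$normalization),
    basis = list(grid_intervals = fit$basis$grid_intervals,
                 n_basis = fit$basis$n_basis,
                 scaling = "sqrt-lambda"),
    prior = unclass(fit$prior),
    seed = fit$seed
  )
}

.archive_to_fit <- function(a) {
  terms <- matrix(as.integer(unlist(a$terms)),
                  nrow = length(a$terms) %||% 0)
  if (is.list(a$terms)) terms <- do.call(rbind, lapply(a$terms, as.integer))
  if (is.null(terms) || length(terms) == 0L) {
    terms <- matrix(integer(0), 0, length(a$feature_names))
  }
  terms <- matrix(as.integer(terms), nrow = nrow(terms))
  colnames(terms) <- a$feature_names
  beta <- do.call(rbind, lapply(a$beta_draws, as.numeric))
  draws <- structure(list(beta_draws = beta,
                          sigma2_draws = as.numeric(a$sigma2_draws),
                          tau2_draws = as.numeric(a$tau2_draws),
                          burn_in = as.integer(a$burn_in)),
                     class = "kl_draws")
  prior <- do.call(prior_spec, a$prior)
  structure(list(
    terms = terms, draws = draws, criterion = a$criterion,
    criterion_trace = .rows_to_tibble(a$criterion_trace),
    best_criterion = as.numeric(a$best_criterion),
    normalization = .rows_to_tibble(a$normalization),
    basis = kl_basis(a$basis$n_basis, a$basis$grid_intervals),
    prior = prior, seed = as.integer(a$seed)
  ), class = "kl_fit")
}

#' Save a fitted model to a JSON archive
#'
#' The archive carries everything needed to re-predict without refitting:
#' term indices, all posterior draws, the normalization spec, the basis
#' fingerprint (the basis itself is rebuilt deterministically on load), the
#' prior configuration and the seed. A format version is embedded so that
#' archives from a newer format are rejected rather than misread.
#'
#' @param model A `kl_fit` or `kl_dynamics` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  payload <- if (inherits(model, "kl_fit")) {
    list(format_version = .klgp_format_version, type = "kl_fit",
         model = .fit_to_archive(model))
  } else if (inherits(model, "kl_dynamics")) {
    list(format_version = .klgp_format_version, type = "kl_dynamics",
         states = model$states, forcing = model$forcing,
         layout = model$layout, time = model$time, seed = model$seed,
         normalization = as.data.frame(model$normalization),
         target_spec = as.data.frame(model$target_spec),
         state_models = lapply(model$state_models, .fit_to_archive))
  } else {
    stop("save_model handles kl_fit and kl_dynamics objects", call. = FALSE)
  }
  ok <- tryCatch({
    # 17 significant digits identify every double uniquely, so reloaded
    # models predict bit-identically
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                         null = "null")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write model archive to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Load a model archive
#'
#' @param path Path written by [save_model()].
#' @return The restored `kl_fit` or `kl_dynamics` object.
#' @export
load_model <- function(path) {
  a <- jsonlite::read_json(path, simplifyVector = FALSE)
  v <- as.integer(a$format_version %||% NA)
  if (is.na(v) || v > .klgp_format_version) {
    stop("model archive format version ", a$format_version,
         " is newer than this package supports (", .klgp_format_version, ")",
         call. = FALSE)
  }
  if (identical(a$type, "kl_fit")) return(.archive_to_fit(a$model))
  if (identical(a$type, "kl_dynamics")) {
    sm <- lapply(a$state_models, .archive_to_fit)
    return(structure(list(
      state_models = sm,
      states = unlist(a$states), forcing = unlist(a$forcing),
      layout = unlist(a$layout),
      normalization = .rows_to_tibble(a$normalization),
      target_spec = .rows_to_tibble(a$target_spec),
      time = a$time, seed = as.integer(a$seed)
    ), class = "kl_dynamics"))
  }
  stop("unknown archive type '", a$type, "'", call. = FALSE)
}

#' Read a timeseries CSV with declared column roles
#'
#' Generic loader for external benchmarks: a CSV with a time column, one or
#' more state columns and optional forcing columns. Validates presence of the
#' declared columns, numeric content, finiteness and strictly increasing time.
#'
#' @param path CSV file path.
#' @param time Time column name.
#' @param states Character vector of state column names.
#' @param forcing Optional character vector of forcing column names.
#' @return Tibble restricted to the declared columns, time first.
#' @export
read_timeseries_csv <- function(path, time = "t", states, forcing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  wanted <- c(time, states, forcing)
  missing <- setdiff(wanted, names(df))
  if (length(missing)) {
    stop("missing declared columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, wanted]
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  bad <- wanted[!vapply(df, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric values in columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(df) || !all(vapply(df, function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite values in declared columns", call. = FALSE)
  }
  if (any(diff(df[[time]]) <= 0)) {
    stop("time column '", time, "' must be strictly increasing", call. = FALSE)
  }
  df
}
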
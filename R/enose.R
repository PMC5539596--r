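#' Per-column min-max normalization statistics
#'
#' Computed over the training database only; applying them to later data can
#' legitimately produce values outside [0, 1] (no clipping). Each column —
#' each sensor, each odorant — gets its own MIN/MAX because sensors and
#' odorants live on incommensurate scales.
#'
#' @param x Numeric matrix (samples x columns), column names kept.
#' @return A list of class `norm_stats` with per-column `min` and `max`.
#' @export
norm_stats <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in data")
  mn <- apply(x, 2, min); mx <- apply(x, 2, max)
  if (any(mx <= mn)) {
    stop("degenerate column(s) with max = min: ",
         paste(colnames(x)[mx <= mn], collapse = ", "))
  }
  structure(list(min = mn, max = mx), class = "norm_stats")
}

#' Min-max normalize
#'
#' y = (x - MIN) / (MAX - MIN), column-wise. Exact inverse: [denormalize()].
#'
#' @param x Numeric vector (one row) or matrix (samples x columns).
#' @param stats A [norm_stats()].
#' @return Normalized values; training-range values map into [0, 1], values
#'   outside the training range map outside it (not clipped).
#' @export
normalize <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  one_row <- is.null(dim(x))
  x <- if (one_row) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != length(stats$min)) {
    stop("expected ", length(stats$min), " columns, got ", ncol(x))
  }
  y <- sweep(sweep(x, 2, stats$min), 2, stats$max - stats$min, "/")
  if (one_row) y[1, ] else y
}

#' @rdname normalize
#' @param y Normalized values to map back to the raw scale.
#' @export
denormalize <- function(y, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  one_row <- is.null(dim(y))
  y <- if (one_row) matrix(y, nrow = 1) else as.matrix(y)
  if (ncol(y) != length(stats$min)) {
    stop("expected ", length(stats$min), " columns, got ", ncol(y))
  }
  x <- sweep(sweep(y, 2, stats$max - stats$min, "*"), 2, stats$min, "+")
  if (one_row) x[1, ] else x
}

#' Configuration of the neural concentration estimator
#'
#' Defaults mirror the architecture selected for the aldehyde array: five
#' hidden layers of twenty logistic-sigmoid neurons each, identity output,
#' input width equal to the number of sensors and output width equal to the
#' number of target odorants. Training minimizes mean squared error on
#' min-max-normalized data with a seeded quasi-Newton optimizer (L-BFGS-B,
#' multi-start); given the same database and seed, training is reproducible.
#'
#' @param hidden_layers Number of hidden layers (default 5).
#' @param neurons_per_layer Neurons in each hidden layer (default 20).
#' @param max_iterations Optimizer iteration cap per start (default 2000).
#' @param n_starts Random restarts; the lowest-training-loss fit wins
#'   (default 3).
#' @param seed RNG seed for the weight initializations.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(hidden_layers = 5L, neurons_per_layer = 20L,
                             max_iterations = 2000L, n_starts = 3L,
                             seed = 1L) {
  stopifnot(hidden_layers >= 1L, neurons_per_layer >= 1L,
            max_iterations >= 1L, n_starts >= 1L)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 neurons_per_layer = as.integer(neurons_per_layer),
                 max_iterations = as.integer(max_iterations),
                 n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "estimator_config")
}

#' Train the concentration estimator on a sensor training database
#'
#' Fits a fully connected feedforward regressor mapping normalized sensor
#' signals to normalized concentrations. Both normalization statistics are
#' stored inside the estimator so prediction can renormalize raw signals and
#' denormalize network outputs transparently.
#'
#' @param db A training database: list with `signals` (samples x sensors
#'   matrix), `concentrations` (samples x odorants matrix), and optionally
#'   `sensors` / `odorants` name vectors (taken from column names otherwise).
#'   See [gen_sensor_training_db()] or [read_training_db_csv()].
#' @param config An [estimator_config()].
#' @return An object of class `concentration_estimator`.
#' @export
train_estimator <- function(db, config = estimator_config()) {
  stopifnot(inherits(config, "estimator_config"))
  X <- as.matrix(db$signals); Y <- as.matrix(db$concentrations)
  if (nrow(X) != nrow(Y)) stop("signal and concentration row counts differ")
  if (nrow(X) < 1L) stop("empty training database")
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("non-finite values in training database")
  }
  if (any(Y < 0)) stop("negative concentrations in training database")
  sensors <- db$sensors %||% colnames(X) %||%
    paste0("sensor_", seq_len(ncol(X)))
  odorants <- db$odorants %||% colnames(Y) %||%
    paste0("odorant_", seq_len(ncol(Y)))
  if (nrow(X) == 1L) {
    warning("training database has a single sample; the fit is ",
            "underdetermined")
    # a single row makes per-column min = max; widen artificially
    stats_in <- structure(list(min = X[1, ] - 1, max = X[1, ] + 1),
                          class = "norm_stats")
    stats_out <- structure(list(min = pmax(Y[1, ] - 1, 0), max = Y[1, ] + 1),
                           class = "norm_stats")
  } else {
    stats_in <- norm_stats(X)
    stats_out <- norm_stats(Y)
  }
  Xn <- normalize(X, stats_in)
  Yn <- normalize(Y, stats_out)
  sizes <- mlp_sizes(ncol(X), config$hidden_layers, config$neurons_per_layer,
                     ncol(Y))
  set.seed(config$seed)
  fit <- mlp_train(Xn, Yn, sizes, config$max_iterations, config$n_starts)
  structure(list(par = fit$par, sizes = sizes, loss = fit$loss,
                 stats_in = stats_in, stats_out = stats_out,
                 sensors = sensors, odorants = odorants, config = config),
            class = "concentration_estimator")
}

#' @export
print.concentration_estimator <- function(x, ...) {
  cat(sprintf(
    "<concentration estimator> %s -> %s\n  architecture %s, train MSE %.3g\n",
    paste(x$sensors, collapse = ","), paste(x$odorants, collapse = ","),
    paste(x$sizes, collapse = "-"), 2 * x$loss))
  invisible(x)
}

#' Estimate constituent concentrations from sensor signals
#'
#' Normalizes the raw signals with the training statistics, runs the forward
#' pass, and denormalizes the outputs to mg/m^3. Negative outputs (possible
#' from the unconstrained network near zero) are clamped to 0.
#'
#' @param signals Numeric vector (one reading per sensor) or matrix
#'   (samples x sensors); length/width must match the training sensor count.
#' @param estimator A trained [train_estimator()] result.
#' @return Named concentration vector (mg/m^3), or a matrix for matrix input.
#' @export
predict_concentrations <- function(signals, estimator) {
  stopifnot(inherits(estimator, "concentration_estimator"))
  one_row <- is.null(dim(signals))
  X <- if (one_row) matrix(as.numeric(signals), nrow = 1) else
    as.matrix(signals)
  if (ncol(X) != length(estimator$sensors)) {
    stop("expected ", length(estimator$sensors), " sensor signals, got ",
         ncol(X))
  }
  net <- mlp_unpack(estimator$par, estimator$sizes)
  Yn <- mlp_forward(normalize(X, estimator$stats_in), net)
  Y <- pmax(denormalize(Yn, estimator$stats_out), 0)
  colnames(Y) <- estimator$odorants
  if (one_row) Y[1, ] else Y
}

#' Average relative error between predicted and reference concentrations
#'
#' 100 * mean over all (sample, odorant) pairs with positive reference of
#' |predicted - reference| / reference. Pairs with a zero reference are
#' excluded (their relative error is undefined); the exclusion count is
#' reported via `message()`.
#'
#' @param predicted,reference Numeric matrices (or vectors) of equal shape.
#' @return ARE in percent.
#' @examples
#' average_relative_error(c(90, 120), c(100, 100))  # 15
#' @export
average_relative_error <- function(predicted, reference) {
  p <- as.matrix(predicted); r <- as.matrix(reference)
  if (!all(dim(p) == dim(r))) stop("shapes of predicted and reference differ")
  use <- r > 0
  if (!any(use)) stop("no positive reference entries to compare against")
  n_excluded <- sum(!use)
  if (n_excluded > 0) {
    message("excluding ", n_excluded,
            " zero-reference pair(s) from the ARE mean")
  }
  100 * mean(abs(p[use] - r[use]) / r[use])
}

#' End-to-end odor intensity from sensor signals
#'
#' The full electronic-nose pipeline for one reading: estimate constituent
#' concentrations from the array signals, then evaluate the family's modified
#' vector model on them.
#'
#' @param signals Numeric vector, one reading per sensor.
#' @param estimator A trained [train_estimator()] result whose target
#'   odorants are all members of `family`.
#' @param family A [family_model()].
#' @return A list: `oi` (mixture odor intensity) and `constituents` (data
#'   frame of estimated concentration, OAV and OI per odorant).
#' @export
signals_to_oi <- function(signals, estimator, family) {
  stopifnot(inherits(family, "family_model"))
  known <- c(family$members$name,
             if ("abbreviation" %in% names(family$members))
               family$members$abbreviation)
  bad <- setdiff(estimator$odorants, known)
  if (length(bad) > 0) {
    stop("estimator odorant(s) not in family '", family$name, "': ",
         paste(bad, collapse = ", "))
  }
  conc <- predict_concentrations(signals, estimator)
  res <- predict_mixture_oi(odor_sample(conc), family, breakdown = TRUE)
  list(oi = res$oi, constituents = res$constituents)
}

#' Persist / restore a trained estimator
#'
#' The estimator is stored as a single JSON file bundling the network
#' weights, both sets of normalization statistics, the sensor and odorant
#' orders, and the training configuration.
#'
#' @param estimator A `concentration_estimator`.
#' @param path Destination file.
#' @return `save_estimator` returns `path` invisibly; `load_estimator`
#'   returns the estimator.
#' @export
save_estimator <- function(estimator, path) {
  stopifnot(inherits(estimator, "concentration_estimator"))
  obj <- list(
    par = estimator$par, sizes = estimator$sizes, loss = estimator$loss,
    stats_in = list(min = estimator$stats_in$min,
                    max = estimator$stats_in$max),
    stats_out = list(min = estimator$stats_out$min,
                     max = estimator$stats_out$max),
    sensors = estimator$sensors, odorants = estimator$odorants,
    config = unclass(estimator$config)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    par = as.numeric(obj$par), sizes = as.integer(obj$sizes),
    loss = as.numeric(obj$loss),
    stats_in = structure(list(min = unlist(obj$stats_in$min),
                              max = unlist(obj$stats_in$max)),
                         class = "norm_stats"),
    stats_out = structure(list(min = unlist(obj$stats_out$min),
                               max = unlist(obj$stats_out$max)),
                          class = "norm_stats"),
    sensors = as.character(obj$sensors),
    odorants = as.character(obj$odorants),
    config = do.call(estimator_config, obj$config)
  ), class = "concentration_estimator")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
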
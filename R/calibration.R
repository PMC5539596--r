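#' Fit the psychophysical law from single-odorant panel records
#'
#' Pools all records across the family's odorants and fits one ordinary
#' least-squares line OI = k * ln(OAV) + b. Pooling reflects the family
#' assumption: odorants of one functional group share a single law, so one
#' line is fitted jointly rather than per odorant. Records with OI = 0
#' (censored sub-threshold ratings, which would bias the unclamped line) are
#' excluded by default, with the count reported via `message()`.
#'
#' @param records Data frame with columns `odorant`, `concentration_mg_m3`,
#'   `oi` — one row per rated sample of a single odorant.
#' @param registry Odorant registry supplying the thresholds for ln(OAV).
#' @param drop_zero_oi Exclude OI = 0 records from the fit (default `TRUE`).
#' @return A [psychophysical_law()] whose `diagnostics` list carries `n`,
#'   `n_dropped`, residual standard error `sigma`, `r_squared`, and a
#'   `per_odorant` table of per-odorant slopes as a diagnostic of pooling.
#' @examples
#' reg <- default_registry()
#' rec <- data.frame(odorant = "Acetaldehyde",
#'                   concentration_mg_m3 = 0.039 * exp(c(1, 2, 3)),
#'                   oi = 5.6 * c(1, 2, 3) - 5.6)
#' fit_psychophysical_law(rec, reg)
#' @export
fit_psychophysical_law <- function(records, registry = default_registry(),
                                   drop_zero_oi = TRUE) {
  check_columns(records, c("odorant", "concentration_mg_m3", "oi"),
                "singles panel")
  if (any(records$concentration_mg_m3 <= 0)) {
    stop("all concentrations must be positive to form ln(OAV)")
  }
  thr <- vapply(records$odorant,
                function(o) get_odorant(registry, o)$odor_threshold,
                numeric(1))
  df <- data.frame(odorant = records$odorant,
                   lnoav = log(records$concentration_mg_m3 / thr),
                   oi = records$oi)
  n_dropped <- 0L
  if (drop_zero_oi) {
    keep <- df$oi > 0
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      message("dropping ", n_dropped,
              " record(s) with OI = 0 (sub-threshold censoring)")
    }
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) < 2L || length(unique(df$lnoav)) < 2L) {
    stop("degenerate fit: need at least two records with distinct ln(OAV)")
  }
  fit <- stats::lm(oi ~ lnoav, data = df)
  k <- unname(stats::coef(fit)["lnoav"])
  b <- unname(stats::coef(fit)["(Intercept)"])
  if (k <= 0) {
    stop("fitted slope is not positive; ",
         "records do not show intensity growing with ln(OAV)")
  }
  s <- suppressWarnings(summary(fit))  # noiseless data fits exactly
  per_odorant <- do.call(rbind, lapply(split(df, df$odorant), function(d) {
    if (nrow(d) < 2L || length(unique(d$lnoav)) < 2L) return(NULL)
    f <- stats::lm(oi ~ lnoav, data = d)
    data.frame(odorant = d$odorant[1],
               k = unname(stats::coef(f)["lnoav"]),
               b = unname(stats::coef(f)["(Intercept)"]),
               n = nrow(d))
  }))
  psychophysical_law(k, b, diagnostics = list(
    n = nrow(df), n_dropped = n_dropped,
    sigma = s$sigma, r_squared = s$r.squared,
    per_odorant = per_odorant
  ))
}

#' Fit the mixture slope OI_mix = s * OI_sum
#'
#' Through-origin least squares of the measured mixture intensity on the sum
#' of its unmixed constituents' intensities, s = sum(x*y) / sum(x^2). The
#' origin constraint reflects that zero summed intensity must map to zero
#' mixture intensity; a free-intercept variant is available for sensitivity
#' analysis.
#'
#' @param records Data frame with columns `oi_sum` (summed unmixed component
#'   intensities) and `oi_mix` (measured mixture intensity); see
#'   [mixture_records()] to build it from per-component intensities.
#' @param intercept Fit a free intercept instead of constraining through the
#'   origin (default `FALSE`).
#' @return A list of class `mixture_slope_fit`: `slope`, `intercept` (0 under
#'   the constraint), `sigma`, `n`.
#' @examples
#' rec <- data.frame(oi_sum = c(10, 20), oi_mix = c(6.2, 12.4))
#' fit_mixture_slope(rec)$slope  # 0.62
#' @export
fit_mixture_slope <- function(records, intercept = FALSE) {
  check_columns(records, c("oi_sum", "oi_mix"), "mixtures panel")
  if (any(records$oi_sum < 0) || any(records$oi_mix < 0)) {
    stop("intensities must be non-negative")
  }
  if (nrow(records) < 1L || all(records$oi_sum == 0)) {
    stop("degenerate fit: need at least one record with OI_sum > 0")
  }
  fit <- if (intercept) {
    stats::lm(oi_mix ~ oi_sum, data = records)
  } else {
    stats::lm(oi_mix ~ 0 + oi_sum, data = records)
  }
  cf <- stats::coef(fit)
  structure(list(
    slope = unname(cf["oi_sum"]),
    intercept = if (intercept) unname(cf["(Intercept)"]) else 0,
    sigma = suppressWarnings(summary(fit))$sigma,
    n = nrow(records)
  ), class = "mixture_slope_fit")
}

#' @export
print.mixture_slope_fit <- function(x, ...) {
  cat(sprintf("<mixture slope fit> OI_mix = %.4f * OI_sum", x$slope))
  if (x$intercept != 0) cat(sprintf(" + %.4f", x$intercept))
  cat(sprintf("  (n = %d, sigma = %.4g)\n", x$n, x$sigma))
  invisible(x)
}

#' Build mixture records from per-component intensities
#'
#' @param components Matrix or data frame of unmixed component intensities,
#'   one row per mixture sample (>= 2 columns).
#' @param oi_mix Measured mixture intensities, one per row.
#' @return Data frame with `oi_sum` and `oi_mix` columns suitable for
#'   [fit_mixture_slope()].
#' @export
mixture_records <- function(components, oi_mix) {
  components <- as.matrix(components)
  if (ncol(components) < 2L) stop("mixtures need at least two components")
  if (nrow(components) != length(oi_mix)) {
    stop("one mixture intensity per component row required")
  }
  if (any(components < 0) || any(oi_mix < 0)) {
    stop("intensities must be non-negative")
  }
  data.frame(oi_sum = rowSums(components), oi_mix = as.numeric(oi_mix))
}

#' Calibrate a full family model from panel data
#'
#' Composes the two fits: the psychophysical law from single-odorant records
#' and the interaction coefficient from the through-origin mixture slope
#' (cos(alpha) = 2 s^2 - 1). Members are the odorants appearing in the
#' singles data.
#'
#' @param singles Singles panel data frame (see [fit_psychophysical_law()]).
#' @param mixtures Mixtures panel data frame (see [fit_mixture_slope()]).
#' @param registry Odorant registry.
#' @param name Family label for the resulting model.
#' @inheritParams fit_psychophysical_law
#' @return A [family_model()] with fit diagnostics attached; the slope fit is
#'   stored in `$slope_fit`.
#' @export
calibrate_family <- function(singles, mixtures, registry = default_registry(),
                             name = "calibrated", drop_zero_oi = TRUE) {
  law <- fit_psychophysical_law(singles, registry, drop_zero_oi = drop_zero_oi)
  slope_fit <- fit_mixture_slope(mixtures)
  members <- registry[registry$name %in% unique(
    vapply(singles$odorant, function(o) get_odorant(registry, o)$name,
           character(1))), , drop = FALSE]
  fam <- family_model(law, cos_alpha_from_slope(slope_fit$slope), members,
                      name = name, slope = slope_fit$slope)
  fam$slope_fit <- slope_fit
  fam
}

# internal: schema check with the offending column named
check_columns <- function(df, required, what) {
  if (!is.data.frame(df)) stop(what, " must be a data frame")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}
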
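#' Log-linear psychophysical law OI = k * ln(OAV) + b
#'
#' Relates perceived odor intensity (OI, on an n-butanol referencing scale) to
#' the natural logarithm of the odor activity value. `k` is the slope in OI
#' units per ln(OAV) unit, `b` the intercept in OI units (negative for
#' odorants that are imperceptible at their threshold, since OAV = 1 gives
#' OI = b).
#'
#' @param k Slope; must be positive (intensity grows with concentration).
#' @param b Intercept.
#' @param diagnostics Optional list of fit diagnostics (attached by
#'   [fit_psychophysical_law()]).
#' @return An object of class `psychophysical_law`.
#' @examples
#' psychophysical_law(5.6, -5.6)
#' @export
psychophysical_law <- function(k, b, diagnostics = NULL) {
  k <- as.numeric(k); b <- as.numeric(b)
  stopifnot(length(k) == 1L, length(b) == 1L, is.finite(k), is.finite(b))
  if (k <= 0) stop("k must be positive: OI must grow with concentration")
  structure(list(k = k, b = b, diagnostics = diagnostics),
            class = "psychophysical_law")
}

#' @export
print.psychophysical_law <- function(x, ...) {
  cat(sprintf("<psychophysical law> OI = %.4g * ln(OAV) + %.4g\n", x$k, x$b))
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf("  fit: n = %d, sigma = %.4g, R^2 = %.4f\n",
                d$n, d$sigma, d$r_squared))
  }
  invisible(x)
}

#' Family model: one law and one interaction coefficient per odorant family
#'
#' The modified vector model's central object. Odorants of one family (same
#' functional group, similar structure and odor type) empirically share a
#' single psychophysical law and a single interaction coefficient cos(alpha),
#' so the perceived intensity of any mixture within the family follows from
#' the constituents' concentrations alone.
#'
#' @param law A [psychophysical_law()].
#' @param cos_alpha Interaction coefficient in [-1, 1]. Negative values encode
#'   odor counteraction (hypo-additivity), positive values synergy.
#' @param members A data frame with columns `name` and `odor_threshold_mg_m3`
#'   (an `odorant_registry` subset works) listing the family's odorants.
#' @param name Family label.
#' @param slope Optional mixture slope s (OI_mix = s * OI_sum) the coefficient
#'   was derived from; stored for reporting.
#' @return An object of class `family_model`.
#' @export
family_model <- function(law, cos_alpha, members, name = NA_character_,
                         slope = NULL) {
  stopifnot(inherits(law, "psychophysical_law"))
  cos_alpha <- as.numeric(cos_alpha)
  if (length(cos_alpha) != 1L || !is.finite(cos_alpha) ||
      cos_alpha < -1 || cos_alpha > 1) {
    stop("cos_alpha must be a single value in [-1, 1]")
  }
  stopifnot(is.data.frame(members),
            all(c("name", "odor_threshold_mg_m3") %in% names(members)))
  structure(
    list(name = name, law = law, cos_alpha = cos_alpha,
         slope = slope, members = members),
    class = "family_model"
  )
}

#' @export
print.family_model <- function(x, ...) {
  cat(sprintf("<family model> %s\n", x$name))
  cat(sprintf("  law:       OI = %.4g * ln(OAV) + %.4g\n", x$law$k, x$law$b))
  if (!is.null(x$slope)) {
    cat(sprintf("  mixing:    OI_mix = %.4g * OI_sum\n", x$slope))
  }
  cat(sprintf("  cos(alpha) = %.4f\n", x$cos_alpha))
  cat(sprintf("  members:   %s\n", paste(x$members$name, collapse = ", ")))
  invisible(x)
}

#' Load a preset family model
#'
#' Two presets ship with the package: `"aldehydes"` (acetaldehyde,
#' propionaldehyde, n-butyraldehyde; OI = 5.6 ln(OAV) - 5.6, mixture slope
#' 0.62) and `"esters"` (ethyl acetate, butyl acetate, ethyl butyrate;
#' OI = 1.4 ln(OAV) - 2.7, mixture slope 0.79). The interaction coefficient is
#' always derived from the stored mixture slope via
#' [cos_alpha_from_slope()] at load time.
#'
#' @param name Preset name, `"aldehydes"` or `"esters"`.
#' @param registry Odorant registry supplying the member thresholds.
#' @param path Optional path to an alternative preset YAML.
#' @return A `family_model`.
#' @examples
#' fam <- family_preset("aldehydes")
#' fam$cos_alpha  # 2 * 0.62^2 - 1
#' @export
family_preset <- function(name, registry = default_registry(), path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "family_presets.yaml", package = "odormvm")
  }
  presets <- yaml::read_yaml(path)
  if (!name %in% names(presets)) {
    stop("unknown family preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  }
  p <- presets[[name]]
  members <- registry[match(p$members, registry$name), , drop = FALSE]
  if (anyNA(members$name)) {
    stop("preset member(s) missing from registry: ",
         paste(setdiff(p$members, registry$name), collapse = ", "))
  }
  fam <- family_model(
    law = psychophysical_law(p$k, p$b),
    cos_alpha = cos_alpha_from_slope(p$slope),
    members = members, name = name, slope = p$slope
  )
  if (!is.null(p$oirs)) {
    fam$oirs <- oirs_scale(p$oirs$base_ppm, p$oirs$ratio, p$oirs$n_levels)
  }
  fam
}

#' Odor intensity referencing scale (OIRS)
#'
#' A geometric series of aqueous n-butanol standards used as anchors for OI
#' ratings: level L corresponds to `base_concentration * ratio^(L-1)` ppm of
#' n-butanol in water.
#'
#' @param base_concentration Level-1 n-butanol concentration in ppm; positive.
#' @param ratio Geometric progression ratio; greater than 1 (2 in practice).
#' @param n_levels Number of levels; at least 2.
#' @return An object of class `oirs_scale`.
#' @examples
#' oirs_scale(10, 2, 12)  # the 12-point scale used for aldehydes
#' @export
oirs_scale <- function(base_concentration, ratio = 2, n_levels = 12) {
  base_concentration <- as.numeric(base_concentration)
  ratio <- as.numeric(ratio)
  n_levels <- as.integer(n_levels)
  if (!is.finite(base_concentration) || base_concentration <= 0) {
    stop("base_concentration must be positive (ppm)")
  }
  if (!is.finite(ratio) || ratio <= 1) stop("ratio must be > 1")
  if (n_levels < 2L) stop("n_levels must be at least 2")
  structure(list(base_concentration = base_concentration, ratio = ratio,
                 n_levels = n_levels),
            class = "oirs_scale")
}

#' @export
print.oirs_scale <- function(x, ...) {
  cat(sprintf(
    "<OIRS> %d-point scale, n-butanol %g ppm at level 1, ratio %g\n",
    x$n_levels, x$base_concentration, x$ratio))
  invisible(x)
}
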
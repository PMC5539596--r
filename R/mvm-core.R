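#' Odor activity value
#'
#' OAV = C / C_Thr: the gas-phase concentration of an odorant divided by its
#' odor threshold. OAV = 1 at threshold; OAV > 1 for perceivable stimuli.
#'
#' @param concentration Gas-phase concentration in mg/m^3; non-negative.
#'   Vectorized.
#' @param odorant An [odorant()] (or anything with a positive
#'   `odor_threshold`).
#' @return Dimensionless OAV, same length as `concentration`.
#' @examples
#' a <- odorant("Acetaldehyde", 0.039)
#' compute_oav(0.39, a)  # 10
#' @export
compute_oav <- function(concentration, odorant) {
  concentration <- as.numeric(concentration)
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop("concentration must be non-negative and finite (mg/m^3)")
  }
  thr <- odorant$odor_threshold
  if (is.null(thr) || !is.finite(thr) || thr <= 0) {
    stop("odorant has no positive odor threshold")
  }
  concentration / thr
}

#' Odor intensity of a single odorant
#'
#' Evaluates the family law OI = k * ln(OAV) + b and clamps the result at 0:
#' stimuli below the perceivable OAV (OAV <= exp(-b/k)) are reported as
#' odorless rather than negatively intense. A zero concentration returns 0.
#'
#' @param concentration Gas-phase concentration in mg/m^3; vectorized.
#' @param odorant An [odorant()].
#' @param law A [psychophysical_law()].
#' @return OI in referencing-scale units, >= 0.
#' @examples
#' a <- odorant("Acetaldehyde", 0.039)
#' law <- psychophysical_law(5.6, -5.6)
#' oi_single(0.39, a, law)  # 5.6 * ln(10) - 5.6 = 7.2945
#' @export
oi_single <- function(concentration, odorant, law) {
  stopifnot(inherits(law, "psychophysical_law"))
  oav <- compute_oav(concentration, odorant)
  oi <- ifelse(oav > 0, law$k * log(oav) + law$b, 0)
  pmax(0, oi)
}

#' Vector-model intensity of a binary mixture
#'
#' The perceived intensity of a two-component mixture is the norm of the
#' vector sum of the component intensities with angle alpha between them:
#' OI_ab^2 = OI_a^2 + OI_b^2 + 2 cos(alpha) OI_a OI_b. cos(alpha) = 1 is
#' perfect additivity, 0 orthogonality, negative values odor counteraction.
#'
#' @param oi_a,oi_b Component odor intensities; non-negative.
#' @param cos_alpha Interaction coefficient in [-1, 1].
#' @return Mixture OI (>= 0). The radicand is clamped at 0 before the square
#'   root (only reachable at cos_alpha = -1, complete counteraction).
#' @examples
#' mixture_oi_binary(3, 4, 0)   # 5
#' mixture_oi_binary(5, 5, -0.2312)  # 6.2 = 0.62 * (5 + 5)
#' @export
mixture_oi_binary <- function(oi_a, oi_b, cos_alpha) {
  mixture_oi(c(oi_a, oi_b), cos_alpha)
}

#' Vector-model intensity of an n-component mixture
#'
#' Generalizes the binary and ternary vector sums to any number of
#' components, with every pairwise interaction sharing the single family
#' coefficient: OI_mix^2 = sum(OI_i^2) + 2 cos(alpha) * sum_{i<j} OI_i OI_j.
#' For n = 2 and n = 3 this is exactly the classical binary/ternary form; a
#' single component returns its own intensity.
#'
#' @param ois Numeric vector of component intensities; non-negative,
#'   length >= 1.
#' @param cos_alpha Interaction coefficient in [-1, 1].
#' @return Mixture OI (>= 0). If the quadratic form goes negative (possible
#'   with strongly negative cos_alpha and several components) it is clamped
#'   at 0 with a warning, read as complete odor counteraction.
#' @examples
#' mixture_oi(c(5, 5, 5), 0)         # sqrt(75)
#' mixture_oi(c(5, 5, 5), -0.2312)   # 6.3498
#' @export
mixture_oi <- function(ois, cos_alpha) {
  ois <- as.numeric(ois)
  if (length(ois) < 1L) stop("need at least one component intensity")
  if (any(!is.finite(ois)) || any(ois < 0)) {
    stop("component intensities must be non-negative and finite")
  }
  cos_alpha <- as.numeric(cos_alpha)
  if (length(cos_alpha) != 1L || !is.finite(cos_alpha) ||
      cos_alpha < -1 || cos_alpha > 1) {
    stop("cos_alpha must be a single value in [-1, 1]")
  }
  sumsq <- sum(ois^2)
  cross <- (sum(ois)^2 - sumsq) / 2  # sum over pairs of OI_i * OI_j
  radicand <- sumsq + 2 * cos_alpha * cross
  if (radicand < 0) {
    # only reachable for cos_alpha near -1 with >= 2 active components
    warning("vector sum collapsed below zero (complete odor counteraction); ",
            "returning 0")
    radicand <- 0
  }
  sqrt(radicand)
}

#' Interaction coefficient from an equal-intensity mixing measurement
#'
#' Inverts the binary vector sum: given the measured intensity of a mixture
#' and of its two unmixed constituents,
#' cos(alpha) = (OI_ab^2 - OI_a^2 - OI_b^2) / (2 OI_a OI_b). The standard
#' protocol mixes two constituents of equal perceived intensity.
#'
#' @param oi_ab Measured mixture intensity.
#' @param oi_a,oi_b Measured unmixed constituent intensities; both positive.
#' @return cos(alpha), dimensionless.
#' @examples
#' cos_alpha_from_measurement(6.2, 5, 5)  # -0.2312
#' @export
cos_alpha_from_measurement <- function(oi_ab, oi_a, oi_b) {
  stopifnot(is.finite(oi_ab), is.finite(oi_a), is.finite(oi_b), oi_ab >= 0)
  if (oi_a <= 0 || oi_b <= 0) {
    stop("both constituent intensities must be positive")
  }
  (oi_ab^2 - oi_a^2 - oi_b^2) / (2 * oi_a * oi_b)
}

#' Interaction coefficient from the mixture slope
#'
#' If equal-intensity binary mixtures follow OI_mix = s * OI_sum, substituting
#' OI_ab = s (OI_a + OI_b) with OI_a = OI_b into the equal-intensity relation
#' gives cos(alpha) = 2 s^2 - 1, so the whole family's interaction coefficient
#' follows from one fitted slope.
#'
#' @param s Slope of OI_mix on OI_sum; in (0, 1].
#' @return cos(alpha) in (-1, 1].
#' @examples
#' cos_alpha_from_slope(0.62)  # -0.2312
#' cos_alpha_from_slope(0.79)  #  0.2482
#' @export
cos_alpha_from_slope <- function(s) {
  s <- as.numeric(s)
  stopifnot(length(s) == 1L, is.finite(s))
  if (s <= 0 || s > 1) stop("mixture slope must be in (0, 1]")
  2 * s^2 - 1
}

#' Mixture slope implied by an interaction coefficient
#'
#' Inverse of [cos_alpha_from_slope()]: s = sqrt((1 + cos(alpha)) / 2).
#'
#' @param c Interaction coefficient in (-1, 1].
#' @return Slope s in (0, 1].
#' @export
slope_from_cos_alpha <- function(c) {
  c <- as.numeric(c)
  stopifnot(length(c) == 1L, is.finite(c))
  if (c <= -1 || c > 1) stop("cos_alpha must be in (-1, 1]")
  sqrt((1 + c) / 2)
}

#' An odor sample: odorants and their gas-phase concentrations
#'
#' @param composition Named numeric vector mapping odorant names to
#'   concentrations in mg/m^3; all non-negative, at least one entry.
#' @return An object of class `odor_sample`.
#' @examples
#' odor_sample(c(Acetaldehyde = 0.39, Propionaldehyde = 0.41))
#' @export
odor_sample <- function(composition) {
  composition <- unlist(composition)
  if (length(composition) < 1L) stop("sample needs at least one constituent")
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be named by odorant")
  }
  if (any(!is.finite(composition)) || any(composition < 0)) {
    stop("concentrations must be non-negative and finite (mg/m^3)")
  }
  structure(list(composition = composition), class = "odor_sample")
}

#' @export
print.odor_sample <- function(x, ...) {
  cat("<odor sample>\n")
  for (nm in names(x$composition)) {
    cat(sprintf("  %s: %g mg/m^3\n", nm, x$composition[[nm]]))
  }
  invisible(x)
}

#' Predict the odor intensity of a sample under a family model
#'
#' The modified vector model end to end: each constituent's OI is computed
#' from its concentration through the family law (via OAV), then the
#' constituent intensities are combined by the vector sum with the family's
#' cos(alpha). A single-constituent sample reduces to [oi_single()].
#'
#' @param sample An [odor_sample()] whose odorants are all family members
#'   (matched by name or abbreviation).
#' @param family A [family_model()].
#' @param breakdown If `TRUE`, return a list with the mixture OI and a
#'   per-constituent table (concentration, OAV, OI) instead of a bare number.
#' @return Mixture OI, or a list if `breakdown = TRUE`.
#' @examples
#' fam <- family_preset("aldehydes")
#' s <- odor_sample(c(Acetaldehyde = 0.39, Propionaldehyde = 0.41))
#' predict_mixture_oi(s, fam)  # 9.0452
#' @export
predict_mixture_oi <- function(sample, family, breakdown = FALSE) {
  stopifnot(inherits(sample, "odor_sample"), inherits(family, "family_model"))
  nm <- names(sample$composition)
  idx <- match(nm, family$members$name)
  if ("abbreviation" %in% names(family$members)) {
    alt <- match(nm, family$members$abbreviation)
    idx[is.na(idx)] <- alt[is.na(idx)]
  }
  if (anyNA(idx)) {
    stop("odorant(s) not in family '", family$name, "': ",
         paste(nm[is.na(idx)], collapse = ", "))
  }
  thr <- family$members$odor_threshold_mg_m3[idx]
  conc <- as.numeric(sample$composition)
  oav <- conc / thr
  ois <- vapply(seq_along(conc), function(i) {
    oi_single(conc[i], odorant(nm[i], thr[i]), family$law)
  }, numeric(1))
  oi_mix <- if (length(ois) == 1L) ois else mixture_oi(ois, family$cos_alpha)
  if (!breakdown) return(oi_mix)
  list(
    oi = oi_mix,
    constituents = data.frame(
      odorant = family$members$name[idx],
      concentration_mg_m3 = conc,
      oav = oav,
      oi = ois
    )
  )
}

#' n-Butanol concentration at an OIRS level
#'
#' Levels form a geometric progression:
#' `base_concentration * ratio^(level - 1)` ppm.
#'
#' @param level Integer level in `1:scale$n_levels`.
#' @param scale An [oirs_scale()].
#' @return Concentration in ppm.
#' @examples
#' oirs_concentration(8, oirs_scale(10, 2, 12))  # 1280
#' @export
oirs_concentration <- function(level, scale) {
  stopifnot(inherits(scale, "oirs_scale"))
  level <- as.numeric(level)
  if (any(level != round(level)) || any(level < 1) ||
      any(level > scale$n_levels)) {
    stop("level must be an integer in 1..", scale$n_levels)
  }
  scale$base_concentration * scale$ratio^(level - 1)
}

#' Quantize a continuous OI to the referencing-scale resolution
#'
#' Assessors report against discrete (or half-step) scale anchors; this
#' rounds a continuous model OI to the nearest multiple of `resolution`,
#' with exact ties rounding up.
#'
#' @param oi Continuous OI, >= 0; vectorized.
#' @param resolution Reporting step in OI levels (e.g. 0.5 for half-levels);
#'   positive.
#' @return Quantized OI.
#' @examples
#' nearest_oirs_level(7.2945, 0.5)  # 7.5
#' nearest_oirs_level(0.25, 0.5)    # 0.5 (tie rounds up)
#' @export
nearest_oirs_level <- function(oi, resolution) {
  oi <- as.numeric(oi)
  if (any(!is.finite(oi)) || any(oi < 0)) stop("oi must be non-negative")
  if (!is.finite(resolution) || resolution <= 0) {
    stop("resolution must be positive")
  }
  floor(oi / resolution + 0.5) * resolution
}
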
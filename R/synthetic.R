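#' Configuration for simulated sensory-panel data
#'
#' The generators emulate a small sensory panel rating odor samples against
#' an n-butanol referencing scale: true intensities follow the family's
#' log-linear law and vector-sum mixing exactly, each assessor adds Gaussian
#' rating noise on the OI scale (truncated at 0), reports at the scale's
#' resolution (half-levels by default), and the panel mean is recorded.
#'
#' @param family Preset name (`"aldehydes"`, `"esters"`) or a list with
#'   elements `k`, `b`, `slope`.
#' @param registry Odorant registry supplying member thresholds.
#' @param odorants Optional character vector restricting the member set.
#' @param n_singles Rated samples per single odorant (default 6).
#' @param n_mixtures Rated samples per mixture pair/triple (default 5).
#' @param lnoav_range Range of ln(OAV) spanned by the single-odorant samples.
#'   Defaults to the perceivable window starting at the law's zero crossing,
#'   `-b/k`, and spanning 2.5 ln units. The law must be non-negative over the
#'   whole range.
#' @param mix_oi_range Range of target component OI for mixture samples
#'   (default levels 1 to 12).
#' @param assessor_sd Per-assessor rating noise sd in OI units (default 0.5,
#'   the accepted scatter of panel ratings).
#' @param n_assessors Panel size (default 8).
#' @param oirs_resolution Reporting step in OI levels; 0 means continuous
#'   ratings (default 0.5, half-levels).
#' @param seed RNG seed; generators are pure functions of (config, seed).
#' @return A list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(family = "aldehydes",
                             registry = default_registry(),
                             odorants = NULL,
                             n_singles = 6L, n_mixtures = 5L,
                             lnoav_range = NULL,
                             mix_oi_range = c(1, 12),
                             assessor_sd = 0.5, n_assessors = 8L,
                             oirs_resolution = 0.5, seed = 1L) {
  if (is.character(family)) {
    fam <- family_preset(family, registry)
    params <- list(k = fam$law$k, b = fam$law$b, slope = fam$slope,
                   name = fam$name)
    members <- fam$members
  } else {
    stopifnot(all(c("k", "b", "slope") %in% names(family)))
    params <- list(k = family$k, b = family$b, slope = family$slope,
                   name = family$name %||% "custom")
    members <- registry
  }
  if (!is.null(odorants)) {
    members <- registry[match(odorants, registry$name), , drop = FALSE]
    if (anyNA(members$name)) stop("odorant(s) not in registry")
  }
  if (is.null(lnoav_range)) {
    lnoav_range <- -params$b / params$k + c(0, 2.5)
  }
  stopifnot(length(lnoav_range) == 2L, diff(lnoav_range) > 0)
  if (params$k * lnoav_range[1] + params$b < -1e-12) {
    stop("lnoav_range extends below the perceivable region ",
         "(k * ln(OAV) + b < 0)")
  }
  stopifnot(assessor_sd >= 0, n_assessors >= 1L, oirs_resolution >= 0,
            params$k > 0, params$slope > 0, params$slope <= 1)
  structure(list(
    k = params$k, b = params$b, slope = params$slope, family = params$name,
    members = members, n_singles = as.integer(n_singles),
    n_mixtures = as.integer(n_mixtures), lnoav_range = lnoav_range,
    mix_oi_range = mix_oi_range, assessor_sd = assessor_sd,
    n_assessors = as.integer(n_assessors),
    oirs_resolution = oirs_resolution, seed = as.integer(seed)
  ), class = "panel_sim_config")
}

# panel-mean rating of a vector of true intensities: per-assessor Gaussian
# noise truncated at 0, quantized to the scale resolution, averaged
rate_panel <- function(oi_true, config) {
  vapply(oi_true, function(o) {
    x <- pmax(0, o + stats::rnorm(config$n_assessors, 0, config$assessor_sd))
    if (config$oirs_resolution > 0) {
      x <- nearest_oirs_level(x, config$oirs_resolution)
    }
    mean(x)
  }, numeric(1))
}

#' Simulate a single-odorant panel dataset
#'
#' For each member odorant, places `n_singles` samples on an even ln(OAV)
#' grid over `lnoav_range`, sets the true OI from the configured law, and
#' records the noisy, quantized panel-mean rating.
#'
#' @param config A [panel_sim_config()].
#' @return Data frame with columns `sample_id`, `odorant`,
#'   `concentration_mg_m3`, `lnoav`, `oi_true`, `oi` — directly consumable by
#'   [fit_psychophysical_law()].
#' @export
gen_single_odorant_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  grid <- seq(config$lnoav_range[1], config$lnoav_range[2],
              length.out = config$n_singles)
  out <- do.call(rbind, lapply(seq_len(nrow(config$members)), function(i) {
    nm <- config$members$name[i]
    thr <- config$members$odor_threshold_mg_m3[i]
    abbr <- config$members$abbreviation[i]
    if (is.null(abbr) || is.na(abbr)) abbr <- nm
    true_oi <- pmax(0, config$k * grid + config$b)
    data.frame(
      sample_id = paste0(abbr, "_", seq_along(grid)),
      odorant = nm,
      concentration_mg_m3 = thr * exp(grid),
      lnoav = grid,
      oi_true = true_oi,
      oi = rate_panel(true_oi, config)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a mixture panel dataset
#'
#' For every pair (or triple) of member odorants, draws `n_mixtures` samples
#' whose component intensities sit on an even grid over `mix_oi_range`
#' (equal-intensity mixing, the standard protocol) or are drawn uniformly
#' from it (unequal mixing). The true mixture OI is the vector sum with
#' cos(alpha) = 2 * slope^2 - 1; component and mixture ratings then receive
#' panel noise independently.
#'
#' @param config A [panel_sim_config()].
#' @param arity Number of components per mixture, 2 or 3.
#' @param equal_intensity Mix components at equal perceived intensity
#'   (default `TRUE`).
#' @return Data frame with one row per mixture sample: `sample_id`,
#'   `mixture` (component names), rated component intensities `oi_1..`,
#'   `oi_sum`, `oi_mix`, and the noise-free `oi_sum_true`, `oi_mix_true`.
#'   Directly consumable by [fit_mixture_slope()].
#' @export
gen_mixture_panel <- function(config, arity = 2L, equal_intensity = TRUE) {
  stopifnot(inherits(config, "panel_sim_config"), arity %in% c(2L, 3L))
  set.seed(config$seed + 1L)  # independent stream from the singles panel
  cos_a <- cos_alpha_from_slope(config$slope)
  sets <- utils::combn(config$members$name, arity, simplify = FALSE)
  grid <- seq(config$mix_oi_range[1], config$mix_oi_range[2],
              length.out = config$n_mixtures)
  rows <- list()
  for (s in seq_along(sets)) {
    for (j in seq_len(config$n_mixtures)) {
      comp_true <- if (equal_intensity) {
        rep(grid[j], arity)
      } else {
        stats::runif(arity, config$mix_oi_range[1], config$mix_oi_range[2])
      }
      mix_true <- mixture_oi(comp_true, cos_a)
      comp_rated <- rate_panel(comp_true, config)
      mix_rated <- rate_panel(mix_true, config)
      row <- data.frame(
        sample_id = paste0("mix", arity, "_", s, "_", j),
        mixture = paste(sets[[s]], collapse = "+")
      )
      for (a in seq_len(arity)) row[[paste0("oi_", a)]] <- comp_rated[a]
      row$oi_sum <- sum(comp_rated)
      row$oi_mix <- mix_rated
      row$oi_sum_true <- sum(comp_true)
      row$oi_mix_true <- mix_true
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default seven-sensor array model
#'
#' A linear response model for the metal-oxide array used for the aldehyde
#' pipeline (TGS2602, TGS2610, MQ6, MC119, MP502, MS1100, WSP2620). The
#' qualitative selectivity pattern follows the array characterization — MQ6,
#' MS1100 and TGS2610 respond to acetaldehyde; WSP2620, MQ6, MP502 and
#' TGS2610 to propionaldehyde; MQ6, TGS2602, MP502 and MC119 to
#' n-butyraldehyde, with MP502 responding more strongly to n-butyraldehyde
#' than to propionaldehyde. Baselines and sensitivity magnitudes are
#' synthetic round numbers chosen for that pattern, not measured device
#' constants.
#'
#' @return A list of class `sensor_array`: `sensors`, `odorants`, `baseline`
#'   (signal units), and `sensitivity` (sensors x odorants matrix, signal
#'   units per mg/m^3).
#' @export
default_sensor_array <- function() {
  sensors <- c("TGS2602", "TGS2610", "MQ6", "MC119", "MP502", "MS1100",
               "WSP2620")
  odorants <- c("Acetaldehyde", "Propionaldehyde", "n-Butyraldehyde")
  S <- rbind(
    TGS2602 = c(0,   0,   1.7),
    TGS2610 = c(1.0, 1.6, 0),
    MQ6     = c(1.8, 1.2, 0.9),
    MC119   = c(0,   0,   1.1),
    MP502   = c(0,   0.5, 2.0),
    MS1100  = c(2.5, 0,   0),
    WSP2620 = c(0,   2.2, 0)
  )
  colnames(S) <- odorants
  baseline <- c(TGS2602 = 0.20, TGS2610 = 0.15, MQ6 = 0.25, MC119 = 0.10,
                MP502 = 0.18, MS1100 = 0.12, WSP2620 = 0.22)
  structure(list(sensors = sensors, odorants = odorants,
                 baseline = baseline[sensors],
                 sensitivity = S[sensors, , drop = FALSE]),
            class = "sensor_array")
}

#' Configuration for simulated sensor-array data
#'
#' @param array A sensor array model (see [default_sensor_array()]).
#' @param conc_range Per-odorant concentration range in mg/m^3: a 2 x n
#'   matrix (rows min/max) or a single c(min, max) recycled to all odorants.
#'   Defaults to the perceivable window of the aldehyde law over the
#'   registry thresholds (ln(OAV) from 1 to 3.5).
#' @param noise_sd Additive Gaussian signal noise sd (signal units,
#'   default 0).
#' @param seed RNG seed.
#' @return A list of class `sensor_sim_config`.
#' @export
sensor_sim_config <- function(array = default_sensor_array(),
                              conc_range = NULL, noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  if (is.null(conc_range)) {
    reg <- default_registry()
    thr <- vapply(array$odorants,
                  function(o) get_odorant(reg, o)$odor_threshold, numeric(1))
    conc_range <- rbind(min = thr * exp(1), max = thr * exp(3.5))
  } else if (is.null(dim(conc_range))) {
    conc_range <- matrix(conc_range, nrow = 2,
                         ncol = length(array$odorants),
                         dimnames = list(c("min", "max"), array$odorants))
  }
  structure(list(array = array, conc_range = conc_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sensor_sim_config")
}

#' Simulate a sensor-array training database
#'
#' Each sensor responds linearly: signal_j = baseline_j +
#' sum_i sensitivity_{j,i} * C_i + Gaussian(0, noise_sd). Mixture response is
#' additive in the constituents (no sensor-level interaction is modeled).
#' The default sampling plan mirrors the calibration campaign: 8 samples per
#' single odorant, 25 per binary pair, 50 for the ternary mixture, with
#' concentrations drawn uniformly from the configured ranges.
#'
#' @param config A [sensor_sim_config()].
#' @param concentrations Optional explicit samples x odorants concentration
#'   matrix; overrides the sampling plan.
#' @param plan Named counts for the default plan
#'   (`c(single = 8, binary = 25, ternary = 50)`).
#' @return A training database: list of class `training_db` with `signals`
#'   (samples x sensors), `concentrations` (samples x odorants), `sensors`,
#'   `odorants`.
#' @export
gen_sensor_training_db <- function(config,
                                   concentrations = NULL,
                                   plan = c(single = 8, binary = 25,
                                            ternary = 50)) {
  stopifnot(inherits(config, "sensor_sim_config"))
  set.seed(config$seed)
  arr <- config$array
  n_od <- length(arr$odorants)
  rng <- config$conc_range
  draw <- function(active, n) {
    C <- matrix(0, n, n_od, dimnames = list(NULL, arr$odorants))
    for (i in active) {
      C[, i] <- stats::runif(n, rng["min", i], rng["max", i])
    }
    C
  }
  if (is.null(concentrations)) {
    parts <- list()
    for (i in seq_len(n_od)) {
      parts[[length(parts) + 1L]] <- draw(i, plan[["single"]])
    }
    if (n_od >= 2) {
      for (pair in utils::combn(n_od, 2, simplify = FALSE)) {
        parts[[length(parts) + 1L]] <- draw(pair, plan[["binary"]])
      }
    }
    if (n_od >= 3) {
      for (tri in utils::combn(n_od, 3, simplify = FALSE)) {
        parts[[length(parts) + 1L]] <- draw(tri, plan[["ternary"]])
      }
    }
    C <- do.call(rbind, parts)
  } else {
    C <- as.matrix(concentrations)
    stopifnot(ncol(C) == n_od)
    colnames(C) <- arr$odorants
  }
  X <- C %*% t(arr$sensitivity) +
    matrix(arr$baseline, nrow(C), length(arr$sensors), byrow = TRUE)
  if (config$noise_sd > 0) {
    X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X))
  }
  colnames(X) <- arr$sensors
  structure(list(signals = X, concentrations = C,
                 sensors = arr$sensors, odorants = arr$odorants),
            class = "training_db")
}
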
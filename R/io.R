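#' Read a single-odorant panel CSV
#'
#' Expected columns: `sample_id` (optional), `odorant`,
#' `concentration_mg_m3`, `oi`.
#'
#' @param path CSV path.
#' @return Data frame suitable for [fit_psychophysical_law()].
#' @export
read_singles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("odorant", "concentration_mg_m3", "oi"), basename(path))
  if (any(!is.finite(df$concentration_mg_m3)) ||
      any(df$concentration_mg_m3 <= 0)) {
    stop("column concentration_mg_m3 must be positive and finite")
  }
  if (any(!is.finite(df$oi)) || any(df$oi < 0)) {
    stop("column oi must be non-negative and finite")
  }
  df
}

#' Read a mixture panel CSV
#'
#' Accepts either the long format — columns `sample_id`, `role`
#' (`"component"` or `"mixture"`), `oi`, with one `mixture` row and two or
#' more `component` rows per sample — or a wide format that already carries
#' `oi_sum` and `oi_mix` columns.
#'
#' @param path CSV path.
#' @return Data frame with `oi_sum` and `oi_mix`, one row per mixture sample.
#' @export
read_mixtures_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("oi_sum", "oi_mix") %in% names(df))) {
    out <- df
  } else {
    check_columns(df, c("sample_id", "role", "oi"), basename(path))
    bad <- setdiff(unique(df$role), c("component", "mixture"))
    if (length(bad) > 0) {
      stop("column role contains unknown value(s): ",
           paste(bad, collapse = ", "))
    }
    out <- do.call(rbind, lapply(split(df, df$sample_id), function(d) {
      comp <- d$oi[d$role == "component"]
      mix <- d$oi[d$role == "mixture"]
      if (length(comp) < 2L || length(mix) != 1L) {
        stop("sample ", d$sample_id[1], " needs >= 2 component rows and ",
             "exactly 1 mixture row")
      }
      data.frame(sample_id = d$sample_id[1], oi_sum = sum(comp), oi_mix = mix)
    }))
    rownames(out) <- NULL
  }
  if (any(out$oi_sum < 0) || any(out$oi_mix < 0)) {
    stop("intensities must be non-negative")
  }
  out
}

#' Write a mixture panel CSV in long format
#'
#' Inverse of the long format accepted by [read_mixtures_csv()]: component
#' intensities are taken from `oi_1`, `oi_2`, ... columns and the mixture
#' intensity from `oi_mix`.
#'
#' @param mixtures Data frame as produced by [gen_mixture_panel()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_mixtures_csv <- function(mixtures, path) {
  comp_cols <- grep("^oi_[0-9]+$", names(mixtures), value = TRUE)
  if (length(comp_cols) < 2L || !"oi_mix" %in% names(mixtures)) {
    stop("mixtures must carry oi_1.. component columns and oi_mix")
  }
  rows <- list()
  for (i in seq_len(nrow(mixtures))) {
    id <- if ("sample_id" %in% names(mixtures)) mixtures$sample_id[i] else
      paste0("mix_", i)
    for (cc in comp_cols) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, role = "component", oi = mixtures[[cc]][i])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = id, role = "mixture", oi = mixtures$oi_mix[i])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read odor-sample compositions from a long CSV
#'
#' Expected columns: `sample_id`, `odorant`, `concentration_mg_m3`; one row
#' per constituent.
#'
#' @param path CSV path.
#' @return Named list of [odor_sample()] objects, in first-appearance order.
#' @export
read_samples_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "odorant", "concentration_mg_m3"),
                basename(path))
  if (nrow(df) == 0L) return(list())
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    d <- df[df$sample_id == id, , drop = FALSE]
    odor_sample(stats::setNames(d$concentration_mg_m3, d$odorant))
  })
  stats::setNames(out, ids)
}

#' Read / write a sensor training database CSV
#'
#' Layout: `sample_id`, one signal column per sensor (any names without the
#' `conc_` prefix), then one `conc_<odorant>` column per target odorant.
#'
#' @param path CSV path.
#' @return A `training_db` list (`signals`, `concentrations`, `sensors`,
#'   `odorants`).
#' @export
read_training_db_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  conc_cols <- grep("^conc_", names(df), value = TRUE)
  if (length(conc_cols) == 0L) {
    stop("training database is missing conc_<odorant> column(s)")
  }
  sensor_cols <- setdiff(names(df), c("sample_id", conc_cols))
  if (length(sensor_cols) == 0L) {
    stop("training database has no sensor signal columns")
  }
  conc <- as.matrix(df[, conc_cols, drop = FALSE])
  colnames(conc) <- sub("^conc_", "", conc_cols)
  structure(list(
    signals = as.matrix(df[, sensor_cols, drop = FALSE]),
    concentrations = conc,
    sensors = sensor_cols,
    odorants = colnames(conc)
  ), class = "training_db")
}

#' @rdname read_training_db_csv
#' @param db A `training_db`.
#' @export
write_training_db_csv <- function(db, path) {
  conc <- as.data.frame(db$concentrations)
  names(conc) <- paste0("conc_", db$odorants)
  sig <- as.data.frame(db$signals)
  names(sig) <- db$sensors
  df <- cbind(data.frame(sample_id = paste0("s", seq_len(nrow(sig)))),
              sig, conc)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a calibrated family model as YAML
#'
#' The file stores the law constants, the mixture slope, and the member
#' table. The interaction coefficient is re-derived from the slope at load
#' time (the slope is the measured quantity; cos(alpha) is algebra), so a
#' hand-edited slope stays consistent.
#'
#' @param family A [family_model()].
#' @param path Destination YAML.
#' @return `write_family_model` returns `path` invisibly;
#'   `read_family_model` returns the `family_model`.
#' @export
write_family_model <- function(family, path) {
  stopifnot(inherits(family, "family_model"))
  obj <- list(
    name = family$name,
    k = family$law$k, b = family$law$b,
    slope = family$slope,
    cos_alpha = family$cos_alpha,
    members = lapply(seq_len(nrow(family$members)), function(i) {
      list(name = family$members$name[i],
           odor_threshold_mg_m3 = family$members$odor_threshold_mg_m3[i])
    })
  )
  if (!is.null(family$law$diagnostics)) {
    d <- family$law$diagnostics
    obj$law_fit <- list(n = d$n, sigma = d$sigma, r_squared = d$r_squared)
  }
  if (!is.null(family$slope_fit)) {
    obj$slope_fit <- list(n = family$slope_fit$n,
                          sigma = family$slope_fit$sigma)
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_family_model
#' @export
read_family_model <- function(path) {
  obj <- yaml::read_yaml(path)
  members <- do.call(rbind, lapply(obj$members, function(m) {
    data.frame(name = m$name,
               odor_threshold_mg_m3 = m$odor_threshold_mg_m3)
  }))
  cos_alpha <- if (!is.null(obj$slope)) cos_alpha_from_slope(obj$slope) else
    obj$cos_alpha
  family_model(psychophysical_law(obj$k, obj$b), cos_alpha, members,
               name = obj$name %||% "loaded", slope = obj$slope)
}
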
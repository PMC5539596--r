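#' Construct an odorant
#'
#' An odorant is identified by name and CAS number and carries the odor
#' threshold used as the denominator of the odor activity value
#' (OAV = C / C_Thr).
#'
#' @param name Odorant name (unique within a registry).
#' @param odor_threshold Odor threshold in mg/m^3; must be positive.
#' @param cas CAS registry number (optional).
#' @param abbreviation Short label, e.g. "A" for acetaldehyde (optional).
#' @param family Odorant family label, e.g. "aldehydes" (optional).
#' @return An object of class `odorant`.
#' @examples
#' odorant("Acetaldehyde", 0.039, cas = "75-07-0", abbreviation = "A")
#' @export
odorant <- function(name, odor_threshold, cas = NA_character_,
                    abbreviation = NA_character_, family = NA_character_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  odor_threshold <- as.numeric(odor_threshold)
  if (length(odor_threshold) != 1L || !is.finite(odor_threshold) ||
      odor_threshold <= 0) {
    stop("odor_threshold must be a single positive number (mg/m^3)")
  }
  structure(
    list(name = name, abbreviation = abbreviation, cas = cas,
         odor_threshold = odor_threshold, family = family),
    class = "odorant"
  )
}

#' @export
print.odorant <- function(x, ...) {
  cat(sprintf("<odorant> %s (%s), CAS %s, threshold %g mg/m^3 [%s]\n",
              x$name, x$abbreviation, x$cas, x$odor_threshold, x$family))
  invisible(x)
}

#' Load the built-in odorant registry
#'
#' The registry ships with the package and lists the eight odorants used for
#' model development (three aldehydes, three esters, plus n-butyl acrylate and
#' vinyl acetate) with panel-measured odor thresholds in mg/m^3.
#'
#' @param path Optional path to a user registry CSV with columns
#'   `name, abbreviation, cas, odor_threshold_mg_m3, family`. Defaults to the
#'   shipped registry.
#' @return A data frame of class `odorant_registry`.
#' @examples
#' reg <- default_registry()
#' get_odorant(reg, "Acetaldehyde")$odor_threshold
#' @export
default_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "odorant_registry.csv", package = "odormvm")
  }
  read_registry_csv(path)
}

#' Read an odorant registry CSV
#'
#' @param path CSV with columns `name, abbreviation, cas,
#'   odor_threshold_mg_m3, family` (abbreviation/cas/family optional).
#' @return A data frame of class `odorant_registry`.
#' @export
read_registry_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "odor_threshold_mg_m3")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("registry is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("abbreviation", "cas", "family")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (anyDuplicated(df$name)) stop("registry has duplicated odorant names")
  if (any(!is.finite(df$odor_threshold_mg_m3)) ||
      any(df$odor_threshold_mg_m3 <= 0)) {
    stop("all odor thresholds must be positive and finite")
  }
  class(df) <- c("odorant_registry", "data.frame")
  df
}

#' Look up an odorant in a registry
#'
#' Matches by name first, then by abbreviation.
#'
#' @param registry An `odorant_registry` (see [default_registry()]).
#' @param name Odorant name or abbreviation.
#' @return An `odorant`.
#' @export
get_odorant <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i)) i <- match(name, registry$abbreviation)
  if (is.na(i)) stop("odorant not found in registry: ", name)
  odorant(registry$name[i], registry$odor_threshold_mg_m3[i],
          cas = registry$cas[i], abbreviation = registry$abbreviation[i],
          family = registry$family[i])
}
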
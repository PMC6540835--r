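#' Observation table of detected groups
#'
#' Validates and classes a data frame of detections: one row per detected
#' group with its transect, perpendicular distance (m, 0-based from the
#' line), group size, the two observers' detection indicators, and any
#' covariate columns. Only groups detected by at least one observer appear.
#'
#' @param data A data frame with columns `transect`, `distance`, `size`,
#'   `det1`, `det2` plus optional covariates.
#' @param w Optional truncation width (m) used to check distances.
#' @return The validated data frame with class `observation_table` and
#'   attribute `w`.
#' @export
observation_table <- function(data, w = NULL) {
  data <- as.data.frame(data)
  required <- c("transect", "distance", "size", "det1", "det2")
  miss <- setdiff(required, names(data))
  if (length(miss))
    abort_validation(paste0("missing required column(s): ",
                            paste(miss, collapse = ", ")))
  bad_rows <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      abort_validation(paste0("row(s) ", paste(utils::head(idx, 10),
                                               collapse = ", "),
                              ": ", what))
  }
  if (nrow(data) > 0) {
    bad_rows(!is.finite(data$distance) | data$distance < 0,
             "distance must be finite and non-negative")
    if (!is.null(w))
      bad_rows(data$distance > w, paste0("distance exceeds w = ", w))
    bad_rows(!is.finite(data$size) | data$size < 1,
             "group size must be at least 1")
    bad_rows(!(data$det1 %in% c(0, 1)) | !(data$det2 %in% c(0, 1)),
             "det1/det2 must be 0 or 1")
    bad_rows(data$det1 + data$det2 < 1,
             "group not detected by either observer (det1 = det2 = 0)")
  }
  structure(data, class = c("observation_table", "data.frame"), w = w)
}

#' Survey design: transects, effort, strata and areas
#'
#' @param transects Data frame with columns `transect`, `length_km` and
#'   optionally `stratum` (defaults to a single stratum `"all"`).
#' @param w Strip half-width (m).
#' @param area_km2 Study area in km^2: a single number, or a named vector
#'   with one entry per stratum.
#' @param sides 1 (both observers search the same side of the aircraft, the
#'   default for tandem fixed-wing surveys) or 2.
#' @return An object of class `survey_design` with total effort `L_km`,
#'   covered area `covered_km2 = sides * (w/1000) * L`, and a per-stratum
#'   summary table.
#' @export
survey_design <- function(transects, w, area_km2, sides = 1) {
  transects <- as.data.frame(transects)
  miss <- setdiff(c("transect", "length_km"), names(transects))
  if (length(miss))
    abort_validation(paste0("transects table missing column(s): ",
                            paste(miss, collapse = ", ")))
  if (is.null(transects$stratum)) transects$stratum <- "all"
  transects$stratum <- as.character(transects$stratum)
  if (any(!is.finite(transects$length_km) | transects$length_km <= 0))
    abort_validation("transect lengths must be positive")
  if (anyDuplicated(transects$transect))
    abort_validation("duplicated transect ids")
  if (!sides %in% c(1, 2)) abort_validation("sides must be 1 or 2")
  if (!is.numeric(w) || w <= 0) abort_validation("w must be positive")
  strata <- sort(unique(transects$stratum))
  if (length(area_km2) == 1 && is.null(names(area_km2))) {
    A <- stats::setNames(rep(area_km2 / length(strata), length(strata)), strata)
  } else {
    if (!all(strata %in% names(area_km2)))
      abort_validation("area_km2 must name every stratum")
    A <- area_km2[strata]
  }
  L_h <- vapply(strata, function(h)
    sum(transects$length_km[transects$stratum == h]), numeric(1))
  a_h <- sides * (w / 1000) * L_h
  if (any(a_h > A + 1e-9))
    abort_validation("covered area exceeds study area in some stratum")
  stratum_table <- data.frame(stratum = strata, area_km2 = as.numeric(A),
                              effort_km = as.numeric(L_h),
                              covered_km2 = as.numeric(a_h),
                              row.names = NULL)
  structure(
    list(transects = transects, w = w, sides = sides,
         area_km2 = sum(A), L_km = sum(L_h),
         covered_km2 = sum(a_h), strata = stratum_table),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(
    "Survey design: %d transects, L = %.1f km, w = %.0f m, %d side(s)\n",
    nrow(x$transects), x$L_km, x$w, x$sides))
  cat(sprintf("  study area %.1f km2, covered %.1f km2 (%.1f%%)\n",
              x$area_km2, x$covered_km2, 100 * x$covered_km2 / x$area_km2))
  if (nrow(x$strata) > 1) print(x$strata)
  invisible(x)
}

# transect stratum lookup for observation rows
obs_stratum <- function(obs, design) {
  m <- match(obs$transect, design$transects$transect)
  if (anyNA(m)) {
    idx <- which(is.na(m))
    abort_validation(paste0("row(s) ", paste(utils::head(idx, 10),
                                             collapse = ", "),
                            ": transect id not present in the design"))
  }
  design$transects$stratum[m]
}

#' Read / write survey tables
#'
#' Flat CSV interfaces: observations have columns
#' `transect,distance,size,det1,det2,<covariates...>`; transects have
#' `transect,length_km,stratum`. Numbers round-trip exactly for
#' text-representable values (written with full precision, "." decimal).
#'
#' @param path File path.
#' @param w Optional truncation width for validation on read.
#' @return `read_observations()` an [observation_table()];
#'   `read_transects()` a data frame.
#' @export
read_observations <- function(path, w = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  observation_table(df, w = w)
}

#' @rdname read_observations
#' @export
read_transects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("transect", "length_km"), names(df))
  if (length(miss))
    abort_validation(paste0("transects file missing column(s): ",
                            paste(miss, collapse = ", ")))
  df
}

#' @rdname read_observations
#' @param x Table to write.
#' @export
write_observations <- function(x, path) {
  # character fields are quoted: covariate labels may contain commas
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_observations
#' @export
write_transects <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a survey configuration file
#'
#' YAML with keys `w`, `sides`, `area_km2`, `form`, `covariates`,
#' `left_truncation`, `seed` (all optional except `w` and `area_km2` for
#' fitting). A commented template ships in
#' `system.file("extdata", "config-template.yml", package = "apexds")`.
#'
#' @param path Path to the YAML file.
#' @return A named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort_validation("config file must contain a mapping")
  cfg
}
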
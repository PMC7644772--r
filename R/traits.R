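# Morphometric diagnostics and range geometry: load a specimen measurement
# table (14 standard external measurements, mm), recompute the printed
# ratio and range diagnostics, and compute the minimum-convex-polygon area
# of occurrence localities on the sphere.

#' The 14 standard morphometric variables (mm)
#'
#' Snout-vent length (SVL), maximum head width (HW), head length (HL),
#' tympanum diameter (TD), eye diameter (ED), eye-nostril distance (END),
#' nostril-snout-tip distance (NSD), internarial distance (NND), hand
#' length (HAL), forelimb length (FORL), hindlimb length (HIL), foot
#' length including tarsus (FOTL), foot length (FOL), tibia length (TIBL).
#' @export
MEASUREMENT_VARS <- c("SVL", "HW", "HL", "TD", "ED", "END", "NSD",
                      "NND", "HAL", "FORL", "HIL", "FOTL", "FOL", "TIBL")

#' Load a specimen measurement table
#'
#' Reads a TSV/CSV table with one row per specimen. Required columns: the
#' 14 measurement abbreviations (see [MEASUREMENT_VARS]) plus `catalogue`,
#' `species`, `sex` and `status`. `sex` entries like `"F (SA)"` mark
#' subadults; `status` values `HT`/`PT` mark holotype/paratype (implying
#' adult unless the subadult flag is present), anything else or blank is
#' read as adult.
#'
#' @param path path to a TSV (default) or CSV file.
#' @return tibble with `catalogue`, `field_number`, `species`, `lineage`,
#'   `sex` (`"M"`/`"F"`), `status` (`"holotype"`, `"paratype"`, `"adult"`,
#'   `"subadult"`), `adult` (logical) and the 14 numeric measurement
#'   columns.
#' @export
load_measurements <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    readr::read_csv else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  missing_vars <- setdiff(MEASUREMENT_VARS, names(raw))
  if (length(missing_vars)) {
    abort(sprintf("measurement table is missing column(s): %s",
                  paste(missing_vars, collapse = ", ")))
  }
  need <- c("catalogue", "species", "sex", "status")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("measurement table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  for (v in MEASUREMENT_VARS) {
    x <- raw[[v]]
    bad <- which(!is.na(x) & x != "" & is.na(suppressWarnings(as.numeric(x))))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' in column %s, row %d",
                    x[bad[1]], v, bad[1]))
    }
    raw[[v]] <- suppressWarnings(as.numeric(x))
    if (any(!is.na(raw[[v]]) & raw[[v]] <= 0)) {
      abort(sprintf("non-positive measurement in column %s", v))
    }
  }
  sex_raw <- raw$sex %||% ""
  subadult <- str_detect(sex_raw, stringr::fixed("(SA)")) |
    str_detect(str_to_upper(raw$status %||% ""), "\\bSA\\b")
  sex <- str_to_upper(stringr::str_trim(sub("\\(.*\\)", "", sex_raw)))
  if (!all(sex %in% c("M", "F", ""))) {
    abort(sprintf("unparseable sex entry '%s'",
                  sex_raw[!sex %in% c("M", "F", "")][1]))
  }
  status_raw <- str_to_upper(raw$status %||% "")
  status <- dplyr::case_when(
    subadult ~ "subadult",
    status_raw == "HT" ~ "holotype",
    status_raw == "PT" ~ "paratype",
    TRUE ~ "adult"
  )
  tibble(
    catalogue = raw$catalogue,
    field_number = raw$field_number %||% NA_character_,
    species = raw$species,
    lineage = raw$lineage %||% NA_character_,
    sex = sex,
    status = status,
    adult = status != "subadult"
  ) |>
    dplyr::bind_cols(raw[, MEASUREMENT_VARS])
}

#' Integer percentage ratio of two measurements
#'
#' `round(100 * numerator / denominator)`, rounding halves away from zero
#' (98.07 -> 98, 66.67 -> 67, 0.5 -> 1).
#'
#' @param numerator,denominator measurements in mm (vectors recycle).
#' @return integer percentages.
#' @export
ratio_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) abort("denominator must be > 0")
  as.integer(round_half_away(100 * numerator / denominator))
}

#' Range of a measurement over a filtered specimen group
#'
#' @param records measurement tibble (see [load_measurements()]).
#' @param variable one of [MEASUREMENT_VARS].
#' @param species,sex optional filters (exact match).
#' @param include_subadults include subadult specimens? Default `FALSE`.
#' @return one-row tibble: `min`, `max`, `n` (non-missing values used).
#' @export
group_range <- function(records, variable, species = NULL, sex = NULL,
                        include_subadults = FALSE) {
  stopifnot(variable %in% names(records))
  sel <- records
  if (!is.null(species)) sel <- sel[sel$species == species, ]
  if (!is.null(sex)) sel <- sel[sel$sex == sex, ]
  if (!include_subadults) sel <- sel[sel$adult, ]
  vals <- sel[[variable]]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) abort("no records match the selection")
  tibble(min = min(vals), max = max(vals), n = length(vals))
}

#' Minimum-convex-polygon area of occurrence localities
#'
#' Convex hull of the points in longitude/latitude, area computed on a
#' sphere of radius 6371.0088 km. Degenerate inputs (fewer than three
#' distinct points, or collinear points) give 0.
#'
#' @param localities tibble with decimal-degree columns `lat` (south
#'   negative) and `lon` (east positive).
#' @param signif_digits significant figures of the result (default 3;
#'   `Inf` for full precision).
#' @return area in square kilometres.
#' @export
mcp_area <- function(localities, signif_digits = 3) {
  stopifnot(all(c("lat", "lon") %in% names(localities)))
  if (any(abs(localities$lat) > 90) || any(abs(localities$lon) > 180)) {
    abort("coordinates out of range")
  }
  pts <- unique(cbind(localities$lon, localities$lat))
  if (nrow(pts) < 3) return(0)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(hull) < 3) return(0)
  poly <- pts[hull, , drop = FALSE]
  # spherical polygon area, radius 6371.0088 km (f = 0 forces the sphere)
  a_m2 <- geosphere::areaPolygon(poly, a = 6371008.8, f = 0)
  a <- a_m2 / 1e6
  if (is.finite(signif_digits)) signif(a, signif_digits) else a
}
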
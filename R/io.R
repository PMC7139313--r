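#' Read a long-format laboratory CSV
#'
#' Expected header: `patient_id,day,marker,value,units,censored`. The
#' `censored` column (logical) marks below-detection values stored at half
#' the detection limit; `units` is carried through unchanged.
#'
#' @param path CSV file.
#' @param panel Marker panel used to reject unknown markers.
#' @param permissive If `TRUE`, unknown markers pass through.
#' @return Tibble of lab samples.
#' @export
read_labs_csv <- function(path, panel = marker_definitions(),
                          permissive = FALSE) {
  labs <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      day = readr::col_double(),
      marker = readr::col_character(),
      value = readr::col_double(),
      units = readr::col_character(),
      censored = readr::col_logical()
    )
  )
  if (!permissive) {
    unknown <- setdiff(unique(labs$marker), panel$marker)
    if (length(unknown) > 0) {
      stop("unknown marker(s) in ", path, ": ",
           paste(unknown, collapse = ", "),
           "; pass permissive = TRUE to keep them", call. = FALSE)
    }
  }
  labs
}

#' Write laboratory samples to CSV
#'
#' @param labs Tibble with at least `patient_id`, `day`, `marker`, `value`;
#'   `units` and `censored` are filled in when absent.
#' @param path Output file.
#' @param panel Marker panel supplying units.
#' @return `path`, invisibly.
#' @export
write_labs_csv <- function(labs, path, panel = marker_definitions()) {
  labs <- tibble::as_tibble(labs)
  if (!"units" %in% names(labs)) {
    labs$units <- panel$units[match(labs$marker, panel$marker)]
  }
  if (!"censored" %in% names(labs)) labs$censored <- FALSE
  labs <- labs[, c("patient_id", "day", "marker", "value", "units", "censored")]
  readr::write_csv(labs, path)
  invisible(path)
}

#' Read a marker definition CSV
#'
#' Expected header: `marker,units,uln,half_life_hours,role`.
#'
#' @param path CSV file.
#' @return Validated marker panel tibble.
#' @export
read_marker_table_csv <- function(path) {
  panel <- readr::read_csv(
    path,
    col_types = readr::cols(
      marker = readr::col_character(),
      units = readr::col_character(),
      uln = readr::col_double(),
      half_life_hours = readr::col_double(),
      role = readr::col_character()
    )
  )
  validate_marker_panel(panel)
  panel
}

#' Read a treatment calendar CSV
#'
#' Expected header:
#' `patient_id,course_index,agents,dose_day,nominal_interval_days`, one row
#' per dose; `agents` uses `+` to join combination partners
#' (e.g. `"nivolumab+ipilimumab"`). Dose days are on the course clock.
#'
#' @param path CSV file.
#' @return Named list (per patient) of lists of [treatment_course()].
#' @export
read_treatment_csv <- function(path) {
  cal <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      course_index = readr::col_integer(),
      agents = readr::col_character(),
      dose_day = readr::col_double(),
      nominal_interval_days = readr::col_double()
    )
  )
  split(cal, cal$patient_id) |>
    lapply(function(pt) {
      pt <- pt[order(pt$course_index, pt$dose_day), , drop = FALSE]
      lapply(split(pt, pt$course_index), function(crs) {
        treatment_course(
          agents = strsplit(crs$agents[1], "+", fixed = TRUE)[[1]],
          dose_days = crs$dose_day,
          nominal_interval_days = crs$nominal_interval_days[1]
        )
      })
    })
}

#' Read an interventions CSV
#'
#' Expected header: `patient_id,kind,day`.
#'
#' @param path CSV file.
#' @return Tibble of interventions.
#' @export
read_interventions_csv <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      kind = readr::col_character(),
      day = readr::col_double()
    )
  )
}
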
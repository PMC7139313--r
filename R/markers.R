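#' Packaged serum marker reference table
#'
#' Reference definitions for the serum analytes used in checkpoint-inhibitor
#' (CPI) laboratory monitoring of metastatic melanoma: the upper limit of
#' normal (ULN) used for normalization, native units, a typical serum
#' clearance half-life, and the monitoring role of each analyte.
#'
#' Roles group analytes by what a rise means:
#' \describe{
#'   \item{immune}{systemic immune activation (IL-6, CRP, monocyte and
#'     eosinophil counts).}
#'   \item{tumor}{tumor-derived release (S100B, LDH).}
#'   \item{organ}{organ tissue damage, i.e. immune-related adverse events
#'     (CK, myoglobin, ALT).}
#' }
#'
#' The S100B ULN is stored as printed in routine laboratory reference tables
#' (11 ug/L). Published serum ranges for melanoma patients (0.11 ug/L up to
#' above 10 ug/L) suggest the decimal point belongs two places to the left;
#' the simulator therefore defaults to 0.11 ug/L via
#' [simulator_marker_panel()]. Both are configurable.
#'
#' Half-lives for S100B (2 h) and LDH (100 h) are the values the detection
#' rationale rests on; the remaining half-lives are typical literature values
#' and act only as simulator parameters.
#'
#' @return A tibble with columns `marker`, `units`, `uln`, `half_life_hours`,
#'   `role`.
#' @examples
#' marker_definitions()
#' @export
marker_definitions <- function() {
  tibble::tribble(
    ~marker,       ~units,  ~uln,  ~half_life_hours, ~role,
    "monocytes",   "/nL",    0.60,  NA_real_,        "immune",
    "eosinophils", "/nL",    0.46,  NA_real_,        "immune",
    "CRP",         "mg/L",   5,     19,              "immune",
    "IL-6",        "pg/mL",  7,      3,              "immune",
    "LDH",         "U/L",    250,  100,              "tumor",
    "S100B",       "ug/L",   11,     2,              "tumor",
    "CK",          "U/L",    190,   12,              "organ",
    "myoglobin",   "ug/L",   72,     3,              "organ",
    "ALT",         "U/L",    50,    47,              "organ"
  )
}

#' Marker panel used by the synthetic-cohort simulator
#'
#' Identical to [marker_definitions()] except that the S100B ULN defaults to
#' 0.11 ug/L, the lower bound of the serum range reported for melanoma
#' patients (see the note in [marker_definitions()]).
#'
#' @param s100b_uln ULN used for S100B, in ug/L.
#' @return A tibble in the format of [marker_definitions()].
#' @export
simulator_marker_panel <- function(s100b_uln = 0.11) {
  stopifnot(is.numeric(s100b_uln), length(s100b_uln) == 1, s100b_uln > 0)
  panel <- marker_definitions()
  panel$uln[panel$marker == "S100B"] <- s100b_uln
  panel
}

#' Look up one marker definition
#'
#' @param name Marker name as it appears in the panel.
#' @param panel Marker definition table; defaults to [marker_definitions()].
#' @return A one-row tibble.
#' @export
marker_def <- function(name, panel = marker_definitions()) {
  validate_marker_panel(panel)
  row <- panel[panel$marker == name, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("unknown marker: ", name, call. = FALSE)
  }
  row
}

#' Validate a marker definition table
#'
#' Checks the invariants every panel must satisfy: required columns, unique
#' marker names, strictly positive ULNs, strictly positive half-lives where
#' present, and recognized roles.
#'
#' @param panel Candidate marker definition table.
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_marker_panel <- function(panel) {
  required <- c("marker", "units", "uln", "half_life_hours", "role")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    stop("marker panel lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(panel$marker) > 0) {
    stop("marker names must be unique within a panel", call. = FALSE)
  }
  if (any(!is.finite(panel$uln)) || any(panel$uln <= 0)) {
    stop("every ULN must be finite and > 0", call. = FALSE)
  }
  hl <- panel$half_life_hours
  if (any(!is.na(hl) & hl <= 0)) {
    stop("half-lives must be > 0 when present", call. = FALSE)
  }
  bad_role <- setdiff(unique(panel$role), c("immune", "tumor", "organ", "hormone"))
  if (length(bad_role) > 0) {
    stop("unknown marker role(s): ", paste(bad_role, collapse = ", "),
         call. = FALSE)
  }
  invisible(panel)
}

#' Normalize a laboratory value to percent of ULN
#'
#' Converts a native-unit measurement to the percent-of-ULN scale on which
#' all detection operates, with 100 corresponding exactly to the upper limit
#' of normal.
#'
#' @param value Numeric vector of measurements in native units; must be
#'   finite and non-negative.
#' @param marker Either a one-row marker definition (see [marker_def()]) or a
#'   positive ULN given directly.
#' @return `100 * value / uln`, a numeric vector in percent of ULN.
#' @examples
#' normalize_to_uln(5, marker_def("CRP"))   # a CRP of 5 mg/L is exactly ULN
#' normalize_to_uln(14, marker_def("IL-6")) # 200% of the 7 pg/mL ULN
#' @export
normalize_to_uln <- function(value, marker) {
  uln <- .extract_uln(marker)
  if (!is.numeric(value)) {
    stop("value must be numeric", call. = FALSE)
  }
  if (any(!is.finite(value))) {
    stop("value must be finite; got non-finite measurement(s)", call. = FALSE)
  }
  if (any(value < 0)) {
    stop("value must be >= 0; negative concentrations are not meaningful",
         call. = FALSE)
  }
  100 * value / uln
}

#' Convert a percent-of-ULN value back to native units
#'
#' Inverse of [normalize_to_uln()]: `pct * uln / 100`.
#'
#' @param pct Numeric vector on the percent-of-ULN scale.
#' @param marker One-row marker definition or a positive ULN.
#' @return Values in native units.
#' @export
denormalize_from_uln <- function(pct, marker) {
  uln <- .extract_uln(marker)
  if (!is.numeric(pct) || any(!is.finite(pct))) {
    stop("pct must be finite numeric", call. = FALSE)
  }
  pct * uln / 100
}

.extract_uln <- function(marker) {
  uln <- if (is.data.frame(marker)) {
    if (nrow(marker) != 1 || is.null(marker$uln)) {
      stop("marker must be a one-row definition with a `uln` column",
           call. = FALSE)
    }
    marker$uln
  } else {
    marker
  }
  if (!is.numeric(uln) || length(uln) != 1 || !is.finite(uln) || uln <= 0) {
    stop("ULN must be a single finite number > 0", call. = FALSE)
  }
  uln
}
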
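.COHORT_MD5 <- "ac5ddb8586a5c1071f452c5277fde2ec"
.COHORT_VERSION <- "1.0"

#' Load the packaged 17-patient melanoma cohort table
#'
#' Per-course records of the packaged monitoring cohort: treatment (agents,
#' cycle counts, induction cycles for combination blocks), the immune marker
#' whose rise paralleled the tumor-marker release (`tmr_im`; `"paradox"`
#' marks the parallel-decline reaction), tumor-marker response days, irAE
#' labels with days and associated immune markers, best response, and
#' survival. Cells that print two days keep the non-parenthetical one as
#' primary (`tmr_days`) and the other as `tmr_day_secondary`; `tmr_lag`
#' marks courses where the S100B peak followed the IL-6 peak by 14 days.
#' One hepatitis day shared across a line-spanning cell is kept with
#' `irae_ambiguous = TRUE`. Survival strings with a `>` prefix are parsed as
#' right-censored.
#'
#' The file is integrity-checked against a packaged md5 checksum.
#'
#' @return Tibble with one row per treatment course (24 rows, 17 patients)
#'   and parsed columns `survival_months`, `survival_censored`,
#'   `tmr_day_primary`.
#' @export
load_cohort_fixture <- function() {
  path <- system.file("extdata", "melanoma_cohort_courses.csv", package = "tolbreak")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged cohort fixture not found", call. = FALSE)
  }
  sum_ <- unname(tools::md5sum(path))
  if (!identical(sum_, .COHORT_MD5)) {
    stop("cohort fixture checksum mismatch: file is corrupted", call. = FALSE)
  }
  rec <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_no = readr::col_integer(),
      tnm = readr::col_character(),
      course_index = readr::col_integer(),
      agents = readr::col_character(),
      cycles = readr::col_integer(),
      induction_cycles = readr::col_integer(),
      tmr_im = readr::col_character(),
      tmr_days = readr::col_character(),
      tmr_day_secondary = readr::col_double(),
      tmr_lag = readr::col_logical(),
      irae = readr::col_character(),
      irae_days = readr::col_character(),
      irae_im = readr::col_character(),
      irae_ambiguous = readr::col_logical(),
      best_response = readr::col_character(),
      survival = readr::col_character()
    )
  )
  rec$survival_censored <- startsWith(rec$survival, ">")
  rec$survival_months <- as.numeric(sub("^>", "", rec$survival))
  rec$tmr_day_primary <- vapply(rec$tmr_days, function(x) {
    if (is.na(x)) NA_real_ else as.numeric(strsplit(x, ";")[[1]][1])
  }, numeric(1), USE.NAMES = FALSE)
  attr(rec, "fixture_version") <- .COHORT_VERSION
  rec
}

#' Cohort-level summary counts
#'
#' Summarizes a per-course cohort table (as returned by
#' [load_cohort_fixture()]) into the headline counts: cohort size, patients
#' with an IL-6-parallel tumor-marker response in any course, patients per
#' regimen class (ipilimumab monotherapy, anti-PD-1 monotherapy,
#' combination; a patient treated sequentially counts in each class
#' received), the latest tumor-marker-response day among ipilimumab
#' monotherapy courses, and patients with a paradox reaction. The summary is
#' invariant under record order.
#'
#' @param records Per-course cohort tibble.
#' @return List of class `cohort_summary` with fields `n_patients`,
#'   `n_il6_parallel_tmr`, `n_per_regimen` (named: `ipilimumab_mono`,
#'   `anti_pd1`, `combination`), `max_tmr_day_ipi_mono`, `n_paradox`.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) == 0) {
    return(structure(
      list(n_patients = 0L, n_il6_parallel_tmr = 0L,
           n_per_regimen = c(ipilimumab_mono = 0L, anti_pd1 = 0L,
                             combination = 0L),
           max_tmr_day_ipi_mono = NA_real_, n_paradox = 0L),
      class = "cohort_summary"
    ))
  }
  has_il6 <- !is.na(records$tmr_im) &
    vapply(strsplit(records$tmr_im, ";"), function(x) "IL-6" %in% x,
           logical(1))
  is_ipi_mono <- records$agents == "ipilimumab"
  is_anti_pd1 <- records$agents %in% c("nivolumab", "pembrolizumab")
  is_combo <- grepl("+", records$agents, fixed = TRUE)
  n_by <- function(keep) length(unique(records$patient_no[keep]))
  ipi_days <- records$tmr_day_primary[is_ipi_mono]
  structure(
    list(
      n_patients = length(unique(records$patient_no)),
      n_il6_parallel_tmr = n_by(has_il6),
      n_per_regimen = c(
        ipilimumab_mono = n_by(is_ipi_mono),
        anti_pd1 = n_by(is_anti_pd1),
        combination = n_by(is_combo)
      ),
      max_tmr_day_ipi_mono = if (all(is.na(ipi_days))) NA_real_ else
        max(ipi_days, na.rm = TRUE),
      n_paradox = n_by(!is.na(records$tmr_im) & records$tmr_im == "paradox")
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat("  patients:                     ", x$n_patients, "\n")
  cat("  IL-6-parallel TMR:            ", x$n_il6_parallel_tmr, "\n")
  cat("  ipilimumab monotherapy:       ", x$n_per_regimen[["ipilimumab_mono"]], "\n")
  cat("  anti-PD-1 monotherapy:        ", x$n_per_regimen[["anti_pd1"]], "\n")
  cat("  combination therapy:          ", x$n_per_regimen[["combination"]], "\n")
  cat("  latest TMR day (ipi. mono):   ", x$max_tmr_day_ipi_mono, "\n")
  cat("  paradox reactions:            ", x$n_paradox, "\n")
  invisible(x)
}

#' Write a structured JSON report
#'
#' Serializes a cohort summary, a (list of) patient classification(s), or a
#' plain list into a deterministic JSON report carrying the tool version and
#' any parameters/seed supplied. Running twice on the same input yields
#' byte-identical files (no timestamps).
#'
#' @param x A `cohort_summary`, `patient_classification`, list of
#'   classifications, or plain list.
#' @param path Output file.
#' @param params Optional parameter set (e.g. [detection_params()]) echoed
#'   into the report.
#' @param seed Optional seed echoed into the report.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, params = NULL, seed = NULL) {
  body <- .report_body(x)
  report <- list(
    tool = "tolbreak",
    version = as.character(utils::packageVersion("tolbreak"))
  )
  if (!is.null(seed)) report$seed <- seed
  if (!is.null(params)) report$parameters <- unclass(params)
  report$content <- body
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.report_body <- function(x) {
  if (inherits(x, "cohort_summary")) {
    y <- unclass(x)
    y$n_per_regimen <- as.list(y$n_per_regimen)
    return(y)
  }
  if (inherits(x, "patient_classification")) {
    return(list(
      patient_id = x$patient_id,
      tmr_day = x$tmr_day, tmr_course = x$tmr_course,
      irae_day = x$irae_day, irae_course = x$irae_course,
      same_cycle = x$same_cycle,
      flags = x$flags,
      calls = x$calls,
      episodes = x$episodes
    ))
  }
  if (is.list(x) && length(x) > 0 &&
      all(vapply(x, inherits, logical(1), "patient_classification"))) {
    return(lapply(x, .report_body))
  }
  x
}
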
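#' Construct a treatment course
#'
#' A course is one block of checkpoint-inhibitor dosing: the agent set, the
#' actual dose days (relative to the first dose of the course, day 0), and
#' the nominal inter-dose interval of the regimen. Actual dose days take
#' precedence over the nominal calendar everywhere; the nominal interval is
#' only used to close the final cycle.
#'
#' @param agents Character vector, subset of
#'   `c("ipilimumab", "nivolumab", "pembrolizumab")`.
#' @param dose_days Strictly increasing numeric vector of dose days; the
#'   first dose defines day 0 of the course.
#' @param nominal_interval_days Nominal inter-dose interval: 14, 21 or 28.
#' @return An object of class `treatment_course`.
#' @examples
#' treatment_course("ipilimumab", dose_days = c(0, 21, 42, 63))
#' @export
treatment_course <- function(agents, dose_days,
                             nominal_interval_days = 21) {
  known <- c("ipilimumab", "nivolumab", "pembrolizumab")
  agents <- unique(agents)
  if (length(agents) == 0 || !all(agents %in% known)) {
    stop("agents must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (length(dose_days) == 0 || any(!is.finite(dose_days))) {
    stop("dose_days must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (is.unsorted(dose_days, strictly = TRUE)) {
    stop("dose_days must be strictly increasing", call. = FALSE)
  }
  if (!nominal_interval_days %in% c(14, 21, 28)) {
    stop("nominal_interval_days must be one of 14, 21, 28", call. = FALSE)
  }
  structure(
    list(
      agents = agents,
      dose_days = as.numeric(dose_days),
      nominal_interval_days = as.numeric(nominal_interval_days)
    ),
    class = "treatment_course"
  )
}

#' @export
print.treatment_course <- function(x, ...) {
  cat("<treatment_course> ", paste(x$agents, collapse = " + "),
      " | doses at day ", paste(x$dose_days, collapse = ", "),
      " | q", x$nominal_interval_days, "d\n", sep = "")
  invisible(x)
}

#' Day on which a course's observation window closes
#'
#' The last cycle extends one nominal interval past the final dose.
#'
#' @param course A [treatment_course()].
#' @return Numeric day.
#' @export
course_end <- function(course) {
  stopifnot(inherits(course, "treatment_course"))
  max(course$dose_days) + course$nominal_interval_days
}

#' Assign a day to a treatment cycle
#'
#' Cycle k is the half-open interval from dose k (inclusive) to dose k+1
#' (exclusive); the final cycle runs one nominal interval past its dose.
#' Every in-range day therefore belongs to exactly one cycle. Days before
#' the first dose or at/after the end of the last cycle get `NA`.
#'
#' @param day Numeric vector of days on the course clock.
#' @param course A [treatment_course()].
#' @return Integer vector of 1-based cycle indices, `NA` where out of range.
#' @examples
#' crs <- treatment_course("ipilimumab", c(0, 21, 42))
#' assign_cycle(c(0, 35, 62, 70), crs)
#' @export
assign_cycle <- function(day, course) {
  stopifnot(inherits(course, "treatment_course"))
  starts <- course$dose_days
  bounds <- c(starts, course_end(course))
  idx <- findInterval(day, bounds)  # half-open [bounds[i], bounds[i+1])
  idx[day < starts[1] | idx > length(starts)] <- NA_integer_
  as.integer(idx)
}

#' Record a corticosteroid intervention
#'
#' @param kind `"corticosteroid_start"` or `"corticosteroid_stop"`.
#' @param day Day of the intervention on the course clock.
#' @return One-row tibble with columns `kind`, `day`.
#' @export
intervention_event <- function(kind, day) {
  kind <- match.arg(kind, c("corticosteroid_start", "corticosteroid_stop"))
  stopifnot(is.numeric(day), length(day) == 1, is.finite(day))
  tibble::tibble(kind = kind, day = as.numeric(day))
}

#' Assemble a patient course
#'
#' Bundles a patient's sequential treatment courses, interventions, lab
#' panel and outcome into the unit the classifier operates on. Lab days are
#' kept on a single patient clock (days since the first dose of the first
#' course); each course's `dose_days` live on its own clock and
#' `course_start_days` maps them onto the patient clock. Classification
#' re-zeroes labs at each course start.
#'
#' @param patient_id Identifier.
#' @param courses A [treatment_course()] or list of them, in treatment order.
#' @param labs Long tibble of laboratory samples with columns
#'   `day`, `marker`, `value`, and optionally `censored` (logical; values at
#'   the detection limit stored as limit/2). Days may be negative for
#'   pre-treatment baselines.
#' @param course_start_days Numeric vector, one entry per course: day of the
#'   course's first dose on the patient clock. Defaults to `0` for a single
#'   course.
#' @param interventions Tibble of [intervention_event()] rows (patient clock),
#'   or `NULL`.
#' @param outcome Best response: `"CR"`, `"PR"`, `"PD"` or `"unknown"`.
#' @return An object of class `patient_course`.
#' @export
patient_course <- function(patient_id, courses, labs,
                           course_start_days = NULL,
                           interventions = NULL,
                           outcome = "unknown") {
  if (inherits(courses, "treatment_course")) courses <- list(courses)
  stopifnot(length(courses) >= 1,
            all(vapply(courses, inherits, logical(1), "treatment_course")))
  if (is.null(course_start_days)) {
    if (length(courses) != 1) {
      stop("course_start_days is required for multi-course patients",
           call. = FALSE)
    }
    course_start_days <- 0
  }
  stopifnot(length(course_start_days) == length(courses),
            !is.unsorted(course_start_days, strictly = TRUE))
  outcome <- match.arg(outcome, c("CR", "PR", "PD", "unknown"))
  labs <- tibble::as_tibble(labs)
  if (!"censored" %in% names(labs)) labs$censored <- FALSE
  if (is.null(interventions)) {
    interventions <- tibble::tibble(kind = character(), day = numeric())
  }
  structure(
    list(
      patient_id = patient_id,
      courses = courses,
      course_start_days = as.numeric(course_start_days),
      interventions = tibble::as_tibble(interventions),
      labs = labs,
      outcome = outcome
    ),
    class = "patient_course"
  )
}

#' @export
print.patient_course <- function(x, ...) {
  cat("<patient_course> ", x$patient_id, ": ", length(x$courses),
      " course(s), ", nrow(x$labs), " lab samples over ",
      length(unique(x$labs$marker)), " markers, outcome ", x$outcome, "\n",
      sep = "")
  invisible(x)
}

#' Validate a patient course
#'
#' Checks every structural invariant and returns violations as data rather
#' than raising: each violation names the patient, the offending field and
#' the broken rule.
#'
#' @param patient A [patient_course()].
#' @param panel Marker panel the labs must reference;
#'   defaults to [marker_definitions()].
#' @param permissive If `TRUE`, unknown markers are tolerated.
#' @return Tibble with columns `patient_id`, `field`, `rule`; zero rows when
#'   everything holds.
#' @export
validate_course <- function(patient, panel = marker_definitions(),
                            permissive = FALSE) {
  stopifnot(inherits(patient, "patient_course"))
  v <- list()
  note <- function(field, rule) {
    v[[length(v) + 1]] <<- tibble::tibble(
      patient_id = patient$patient_id, field = field, rule = rule
    )
  }

  for (i in seq_along(patient$courses)) {
    dd <- patient$courses[[i]]$dose_days
    if (is.unsorted(dd, strictly = TRUE)) {
      note(sprintf("courses[%d]$dose_days", i), "strictly increasing")
    }
  }
  # courses must not overlap on the patient clock
  if (length(patient$courses) > 1) {
    ends <- patient$course_start_days +
      vapply(patient$courses, course_end, numeric(1))
    if (any(ends[-length(ends)] > patient$course_start_days[-1])) {
      note("courses", "courses must not overlap in dose days")
    }
  }

  labs <- patient$labs
  if (!permissive) {
    unknown <- setdiff(unique(labs$marker), panel$marker)
    if (length(unknown) > 0) {
      note("labs$marker",
           paste("unknown marker(s):", paste(unknown, collapse = ", ")))
    }
  }
  for (m in unique(labs$marker)) {
    s <- labs[labs$marker == m, , drop = FALSE]
    if (is.unsorted(s$day, strictly = TRUE)) {
      note(sprintf("labs[%s]$day", m), "days strictly increasing")
    }
    if (any(!is.finite(s$value)) || any(s$value < 0)) {
      note(sprintf("labs[%s]$value", m), "values finite and >= 0")
    }
  }

  iv <- patient$interventions
  if (nrow(iv) > 0) {
    start <- iv$day[iv$kind == "corticosteroid_start"]
    stop_ <- iv$day[iv$kind == "corticosteroid_stop"]
    if (length(start) > 0 && length(stop_) > 0 &&
        min(start) >= min(stop_)) {
      note("interventions", "corticosteroid start must precede stop")
    }
  }

  if (length(v) == 0) {
    tibble::tibble(patient_id = character(), field = character(),
                   rule = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Extract one marker's series from a patient's labs
#'
#' @param patient A [patient_course()].
#' @param marker Marker name.
#' @param course_index Which course's clock to use; samples are restricted
#'   to `[course_start - baseline_window, course_start + course_end]` and
#'   re-zeroed at the course start.
#' @param baseline_window Days of pre-course samples retained.
#' @return Tibble `day`, `value`, `censored` on the course clock.
#' @export
course_series <- function(patient, marker, course_index = 1,
                          baseline_window = 14) {
  stopifnot(inherits(patient, "patient_course"))
  start <- patient$course_start_days[course_index]
  end <- start + course_end(patient$courses[[course_index]])
  s <- patient$labs[patient$labs$marker == marker, , drop = FALSE]
  s <- s[s$day >= start - baseline_window & s$day <= end, , drop = FALSE]
  tibble::tibble(day = s$day - start, value = s$value, censored = s$censored)
}
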
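#' Simulator configuration for one patient archetype
#'
#' Bundles everything [generate_patient()] needs. Archetypes encode the
#' qualitative courses seen under checkpoint inhibition:
#' \describe{
#'   \item{responder}{immune-mediated kill events shrink the tumor; final
#'     tumor-marker release ends below its pre-treatment value.}
#'   \item{non_responder}{no kills, tumor keeps growing; markers drift up
#'     slowly.}
#'   \item{paradox}{from the first dose, tumor marker release and the
#'     autocrine IL-6 loop shut down (cell-cycle arrest), producing the
#'     steep parallel first-cycle decline of S100B and IL-6.}
#'   \item{autocrine_progressor}{growing tumor that itself secretes IL-6, so
#'     S100B and IL-6 rise in parallel, imitating an immune response.}
#'   \item{irae_coupled}{responder plus organ-damage events (e.g. CK
#'     myositis).}
#'   \item{flat_control}{no kills, no growth, no immune pulses; every series
#'     is flat apart from sampling noise. Used as the detection null.}
#' }
#'
#' Unset fields get archetype-appropriate defaults; any field can be
#' overridden explicitly. The seed is mandatory and is echoed into every
#' output.
#'
#' @param archetype One of the six archetypes above.
#' @param seed Integer random seed (recorded in all outputs).
#' @param course Treatment calendar; default five q21d doses.
#' @param kill_events,irae_events Ground-truth event tibbles
#'   ([kill_event()], [irae_event()]); archetype defaults when `NULL`.
#' @param tumor,immune Parameter sets; archetype defaults when `NULL`.
#' @param sampling_interval_days Lab draw spacing, days (weekly default).
#' @param noise_cv Lognormal coefficient of variation of measurement noise.
#' @param detection_limits Named numeric vector of per-marker detection
#'   limits in native units; `NULL` disables censoring.
#' @param step Dense-grid step, days (1/96 d = 15 min).
#' @param panel Marker panel; defaults to [simulator_marker_panel()] (S100B
#'   ULN 0.11 ug/L).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(archetype = c("responder", "non_responder",
                                          "paradox", "autocrine_progressor",
                                          "irae_coupled", "flat_control"),
                            seed,
                            course = NULL,
                            kill_events = NULL,
                            irae_events = NULL,
                            tumor = NULL,
                            immune = NULL,
                            sampling_interval_days = 7,
                            noise_cv = 0.15,
                            detection_limits = NULL,
                            step = 1 / 96,
                            panel = simulator_marker_panel()) {
  archetype <- match.arg(archetype)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(sampling_interval_days > 0, noise_cv >= 0, step > 0)
  seed <- as.integer(seed)
  if (is.null(course)) {
    course <- treatment_course("nivolumab", dose_days = seq(0, 84, by = 21),
                               nominal_interval_days = 21)
  }

  if (is.null(tumor)) {
    tumor <- switch(
      archetype,
      responder = tumor_params(),
      non_responder = tumor_params(),
      paradox = tumor_params(autocrine_il6_c = 28),
      autocrine_progressor = tumor_params(growth_rate_g = 0.01,
                                          autocrine_il6_c = 20),
      irae_coupled = tumor_params(),
      flat_control = tumor_params(growth_rate_g = 0)
    )
  }
  if (is.null(immune)) {
    immune <- switch(
      archetype,
      # paradox patients are hypothesized autocrine-IL-6 dominated (most
      # baseline IL-6 from the tumor, little immune tone) and show no
      # post-dose immune pulses -- the parallel decline IS the phenotype
      paradox = immune_pulse_params(base_amplitude = 0,
                                    il6_basal_pct_uln = 10),
      flat_control = immune_pulse_params(base_amplitude = 0),
      immune_pulse_params()
    )
  }
  if (is.null(kill_events)) {
    kill_events <- switch(
      archetype,
      responder = ,
      irae_coupled = kill_event(day = course$dose_days[2] + 2.5,
                                intensity_kappa = 1),
      kill_event(numeric(0), numeric(0))
    )
  }
  if (is.null(irae_events)) {
    irae_events <- if (archetype == "irae_coupled") {
      irae_event(day = course$dose_days[3] + 2)
    } else {
      irae_event(numeric(0), character(0), numeric(0))
    }
  }
  structure(
    list(archetype = archetype, seed = seed, course = course,
         kill_events = kill_events, irae_events = irae_events,
         tumor = tumor, immune = immune,
         sampling_interval_days = sampling_interval_days,
         noise_cv = noise_cv, detection_limits = detection_limits,
         step = step, panel = panel),
    class = "scenario_config"
  )
}

#' Generate one synthetic patient
#'
#' Runs the full kinetic model for a [scenario_config()]: tumor mass under
#' growth and kills, phasic immune activity, marker release (turnover, kill,
#' autocrine, irAE) and one-compartment serum kinetics, then samples noisy
#' labs on the configured schedule. Identical configs (including seed) give
#' identical output.
#'
#' @param config A [scenario_config()].
#' @param interventions Optional tibble of [intervention_event()] rows.
#' @param patient_id Identifier written into the labs.
#' @param include_dense Keep the dense trajectories (memory-heavier) for
#'   diagnostics and conservation checks.
#' @return List of class `simulated_patient` with elements
#'   `patient` (a [patient_course()]), `ground_truth` (archetype, kill and
#'   irAE days, seed, warnings) and, when requested, `dense`
#'   (tibble `time`, `marker`, `release`, `conc`).
#' @export
generate_patient <- function(config, interventions = NULL,
                             patient_id = paste0("sim-", config$seed),
                             include_dense = TRUE) {
  stopifnot(inherits(config, "scenario_config"))
  warnings <- character()
  if (config$archetype == "paradox" && config$tumor$autocrine_il6_c == 0) {
    warnings <- c(warnings,
                  "paradox archetype with autocrine_il6_c = 0: IL-6 has no tumor-derived component to lose")
  }
  course <- config$course
  horizon <- course_end(course)
  panel <- config$panel

  tumor_traj <- simulate_tumor_mass(config$tumor, config$kill_events,
                                    horizon = horizon, step = config$step)
  times <- tumor_traj$time
  immune_traj <- simulate_immune_activity(config$immune, course,
                                          interventions = interventions,
                                          horizon = horizon,
                                          step = config$step, panel = panel)

  # release shutdown multiplier (paradox archetype only)
  decline <- if (config$archetype == "paradox") {
    fl <- config$tumor$release_decline_floor
    fl + (1 - fl) * exp(-pmax(times - course$dose_days[1], 0) /
                          config$tumor$release_decline_tau_days)
  } else {
    rep(1, length(times))
  }

  tum <- config$tumor
  turnover <- tum$per_cell_release_c * tum$cell_loss_fraction_phi *
    tumor_traj$mass * decline
  if (tum$expression_loss) turnover <- turnover * 0
  kill_release <- tum$kill_release_c *
    .release_compartment(times, tumor_traj$killed_mass_rate,
                         tum$kill_release_tau_days)
  if (tum$expression_loss) kill_release <- kill_release * 0
  s100b_release <- turnover + kill_release

  il6_release <- immune_traj$il6_release +
    tum$autocrine_il6_c * tumor_traj$mass * decline
  crp_release <- immune_traj$crp_release

  release_tbl <- list(
    "S100B" = s100b_release,
    "IL-6" = il6_release,
    "CRP" = crp_release
  )
  # organ markers: flat basal turnover at 25 %ULN plus irAE pulses
  irae_rel <- simulate_irae(config$irae_events, immune_traj)
  for (m in unique(irae_rel$marker)) {
    md <- marker_def(m, panel)
    basal <- 0.25 * md$uln * clearance_lambda(md)
    release_tbl[[m]] <- basal + irae_rel$release[irae_rel$marker == m]
  }

  dense <- dplyr::bind_rows(lapply(names(release_tbl), function(m) {
    md <- marker_def(m, panel)
    serum <- simulate_marker_serum(times, release_tbl[[m]], md)
    tibble::tibble(time = times, marker = m,
                   release = release_tbl[[m]], conc = serum$conc)
  }))

  labs <- withr::with_seed(
    config$seed,
    sample_labs(dense, config)
  )
  labs$patient_id <- patient_id
  labs <- labs[, c("patient_id", "day", "marker", "value", "censored")]

  outcome <- switch(config$archetype,
                    responder = "PR", irae_coupled = "PR",
                    non_responder = "PD", autocrine_progressor = "PD",
                    paradox = "PD", flat_control = "unknown")
  patient <- patient_course(
    patient_id = patient_id, courses = course, labs = labs,
    interventions = interventions, outcome = outcome
  )
  out <- list(
    patient = patient,
    ground_truth = list(
      archetype = config$archetype,
      kill_days = config$kill_events$day,
      irae_days = config$irae_events$day,
      seed = config$seed,
      warnings = warnings
    )
  )
  if (include_dense) out$dense <- dense
  structure(out, class = "simulated_patient")
}

#' @export
print.simulated_patient <- function(x, ...) {
  gt <- x$ground_truth
  cat("<simulated_patient> ", x$patient$patient_id, " (", gt$archetype,
      ", seed ", gt$seed, ")\n", sep = "")
  if (length(gt$kill_days) > 0) {
    cat("  kill events at day:", paste(round(gt$kill_days, 1), collapse = ", "), "\n")
  }
  if (length(gt$irae_days) > 0) {
    cat("  irAE events at day:", paste(round(gt$irae_days, 1), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sample noisy laboratory draws from dense trajectories
#'
#' Samples at `0, delta, 2 delta, ...` up to the end of the grid, applies
#' multiplicative lognormal noise with the configured coefficient of
#' variation (mean-preserving parameterization), and censors values below
#' the per-marker detection limit at half the limit.
#'
#' @param dense Tibble `time`, `marker`, `conc`.
#' @param config A [scenario_config()] (uses `sampling_interval_days`,
#'   `noise_cv`, `detection_limits`).
#' @return Tibble `day`, `marker`, `value`, `censored`.
#' @export
sample_labs <- function(dense, config) {
  delta <- config$sampling_interval_days
  stopifnot(delta > 0)
  days <- seq(0, max(dense$time), by = delta)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  out <- lapply(unique(dense$marker), function(m) {
    d <- dense[dense$marker == m, , drop = FALSE]
    truth <- stats::approx(d$time, d$conc, xout = days, rule = 2)$y
    noise <- if (config$noise_cv > 0) {
      exp(stats::rnorm(length(days), mean = -sdlog^2 / 2, sd = sdlog))
    } else {
      rep(1, length(days))
    }
    value <- truth * noise
    censored <- rep(FALSE, length(days))
    lim <- config$detection_limits[[m]]
    if (!is.null(lim)) {
      censored <- value < lim
      value[censored] <- lim / 2
    }
    tibble::tibble(day = days, marker = m, value = value,
                   censored = censored)
  })
  dplyr::bind_rows(out)
}

#' Generate a seeded cohort of one archetype
#'
#' Draws per-patient seeds and (for responder-type archetypes) randomized
#' kill timing from a single master seed: the kill lands in a uniformly
#' chosen cycle among the first three, one to four days after its dose,
#' mirroring immune-mediated kill following the post-dose pulse.
#'
#' @param n Number of patients.
#' @param archetype Archetype passed to [scenario_config()].
#' @param seed Master seed.
#' @param sampling_interval_days Lab spacing, days.
#' @param include_dense Keep dense trajectories per patient.
#' @param ... Further arguments forwarded to [scenario_config()].
#' @return List of `simulated_patient` objects, length `n`.
#' @export
generate_cohort <- function(n, archetype, seed,
                            sampling_interval_days = 7,
                            include_dense = FALSE, ...) {
  draws <- withr::with_seed(as.integer(seed), {
    tibble::tibble(
      patient_seed = sample.int(.Machine$integer.max - 1, n),
      kill_cycle = sample(1:3, n, replace = TRUE),
      kill_offset = stats::runif(n, 1, 4)
    )
  })
  lapply(seq_len(n), function(i) {
    extra <- list(...)
    args <- c(
      list(archetype = archetype, seed = draws$patient_seed[i],
           sampling_interval_days = sampling_interval_days),
      extra
    )
    cfg <- do.call(scenario_config, args)
    if (archetype %in% c("responder", "irae_coupled") &&
        !"kill_events" %in% names(extra)) {
      day <- cfg$course$dose_days[draws$kill_cycle[i]] + draws$kill_offset[i]
      args$kill_events <- kill_event(day = day, intensity_kappa = 1)
      cfg <- do.call(scenario_config, args)
    }
    generate_patient(cfg, patient_id = sprintf("%s-%03d", archetype, i),
                     include_dense = include_dense)
  })
}
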
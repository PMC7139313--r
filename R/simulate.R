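#' Tumor compartment parameters
#'
#' Parameters of the tumor-mass and marker-release model. Tumor mass `M(t)`
#' follows `dM/dt = (g - k(t)) M` where `k(t)` is the kill-rate density of
#' the configured [kill_event()]s. Marker release has two routes:
#' steady turnover release `per_cell_release_c * phi * M(t)` driven by the
#' spontaneous cell loss fraction `phi`, and kill release
#' `kill_release_c * k(t) M(t)` from immune-mediated destruction. Killed-cell
#' marker content drains into serum through a first-order tissue-release
#' compartment with time constant `kill_release_tau_days` (necrotic debris is
#' not lysed instantaneously), which is what stretches a one-day kill into a
#' week-scale serum elevation observable at weekly sampling.
#'
#' @param M0 Initial tumor mass, arbitrary mass units.
#' @param growth_rate_g Net per-day growth rate.
#' @param cell_loss_fraction_phi Fraction of turnover lost to cell death,
#'   in \[0, 1\]; melanoma estimates reach 0.7.
#' @param per_cell_release_c Marker units released per mass unit per day via
#'   turnover.
#' @param kill_release_c Marker units released per unit of killed mass.
#' @param kill_release_tau_days Time constant (days) of the tissue-release
#'   compartment for killed-cell marker content.
#' @param expression_loss If `TRUE` the tumor has lost marker expression and
#'   releases none (S100B-negative progression).
#' @param autocrine_il6_c IL-6 units released per mass unit per day by the
#'   tumor itself (autocrine loop); 0 disables.
#' @param release_decline_tau_days,release_decline_floor Shape of the
#'   release shutdown used by the paradox archetype: from the first dose,
#'   turnover and autocrine release are multiplied by
#'   `floor + (1 - floor) exp(-t / tau)`.
#' @return List of class `tumor_params`.
#' @export
tumor_params <- function(M0 = 1,
                         growth_rate_g = 0.005,
                         cell_loss_fraction_phi = 0.7,
                         per_cell_release_c = 0.26,
                         kill_release_c = 12,
                         kill_release_tau_days = 4,
                         expression_loss = FALSE,
                         autocrine_il6_c = 0,
                         release_decline_tau_days = 4,
                         release_decline_floor = 0.05) {
  stopifnot(M0 > 0,
            cell_loss_fraction_phi >= 0, cell_loss_fraction_phi <= 1,
            per_cell_release_c >= 0, kill_release_c >= 0,
            kill_release_tau_days > 0, autocrine_il6_c >= 0,
            release_decline_tau_days > 0,
            release_decline_floor >= 0, release_decline_floor <= 1)
  structure(as.list(environment()), class = "tumor_params")
}

#' Phasic immune pulse parameters
#'
#' Each checkpoint-inhibitor dose triggers a pulse of immune activity shaped
#' as a difference of exponentials (rise and decay time constants). A pulse
#' consists of `n_subpeaks` sub-peaks spaced `oscillation_period_days` apart,
#' reproducing the few-day oscillations and double peaks seen in monitored
#' patients. Pulse amplitude grows geometrically with cycle number
#' (`booster_factor_b`, the treatment-induced booster effect) and is damped
#' multiplicatively by `cort_suppression_s` for every dose at or after a
#' corticosteroid start. Activity is phasic: it decays toward the basal level
#' between doses rather than accumulating.
#'
#' IL-6 and CRP serum release rates are affine in activity:
#' basal release holding the marker at `*_basal_pct_uln` percent of ULN plus
#' `*_release_per_activity` times the activity.
#'
#' @param base_amplitude First-cycle pulse amplitude (activity units).
#' @param rise_tau_days,decay_tau_days Pulse rise/decay time constants, days.
#' @param booster_factor_b Multiplicative amplitude growth per cycle
#'   (1 = none).
#' @param oscillation_period_days Spacing of sub-peaks within a pulse, days.
#' @param n_subpeaks Sub-peaks per pulse (2 gives the classic double peak).
#' @param cort_suppression_s Multiplier in \[0, 1\] applied to pulse
#'   amplitudes from the corticosteroid start onward (1 = no steroids).
#' @param il6_release_per_activity,crp_release_per_activity Release-rate
#'   coefficients (native units per mL-equivalent per day per activity unit).
#' @param il6_basal_pct_uln,crp_basal_pct_uln Steady basal level, % of ULN.
#' @return List of class `immune_pulse_params`.
#' @export
immune_pulse_params <- function(base_amplitude = 1,
                                rise_tau_days = 1,
                                decay_tau_days = 3,
                                booster_factor_b = 1.2,
                                oscillation_period_days = 4,
                                n_subpeaks = 2,
                                cort_suppression_s = 1,
                                il6_release_per_activity = 60,
                                crp_release_per_activity = 9,
                                il6_basal_pct_uln = 30,
                                crp_basal_pct_uln = 20) {
  stopifnot(base_amplitude >= 0, rise_tau_days > 0, decay_tau_days > 0,
            rise_tau_days < decay_tau_days,
            booster_factor_b >= 0, oscillation_period_days > 0,
            n_subpeaks >= 1,
            cort_suppression_s >= 0, cort_suppression_s <= 1)
  structure(as.list(environment()), class = "immune_pulse_params")
}

#' A ground-truth tumor kill event
#'
#' Immune-mediated tumor destruction modeled as a top-hat kill-rate pulse of
#' width one day starting at `day`, with integrated per-capita kill
#' `intensity_kappa` (so surviving fraction `exp(-kappa)` when growth is
#' negligible). The day is the ground truth against which detection recovery
#' is scored.
#'
#' @param day Start day of the kill pulse.
#' @param intensity_kappa Integrated per-capita kill, dimensionless, >= 0.
#' @return One-row tibble.
#' @export
kill_event <- function(day, intensity_kappa = 1) {
  stopifnot(is.finite(day), intensity_kappa >= 0)
  tibble::tibble(day = as.numeric(day),
                 intensity_kappa = as.numeric(intensity_kappa))
}

#' A ground-truth immune-related adverse event
#'
#' Injects an organ-marker release pulse peaking at `day`, scaled by the
#' immune activity at that day (irAE severity tracks concurrent immune
#' activation).
#'
#' @param day Day of peak organ-marker release.
#' @param organ_marker Name of the organ marker (e.g. `"CK"`, `"ALT"`,
#'   `"myoglobin"`).
#' @param release_magnitude Release-rate scale, native units per day per
#'   activity unit; >= 0.
#' @return One-row tibble.
#' @export
irae_event <- function(day, organ_marker = "CK", release_magnitude = 700) {
  stopifnot(is.finite(day), release_magnitude >= 0)
  tibble::tibble(day = as.numeric(day), organ_marker = organ_marker,
                 release_magnitude = as.numeric(release_magnitude))
}

#' Clearance rate constant of a marker, per day
#'
#' @param marker One-row marker definition with `half_life_hours`.
#' @return `log(2) / (half_life_hours / 24)`.
#' @export
clearance_lambda <- function(marker) {
  hl <- if (is.data.frame(marker)) marker$half_life_hours else marker
  if (is.na(hl) || !is.finite(hl) || hl <= 0) {
    stop("marker has no usable serum half-life; supply half_life_hours > 0",
         call. = FALSE)
  }
  log(2) / (hl / 24)
}

# Normalized difference-of-exponentials pulse kernel, peak value 1 at
# t_peak = log(td/tr) * tr * td / (td - tr); zero for u < 0.
.pulse_kernel <- function(u, rise_tau, decay_tau) {
  peak_t <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  norm <- exp(-peak_t / decay_tau) - exp(-peak_t / rise_tau)
  out <- numeric(length(u))
  pos <- u >= 0
  out[pos] <- (exp(-u[pos] / decay_tau) - exp(-u[pos] / rise_tau)) / norm
  out
}

.pulse_kernel_peak_time <- function(rise_tau, decay_tau) {
  log(decay_tau / rise_tau) * rise_tau * decay_tau / (decay_tau - rise_tau)
}

#' Simulate tumor mass under growth and kill events
#'
#' Integrates `dM/dt = (g - k(t)) M` on a regular grid with exact
#' exponential steps; the per-step integral of the top-hat kill density is
#' computed in closed form, so a single kill of intensity `kappa` at zero
#' growth leaves exactly `M0 * exp(-kappa)`.
#'
#' @param tumor A [tumor_params()].
#' @param kills Tibble of [kill_event()] rows (may be empty or `NULL`).
#' @param horizon Simulation end, days; must be > 0.
#' @param step Grid step, days.
#' @return Tibble `time`, `mass`, `killed_mass_rate` (mass units/day).
#' @export
simulate_tumor_mass <- function(tumor, kills = NULL, horizon, step = 1 / 96) {
  stopifnot(inherits(tumor, "tumor_params"), step > 0)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  if (is.null(kills)) kills <- kill_event(numeric(0), numeric(0))
  times <- seq(0, horizon, by = step)
  n <- length(times)
  # exact per-step integral of k(t): sum over top-hat pulses of width 1
  kcum <- numeric(n)
  if (nrow(kills) > 0) {
    for (j in seq_len(nrow(kills))) {
      frac <- pmin(pmax(times - kills$day[j], 0), 1)  # integral of unit-height hat
      kcum <- kcum + kills$intensity_kappa[j] * frac
    }
  }
  dk <- diff(kcum)
  g <- tumor$growth_rate_g
  mass <- numeric(n)
  mass[1] <- tumor$M0
  growth_step <- exp(g * step)
  for (i in seq_len(n - 1)) {
    mass[i + 1] <- mass[i] * growth_step * exp(-dk[i])
  }
  killed_rate <- c(dk / step, 0) * mass  # k(t) * M(t), density per day
  tibble::tibble(time = times, mass = mass, killed_mass_rate = killed_rate)
}

#' Simulate serum concentration from a release-rate trajectory
#'
#' One-compartment kinetics `dS/dt = R(t)/V - lambda S` with
#' `lambda = log(2) / half-life`. Integration uses the exact solution per
#' step with the release rate held at its step average, so a release-free
#' series halves in exactly one half-life.
#'
#' @param times Regular time grid, days.
#' @param release Release rate `R(t)` on the grid, native units * V / day.
#' @param marker One-row marker definition carrying `half_life_hours`.
#' @param volume Distribution volume constant `V` (default 1).
#' @param s0 Initial serum concentration; `NULL` starts at the steady state
#'   implied by `release[1]`.
#' @return Tibble `time`, `conc` (native units).
#' @export
simulate_marker_serum <- function(times, release, marker, volume = 1,
                                  s0 = NULL) {
  stopifnot(length(times) == length(release), volume > 0,
            all(release >= 0))
  lambda <- clearance_lambda(marker)
  n <- length(times)
  dt <- times[2] - times[1]
  decay <- exp(-lambda * dt)
  gain <- (1 - decay) / (volume * lambda)
  conc <- numeric(n)
  conc[1] <- if (is.null(s0)) release[1] / (volume * lambda) else s0
  rbar <- (release[-n] + release[-1]) / 2
  for (i in seq_len(n - 1)) {
    conc[i + 1] <- conc[i] * decay + rbar[i] * gain
  }
  tibble::tibble(time = times, conc = conc)
}

#' Relative mass-balance error of a serum simulation
#'
#' Checks conservation: total marker released must equal the concentration
#' change plus total cleared,
#' `int R dt = V (S(T) - S(0)) + V lambda int S dt`.
#'
#' @param times,release Inputs given to [simulate_marker_serum()].
#' @param conc Its output concentrations.
#' @param marker One-row marker definition.
#' @param volume Distribution volume.
#' @return Relative error (dimensionless, >= 0).
#' @export
mass_balance_error <- function(times, release, conc, marker, volume = 1) {
  lambda <- clearance_lambda(marker)
  trapz <- function(y) sum(diff(times) * (y[-length(y)] + y[-1]) / 2)
  released <- trapz(release)
  accounted <- volume * (conc[length(conc)] - conc[1]) +
    volume * lambda * trapz(conc)
  denom <- max(released, volume * lambda * trapz(conc), .Machine$double.eps)
  abs(released - accounted) / denom
}

#' Simulate phasic immune activity and IL-6/CRP release
#'
#' One pulse per dose day with amplitude
#' `base * b^(cycle - 1)`, multiplied by `cort_suppression_s` for doses at or
#' after the first corticosteroid start; each pulse carries `n_subpeaks`
#' sub-peaks spaced `oscillation_period_days` apart. Activity returns toward
#' zero between pulses (phasic, non-cumulative).
#'
#' @param immune An [immune_pulse_params()].
#' @param course A [treatment_course()].
#' @param interventions Tibble of [intervention_event()] rows or `NULL`.
#' @param horizon End of simulation, days; defaults to [course_end()].
#' @param step Grid step, days.
#' @param panel Marker panel supplying IL-6/CRP ULNs and half-lives for the
#'   basal release rates.
#' @return Tibble `time`, `activity`, `il6_release`, `crp_release`.
#' @export
simulate_immune_activity <- function(immune, course, interventions = NULL,
                                     horizon = NULL, step = 1 / 96,
                                     panel = simulator_marker_panel()) {
  stopifnot(inherits(immune, "immune_pulse_params"),
            inherits(course, "treatment_course"))
  if (is.null(horizon)) horizon <- course_end(course)
  times <- seq(0, horizon, by = step)
  cort_start <- Inf
  if (!is.null(interventions) && nrow(interventions) > 0) {
    starts <- interventions$day[interventions$kind == "corticosteroid_start"]
    if (length(starts) > 0) cort_start <- min(starts)
  }
  activity <- numeric(length(times))
  doses <- course$dose_days
  for (j in seq_along(doses)) {
    amp <- immune$base_amplitude * immune$booster_factor_b^(j - 1)
    if (doses[j] >= cort_start) amp <- amp * immune$cort_suppression_s
    for (m in seq_len(immune$n_subpeaks) - 1) {
      activity <- activity + amp * .pulse_kernel(
        times - doses[j] - m * immune$oscillation_period_days,
        immune$rise_tau_days, immune$decay_tau_days
      )
    }
  }
  il6 <- marker_def("IL-6", panel)
  crp <- marker_def("CRP", panel)
  il6_basal <- immune$il6_basal_pct_uln / 100 * il6$uln * clearance_lambda(il6)
  crp_basal <- immune$crp_basal_pct_uln / 100 * crp$uln * clearance_lambda(crp)
  tibble::tibble(
    time = times,
    activity = activity,
    il6_release = il6_basal + immune$il6_release_per_activity * activity,
    crp_release = crp_basal + immune$crp_release_per_activity * activity
  )
}

#' Simulate organ-marker release from irAE events
#'
#' Each event injects a difference-of-exponentials release pulse (rise 1 d,
#' decay 3 d) whose peak sits at the event day, scaled by
#' `release_magnitude` times the immune activity at that day. Release is
#' additive across events (superposition).
#'
#' @param irae_events Tibble of [irae_event()] rows (may be empty or `NULL`).
#' @param immune_traj Output of [simulate_immune_activity()] (columns
#'   `time`, `activity`).
#' @param rise_tau_days,decay_tau_days Release pulse shape, days.
#' @return Tibble `time`, `marker`, `release`, one block per organ marker
#'   named in the events; zero rows when there are no events.
#' @export
simulate_irae <- function(irae_events, immune_traj,
                          rise_tau_days = 1, decay_tau_days = 3) {
  times <- immune_traj$time
  if (is.null(irae_events) || nrow(irae_events) == 0) {
    return(tibble::tibble(time = numeric(), marker = character(),
                          release = numeric()))
  }
  peak_shift <- .pulse_kernel_peak_time(rise_tau_days, decay_tau_days)
  out <- lapply(unique(irae_events$organ_marker), function(m) {
    ev <- irae_events[irae_events$organ_marker == m, , drop = FALSE]
    release <- numeric(length(times))
    for (j in seq_len(nrow(ev))) {
      a_at <- stats::approx(times, immune_traj$activity, xout = ev$day[j],
                            rule = 2)$y
      release <- release + ev$release_magnitude[j] * a_at *
        .pulse_kernel(times - (ev$day[j] - peak_shift),
                      rise_tau_days, decay_tau_days)
    }
    tibble::tibble(time = times, marker = m, release = release)
  })
  dplyr::bind_rows(out)
}

# First-order tissue-release compartment: D' = input - D / tau, output D/tau.
# Exact exponential stepping with step-averaged input.
.release_compartment <- function(times, input, tau) {
  n <- length(times)
  dt <- times[2] - times[1]
  decay <- exp(-dt / tau)
  d <- numeric(n)
  inbar <- (input[-n] + input[-1]) / 2
  gain <- tau * (1 - decay)
  for (i in seq_len(n - 1)) {
    d[i + 1] <- d[i] * decay + inbar[i] * gain
  }
  d / tau
}
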
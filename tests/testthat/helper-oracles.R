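# Independent oracles and small fixture builders shared across tests.

# Exhaustive-search episode oracle: enumerates every (baseline, peak, end)
# index triple and keeps those satisfying the episode definition directly.
# Written against the definition, not against the detector's sweep.
oracle_episodes <- function(series, rel_rise_rho = 0.5, abs_rise_delta = 20) {
  v <- series$value
  d <- series$day
  n <- length(v)
  rows <- list()
  if (n < 3) return(data.frame())
  for (b in seq_len(n)) {
    for (p in b:n) {
      for (e in p:n) {
        if (p < 2 || p > n - 1) next
        if (!(v[p] > v[p - 1])) next            # plateau-earliest local max
        q <- p
        while (q < n && v[q + 1] == v[p]) q <- q + 1
        if (q >= n || v[q + 1] >= v[p]) next
        if (e < q) next
        # baseline run b..p non-decreasing and maximal
        if (p > b && any(diff(v[b:p]) < 0)) next
        if (b > 1 && v[b - 1] <= v[b]) next
        # falling run p..e non-increasing and maximal
        if (e > p && any(diff(v[p:e]) > 0)) next
        if (e < n && v[e + 1] <= v[e]) next
        if (!(v[p] >= v[b] * (1 + rel_rise_rho) &&
              v[p] >= v[b] + abs_rise_delta)) next
        rows[[length(rows) + 1]] <-
          data.frame(start_day = d[b], peak_day = d[p], end_day = d[e],
                     baseline_pct_uln = v[b], peak_pct_uln = v[p])
      }
    }
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  out[order(out$peak_day), , drop = FALSE]
}

# Random short %ULN series with ties and plateaus (integer multiples of 10).
random_series <- function() {
  n <- sample(3:12, 1)
  tibble::tibble(
    day = cumsum(sample(1:7, n, replace = TRUE)),
    value = sample(0:14, n, replace = TRUE) * 10
  )
}

# Reference serum kinetics via lsoda with a forced release rate.
desolve_serum <- function(times, release, marker, volume = 1, s0 = 0) {
  lambda <- tolbreak::clearance_lambda(marker)
  rfun <- stats::approxfun(times, release, rule = 2)
  rhs <- function(t, y, parms) list(rfun(t) / volume - lambda * y)
  out <- deSolve::lsoda(c(S = s0), times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  unname(out[, "S"])
}

# Brute-force Euler integration of dM/dt = (g - k(t)) M at a refined step.
euler_tumor_mass <- function(tumor, kills, horizon, step) {
  times <- seq(0, horizon, by = step)
  k_at <- function(t) {
    if (nrow(kills) == 0) return(0)
    sum(kills$intensity_kappa[t >= kills$day & t < kills$day + 1])
  }
  m <- numeric(length(times))
  m[1] <- tumor$M0
  for (i in seq_len(length(times) - 1)) {
    m[i + 1] <- m[i] + step * (tumor$growth_rate_g - k_at(times[i])) * m[i]
  }
  tibble::tibble(time = times, mass = m)
}

# Difference-of-exponentials pulse (rise 1 d, decay 3 d), peak-normalized.
.pulse_shape_for_tests <- function(u) {
  out <- numeric(length(u))
  pos <- u >= 0
  raw <- exp(-u[pos] / 3) - exp(-u[pos] / 1)
  out[pos] <- raw
  if (any(pos)) out <- out / max(out)
  out
}

# A hand-built patient resembling the combination-therapy tolerance-breakage
# course: IL-6, CRP, S100B and ALT all peaking at day 40 of a two-dose q21d
# course (doses at days 0 and 21).
combo_breakage_patient <- function() {
  days <- c(0, 7, 14, 21, 28, 35, 40, 42)
  labs <- dplyr::bind_rows(
    tibble::tibble(day = days, marker = "IL-6",
                   value = c(1.8, 1.6, 2.0, 1.7, 2.1, 5.6, 18.2, 8.4)),
    tibble::tibble(day = days, marker = "CRP",
                   value = c(1.2, 1.1, 1.4, 1.3, 1.6, 4.1, 13.0, 6.0)),
    tibble::tibble(day = days, marker = "S100B",
                   value = c(3.3, 3.1, 3.8, 3.9, 4.4, 9.9, 23.1, 11.0)),
    tibble::tibble(day = days, marker = "ALT",
                   value = c(20, 21, 19, 23, 25, 60, 150, 90))
  )
  labs$patient_id <- "combo-breakage"
  patient_course(
    patient_id = "combo-breakage",
    courses = treatment_course(c("nivolumab", "ipilimumab"),
                               dose_days = c(0, 21)),
    labs = labs, outcome = "CR"
  )
}
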
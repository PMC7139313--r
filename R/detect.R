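#' Detection parameters
#'
#' Thresholds formalizing the visual judgment used when calling events on
#' plotted time courses. A rise episode must exceed its baseline by both a
#' relative factor `1 + rel_rise_rho` and an absolute `abs_rise_delta`
#' percent of ULN; a tumor/organ peak is coincident with an immune peak when
#' it falls within `window_w_days` before to `max_lag_days` after it (the lag
#' side accommodates the observed 14-day S100B-after-IL-6 delay); the
#' paradox rule requires both S100B and IL-6 to sit at least
#' `decline_fraction` below their day-0 values at the first two post-dose
#' draws of cycle 1.
#'
#' @param rel_rise_rho Relative rise threshold (0.5 = peak at least 1.5x
#'   baseline).
#' @param abs_rise_delta Absolute rise threshold, % of ULN.
#' @param window_w_days Days a partner peak may precede the immune peak.
#' @param max_lag_days Days a partner peak may follow the immune peak.
#' @param decline_fraction Minimum fractional decline for the paradox flag.
#' @param baseline_window Days of pre-course samples kept when re-zeroing a
#'   course.
#' @return List of class `detection_params`.
#' @export
detection_params <- function(rel_rise_rho = 0.5,
                             abs_rise_delta = 20,
                             window_w_days = 7,
                             max_lag_days = 14,
                             decline_fraction = 0.3,
                             baseline_window = 14) {
  stopifnot(rel_rise_rho >= 0, abs_rise_delta >= 0,
            window_w_days >= 0, max_lag_days >= 0,
            decline_fraction > 0, decline_fraction < 1)
  structure(as.list(environment()), class = "detection_params")
}

.empty_episodes <- function() {
  tibble::tibble(marker = character(), start_day = numeric(),
                 peak_day = numeric(), end_day = numeric(),
                 baseline_pct_uln = numeric(), peak_pct_uln = numeric(),
                 auc_pct_uln_days = numeric())
}

#' Detect rise episodes in a percent-of-ULN series
#'
#' An episode is a maximal run around a local maximum: the peak must be
#' strictly greater than both neighbors (a plateau counts once, at its
#' earliest day), the baseline is the value at the start of the maximal
#' non-decreasing run into the peak (the minimum of the run; the first
#' sample if the series rises from its start), and the episode ends where
#' values stop falling. An episode is kept only when the peak is at least
#' `(1 + rho)` times and `delta` %ULN above its baseline. Episodes are
#' returned in time order with interiors disjoint (consecutive episodes may
#' share a valley sample). Detection operates on relative rises, so markers
#' that react below ULN still produce episodes.
#'
#' @param series Tibble with `day` (strictly increasing) and `value`
#'   (percent of ULN).
#' @param rel_rise_rho,abs_rise_delta Thresholds, see [detection_params()].
#' @param marker Marker name written into the result.
#' @return Episode tibble (see [detection_params()] for the semantics);
#'   zero rows, with a notice, for series shorter than 3 samples.
#' @examples
#' s <- tibble::tibble(day = c(0, 7, 14, 21), value = c(50, 60, 180, 70))
#' detect_episodes(s)
#' @export
detect_episodes <- function(series, rel_rise_rho = 0.5, abs_rise_delta = 20,
                            marker = NA_character_) {
  v <- series$value
  d <- series$day
  n <- length(v)
  if (n < 3) {
    message("detect_episodes: fewer than 3 samples; no episodes detectable")
    return(.empty_episodes())
  }
  stopifnot(!is.unsorted(d, strictly = TRUE), all(is.finite(v)))

  eps <- list()
  for (p in 2:(n - 1)) {
    if (!(v[p] > v[p - 1])) next           # plateau peaks: earliest day only
    q <- p
    while (q < n && v[q + 1] == v[p]) q <- q + 1
    if (q == n || v[q + 1] >= v[p]) next   # needs a strict drop after plateau
    # baseline: start of the maximal non-decreasing run into the peak
    b <- p
    while (b > 1 && v[b - 1] <= v[b]) b <- b - 1
    # end: last sample of the non-increasing run out of the plateau
    e <- q
    while (e < n && v[e + 1] <= v[e]) e <- e + 1
    base <- v[b]
    if (v[p] >= base * (1 + rel_rise_rho) && v[p] >= base + abs_rise_delta) {
      eps[[length(eps) + 1]] <-
        tibble::tibble(marker = marker, start_day = d[b], peak_day = d[p],
                       end_day = d[e], baseline_pct_uln = base,
                       peak_pct_uln = v[p])
    }
  }
  if (length(eps) == 0) return(.empty_episodes())
  out <- dplyr::bind_rows(eps)
  out$auc_pct_uln_days <- vapply(seq_len(nrow(out)), function(i) {
    compute_auc(out[i, ], series)
  }, numeric(1))
  out
}

#' Baseline-subtracted trapezoidal AUC of an episode
#'
#' Trapezoidal area of `max(value - baseline, 0)` over the episode's
#' `[start_day, end_day]`, in %ULN x days.
#'
#' @param episode One episode row from [detect_episodes()].
#' @param series The series the episode was detected on.
#' @return AUC in %ULN-days, >= 0.
#' @export
compute_auc <- function(episode, series) {
  inside <- series$day >= episode$start_day & series$day <= episode$end_day
  d <- series$day[inside]
  if (length(d) < 2) return(0)
  y <- pmax(series$value[inside] - episode$baseline_pct_uln, 0)
  sum(diff(d) * (y[-length(y)] + y[-1]) / 2)
}

#' Pair tumor/organ episodes with immune episodes
#'
#' Emits an event call when a partner (tumor or organ marker) episode peak
#' lies within `[immune_peak - w, immune_peak + max_lag]` of an immune
#' episode peak. Each partner episode pairs with at most one immune episode:
#' IL-6 is preferred over CRP (and CRP over cell counts), then the nearest
#' peak wins, then the earlier immune peak on ties. Call kind follows the
#' partner marker's role: `tolerance_breakage` for tumor markers, `irae` for
#' organ markers; the recorded day is the partner peak day.
#'
#' @param immune_episodes,partner_episodes Episode tibbles from
#'   [detect_episodes()] with a `marker` column.
#' @param window_w_days,max_lag_days Coincidence window, see
#'   [detection_params()].
#' @param course Optional [treatment_course()] used to attach cycle indices.
#' @param panel Marker panel supplying roles.
#' @return Event-call tibble: `kind`, `day`, `cycle_index`, `immune_marker`,
#'   `immune_peak_day`, `immune_start_day`, `partner_marker`,
#'   `partner_peak_day`, `partner_start_day`, `lag_days`,
#'   `autocrine_suspect`.
#' @export
detect_coincidence <- function(immune_episodes, partner_episodes,
                               window_w_days = 7, max_lag_days = 14,
                               course = NULL,
                               panel = marker_definitions()) {
  empty <- tibble::tibble(
    kind = character(), day = numeric(), cycle_index = integer(),
    immune_marker = character(), immune_peak_day = numeric(),
    immune_start_day = numeric(), partner_marker = character(),
    partner_peak_day = numeric(), partner_start_day = numeric(),
    lag_days = numeric(), autocrine_suspect = logical()
  )
  if (nrow(immune_episodes) == 0 || nrow(partner_episodes) == 0) {
    return(empty)
  }
  pref <- function(m) ifelse(m == "IL-6", 1L, ifelse(m == "CRP", 2L, 3L))
  calls <- list()
  for (i in seq_len(nrow(partner_episodes))) {
    pe <- partner_episodes[i, ]
    lag <- pe$peak_day - immune_episodes$peak_day
    ok <- lag >= -window_w_days & lag <= max_lag_days
    if (!any(ok)) next
    cand <- immune_episodes[ok, ]
    cand_lag <- lag[ok]
    ord <- order(pref(cand$marker), abs(cand_lag), cand$peak_day)
    im <- cand[ord[1], ]
    role <- panel$role[match(pe$marker, panel$marker)]
    kind <- switch(role, tumor = "tolerance_breakage", organ = "irae",
                   NA_character_)
    if (is.na(kind)) next
    calls[[length(calls) + 1]] <- tibble::tibble(
      kind = kind, day = pe$peak_day,
      cycle_index = if (is.null(course)) NA_integer_ else
        assign_cycle(pe$peak_day, course),
      immune_marker = im$marker, immune_peak_day = im$peak_day,
      immune_start_day = im$start_day,
      partner_marker = pe$marker, partner_peak_day = pe$peak_day,
      partner_start_day = pe$start_day,
      lag_days = cand_lag[ord[1]], autocrine_suspect = FALSE
    )
  }
  if (length(calls) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(calls), .data$day)
}

#' Flag the paradox reaction (parallel first-cycle decline)
#'
#' Flags the immediate parallel decline of tumor marker and IL-6 after the
#' first dose: within cycle 1, both series must sit at least
#' `decline_fraction` below their day-0 value at each of the first two
#' post-dose draws, without rebounding between them.
#'
#' @param tumor_series,il6_series Tibbles `day`, `value` on the course
#'   clock (any common scale; the rule is ratio-based).
#' @param course A [treatment_course()].
#' @param decline_fraction Minimum fractional decline (default 0.3).
#' @return List `flag` (logical) and `onset_day` (first post-dose day at
#'   which both series have declined by the threshold; `NA` when not
#'   flagged).
#' @export
detect_paradox <- function(tumor_series, il6_series, course,
                           decline_fraction = 0.3) {
  first_dose <- course$dose_days[1]
  cyc1_end <- if (length(course$dose_days) > 1) course$dose_days[2] else
    course_end(course)
  pick <- function(s) {
    ref_idx <- which(s$day <= first_dose)
    post <- s[s$day > first_dose & s$day < cyc1_end, , drop = FALSE]
    list(ref = if (length(ref_idx) > 0) s$value[max(ref_idx)] else NA_real_,
         post = post)
  }
  tu <- pick(tumor_series)
  il <- pick(il6_series)
  not_flagged <- list(flag = FALSE, onset_day = NA_real_)
  if (is.na(tu$ref) || is.na(il$ref) ||
      nrow(tu$post) < 2 || nrow(il$post) < 2) {
    return(not_flagged)
  }
  thr_t <- (1 - decline_fraction) * tu$ref
  thr_i <- (1 - decline_fraction) * il$ref
  t2 <- tu$post$value[1:2]
  i2 <- il$post$value[1:2]
  declined <- all(t2 <= thr_t) && all(i2 <= thr_i)
  monotone <- t2[2] <= t2[1] && i2[2] <= i2[1]
  if (!(declined && monotone)) return(not_flagged)
  both_days <- intersect(tu$post$day, il$post$day)
  onset <- NA_real_
  for (dd in sort(both_days)) {
    if (tu$post$value[tu$post$day == dd] <= thr_t &&
        il$post$value[il$post$day == dd] <= thr_i) {
      onset <- dd
      break
    }
  }
  if (is.na(onset)) onset <- tu$post$day[1]
  list(flag = TRUE, onset_day = onset)
}

#' Flag tolerance-breakage calls that may be autocrine IL-6 mimicry
#'
#' A progressing tumor that itself secretes IL-6 produces a parallel
#' S100B/IL-6 rise that imitates an immune response. Tolerance-breakage
#' calls in a patient with progressive disease whose rise is sustained
#' (the partner rise spans at least two treatment cycles, or lasts at least
#' one nominal interval) are labelled `autocrine_suspect`; the calls are
#' kept, not removed.
#'
#' @param calls Event-call tibble from [detect_coincidence()].
#' @param outcome Best response of the patient (`"PD"` triggers the flag).
#' @param course The [treatment_course()] the calls belong to.
#' @return The calls with `autocrine_suspect` updated.
#' @export
flag_autocrine_suspect <- function(calls, outcome, course) {
  if (nrow(calls) == 0 || !identical(outcome, "PD")) return(calls)
  tb <- calls$kind == "tolerance_breakage"
  start_cycle <- assign_cycle(calls$partner_start_day, course)
  peak_cycle <- assign_cycle(calls$partner_peak_day, course)
  sustained <- (!is.na(start_cycle) & !is.na(peak_cycle) &
                  peak_cycle > start_cycle) |
    (calls$partner_peak_day - calls$partner_start_day >=
       course$nominal_interval_days)
  calls$autocrine_suspect <- calls$autocrine_suspect | (tb & sustained)
  calls
}

#' Classify one patient's full course
#'
#' Runs the complete chain per course: ULN normalization, episode detection
#' on every marker, immune/partner coincidence pairing, the paradox rule,
#' and autocrine flagging; then summarizes the first tolerance-breakage day
#' (TMR day), first irAE day, and whether both fall in the same treatment
#' cycle. Hormone-axis markers are accepted in the labs but never drive
#' organ-damage calls. Labs are re-zeroed at each course start and analyzed
#' per course.
#'
#' @param patient A [patient_course()].
#' @param params A [detection_params()].
#' @param panel Marker panel (ULNs, roles).
#' @return List of class `patient_classification`: `patient_id`, `calls`
#'   (tibble with a `course_index` column), `episodes`, `tmr_day`,
#'   `tmr_course`, `irae_day`, `irae_course`, `same_cycle`, and
#'   `flags` (`paradox`, `paradox_onset_day`, `masked_by_autocrine`).
#' @export
classify_patient <- function(patient, params = detection_params(),
                             panel = marker_definitions()) {
  stopifnot(inherits(patient, "patient_course"),
            inherits(params, "detection_params"))
  problems <- validate_course(patient, panel = panel, permissive = TRUE)
  if (nrow(problems) > 0) {
    stop("patient fails validation: ",
         paste(problems$field, problems$rule, sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  all_calls <- list()
  all_eps <- list()
  paradox_flag <- FALSE
  paradox_onset <- NA_real_

  for (ci in seq_along(patient$courses)) {
    course <- patient$courses[[ci]]
    eps_by_marker <- list()
    for (m in intersect(unique(patient$labs$marker), panel$marker)) {
      s <- course_series(patient, m, course_index = ci,
                        baseline_window = params$baseline_window)
      if (nrow(s) < 3) next
      s$value <- normalize_to_uln(s$value, marker_def(m, panel))
      eps_by_marker[[m]] <- detect_episodes(
        s, rel_rise_rho = params$rel_rise_rho,
        abs_rise_delta = params$abs_rise_delta, marker = m
      )
    }
    eps <- dplyr::bind_rows(eps_by_marker)
    if (nrow(eps) > 0) {
      eps$course_index <- ci
      all_eps[[ci]] <- eps
    }
    roles <- panel$role[match(names(eps_by_marker), panel$marker)]
    immune_eps <- dplyr::bind_rows(eps_by_marker[roles == "immune"])
    partner_eps <- dplyr::bind_rows(eps_by_marker[roles %in% c("tumor", "organ")])
    if (is.null(immune_eps)) immune_eps <- .empty_episodes()
    if (is.null(partner_eps)) partner_eps <- .empty_episodes()
    calls <- detect_coincidence(
      immune_eps, partner_eps,
      window_w_days = params$window_w_days,
      max_lag_days = params$max_lag_days,
      course = course, panel = panel
    )
    calls <- flag_autocrine_suspect(calls, patient$outcome, course)
    if (nrow(calls) > 0) {
      calls$course_index <- ci
      all_calls[[ci]] <- calls
    }

    # paradox: first course only needs checking per course; prefer S100B
    tum_marker <- intersect(c("S100B", "LDH"), unique(patient$labs$marker))[1]
    if (!is.na(tum_marker) && "IL-6" %in% patient$labs$marker) {
      ts <- course_series(patient, tum_marker, course_index = ci,
                          baseline_window = params$baseline_window)
      is_ <- course_series(patient, "IL-6", course_index = ci,
                           baseline_window = params$baseline_window)
      px <- detect_paradox(ts, is_, course,
                           decline_fraction = params$decline_fraction)
      if (px$flag && !paradox_flag) {
        paradox_flag <- TRUE
        paradox_onset <- px$onset_day
      }
    }
  }

  calls <- if (length(all_calls) > 0) dplyr::bind_rows(all_calls) else
    dplyr::mutate(detect_coincidence(.empty_episodes(), .empty_episodes()),
                  course_index = integer(0))
  episodes <- if (length(all_eps) > 0) dplyr::bind_rows(all_eps) else {
    e <- .empty_episodes()
    e$course_index <- integer(0)
    e
  }

  first_of <- function(kind) {
    k <- calls[calls$kind == kind, , drop = FALSE]
    if (nrow(k) == 0) return(list(day = NA_real_, course = NA_integer_))
    k <- k[order(k$course_index, k$day), ]
    list(day = k$day[1], course = k$course_index[1])
  }
  tmr <- first_of("tolerance_breakage")
  irae <- first_of("irae")
  same_cycle <- if (is.na(tmr$day) || is.na(irae$day)) {
    NA
  } else if (tmr$course != irae$course) {
    FALSE
  } else {
    crs <- patient$courses[[tmr$course]]
    isTRUE(assign_cycle(tmr$day, crs) == assign_cycle(irae$day, crs))
  }

  structure(
    list(
      patient_id = patient$patient_id,
      calls = calls,
      episodes = episodes,
      tmr_day = tmr$day, tmr_course = tmr$course,
      irae_day = irae$day, irae_course = irae$course,
      same_cycle = same_cycle,
      flags = list(paradox = paradox_flag,
                   paradox_onset_day = paradox_onset,
                   masked_by_autocrine = any(calls$autocrine_suspect))
    ),
    class = "patient_classification"
  )
}

#' @export
print.patient_classification <- function(x, ...) {
  cat("<patient_classification> ", x$patient_id, "\n", sep = "")
  cat("  calls: ", nrow(x$calls),
      " | TMR day: ", ifelse(is.na(x$tmr_day), "-", x$tmr_day),
      " | irAE day: ", ifelse(is.na(x$irae_day), "-", x$irae_day),
      " | same cycle: ", ifelse(is.na(x$same_cycle), "-", x$same_cycle),
      "\n", sep = "")
  if (x$flags$paradox) {
    cat("  paradox reaction, onset day ", x$flags$paradox_onset_day, "\n",
        sep = "")
  }
  if (x$flags$masked_by_autocrine) cat("  autocrine-IL-6 suspect\n")
  invisible(x)
}
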
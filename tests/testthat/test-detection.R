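test_that("episode detection finds the documented single-peak case", {
  s <- tibble::tibble(day = c(0, 7, 14, 21), value = c(50, 60, 180, 70))
  eps <- detect_episodes(s, rel_rise_rho = 0.5, abs_rise_delta = 20)
  expect_identical(nrow(eps), 1L)
  expect_equal(eps$peak_day, 14)
  expect_equal(eps$baseline_pct_uln, 50)
  expect_equal(eps$start_day, 0)
  expect_equal(eps$end_day, 21)
  # agrees with the exhaustive-search oracle
  orc <- oracle_episodes(s)
  expect_equal(eps$peak_day, orc$peak_day)
  expect_equal(eps$baseline_pct_uln, orc$baseline_pct_uln)
})

test_that("constant and monotone-decreasing series yield no episodes", {
  flat <- tibble::tibble(day = 0:5 * 7, value = rep(80, 6))
  expect_identical(nrow(detect_episodes(flat)), 0L)
  down <- tibble::tibble(day = 0:5 * 7, value = seq(200, 100, by = -20))
  expect_identical(nrow(detect_episodes(down)), 0L)
})

test_that("short series return empty with a notice", {
  s <- tibble::tibble(day = c(0, 7), value = c(10, 400))
  expect_message(eps <- detect_episodes(s), "fewer than 3")
  expect_identical(nrow(eps), 0L)
})

test_that("episode detector matches the exhaustive oracle on random series", {
  withr::with_seed(914, {
    for (i in 1:200) {
      s <- random_series()
      got <- detect_episodes(s)
      want <- oracle_episodes(s)
      expect_identical(nrow(got), nrow(want))
      if (nrow(want) > 0) {
        expect_equal(got$start_day, want$start_day)
        expect_equal(got$peak_day, want$peak_day)
        expect_equal(got$end_day, want$end_day)
        expect_equal(got$baseline_pct_uln, want$baseline_pct_uln)
        expect_equal(got$peak_pct_uln, want$peak_pct_uln)
      }
    }
  })
})

test_that("episode AUC is the baseline-subtracted trapezoid", {
  s <- tibble::tibble(day = c(0, 7, 14), value = c(100, 200, 100))
  ep <- tibble::tibble(start_day = 0, end_day = 14, baseline_pct_uln = 100)
  expect_equal(compute_auc(ep, s), 700)
  flat <- tibble::tibble(day = c(0, 7, 14), value = c(100, 100, 100))
  expect_equal(compute_auc(ep, flat), 0)
})

test_that("weekly trapezoid AUC is within 10% of the fine-grid integral", {
  # a week-scale release episode (rise 3 d, decay 10 d), the regime the AUC
  # quantification is meant for
  pulse <- function(d) {
    u <- pmax(d - 14, 0)
    shape <- exp(-u / 10) - exp(-u / 3)
    50 + 200 * shape / max(shape)
  }
  auc_at <- function(days) {
    s <- tibble::tibble(day = days, value = pulse(days))
    eps <- detect_episodes(s)
    expect_identical(nrow(eps), 1L)
    eps$auc_pct_uln_days
  }
  fine <- auc_at(seq(0, 63, by = 0.1))
  weekly <- auc_at(seq(0, 63, by = 7))
  expect_lt(abs(weekly - fine) / fine, 0.10)
})

test_that("coincidence pairing respects the window and records lags", {
  imm <- tibble::tibble(marker = "IL-6", start_day = 48, peak_day = 62,
                        end_day = 76, baseline_pct_uln = 20,
                        peak_pct_uln = 90, auc_pct_uln_days = 300)
  tum <- tibble::tibble(marker = "S100B", start_day = 55, peak_day = 62,
                        end_day = 70, baseline_pct_uln = 60,
                        peak_pct_uln = 160, auc_pct_uln_days = 400)
  crs <- treatment_course("ipilimumab", seq(0, 63, by = 21), 21)
  calls <- detect_coincidence(imm, tum, course = crs)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$kind, "tolerance_breakage")
  expect_equal(calls$day, 62)
  expect_equal(calls$lag_days, 0)

  # outside the window: immune day 10, tumor day 40
  far <- dplyr::mutate(tum, start_day = 35, peak_day = 40, end_day = 47)
  near10 <- dplyr::mutate(imm, start_day = 3, peak_day = 10, end_day = 17)
  expect_identical(nrow(detect_coincidence(near10, far)), 0L)

  # the 14-day tumor-after-immune lag is still a call
  imm98 <- dplyr::mutate(imm, start_day = 91, peak_day = 98, end_day = 105)
  tum112 <- dplyr::mutate(tum, start_day = 105, peak_day = 112, end_day = 119)
  lagged <- detect_coincidence(imm98, tum112)
  expect_identical(nrow(lagged), 1L)
  expect_equal(lagged$lag_days, 14)
})

test_that("coincidence prefers IL-6 over CRP and nearest-then-earlier peaks", {
  il6 <- tibble::tibble(marker = "IL-6", start_day = 0, peak_day = 58,
                        end_day = 70, baseline_pct_uln = 20,
                        peak_pct_uln = 100, auc_pct_uln_days = 100)
  crp <- dplyr::mutate(il6, marker = "CRP", peak_day = 62)
  tum <- tibble::tibble(marker = "S100B", start_day = 55, peak_day = 62,
                        end_day = 70, baseline_pct_uln = 60,
                        peak_pct_uln = 160, auc_pct_uln_days = 400)
  calls <- detect_coincidence(dplyr::bind_rows(crp, il6), tum)
  expect_identical(calls$immune_marker, "IL-6")  # despite CRP being nearer

  # equidistant immune peaks of the same marker: earlier wins
  two <- dplyr::bind_rows(
    dplyr::mutate(il6, peak_day = 55),
    dplyr::mutate(il6, peak_day = 69)
  )
  call2 <- detect_coincidence(two, tum)
  expect_equal(call2$immune_peak_day, 55)

  # organ partners are classified as irae
  alt <- dplyr::mutate(tum, marker = "ALT")
  expect_identical(detect_coincidence(il6, alt)$kind, "irae")
})

test_that("paradox rule needs a deep, monotone, two-marker decline", {
  crs <- treatment_course("pembrolizumab", c(0, 21), 21)
  halves <- tibble::tibble(day = c(0, 7, 14), value = c(100, 45, 25))
  il6 <- tibble::tibble(day = c(0, 7, 14), value = c(80, 40, 20))
  px <- detect_paradox(halves, il6, crs)
  expect_true(px$flag)
  expect_equal(px$onset_day, 7)

  rising <- tibble::tibble(day = c(0, 7, 14), value = c(50, 80, 120))
  expect_false(detect_paradox(rising, rising, crs)$flag)
  expect_false(detect_paradox(halves, rising, crs)$flag)

  # a decline that rebounds between the first two draws is not paradox
  rebound <- tibble::tibble(day = c(0, 7, 14), value = c(100, 40, 60))
  expect_false(detect_paradox(rebound, il6, crs)$flag)
})

test_that("autocrine suspicion flags sustained rises only under PD", {
  crs <- treatment_course("pembrolizumab", seq(0, 84, by = 21), 21)
  calls <- tibble::tibble(
    kind = "tolerance_breakage", day = 98, cycle_index = 5L,
    immune_marker = "IL-6", immune_peak_day = 98, immune_start_day = 70,
    partner_marker = "S100B", partner_peak_day = 98, partner_start_day = 70,
    lag_days = 0, autocrine_suspect = FALSE
  )
  flagged <- flag_autocrine_suspect(calls, "PD", crs)
  expect_true(flagged$autocrine_suspect)
  expect_false(flag_autocrine_suspect(calls, "CR", crs)$autocrine_suspect)
  empty <- calls[0, ]
  expect_identical(nrow(flag_autocrine_suspect(empty, "PD", crs)), 0L)

  # a short within-cycle rise is not sustained
  short <- dplyr::mutate(calls, partner_start_day = 92, immune_start_day = 92,
                         day = 98)
  expect_false(flag_autocrine_suspect(short, "PD", crs)$autocrine_suspect)
})

test_that("the combination-therapy course classifies as same-cycle breakage", {
  cls <- classify_patient(combo_breakage_patient())
  expect_equal(cls$tmr_day, 40)
  expect_equal(cls$irae_day, 40)
  expect_true(cls$same_cycle)
  expect_identical(
    sort(unique(cls$calls$kind)), c("irae", "tolerance_breakage")
  )
})

test_that("a flat patient yields no calls and no days", {
  labs <- dplyr::bind_rows(lapply(c("IL-6", "S100B", "CRP"), function(m) {
    tibble::tibble(patient_id = "flat", day = seq(0, 105, by = 7),
                   marker = m, value = marker_def(m)$uln * 0.4)
  }))
  pt <- patient_course("flat", treatment_course("nivolumab", seq(0, 84, 21)),
                       labs = labs)
  cls <- classify_patient(pt)
  expect_identical(nrow(cls$calls), 0L)
  expect_true(is.na(cls$tmr_day))
  expect_true(is.na(cls$same_cycle))
})

test_that("irAE-coupled simulations localize the organ-damage day", {
  panel <- simulator_marker_panel()
  sims <- generate_cohort(10, "irae_coupled", seed = 515)
  hit <- vapply(sims, function(sim) {
    cls <- classify_patient(sim$patient, panel = panel)
    !is.na(cls$irae_day) &&
      abs(cls$irae_day - sim$ground_truth$irae_days[1]) <= 7
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("steroid suppression stops immune episodes but not tumor release", {
  panel <- simulator_marker_panel()
  cort <- tibble::tibble(kind = "corticosteroid_start", day = 30)
  cfg <- scenario_config(
    "responder", seed = 606,
    immune = immune_pulse_params(cort_suppression_s = 0),
    kill_events = kill_event(day = 44, intensity_kappa = 1)
  )
  sims <- lapply(1:5, function(i) {
    cfg$seed <- 606L + i
    generate_patient(cfg, interventions = cort)
  })
  for (sim in sims) {
    cls <- classify_patient(sim$patient, panel = panel)
    imm <- cls$episodes[cls$episodes$marker %in% c("IL-6", "CRP"), ]
    if (nrow(imm) > 0) expect_true(all(imm$peak_day <= 30))
    tum <- cls$episodes[cls$episodes$marker == "S100B", ]
    expect_gt(nrow(tum), 0)         # tumor-marker release persists
    expect_true(all(cls$calls$day <= 30 + 14))
  }
})

test_that("classification is deterministic for identical input", {
  sim <- generate_patient(scenario_config("responder", seed = 77))
  a <- classify_patient(sim$patient, panel = simulator_marker_panel())
  b <- classify_patient(sim$patient, panel = simulator_marker_panel())
  expect_identical(a$calls, b$calls)
  expect_identical(a$episodes, b$episodes)
})
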
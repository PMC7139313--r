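test_that("tumor mass conserves without growth and matches closed forms", {
  tum <- tumor_params(growth_rate_g = 0)
  traj <- simulate_tumor_mass(tum, horizon = 50)
  expect_true(all(abs(traj$mass - tum$M0) < 1e-12))

  # single kill of intensity log(2) halves the mass
  kill <- kill_event(day = 10, intensity_kappa = log(2))
  traj2 <- simulate_tumor_mass(tum, kill, horizon = 50)
  expect_equal(traj2$mass[traj2$time >= 12][1], tum$M0 / 2, tolerance = 1e-12)
  expect_true(all(traj2$mass >= 0))
})

test_that("tumor mass with growth and kill matches fine-step Euler", {
  tum <- tumor_params(growth_rate_g = 0.02)
  kills <- kill_event(day = c(8, 20), intensity_kappa = c(1, 0.5))
  step <- 0.05
  traj <- simulate_tumor_mass(tum, kills, horizon = 40, step = step)
  oracle <- euler_tumor_mass(tum, kills, horizon = 40, step = step / 100)
  at <- oracle$mass[match(round(traj$time, 6), round(oracle$time, 6))]
  expect_lt(max(abs(traj$mass - at) / at), 1e-3)
})

test_that("serum kinetics: release-free decay halves per half-life", {
  s100b <- marker_def("S100B", simulator_marker_panel())
  times <- seq(0, 1, by = 1 / 96)
  out <- simulate_marker_serum(times, rep(0, length(times)), s100b, s0 = 1)
  two_h <- which.min(abs(times - 2 / 24))
  expect_equal(out$conc[two_h], 0.5, tolerance = 1e-9)
  expect_true(all(out$conc >= 0))
})

test_that("serum kinetics: constant release reaches R/(V*lambda)", {
  ldh <- marker_def("LDH")
  lambda <- clearance_lambda(ldh)
  times <- seq(0, 100, by = 1 / 96)  # ~24 half-lives of 100 h
  out <- simulate_marker_serum(times, rep(40, length(times)), ldh, s0 = 0)
  expect_equal(out$conc[length(times)], 40 / lambda, tolerance = 1e-4)
})

test_that("serum response to a pulse matches lsoda to <0.5%", {
  skip_if_not_installed("deSolve")
  myo <- marker_def("myoglobin")
  times <- seq(0, 30, by = 1 / 96)
  release <- 500 * exp(-((times - 10)^2) / 2)
  ours <- simulate_marker_serum(times, release, myo, s0 = 0)
  ref <- desolve_serum(times, release, myo, s0 = 0)
  scale <- max(ref)
  expect_lt(max(abs(ours$conc - ref)) / scale, 5e-3)
})

test_that("serum mass balance closes to <0.5% on archetype runs", {
  for (arch in c("responder", "non_responder", "paradox",
                 "autocrine_progressor", "irae_coupled")) {
    sim <- generate_patient(scenario_config(arch, seed = 99),
                            include_dense = TRUE)
    panel <- simulator_marker_panel()
    for (m in unique(sim$dense$marker)) {
      d <- sim$dense[sim$dense$marker == m, ]
      err <- mass_balance_error(d$time, d$release, d$conc,
                                marker_def(m, panel))
      expect_lt(err, 0.005)
    }
    expect_true(all(sim$dense$conc >= 0))
  }
})

test_that("immune pulses scale geometrically with the booster factor", {
  crs <- treatment_course("ipilimumab", c(0, 21, 42), 21)
  flat <- simulate_immune_activity(immune_pulse_params(booster_factor_b = 1),
                                   crs)
  peaks <- vapply(1:3, function(k) {
    w <- flat$time >= (k - 1) * 21 & flat$time < k * 21
    max(flat$activity[w])
  }, numeric(1))
  expect_equal(peaks / peaks[1], c(1, 1, 1), tolerance = 0.02)

  boosted <- simulate_immune_activity(
    immune_pulse_params(booster_factor_b = 2), crs)
  peaks2 <- vapply(1:3, function(k) {
    w <- boosted$time >= (k - 1) * 21 & boosted$time < k * 21
    max(boosted$activity[w])
  }, numeric(1))
  expect_equal(peaks2 / peaks2[1], c(1, 2, 4), tolerance = 0.02)
})

test_that("immune activity is phasic and fully suppressed by steroids", {
  imm <- immune_pulse_params()
  crs <- treatment_course("nivolumab", seq(0, 63, by = 21), 21)
  act <- simulate_immune_activity(imm, crs)
  # between doses >= 5 decay taus apart, activity returns below 10% of the
  # preceding pulse peak just before the next dose
  for (k in 1:3) {
    w <- act$time >= (k - 1) * 21 & act$time < k * 21
    peak <- max(act$activity[w])
    pre_next <- act$activity[max(which(w))]
    expect_lt(pre_next, 0.10 * peak)
  }

  # cort_suppression_s = 0: activity 5 decay taus past the start is < 1% of
  # the pre-intervention peak
  cort <- tibble::tibble(kind = "corticosteroid_start", day = 30)
  sup <- simulate_immune_activity(
    immune_pulse_params(cort_suppression_s = 0), crs, interventions = cort)
  pre_peak <- max(sup$activity[sup$time < 30])
  after <- sup$activity[sup$time >= 30 + 5 * imm$decay_tau_days]
  expect_lt(max(after), 0.01 * pre_peak)
})

test_that("irAE release is zero without events, peaks on time, superposes", {
  crs <- treatment_course("pembrolizumab", seq(0, 147, by = 21), 21)
  act <- simulate_immune_activity(immune_pulse_params(), crs, horizon = 168)

  none <- simulate_irae(NULL, act)
  expect_identical(nrow(none), 0L)

  ck <- marker_def("CK")
  ev <- irae_event(day = 148, organ_marker = "CK")
  rel <- simulate_irae(ev, act)
  serum <- simulate_marker_serum(rel$time, rel$release, ck)
  expect_lt(abs(serum$time[which.max(serum$conc)] - 148), 1)

  # two disjoint events superpose
  ev2 <- irae_event(day = 60, organ_marker = "CK")
  both <- simulate_irae(dplyr::bind_rows(ev, ev2), act)
  single_sum <- rel$release + simulate_irae(ev2, act)$release
  expect_equal(both$release, single_sum, tolerance = 1e-12)
})

test_that("lab sampling hits the schedule and reproduces the noise CV", {
  cfg <- scenario_config("responder", seed = 3, noise_cv = 0)
  dense <- tibble::tibble(time = seq(0, 28, by = 0.25), marker = "CRP",
                          conc = 3 + sin(seq(0, 28, by = 0.25)))
  labs <- withr::with_seed(1, sample_labs(dense, cfg))
  expect_identical(nrow(labs), 5L)  # days 0, 7, 14, 21, 28
  truth <- stats::approx(dense$time, dense$conc, xout = labs$day)$y
  expect_equal(labs$value, truth)

  # Monte-Carlo CV check on a constant trajectory
  cfg15 <- scenario_config("responder", seed = 3, noise_cv = 0.15,
                           sampling_interval_days = 1)
  const <- tibble::tibble(time = seq(0, 999, by = 1), marker = "CRP",
                          conc = 10)
  vals <- withr::with_seed(7, sample_labs(const, cfg15))$value
  expect_gt(stats::sd(vals) / mean(vals), 0.13)
  expect_lt(stats::sd(vals) / mean(vals), 0.17)
})

test_that("below-detection values are censored at half the limit", {
  cfg <- scenario_config("responder", seed = 5, noise_cv = 0,
                         detection_limits = c("S100B" = 0.05))
  dense <- tibble::tibble(time = 0:14, marker = "S100B",
                          conc = c(rep(0.02, 8), rep(0.2, 7)))
  labs <- withr::with_seed(1, sample_labs(dense, cfg))
  low <- labs$day <= 7
  expect_true(all(labs$censored[low]))
  expect_true(all(labs$value[low] == 0.025))
  expect_true(all(!labs$censored[!low]))
})

test_that("patient generation is deterministic down to the written bytes", {
  cfg <- scenario_config("responder", seed = 42)
  a <- generate_patient(cfg)
  b <- generate_patient(cfg)
  expect_identical(a$patient$labs, b$patient$labs)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_labs_csv(a$patient$labs, f1, panel = simulator_marker_panel())
  write_labs_csv(b$patient$labs, f2, panel = simulator_marker_panel())
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("a strong kill leaves final tumor-marker release below baseline", {
  cfg <- scenario_config(
    "responder", seed = 8,
    kill_events = kill_event(day = 23.5, intensity_kappa = 2)
  )
  sim <- generate_patient(cfg)
  s <- sim$patient$labs[sim$patient$labs$marker == "S100B", ]
  expect_lt(s$value[nrow(s)], s$value[1])
})

test_that("paradox archetype declines in parallel over the first cycle", {
  sim <- generate_patient(scenario_config("paradox", seed = 21))
  labs <- sim$patient$labs
  cyc1 <- labs$day < 21
  il6 <- labs$value[labs$marker == "IL-6" & cyc1]
  s100b <- labs$value[labs$marker == "S100B" & cyc1]
  expect_gt(stats::cor(il6, s100b, method = "spearman"), 0.9)
  expect_lt(il6[length(il6)], il6[1])
  expect_lt(s100b[length(s100b)], s100b[1])
})

test_that("paradox without an autocrine loop records a warning", {
  cfg <- scenario_config("paradox", seed = 2,
                         tumor = tumor_params(autocrine_il6_c = 0))
  sim <- generate_patient(cfg)
  expect_match(sim$ground_truth$warnings, "autocrine", all = FALSE)
})

test_that("fast clearance gives larger peak-to-trough swing than slow", {
  # same release pulse driving a 2 h and a 100 h half-life marker
  panel <- simulator_marker_panel()
  times <- seq(0, 42, by = 1 / 96)
  release <- 1 + 50 * .pulse_shape_for_tests(times - 10)
  fast <- simulate_marker_serum(times, release, marker_def("S100B", panel))
  slow <- simulate_marker_serum(times, release, marker_def("LDH", panel))
  ratio <- function(x) max(x$conc) / min(x$conc[x$time > 10])
  expect_gt(ratio(fast), ratio(slow))
})
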
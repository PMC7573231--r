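test_that("compute_flux converts concentration slope to mass-specific flux", {
  # constant concentration -> zero flux everywhere
  t <- seq(0, 600)
  tr <- oxygen_trace(t, rep(300, length(t)), chamber_volume = 2,
                     tissue_mass = 2, protocol_id = "B")
  fs <- compute_flux(tr)
  expect_true(all(abs(fs$flux) < 1e-9, na.rm = TRUE))

  # 1 nmol/ml/s decline, 2 ml chamber, 2 mg tissue -> 1000 pmol/s/mg
  fs <- compute_flux(linear_trace(slope = 0.5, duration = 300))
  mid <- fs$flux[50:250]
  expect_equal(mid, rep(500, length(mid)), tolerance = 1e-9)
  fs <- compute_flux(linear_trace(slope = 1, duration = 200, start = 400))
  expect_equal(fs$flux[100], 1000, tolerance = 1e-9)

  # volume/mass scaling: halving mass doubles flux
  fs2 <- compute_flux(linear_trace(slope = 0.5, duration = 300, mass = 1))
  expect_equal(fs2$flux[100], 1000, tolerance = 1e-9)
})

test_that("compute_flux validates its window", {
  tr <- linear_trace(0.1, duration = 300)
  expect_error(compute_flux(tr, smoothing_window = 400),
               class = "sealmito_invalid_input")
  t <- seq(0, 300, by = 15)
  tr <- oxygen_trace(t, 400 - 0.1 * t, chamber_volume = 2, tissue_mass = 2)
  expect_error(compute_flux(tr, smoothing_window = 20),
               class = "sealmito_insufficient_data")
})

test_that("compute_flux recovers a noisy plateau within 5%", {
  sim <- simulate_trace(trace_spec(protocol_id = "B", noise_sd = 0.5,
                                   chamber_volume = 2, tissue_mass = 2,
                                   true_state_fluxes = c(Ln = 5, OXPHOS = 40,
                                                         LOmy = 8, ETS = 55),
                                   seed = 42))
  run <- suppressWarnings(analyze_run(sim$trace))
  expect_lt(abs(state_flux(run, "OXPHOS") - 40) / 40, 0.05)
})

test_that("detect_steady_states labels protocol-B plateaus from a noiseless trace", {
  sim <- simulate_trace(trace_spec(
    protocol_id = "B", noise_sd = 0,
    true_state_fluxes = c(Ln = 5, OXPHOS = 40, LOmy = 8, ETS = 55),
    baseline_flux = 0, seed = 1))
  st <- detect_steady_states(compute_flux(sim$trace), suit_protocols()$B)
  expect_equal(st$flux[st$state == "Ln"], 5, tolerance = 1e-6)
  expect_equal(st$flux[st$state == "OXPHOS"], 40, tolerance = 1e-6)
  expect_equal(st$flux[st$state == "LOmy"], 8, tolerance = 1e-6)
  expect_equal(st$flux[st$state == "ETS"], 55, tolerance = 1e-6)
  expect_true(all(st$qc == "ok"))
})

test_that("a trace with zero events yields only the baseline state", {
  tr <- linear_trace(0.01, duration = 400)
  st <- detect_steady_states(compute_flux(tr), suit_protocols()$B)
  expect_equal(nrow(st), 1L)
  expect_equal(st$state, "baseline")
  expect_equal(st$flux, 10, tolerance = 1e-6)
})

test_that("a monotone ramp steeper than the tolerance is flagged, not reported", {
  t <- seq(0, 600)
  tr <- oxygen_trace(t, 400 - 1e-4 * t^2, chamber_volume = 2, tissue_mass = 2)
  st <- detect_steady_states(compute_flux(tr), suit_protocols()$B)
  expect_true(is.na(st$flux))
  expect_equal(st$qc, "unstable")
})

test_that("detector reports a protocol/event mismatch by run", {
  sim <- simulate_trace(trace_spec(protocol_id = "B", noise_sd = 0, seed = 1))
  expect_error(
    detect_steady_states(compute_flux(sim$trace), suit_protocols()$A),
    class = "sealmito_protocol_mismatch")
})

test_that("baseline correction subtracts, clips and flags", {
  st <- data.frame(state = c("baseline", "OXPHOS", "Ln"),
                   flux = c(2, 42, 4), qc = "ok", baseline_corrected = FALSE,
                   stringsAsFactors = FALSE)
  out <- baseline_correct(st)
  expect_equal(out$flux[out$state == "OXPHOS"], 40)
  expect_true(all(out$baseline_corrected[out$state != "baseline"]))

  # baseline 0 -> unchanged
  st0 <- st; st0$flux[1] <- 0
  expect_equal(baseline_correct(st0)$flux[-1], st0$flux[-1])

  # negative corrected flux clips to zero with a warning
  st5 <- st; st5$flux[1] <- 5
  expect_warning(out5 <- baseline_correct(st5), "clipped")
  expect_equal(out5$flux[out5$state == "Ln"], 0)

  # missing baseline is an error naming the run
  expect_error(baseline_correct(st[-1, ]), class = "sealmito_missing_baseline")
})

test_that("cytochrome-c threshold is strict at 10%", {
  expect_true(cytc_test(40, 44.0))   # exactly 10%: pass
  expect_true(cytc_test(40, 40))     # no change
  expect_false(cytc_test(40, 46))    # 15% increase: fail
  expect_error(cytc_test(0, 10), class = "sealmito_undefined_ratio")
  expect_error(cytc_test(-1, 10), class = "sealmito_undefined_ratio")
})

test_that("oxygen-window QC reports closed-bound excursions as warnings only", {
  t <- seq(0, 500)
  conc <- rep(300, length(t))
  tr <- oxygen_trace(t, conc, chamber_volume = 2, tissue_mass = 2)
  expect_equal(nrow(check_oxygen_window(tr)), 0L)

  conc[101:130] <- 240   # 30 s dip
  tr <- oxygen_trace(t, conc, chamber_volume = 2, tissue_mass = 2)
  expect_warning(iv <- check_oxygen_window(tr), "oxygen left")
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$duration_s, 29)    # samples 101..130 span 29 s
  expect_equal(iv$direction, "low")

  # 400 exactly is in range (closed bounds)
  tr <- oxygen_trace(t, rep(400, length(t)), chamber_volume = 2, tissue_mass = 2)
  expect_equal(nrow(check_oxygen_window(tr)), 0L)
})

test_that("aggregation pools repeated states and standardizes single measures", {
  runs <- list(
    make_run("A", c(Ln = 10, OXPHOS = 40, ETS = 52)),
    make_run("B", c(Ln = 12, OXPHOS = 44, LOmy = 22, ETS = 56)),
    make_run("CI", c(OXPHOS = 40, ETS = 54, CI = 30)),
    make_run("CII", c(OXPHOS = 44, ETS = 58, CII = 33))
  )
  s <- aggregate_sample(runs)
  expect_equal(s$mean_OXPHOS, 42)           # pooled over all four protocols
  expect_equal(s$mean_Ln, 11)
  expect_equal(s$mean_ETS, 55)
  expect_equal(s$std_CI, 30 / 40 * 42)      # 31.5, the stated formula
  expect_equal(s$std_CII, 33 / 44 * 42)
  expect_equal(s$std_LOmy, 22 / 44 * 42)
  rr <- respiratory_ratios(s)
  expect_equal(rr$SCR_CI, 0.75)
  expect_equal(rr$CCR_Ln, 11 / 42)
  expect_equal(rr$FCR, 42 / 55)
})

test_that("standardization is the identity when every run's OXPHOS equals the mean", {
  runs <- list(
    make_run("B", c(Ln = 10, OXPHOS = 40, LOmy = 18, ETS = 50)),
    make_run("CI", c(OXPHOS = 40, CI = 28)),
    make_run("CII", c(OXPHOS = 40, CII = 26))
  )
  s <- aggregate_sample(runs)
  expect_equal(s$std_LOmy, 18)
  expect_equal(s$std_CI, 28)
  expect_equal(s$std_CII, 26)
  # single run with X == OXPHOS gives std_X == mean_OXPHOS
  s1 <- aggregate_sample(list(make_run("CI", c(OXPHOS = 40, CI = 40))))
  expect_equal(s1$std_CI, s1$mean_OXPHOS)
})

test_that("excluded runs contribute no states and exclusion is monotone", {
  runs <- list(
    make_run("A", c(Ln = 10, OXPHOS = 40, ETS = 52)),
    make_run("B", c(Ln = 20, OXPHOS = 60, LOmy = 22, ETS = 70),
             cytc_pass = FALSE)
  )
  s <- aggregate_sample(runs)
  expect_equal(s$mean_OXPHOS, 40)   # failing run absent from all means
  expect_equal(s$mean_Ln, 10)
  expect_true(is.na(s$std_LOmy))    # LOmy only measured in the excluded run
  expect_equal(s$n_runs, 1L)

  # marking a run excluded never increases the states entering a mean
  both <- aggregate_sample(list(
    make_run("A", c(Ln = 10, OXPHOS = 40, ETS = 52)),
    make_run("B", c(Ln = 20, OXPHOS = 60, LOmy = 22, ETS = 70))))
  expect_gte(both$n_runs, s$n_runs)
  expect_equal(both$mean_OXPHOS, 50)

  expect_warning(
    all_out <- aggregate_sample(list(
      make_run("A", c(Ln = 10, OXPHOS = 40), cytc_pass = FALSE))),
    "all runs excluded")
  expect_true(all_out$excluded)
})

test_that("ratio errors and warnings follow the contract", {
  s <- aggregate_sample(list(make_run("B", c(Ln = 10, OXPHOS = 40,
                                             LOmy = 18, ETS = 50))))
  expect_silent(rr <- respiratory_ratios(s))
  expect_equal(rr$SCR_CI, NA_real_)         # CI not measured
  s$mean_OXPHOS <- 0
  expect_error(respiratory_ratios(s), class = "sealmito_zero_denominator")
  s$mean_OXPHOS <- 40; s$mean_ETS <- 30     # FCR > 1: warn, don't fail
  expect_warning(respiratory_ratios(s), "outside")
})

test_that("paired comparison matches the closed form and flags no-variance", {
  pre <- c(10, 12, 9, 14); post <- c(11, 15, 10, 13)
  res <- paired_compare(pre, post)
  # textbook formula computed independently
  d <- post - pre
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, t_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3))
  expect_equal(res$mean_diff, 1)
  # and the reference implementation agrees
  tt <- t.test(post, pre, paired = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$p, tt$p.value)

  expect_error(paired_compare(pre, pre), class = "sealmito_no_variance")
  expect_error(paired_compare(c(1, 2, 3), c(2, 3, 4)),
               class = "sealmito_no_variance")   # all diffs equal
  # listwise deletion of incomplete pairs
  res2 <- paired_compare(c(pre, NA), c(post, 1))
  expect_equal(res2$n, 4L)
  expect_equal(res2$t, res$t)
})

test_that("steady windows never overlap reoxygenation intervals", {
  sim <- simulate_trace(trace_spec(protocol_id = "B", noise_sd = 0.3,
                                   tissue_mass = 5, dwell = 400, seed = 3))
  ev <- sim$trace$events
  reox <- ev$time_s[ev$agent == "REOX"]
  expect_gt(length(reox), 0L)   # the fixture does reoxygenate
  st <- detect_steady_states(compute_flux(sim$trace), suit_protocols()$B)
  for (i in which(!is.na(st$flux))) {
    expect_false(any(reox >= st$t_start[i] & reox <= st$t_end[i]))
  }
})

test_that("a run failing the cytochrome-c test is excluded end to end", {
  sim <- simulate_trace(trace_spec(protocol_id = "B", noise_sd = 0,
                                   cytc_bump_frac = 0.15, seed = 5))
  run <- analyze_run(sim$trace)
  expect_false(run$cytc_pass)
  expect_true(run$excluded)
})
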
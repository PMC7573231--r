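test_that("trace generator round-trips through the analyzer (noiseless)", {
  fluxes <- c(Ln = 5, OXPHOS = 40, LOmy = 8, ETS = 55)
  sim <- simulate_trace(trace_spec(protocol_id = "B", noise_sd = 0,
                                   true_state_fluxes = fluxes, seed = 4))
  run <- analyze_run(sim$trace)
  for (st in names(fluxes)) {
    expect_equal(state_flux(run, st), unname(fluxes[st]), tolerance = 1e-6)
  }
  expect_true(run$cytc_pass)
})

test_that("generators are deterministic given a seed", {
  a <- simulate_trace(trace_spec(seed = 11))
  b <- simulate_trace(trace_spec(seed = 11))
  expect_identical(a$trace$conc, b$trace$conc)
  expect_identical(a$trace$events, b$trace$events)
  expect_identical(simulate_cohort(5, seed = 2), simulate_cohort(5, seed = 2))
  expect_identical(simulate_de_table(100, 0.1, 0.1, seed = 3),
                   simulate_de_table(100, 0.1, 0.1, seed = 3))
})

test_that("seeded generator output matches frozen cross-platform checksums", {
  s <- simulate_trace(trace_spec(protocol_id = "CI", noise_sd = 0.5, seed = 123))
  expect_equal(sum(s$trace$conc), 613210.365101, tolerance = 1e-10)
  expect_equal(s$trace$conc[500], 384.092079, tolerance = 1e-8)
  expect_equal(s$trace$conc[1500], 277.938186, tolerance = 1e-8)
  ch <- simulate_cohort(3, seed = 99)
  expect_equal(ch$mass_pre_kg[1], 398.6981251, tolerance = 1e-8)
  expect_equal(ch$mass_post_kg[3], 291.6500305, tolerance = 1e-8)
  de <- simulate_de_table(50, 0.1, 0.1, seed = 77)
  expect_equal(sum(de$log2fc), -0.74849542, tolerance = 1e-7)
  expect_equal(sum(de$pvalue), 19.85464651, tolerance = 1e-7)
})

test_that("simulated oxygen stays in range and reoxygenation is recorded", {
  # the noise-free path never leaves (0, o2_start]
  sim <- simulate_trace(trace_spec(protocol_id = "B", noise_sd = 0,
                                   tissue_mass = 5, dwell = 400, seed = 6))
  expect_true(all(sim$trace$conc > 0 & sim$trace$conc <= 400))
  ev <- sim$trace$events
  expect_true("REOX" %in% ev$agent)
  # concentration is restored at each recorded REOX event
  for (r in ev$time_s[ev$agent == "REOX"]) {
    expect_equal(sim$trace$conc[sim$trace$time_s == r], 400)
  }
})

test_that("impossible specs and bad compositions are rejected", {
  expect_error(
    simulate_trace(trace_spec(true_state_fluxes = c(Ln = 5, OXPHOS = 4000,
                                                    LOmy = 8, ETS = 5000),
                              tissue_mass = 5)),
    class = "sealmito_invalid_spec")
  expect_error(trace_spec(reoxygenate_at = 500), class = "sealmito_invalid_spec")
  expect_error(trace_spec(baseline_flux = -1), class = "sealmito_invalid_spec")
  expect_error(simulate_de_table(100, 0.6, 0.6), class = "sealmito_invalid_spec")
})

test_that("cohort generator reproduces degenerate and stated-world cases", {
  # sd 0 everywhere: every record loses exactly loss * days
  ch <- simulate_cohort(3, mass_pre_mean = 388, mass_pre_sd = 0,
                        loss_mean = 3, loss_sd = 0, days_mean = 34,
                        days_sd = 0, seed = 1)
  expect_equal(ch$mass_pre_kg - ch$mass_post_kg, rep(102, 3))
  expect_equal(nrow(simulate_cohort(1, seed = 5)), 1L)
  # absurd loss rates are floored at half the pre-molt mass
  expect_warning(
    fl <- simulate_cohort(2, loss_mean = 12, loss_sd = 0, seed = 8),
    "floored")
  expect_true(all(fl$mass_post_kg >= 0.5 * fl$mass_pre_kg))
})

test_that("DE generator spikes are recoverable and nulls are quiet", {
  # null table: expected false positives below 5% of genes
  de0 <- simulate_de_table(2000, 0, 0, seed = 12)
  called <- filter_de(de0)
  expect_lt(length(called$up) + length(called$down), 0.05 * 2000)
  # strong spiking: at least 90% of spiked genes recovered
  de1 <- simulate_de_table(2000, frac_up = 0.1, effect_lfc = 2, seed = 13)
  up_true <- de1$gene_id[de1$spiked == "up"]
  hit <- filter_de(de1)$up
  expect_gte(length(intersect(hit, up_true)) / length(up_true), 0.9)
})
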
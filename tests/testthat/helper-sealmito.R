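# A respiro_run built directly from known state fluxes, bypassing the
# detector: used to test aggregation/ratio logic in isolation.
make_run <- function(protocol_id, fluxes, cytc_pass = TRUE,
                     excluded = isTRUE(!cytc_pass),
                     animal = "a1", tp = "pre") {
  states <- data.frame(state = names(fluxes), flux = unname(fluxes),
                       qc = "ok", baseline_corrected = TRUE,
                       stringsAsFactors = FALSE)
  structure(list(
    run_id = paste(animal, tp, protocol_id, sep = "_"),
    animal_id = animal, timepoint = tp, protocol_id = protocol_id,
    states = states, raw_states = states,
    cytc_pass = cytc_pass, excluded = excluded,
    o2_excursions = data.frame()
  ), class = "respiro_run")
}

# a plain linear-decline trace with no events
linear_trace <- function(slope, duration = 600, volume = 2, mass = 2,
                         start = 400, dt = 1) {
  t <- seq(0, duration, by = dt)
  oxygen_trace(t, start - slope * t, chamber_volume = volume,
               tissue_mass = mass, protocol_id = "B")
}

# independent hypergeometric-tail oracle: explicit enumeration of
# P(overlap >= o) via binomial-coefficient sums
hyper_oracle <- function(N, t, q, o) {
  ks <- o:min(q, t)
  sum(choose(t, ks) * choose(N - t, q - ks)) / choose(N, q)
}

# extract one state's flux from an analyzed run
state_flux <- function(run, state) {
  run$states$flux[run$states$state == state]
}
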
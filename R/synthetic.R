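#' Default true state fluxes for simulated muscle
#'
#' A single stated set of respiratory-state fluxes (pmol O2 s-1 mg-1) used
#' by the trace generator: leak without adenylates (Ln) at 13 — the lowest
#' leak measure reported for molting seal muscle — oligomycin leak (LOmy)
#' about twice that, OXPHOS 55, uncoupled ETS 70, and uncoupled maxima
#' through complex I and II of 40 and 35.
#'
#' @return named numeric vector
#' @export
default_state_fluxes <- function() {
  c(Ln = 13, OXPHOS = 55, LOmy = 26, ETS = 70, CI = 40, CII = 35)
}

#' Specification for a simulated respirometry trace
#'
#' The stated world of the generator: piecewise-steady oxygen decline with a
#' step change at each titration, i.i.d. Gaussian measurement noise on
#' concentration (instrument noise arises on the oxygen signal, not on
#' flux), automatic reoxygenation whenever the chamber oxygen falls to
#' `reoxygenate_at`, and a cytochrome-c flux bump of `cytc_bump_frac`
#' (healthy membranes ~2%; set above 10% to synthesize a failing run).
#' Intermediate protocol steps without a named state (complex-I substrates
#' plus ADP, before succinate) run at 75% of OXPHOS.
#'
#' @param protocol_id one of `"A"`, `"B"`, `"CI"`, `"CII"`
#' @param true_state_fluxes named vector, state -> pmol O2 s-1 mg-1
#' @param baseline_flux instrument/chemical background flux (default 2)
#' @param noise_sd concentration noise sd, nmol/ml (default 0.5)
#' @param chamber_volume ml (default 2)
#' @param tissue_mass mg (default 3.5, middle of the 2-5 mg range used)
#' @param o2_start starting oxygen, nmol/ml (default 400)
#' @param reoxygenate_at reoxygenation trigger, nmol/ml (default 250)
#' @param cytc_bump_frac fractional flux increase after CytC (default 0.02)
#' @param dwell nominal duration of each titration segment, s (default 300)
#' @param dwell_jitter_sd sd of segment-duration jitter, s (default 0)
#' @param dt sampling interval, s (default 1)
#' @param seed integer seed (NULL = ambient RNG)
#' @param animal_id,timepoint,run_id trace metadata
#' @return list of class `trace_spec`
#' @export
trace_spec <- function(protocol_id = "B",
                       true_state_fluxes = default_state_fluxes(),
                       baseline_flux = 2, noise_sd = 0.5,
                       chamber_volume = 2, tissue_mass = 3.5,
                       o2_start = 400, reoxygenate_at = 250,
                       cytc_bump_frac = 0.02, dwell = 300,
                       dwell_jitter_sd = 0, dt = 1, seed = NULL,
                       animal_id = "sim", timepoint = "pre", run_id = NULL) {
  if (any(true_state_fluxes < 0) || baseline_flux < 0)
    smt_stop("fluxes must be >= 0", "sealmito_invalid_spec")
  if (!(reoxygenate_at > 0 && reoxygenate_at < o2_start))
    smt_stop("need 0 < reoxygenate_at < o2_start", "sealmito_invalid_spec")
  structure(as.list(environment()), class = "trace_spec")
}

#' Simulate an annotated SUIT respirometry trace with known ground truth
#'
#' Concentration integrates `-(baseline + state flux) * mass / volume` per
#' step of the protocol (Table-ordered titration events), reoxygenation
#' events restore the chamber to `o2_start` whenever it reaches
#' `reoxygenate_at`, and Gaussian noise is added to the observed
#' concentration (clamped to the physical range). Deterministic given
#' `spec$seed`.
#'
#' @param spec a [trace_spec()]
#' @param protocols protocol definitions (default [suit_protocols()])
#' @return list of class `sim_trace`: `trace` (an [oxygen_trace()]) and
#'   `truth` (data.frame `step`, `state`, `true_flux`, `t_start`, `t_end`;
#'   `true_flux` excludes the baseline component)
#' @export
simulate_trace <- function(spec, protocols = suit_protocols()) {
  stopifnot(inherits(spec, "trace_spec"))
  protocol <- protocols[[spec$protocol_id]]
  if (is.null(protocol))
    smt_stop(paste0("no protocol definition for ", spec$protocol_id),
             "sealmito_invalid_spec")
  fl <- spec$true_state_fluxes
  oxphos <- fl[["OXPHOS"]]
  step_state_flux <- function(state) {
    switch(state,
      baseline = 0,
      none = 0.75 * oxphos,
      cytc_check = oxphos * (1 + spec$cytc_bump_frac),
      {
        if (!state %in% names(fl))
          smt_stop(paste0("true_state_fluxes lacks state ", state),
                   "sealmito_invalid_spec")
        fl[[state]]
      })
  }
  steps <- protocol$steps
  state_flux <- vapply(steps$state, step_state_flux, numeric(1))
  total_flux <- spec$baseline_flux + state_flux
  rate <- total_flux * spec$tissue_mass / (1000 * spec$chamber_volume)  # nmol/ml/s
  # a segment must leave room for at least one detector window between
  # reoxygenations; reject specs whose decline is too fast for any plateau
  span <- spec$o2_start - spec$reoxygenate_at
  too_fast <- rate > 0 & (span / rate) < 120
  if (any(too_fast))
    smt_stop(sprintf(
      "flux too high for steady state before reoxygenation in step(s): %s",
      paste(steps$state[too_fast], collapse = ", ")), "sealmito_invalid_spec")
  maybe_seed(spec$seed, {
    nstep <- nrow(steps)
    dur <- spec$dwell + if (spec$dwell_jitter_sd > 0)
      stats::rnorm(nstep, 0, spec$dwell_jitter_sd) else rep(0, nstep)
    dur <- pmax(dur, 120)
    bounds <- cumsum(c(0, dur))
    t <- seq(0, bounds[nstep + 1L], by = spec$dt)
    step_of <- findInterval(t, bounds, rightmost.closed = TRUE)
    step_of[step_of > nstep] <- nstep
    n <- length(t)
    conc <- numeric(n)
    conc[1] <- spec$o2_start
    reox_t <- numeric(0)
    for (i in 2:n) {
      nxt <- conc[i - 1] - rate[step_of[i]] * spec$dt
      if (nxt <= spec$reoxygenate_at) {
        reox_t <- c(reox_t, t[i])
        nxt <- spec$o2_start
      }
      conc[i] <- nxt
    }
    # noise rides on the sensor reading and is not truncated by the chamber
    # bound: clamping at o2_start would bias slopes low wherever the true
    # concentration sits near the bound (the whole baseline segment)
    obs <- conc + if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd)
                  else 0
    obs <- pmax(obs, 1e-9)
    ag <- suit_agents()
    ev <- do.call(rbind, lapply(seq_len(nstep - 1L), function(i) {
      agents <- protocol$agent_list[[i + 1L]]
      info <- ag[match(agents, ag$agent), ]
      data.frame(time_s = bounds[i + 1L], agent = agents,
                 target_conc = info$target_conc, unit = info$unit,
                 stringsAsFactors = FALSE)
    }))
    if (length(reox_t)) {
      ev <- rbind(ev, data.frame(time_s = reox_t, agent = "REOX",
                                 target_conc = NA_real_, unit = "",
                                 stringsAsFactors = FALSE))
    }
    trace <- oxygen_trace(
      time_s = t, conc = obs, events = ev,
      chamber_volume = spec$chamber_volume, tissue_mass = spec$tissue_mass,
      animal_id = spec$animal_id, timepoint = spec$timepoint,
      protocol_id = spec$protocol_id, run_id = spec$run_id
    )
    truth <- data.frame(step = steps$step, state = steps$state,
                        true_flux = state_flux,
                        t_start = bounds[-length(bounds)], t_end = bounds[-1],
                        stringsAsFactors = FALSE)
    structure(list(trace = trace, truth = truth), class = "sim_trace")
  })
}

#' Simulate a molt cohort
#'
#' Seeded normal draws of pre-molt mass, daily loss rate and days ashore;
#' `mass_post = mass_pre - daily_loss * days`, floored at half the pre-molt
#' mass (with a warning) since no fasting seal halves its body mass.
#' Defaults are the published cohort conditions: 388 +/- 50 kg pre-molt,
#' 3 kg/day loss, ~34 days ashore.
#'
#' @param n_animals number of animals (>= 1)
#' @param mass_pre_mean,mass_pre_sd pre-molt mass distribution, kg
#' @param loss_mean,loss_sd daily loss distribution, kg/day
#' @param days_mean,days_sd days-ashore distribution
#' @param seed integer seed (NULL = ambient RNG)
#' @return data.frame: `animal_id`, `mass_pre_kg`, `mass_post_kg`,
#'   `days_ashore`
#' @export
simulate_cohort <- function(n_animals = 6, mass_pre_mean = 388,
                            mass_pre_sd = 50, loss_mean = 3, loss_sd = 0.5,
                            days_mean = 34, days_sd = 3, seed = NULL) {
  stopifnot(n_animals >= 1, mass_pre_mean > 0, loss_mean > 0, days_mean > 0)
  maybe_seed(seed, {
    pre <- pmax(stats::rnorm(n_animals, mass_pre_mean, mass_pre_sd),
                0.2 * mass_pre_mean)
    loss <- pmax(stats::rnorm(n_animals, loss_mean, loss_sd), 0)
    days <- pmax(stats::rnorm(n_animals, days_mean, days_sd), 1)
    post <- pre - loss * days
    floor_at <- 0.5 * pre
    if (any(post < floor_at)) {
      warning(sprintf("%d simulated animal(s) floored at half pre-molt mass",
                      sum(post < floor_at)), call. = FALSE)
      post <- pmax(post, floor_at)
    }
    data.frame(
      animal_id = sprintf("seal%02d", seq_len(n_animals)),
      mass_pre_kg = pre, mass_post_kg = post, days_ashore = days,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a differential-expression table
#'
#' Null genes get `log2fc ~ N(0, 0.3)` and `p ~ U(0, 1)`; spiked genes get
#' `|log2fc| >= effect_lfc` (plus a small positive jitter) and p-values
#' drawn uniformly below 1e-6. BH adjustment produces `padj`.
#'
#' @param n_genes number of genes
#' @param frac_up,frac_down fractions of genes spiked up/down
#'   (`frac_up + frac_down <= 1`)
#' @param effect_lfc minimum |log2 fold change| of spiked genes (default 2)
#' @param seed integer seed (NULL = ambient RNG)
#' @return data.frame: `gene_id`, `log2fc`, `pvalue`, `padj`, `spiked`
#'   ("up", "down" or "null")
#' @export
simulate_de_table <- function(n_genes = 2000, frac_up = 0, frac_down = 0,
                              effect_lfc = 2, seed = NULL) {
  if (frac_up + frac_down > 1)
    smt_stop("frac_up + frac_down must be <= 1", "sealmito_invalid_spec")
  maybe_seed(seed, {
    n_up <- round(n_genes * frac_up)
    n_down <- round(n_genes * frac_down)
    lab <- rep("null", n_genes)
    if (n_up > 0) lab[seq_len(n_up)] <- "up"
    if (n_down > 0) lab[n_up + seq_len(n_down)] <- "down"
    lab <- sample(lab)
    lfc <- stats::rnorm(n_genes, 0, 0.3)
    p <- stats::runif(n_genes)
    spk <- lab != "null"
    lfc[spk] <- (effect_lfc + abs(stats::rnorm(sum(spk), 0, 0.25))) *
      ifelse(lab[spk] == "up", 1, -1)
    p[spk] <- stats::runif(sum(spk), 0, 1e-6)
    data.frame(
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      log2fc = lfc, pvalue = p, padj = bh_adjust(p), spiked = lab,
      stringsAsFactors = FALSE
    )
  })
}
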
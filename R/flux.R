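#' Mass-specific oxygen flux from a concentration trace
#'
#' Estimates the local slope of oxygen concentration by a local polynomial
#' fit over `smoothing_window` seconds and converts it to tissue
#' mass-specific flux:
#' `flux = -d[O2]/dt * chamber_volume / tissue_mass * 1000` (pmol O2 s-1
#' mg-1, from nmol ml-1 s-1). Samples within `smoothing_window` seconds of a
#' reoxygenation (`REOX`) event are masked (`NA`): the concentration jump
#' makes the derivative meaningless there.
#'
#' On a uniformly sampled trace the local quadratic fit reduces to a
#' Savitzky-Golay derivative convolution (the even terms cancel on a
#' symmetric window), which is what is used; non-uniform traces fall back to
#' per-point weighted quadratic fits.
#'
#' @param trace an [oxygen_trace()]
#' @param smoothing_window width of the local fit, seconds (default 20)
#' @return a `flux_series`: data.frame with columns `t`, `conc`, `flux`,
#'   `masked`, carrying the trace metadata as attributes
#' @export
compute_flux <- function(trace, smoothing_window = 20) {
  stopifnot(inherits(trace, "oxygen_trace"))
  t <- trace$time_s; y <- trace$conc
  span <- t[length(t)] - t[1]
  if (smoothing_window >= span)
    smt_stop("smoothing_window must be shorter than the trace span",
             "sealmito_invalid_input")
  dts <- diff(t)
  dt <- stats::median(dts)
  if (smoothing_window / dt < 2)
    smt_stop("fewer than 3 samples fit in the smoothing window",
             "sealmito_insufficient_data")
  uniform <- (max(dts) - min(dts)) < 1e-9 * dt
  k <- max(1L, as.integer(round(smoothing_window / (2 * dt))))
  if (uniform) {
    offs <- (-k:k) * dt
    kern <- offs / sum(offs^2)
    # stats::filter applies coefficients from the most advanced lag down,
    # so reverse the kernel to align offsets
    slope <- as.numeric(stats::filter(y, rev(kern), sides = 2))
  } else {
    slope <- vapply(seq_along(t), function(i) {
      sel <- abs(t - t[i]) <= smoothing_window / 2
      if (sum(sel) < 3L) return(NA_real_)
      fit <- stats::lm.fit(cbind(1, t[sel] - t[i], (t[sel] - t[i])^2), y[sel])
      fit$coefficients[2]
    }, numeric(1))
  }
  scale <- 1000 * trace$chamber_volume / trace$tissue_mass
  flux <- -slope * scale
  masked <- rep(FALSE, length(t))
  reox <- trace$events$time_s[trace$events$agent == "REOX"]
  for (r in reox) masked[abs(t - r) <= smoothing_window] <- TRUE
  flux[masked] <- NA_real_
  res <- data.frame(t = t, conc = y, flux = flux, masked = masked)
  attr(res, "chamber_volume") <- trace$chamber_volume
  attr(res, "tissue_mass") <- trace$tissue_mass
  attr(res, "flux_scale") <- scale
  attr(res, "smoothing_window") <- smoothing_window
  attr(res, "events") <- trace$events
  attr(res, "run_id") <- trace$run_id
  class(res) <- c("flux_series", "data.frame")
  res
}

# Steadiness test on concentration over [a, b]: split the span in half,
# compare the two half-span slopes. Steady when the halves agree to within
# stability_tol of the whole-span flux OR to within 3 SE of their difference
# (noise-aware escape: with clean data SE ~ 0 and the relative rule is
# exact; with honest instrument noise the slope difference cannot be
# resolved and the window must not be rejected for noise alone).
steady_stat <- function(fs, a, b, stability_tol) {
  scale <- attr(fs, "flux_scale")
  idx <- which(fs$t >= a & fs$t <= b & !fs$masked)
  if (length(idx) < 6L) return(NULL)
  t <- fs$t[idx]; y <- fs$conc[idx]
  mid <- (a + b) / 2
  h1 <- t <= mid
  if (sum(h1) < 3L || sum(!h1) < 3L) return(NULL)
  full <- slope_se(t, y)
  s1 <- slope_se(t[h1], y[h1])
  s2 <- slope_se(t[!h1], y[!h1])
  flux <- -full[1] * scale
  dflux <- (s1[1] - s2[1]) * scale     # flux2 - flux1 in flux units
  se_d <- sqrt(s1[2]^2 + s2[2]^2) * scale
  steady <- abs(dflux) <= max(stability_tol * abs(flux), 3 * se_d)
  list(flux = flux, dflux = dflux, se_d = se_d, steady = steady,
       slope_residual = dflux / ((b - a) / 2))
}

# Cluster titration events into steps: additions within group_tol seconds
# count as one titration step (a step's agents are added back-to-back).
event_groups <- function(events, group_tol = 5) {
  ev <- events[events$agent != "REOX", , drop = FALSE]
  if (nrow(ev) == 0L) return(ev[0, ])
  ev <- ev[order(ev$time_s), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(ev$time_s) > group_tol))
  data.frame(
    t = vapply(split(ev$time_s, grp), max, numeric(1)),
    agents = vapply(split(ev$agent, grp),
                    function(a) paste(sort(unique(a)), collapse = ";"),
                    character(1)),
    stringsAsFactors = FALSE
  )
}

#' Detect steady-state fluxes for each protocol step
#'
#' Partitions the run into inter-titration segments (step 1 = baseline before
#' the first titration), then within each segment slides a fixed-length
#' window backwards from the segment end and accepts the latest window whose
#' concentration slope is stable (see Details). Once a stable window is
#' found it is extended backwards while stability holds and the reported
#' flux is the linear-regression slope of concentration over the maximal
#' stable span — identical to the window mean for clean data, far less
#' variable for noisy data. Windows never overlap reoxygenation intervals,
#' and a margin of one smoothing window is kept clear of every titration
#' (derivative estimates straddling a step change are corrupted).
#'
#' Steps with no qualifying window are returned with `flux = NA` and a QC
#' flag (`"no_window"` or `"unstable"`), never silently dropped. A trace with
#' zero titration events yields only the baseline state.
#'
#' @param fs a `flux_series` from [compute_flux()]
#' @param protocol a [suit_protocol()] matching the run
#' @param stability_tol relative slope tolerance (default 0.02: the
#'   half-span fluxes must agree within 2% of the span flux, or within
#'   statistical noise)
#' @param window sliding-window length, seconds (default 60)
#' @param slide_step slide/extension increment, seconds (default 10)
#' @param margin clearance kept after/before each titration event, seconds
#'   (default: the smoothing window of `fs`)
#' @return data.frame of class `steady_states`: `step`, `state`, `t_start`,
#'   `t_end`, `flux`, `slope_residual`, `qc`, `baseline_corrected`
#' @export
detect_steady_states <- function(fs, protocol, stability_tol = 0.02,
                                 window = 60, slide_step = 10, margin = NULL) {
  stopifnot(inherits(fs, "flux_series"), inherits(protocol, "suit_protocol"))
  margin <- margin %||% attr(fs, "smoothing_window")
  events <- attr(fs, "events")
  grp <- event_groups(events)
  steps <- protocol$steps
  t0 <- fs$t[1]; t_end <- fs$t[length(fs$t)]
  if (nrow(grp) == 0L) {
    steps <- steps[steps$state == "baseline", , drop = FALSE]
    seg <- data.frame(start = t0, end = t_end)
  } else {
    if (nrow(grp) != nrow(steps) - 1L)
      smt_stop(sprintf(
        "run %s: %d titration step(s) found but protocol %s defines %d",
        attr(fs, "run_id"), nrow(grp), protocol$protocol_id, nrow(steps) - 1L),
        "sealmito_protocol_mismatch")
    seg <- data.frame(start = c(t0, grp$t),
                      end = c(grp$t, t_end))
  }
  reox_t <- events$time_s[events$agent == "REOX"]
  out <- lapply(seq_len(nrow(seg)), function(i) {
    row <- data.frame(step = steps$step[i], state = steps$state[i],
                      t_start = NA_real_, t_end = NA_real_,
                      flux = NA_real_, slope_residual = NA_real_,
                      qc = "ok", baseline_corrected = FALSE,
                      stringsAsFactors = FALSE)
    a0 <- seg$start[i] + margin
    b0 <- seg$end[i] - margin
    # reoxygenation splits a segment; use the latest clean piece
    rin <- reox_t[reox_t > seg$start[i] & reox_t < seg$end[i]]
    if (length(rin)) a0 <- max(a0, max(rin) + margin)
    if (b0 - a0 < window) { row$qc <- "no_window"; return(row) }
    w_end <- b0
    accepted <- NULL
    while (w_end - window >= a0) {
      st <- steady_stat(fs, w_end - window, w_end, stability_tol)
      if (!is.null(st) && st$steady) { accepted <- list(end = w_end, st = st); break }
      w_end <- w_end - slide_step
    }
    if (is.null(accepted)) { row$qc <- "unstable"; return(row) }
    # extend the stable span backwards for precision
    a <- accepted$end - window
    best <- accepted$st
    while (a - slide_step >= a0) {
      st <- steady_stat(fs, a - slide_step, accepted$end, stability_tol)
      if (is.null(st) || !st$steady) break
      a <- a - slide_step
      best <- st
    }
    row$t_start <- a; row$t_end <- accepted$end
    row$flux <- best$flux
    row$slope_residual <- best$slope_residual
    row
  })
  res <- do.call(rbind, out)
  attr(res, "run_id") <- attr(fs, "run_id")
  class(res) <- c("steady_states", "data.frame")
  res
}

#' Subtract instrument baseline flux from detected states
#'
#' Every non-baseline state has the chamber's baseline oxygen flux (measured
#' at the start of the protocol, before any titration) subtracted. Corrected
#' fluxes that come out negative are clipped to zero with a warning:
#' respiration below instrument background is non-physical and reflects
#' noise.
#'
#' @param states a `steady_states` data.frame from [detect_steady_states()]
#' @param baseline_flux optional explicit baseline flux; default is the
#'   run's own baseline state
#' @return the corrected `steady_states` (baseline row left untouched,
#'   `baseline_corrected = TRUE` on the others)
#' @export
baseline_correct <- function(states, baseline_flux = NULL) {
  if (is.null(baseline_flux)) {
    b <- states$flux[states$state == "baseline"]
    if (length(b) != 1L || is.na(b))
      smt_stop(paste0("missing baseline flux for run ",
                      attr(states, "run_id") %||% "<unknown>"),
               "sealmito_missing_baseline")
    baseline_flux <- b
  }
  sel <- states$state != "baseline" & !is.na(states$flux)
  corrected <- states$flux[sel] - baseline_flux
  if (any(corrected < 0)) {
    warning(sprintf("%d corrected flux(es) < 0 clipped to 0 (run %s)",
                    sum(corrected < 0),
                    attr(states, "run_id") %||% "<unknown>"), call. = FALSE)
    corrected[corrected < 0] <- 0
  }
  states$flux[sel] <- corrected
  states$baseline_corrected[states$state != "baseline"] <- TRUE
  states
}

#' Cytochrome-c outer-membrane integrity test
#'
#' A flux increase of strictly more than 10% after exogenous cytochrome c
#' indicates damaged outer mitochondrial membranes and invalidates the run.
#'
#' @param flux_before flux before the CytC titration (usually the OXPHOS
#'   state), must be > 0
#' @param flux_after flux after the CytC titration
#' @param threshold fractional increase threshold (default 0.10, strict)
#' @return `TRUE` (pass) or `FALSE` (fail / run excluded)
#' @export
cytc_test <- function(flux_before, flux_after, threshold = 0.10) {
  if (!is.finite(flux_before) || flux_before <= 0)
    smt_stop("cytc_test: flux_before must be > 0 (undefined ratio)",
             "sealmito_undefined_ratio")
  (flux_after - flux_before) / flux_before <= threshold
}

#' Analyze one chamber run end to end
#'
#' Flux estimation, steady-state detection, baseline correction, the
#' cytochrome-c membrane test (OXPHOS flux vs the post-CytC flux, on
#' baseline-corrected values) and the oxygen-window QC, bundled into a
#' per-run result for [aggregate_sample()].
#'
#' @param trace an [oxygen_trace()]
#' @param protocol optional [suit_protocol()]; default looked up from the
#'   trace's `protocol_id` in [suit_protocols()]
#' @param smoothing_window,stability_tol,window detector parameters, see
#'   [compute_flux()] and [detect_steady_states()]
#' @return object of class `respiro_run`: `states` (corrected), `raw_states`,
#'   `cytc_pass`, `excluded`, `o2_excursions`, and the run metadata
#' @export
analyze_run <- function(trace, protocol = NULL, smoothing_window = 20,
                        stability_tol = 0.02, window = 60) {
  stopifnot(inherits(trace, "oxygen_trace"))
  protocol <- protocol %||% suit_protocols()[[trace$protocol_id]]
  fs <- compute_flux(trace, smoothing_window = smoothing_window)
  raw <- detect_steady_states(fs, protocol, stability_tol = stability_tol,
                              window = window)
  o2 <- withCallingHandlers(
    check_oxygen_window(trace),
    warning = function(w) invokeRestart("muffleWarning"))
  states <- baseline_correct(raw)
  ox <- states$flux[states$state == "OXPHOS"]
  cc <- states$flux[states$state == "cytc_check"]
  cytc_pass <- if (length(ox) == 1L && length(cc) == 1L &&
                   is.finite(ox) && is.finite(cc) && ox > 0) {
    cytc_test(ox, cc)
  } else NA
  structure(list(
    run_id = trace$run_id, animal_id = trace$animal_id,
    timepoint = trace$timepoint, protocol_id = trace$protocol_id,
    states = states, raw_states = raw,
    cytc_pass = cytc_pass, excluded = isTRUE(!cytc_pass),
    o2_excursions = o2
  ), class = "respiro_run")
}

#' @export
print.respiro_run <- function(x, ...) {
  cat(sprintf("<respiro_run %s> cytc %s%s\n", x$run_id,
              if (is.na(x$cytc_pass)) "untested"
              else if (x$cytc_pass) "pass" else "FAIL",
              if (x$excluded) " [excluded]" else ""))
  print(x$states[, c("state", "flux", "qc")])
  invisible(x)
}
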
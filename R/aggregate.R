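run_state_flux <- function(run, state) {
  s <- run$states
  v <- s$flux[s$state == state & s$qc == "ok"]
  v <- v[is.finite(v)]
  if (length(v)) v[1] else NA_real_
}

#' Aggregate protocol runs into one sample's respiratory-state set
#'
#' One animal x timepoint is measured with up to four SUIT protocols.
#' States measured repeatedly across protocols (Ln, OXPHOS, ETS) are
#' arithmetic means over the non-excluded runs measuring them; OXPHOS is
#' pooled across all four protocols unconditionally. States with a single
#' inhibitory-titration measure (LOmy, CI, CII) are standardized to the
#' sample's mean OXPHOS: the fractional reduction from that run's own OXPHOS
#' is multiplied by the mean OXPHOS, `std_X = (X_p / OXPHOS_p) * mean_OXPHOS`.
#' Runs failing the cytochrome-c test contribute no states. The two leak
#' estimates Ln and LOmy are kept distinct throughout and never pooled.
#'
#' @param runs list of `respiro_run` objects from [analyze_run()], all from
#'   the same animal and timepoint
#' @return object of class `sample_state_set` with fields `animal_id`,
#'   `timepoint`, `mean_Ln`, `mean_OXPHOS`, `mean_ETS`, `std_LOmy`,
#'   `std_CI`, `std_CII`, `cytc_pass`, `excluded`, `n_runs`
#' @export
aggregate_sample <- function(runs) {
  stopifnot(length(runs) >= 1L, all(vapply(runs, inherits, logical(1), "respiro_run")))
  animal_id <- runs[[1]]$animal_id
  timepoint <- runs[[1]]$timepoint
  active <- Filter(function(r) !r$excluded, runs)
  empty <- structure(list(
    animal_id = animal_id, timepoint = timepoint,
    mean_Ln = NA_real_, mean_OXPHOS = NA_real_, mean_ETS = NA_real_,
    std_LOmy = NA_real_, std_CI = NA_real_, std_CII = NA_real_,
    cytc_pass = FALSE, excluded = TRUE, n_runs = 0L
  ), class = "sample_state_set")
  if (length(active) == 0L) {
    warning(sprintf("sample %s/%s: all runs excluded", animal_id, timepoint),
            call. = FALSE)
    return(empty)
  }
  pooled <- function(state) {
    v <- vapply(active, run_state_flux, numeric(1), state = state)
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }
  mean_OXPHOS <- pooled("OXPHOS")
  if (!is.finite(mean_OXPHOS))
    smt_stop(sprintf("sample %s/%s: no run yields an OXPHOS flux",
                     animal_id, timepoint), "sealmito_missing_oxphos")
  std_single <- function(state) {
    vals <- unlist(lapply(active, function(r) {
      x <- run_state_flux(r, state)
      if (!is.finite(x)) return(NULL)
      ox <- run_state_flux(r, "OXPHOS")
      if (!is.finite(ox) || ox <= 0) return(NA_real_)  # OXPHOS missing in that run
      (x / ox) * mean_OXPHOS
    }))
    vals <- vals[is.finite(vals)]
    if (length(vals)) mean(vals) else NA_real_
  }
  structure(list(
    animal_id = animal_id, timepoint = timepoint,
    mean_Ln = pooled("Ln"), mean_OXPHOS = mean_OXPHOS, mean_ETS = pooled("ETS"),
    std_LOmy = std_single("LOmy"), std_CI = std_single("CI"),
    std_CII = std_single("CII"),
    cytc_pass = all(vapply(active, function(r) isTRUE(r$cytc_pass), logical(1))),
    excluded = FALSE, n_runs = length(active)
  ), class = "sample_state_set")
}

#' @export
print.sample_state_set <- function(x, ...) {
  cat(sprintf("<sample_state_set %s/%s> (%d run(s)%s)\n", x$animal_id,
              x$timepoint, x$n_runs, if (x$excluded) ", EXCLUDED" else ""))
  v <- unlist(x[c("mean_Ln", "mean_OXPHOS", "mean_ETS",
                  "std_LOmy", "std_CI", "std_CII")])
  print(round(v, 2))
  invisible(x)
}

#' Respiratory control ratios for one sample
#'
#' Substrate control ratios `SCR_CI = std_CI / mean_OXPHOS` and
#' `SCR_CII = std_CII / mean_OXPHOS` (relative contribution of each complex
#' to OXPHOS capacity), coupling control ratio `CCR_Ln = mean_Ln /
#' mean_OXPHOS` (leak share of OXPHOS), and flux control ratio
#' `FCR = mean_OXPHOS / mean_ETS` (OXPHOS share of uncoupled ETS capacity).
#' CCR and FCR are expected in (0, 1] for physically sensible inputs; values
#' outside that range warn but do not fail.
#'
#' @param s a `sample_state_set` from [aggregate_sample()]
#' @return list of class `respiratory_ratios` with `SCR_CI`, `SCR_CII`,
#'   `CCR_Ln`, `FCR` (a ratio is `NA` when its numerator state is missing)
#' @export
respiratory_ratios <- function(s) {
  stopifnot(inherits(s, "sample_state_set"))
  if (is.finite(s$mean_OXPHOS) && s$mean_OXPHOS == 0)
    smt_stop("mean_OXPHOS is zero: SCR/CCR undefined", "sealmito_zero_denominator")
  if (!is.finite(s$mean_OXPHOS))
    smt_stop("mean_OXPHOS missing", "sealmito_zero_denominator")
  ratio <- function(num, den) if (is.finite(num)) num / den else NA_real_
  fcr <- if (is.finite(s$mean_ETS)) {
    if (s$mean_ETS == 0)
      smt_stop("mean_ETS is zero: FCR undefined", "sealmito_zero_denominator")
    s$mean_OXPHOS / s$mean_ETS
  } else NA_real_
  out <- structure(list(
    SCR_CI = ratio(s$std_CI, s$mean_OXPHOS),
    SCR_CII = ratio(s$std_CII, s$mean_OXPHOS),
    CCR_Ln = ratio(s$mean_Ln, s$mean_OXPHOS),
    FCR = fcr
  ), class = "respiratory_ratios")
  for (nm in c("CCR_Ln", "FCR")) {
    v <- out[[nm]]
    if (is.finite(v) && (v <= 0 || v > 1))
      warning(sprintf("%s = %.3f outside (0, 1]: check inputs (%s/%s)",
                      nm, v, s$animal_id, s$timepoint), call. = FALSE)
  }
  out
}

#' Paired pre/post comparison
#'
#' Two-sided paired t-test on post-minus-pre differences, matched by
#' position (pair the vectors by animal before calling). Pairs with a
#' missing member are dropped listwise. If all differences are identical
#' the t statistic is undefined and a no-variance error is raised.
#'
#' @param pre,post numeric vectors of equal length, paired by animal
#' @param alpha significance threshold (default 0.05)
#' @return list: `t`, `df`, `p`, `mean_diff` (post - pre), `n`,
#'   `significant`
#' @export
paired_compare <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post))
    smt_stop("pre and post must have equal length", "sealmito_invalid_input")
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  n <- length(pre)
  if (n < 2L)
    smt_stop("need at least 2 complete pairs", "sealmito_invalid_input")
  d <- post - pre
  sdd <- stats::sd(d)
  if (sdd == 0)
    smt_stop("all paired differences are identical: t undefined (no variance)",
             "sealmito_no_variance")
  tval <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(-abs(tval), df = n - 1L)
  list(t = tval, df = n - 1L, p = p, mean_diff = mean(d), n = n,
       significant = p < alpha)
}
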
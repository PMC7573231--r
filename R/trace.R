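#' Titration agents and target concentrations
#'
#' The eleven agents used across the four SUIT protocols, with the working
#' concentrations they are titrated to, plus the pseudo-agent `REOX` marking
#' chamber reoxygenation events.
#'
#' @format data.frame with columns `agent`, `target_conc`, `unit`
#' @export
suit_agents <- function() {
  data.frame(
    agent       = c("OC", "P", "M", "G", "S", "ADP", "CytC", "OM", "CCCP",
                    "Rot", "Mal", "REOX"),
    target_conc = c(0.5, 10, 0.5, 10, 10, 5, 10, 5, 0.5, 1, 10, NA),
    unit        = c("mM", "mM", "mM", "mM", "mM", "mM", "uM", "uM", "uM",
                    "uM", "mM", ""),
    stringsAsFactors = FALSE
  )
}

#' Construct an annotated oxygen trace
#'
#' A single respirometer chamber run: an oxygen-concentration time series plus
#' the titration events that drive the tissue through the protocol's
#' respiratory states.
#'
#' @param time_s sample times in seconds, strictly increasing
#' @param conc oxygen concentration, nmol O2 per ml, non-negative
#' @param events data.frame with columns `time_s`, `agent`, `target_conc`,
#'   `unit`; agents must be among [suit_agents()] (including `REOX`)
#' @param chamber_volume chamber volume in ml (> 0)
#' @param tissue_mass wet tissue mass in mg (> 0; typically 2-5 mg)
#' @param animal_id,timepoint,protocol_id,run_id run metadata; `timepoint` is
#'   `"pre"` or `"post"`, `protocol_id` one of `"A"`, `"B"`, `"CI"`, `"CII"`
#' @return an object of class `oxygen_trace`
#' @export
oxygen_trace <- function(time_s, conc, events = NULL, chamber_volume, tissue_mass,
                         animal_id = "unknown", timepoint = c("pre", "post"),
                         protocol_id = c("A", "B", "CI", "CII"), run_id = NULL) {
  timepoint <- match.arg(timepoint)
  protocol_id <- match.arg(protocol_id)
  time_s <- as.numeric(time_s); conc <- as.numeric(conc)
  if (length(time_s) != length(conc))
    smt_stop("time_s and conc must have equal length", "sealmito_invalid_trace")
  if (length(time_s) < 2L || any(diff(time_s) <= 0))
    smt_stop("time_s must be strictly increasing with at least 2 samples",
             "sealmito_invalid_trace")
  if (any(conc < 0) || any(!is.finite(conc)))
    smt_stop("conc must be finite and non-negative", "sealmito_invalid_trace")
  if (!is.numeric(chamber_volume) || chamber_volume <= 0)
    smt_stop("chamber_volume must be > 0", "sealmito_invalid_trace")
  if (!is.numeric(tissue_mass) || tissue_mass <= 0)
    smt_stop("tissue_mass must be > 0", "sealmito_invalid_trace")
  if (is.null(events)) {
    events <- data.frame(time_s = numeric(0), agent = character(0),
                         target_conc = numeric(0), unit = character(0),
                         stringsAsFactors = FALSE)
  }
  if (!all(c("time_s", "agent") %in% names(events)))
    smt_stop("events needs columns time_s and agent", "sealmito_invalid_trace")
  bad <- setdiff(events$agent, suit_agents()$agent)
  if (length(bad))
    smt_stop(paste0("unknown titration agent(s): ", paste(bad, collapse = ", ")),
             "sealmito_invalid_trace")
  events <- events[order(events$time_s), , drop = FALSE]
  if (!"target_conc" %in% names(events)) events$target_conc <- NA_real_
  if (!"unit" %in% names(events)) events$unit <- ""
  rownames(events) <- NULL
  structure(list(
    run_id = run_id %||% paste(animal_id, timepoint, protocol_id, sep = "_"),
    animal_id = animal_id, timepoint = timepoint, protocol_id = protocol_id,
    time_s = time_s, conc = conc,
    chamber_volume = chamber_volume, tissue_mass = tissue_mass,
    events = events
  ), class = "oxygen_trace")
}

#' @export
print.oxygen_trace <- function(x, ...) {
  cat(sprintf("<oxygen_trace %s> protocol %s, %d samples over %.0f s, %d events\n",
              x$run_id, x$protocol_id, length(x$time_s),
              diff(range(x$time_s)), nrow(x$events)))
  invisible(x)
}

#' Flag intervals where chamber oxygen leaves the working window
#'
#' Runs are performed with chamber oxygen held between `lower` and `upper`
#' (closed bounds) to avoid diffusion limitation. Excursions are reported as
#' warnings and returned as intervals; they never exclude a run.
#'
#' @param trace an [oxygen_trace()]
#' @param lower,upper working window in nmol per ml (defaults 250 and 400)
#' @return data.frame with one row per excursion: `t_start`, `t_end`,
#'   `duration_s`, `direction` ("low"/"high")
#' @export
check_oxygen_window <- function(trace, lower = 250, upper = 400) {
  stopifnot(inherits(trace, "oxygen_trace"))
  mk <- function(x, dir) {
    r <- runs_of(x)
    r$direction <- if (nrow(r)) dir else character(0)
    r
  }
  out <- rbind(mk(trace$conc < lower, "low"), mk(trace$conc > upper, "high"))
  if (nrow(out) == 0L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_s = numeric(0), direction = character(0)))
  }
  res <- data.frame(
    t_start = trace$time_s[out$start_idx],
    t_end = trace$time_s[out$end_idx],
    direction = out$direction,
    stringsAsFactors = FALSE
  )
  res$duration_s <- res$t_end - res$t_start
  res <- res[order(res$t_start), c("t_start", "t_end", "duration_s", "direction")]
  rownames(res) <- NULL
  warning(sprintf("oxygen left [%g, %g] nmol/ml in %d interval(s) (run %s)",
                  lower, upper, nrow(res), trace$run_id), call. = FALSE)
  res
}

parse_comment_meta <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)\\s*$", h))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

#' Read a trace CSV with its events sidecar
#'
#' Expects a CSV with header `time_s,o2_nmol_per_ml`, optionally preceded by a
#' `# key: value` comment block carrying run metadata (`animal_id`,
#' `timepoint`, `protocol_id`, `chamber_volume_ml`, `tissue_mass_mg`,
#' `run_id`). A JSON sidecar `<stem>.json`, if present, supplies or overrides
#' the same keys. Events are read from `<stem>_events.csv`
#' (`time_s,agent,target_conc,unit`).
#'
#' @param path path to the trace CSV
#' @param events_path optional explicit path to the events CSV
#' @return an [oxygen_trace()]
#' @export
read_trace <- function(path, events_path = NULL) {
  lines <- readLines(path)
  meta <- parse_comment_meta(lines)
  stem <- sub("\\.csv$", "", path)
  json_path <- paste0(stem, ".json")
  if (file.exists(json_path)) {
    jm <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    meta[names(jm)] <- jm
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("time_s", "o2_nmol_per_ml") %in% names(df)))
    smt_stop(paste0(path, ": expected columns time_s,o2_nmol_per_ml"),
             "sealmito_io_error")
  events_path <- events_path %||% paste0(stem, "_events.csv")
  events <- if (file.exists(events_path)) utils::read.csv(events_path) else NULL
  need <- c("animal_id", "timepoint", "protocol_id", "chamber_volume_ml",
            "tissue_mass_mg")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    smt_stop(paste0(path, ": missing metadata key(s): ",
                    paste(missing, collapse = ", ")), "sealmito_io_error")
  oxygen_trace(
    time_s = df$time_s, conc = df$o2_nmol_per_ml, events = events,
    chamber_volume = as.numeric(meta$chamber_volume_ml),
    tissue_mass = as.numeric(meta$tissue_mass_mg),
    animal_id = as.character(meta$animal_id),
    timepoint = as.character(meta$timepoint),
    protocol_id = as.character(meta$protocol_id),
    run_id = if (!is.null(meta$run_id)) as.character(meta$run_id) else NULL
  )
}

#' Write a trace (and its events sidecar) to CSV
#'
#' Inverse of [read_trace()]: metadata goes into the leading comment block,
#' events into `<stem>_events.csv`.
#'
#' @param trace an [oxygen_trace()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "oxygen_trace"))
  hdr <- c(
    paste0("# run_id: ", trace$run_id),
    paste0("# animal_id: ", trace$animal_id),
    paste0("# timepoint: ", trace$timepoint),
    paste0("# protocol_id: ", trace$protocol_id),
    paste0("# chamber_volume_ml: ", fmt_num(trace$chamber_volume, 10)),
    paste0("# tissue_mass_mg: ", fmt_num(trace$tissue_mass, 10))
  )
  body <- paste(trace$time_s, fmt_num(trace$conc, 10), sep = ",")
  writeLines(c(hdr, "time_s,o2_nmol_per_ml", body), path)
  stem <- sub("\\.csv$", "", path)
  utils::write.csv(trace$events, paste0(stem, "_events.csv"), row.names = FALSE)
  invisible(path)
}
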
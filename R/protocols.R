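STATE_LABELS <- c("baseline", "Ln", "OXPHOS", "LOmy", "ETS", "CI", "CII",
                  "cytc_check", "none")
POOLED_STATES <- c("Ln", "OXPHOS", "ETS")   # measured in several protocols
SINGLE_STATES <- c("LOmy", "CI", "CII")     # one inhibitory titration each

#' Construct a SUIT protocol step table
#'
#' A protocol is an ordered sequence of titration steps, each adding a set of
#' agents and inducing a labelled respiratory state. Step 1 is always the
#' sealed-chamber baseline (no additions). Every protocol must contain an
#' OXPHOS step and a cytochrome-c membrane-integrity step.
#'
#' @param protocol_id one of `"A"`, `"B"`, `"CI"`, `"CII"` (or a custom label)
#' @param steps data.frame with columns `step` (1..n), `agents`
#'   (semicolon-separated agent codes, empty for baseline) and `state`
#'   (one of baseline, Ln, OXPHOS, LOmy, ETS, CI, CII, cytc_check, none)
#' @return object of class `suit_protocol`
#' @export
suit_protocol <- function(protocol_id, steps) {
  stopifnot(all(c("step", "agents", "state") %in% names(steps)))
  steps <- steps[order(steps$step), , drop = FALSE]
  bad <- setdiff(steps$state, STATE_LABELS)
  if (length(bad))
    smt_stop(paste0("unknown state label(s): ", paste(bad, collapse = ", ")),
             "sealmito_invalid_protocol")
  if (steps$state[1] != "baseline")
    smt_stop("step 1 must be the baseline state", "sealmito_invalid_protocol")
  if (!"OXPHOS" %in% steps$state || !"cytc_check" %in% steps$state)
    smt_stop(paste0("protocol ", protocol_id,
                    " must contain an OXPHOS step and a CytC step"),
             "sealmito_invalid_protocol")
  agent_list <- lapply(strsplit(as.character(steps$agents), ";", fixed = TRUE),
                       function(a) a[nzchar(a)])
  known <- suit_agents()$agent
  bad <- setdiff(unlist(agent_list), known)
  if (length(bad))
    smt_stop(paste0("unknown agent(s) in protocol ", protocol_id, ": ",
                    paste(bad, collapse = ", ")), "sealmito_invalid_protocol")
  rownames(steps) <- NULL
  structure(list(protocol_id = protocol_id, steps = steps,
                 agent_list = agent_list),
            class = "suit_protocol")
}

#' @export
print.suit_protocol <- function(x, ...) {
  cat(sprintf("<suit_protocol %s> %d steps: %s\n", x$protocol_id,
              nrow(x$steps), paste(x$steps$state, collapse = " -> ")))
  invisible(x)
}

#' Load SUIT protocol definitions
#'
#' Reads the protocol step tables from a TSV with columns
#' `protocol_id`, `step`, `agents`, `state`. The default file shipped with
#' the package defines the four protocols A, B, CI and CII: A and B measure
#' leak without adenylates (Ln), OXPHOS and uncoupled ETS capacity (B
#' additionally measures oligomycin-inhibited leak, LOmy); CI and CII measure
#' OXPHOS and ETS and then isolate maximal uncoupled complex I flux
#' (malonate) or complex II flux (rotenone). Octanoylcarnitine is present
#' only in protocols A and B.
#'
#' @param path optional path to a user protocol TSV; default uses the
#'   packaged definitions
#' @return named list of [suit_protocol()] objects
#' @export
suit_protocols <- function(path = NULL) {
  path <- path %||% system.file("extdata", "suit_protocols.tsv",
                                package = "sealmito", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  df$agents[is.na(df$agents)] <- ""
  ids <- unique(df$protocol_id)
  out <- lapply(ids, function(id)
    suit_protocol(id, df[df$protocol_id == id,
                         c("step", "agents", "state"), drop = FALSE]))
  names(out) <- ids
  out
}
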
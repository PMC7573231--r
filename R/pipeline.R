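MEASURES <- c("mean_Ln", "mean_OXPHOS", "mean_ETS",
              "std_LOmy", "std_CI", "std_CII")
RATIO_NAMES <- c("SCR_CI", "SCR_CII", "CCR_Ln", "FCR")

sample_row <- function(s, source) {
  data.frame(animal_id = s$animal_id, timepoint = s$timepoint,
             mean_Ln = s$mean_Ln, mean_OXPHOS = s$mean_OXPHOS,
             mean_ETS = s$mean_ETS, std_LOmy = s$std_LOmy,
             std_CI = s$std_CI, std_CII = s$std_CII,
             cytc_pass = s$cytc_pass, excluded = s$excluded,
             n_runs = s$n_runs, source = source,
             sealmito_version = as.character(utils::packageVersion("sealmito")),
             stringsAsFactors = FALSE)
}

#' Analyze a set of chamber runs into sample and comparison tables
#'
#' Groups analyzed runs by animal and timepoint, aggregates each sample,
#' computes control ratios, and runs the paired pre/post comparison for
#' every respiratory state and ratio (animals missing either timepoint are
#' dropped listwise for that comparison).
#'
#' @param runs list of `respiro_run` objects
#' @param source provenance string recorded on every output row
#' @return list: `states` (per-sample data.frame), `ratios`, `prepost`
#'   (paired-test table), `qc` (list of excluded runs and oxygen warnings)
#' @export
respirometry_tables <- function(runs, source = "traces") {
  key <- vapply(runs, function(r) paste(r$animal_id, r$timepoint, sep = "\r"),
                character(1))
  samples <- lapply(split(runs, key), aggregate_sample)
  states <- do.call(rbind, lapply(samples, sample_row, source = source))
  ratios <- do.call(rbind, lapply(samples, function(s) {
    if (s$excluded) return(NULL)
    rr <- suppressWarnings(respiratory_ratios(s))
    data.frame(animal_id = s$animal_id, timepoint = s$timepoint,
               SCR_CI = rr$SCR_CI, SCR_CII = rr$SCR_CII,
               CCR_Ln = rr$CCR_Ln, FCR = rr$FCR, source = source,
               stringsAsFactors = FALSE)
  }))
  wide <- merge(states[!states$excluded, c("animal_id", "timepoint", MEASURES)],
                ratios[, c("animal_id", "timepoint", RATIO_NAMES)],
                by = c("animal_id", "timepoint"), all = TRUE)
  prepost <- do.call(rbind, lapply(c(MEASURES, RATIO_NAMES), function(m) {
    pre <- wide[wide$timepoint == "pre", c("animal_id", m)]
    post <- wide[wide$timepoint == "post", c("animal_id", m)]
    common <- intersect(pre$animal_id, post$animal_id)
    res <- tryCatch(
      paired_compare(pre[[m]][match(common, pre$animal_id)],
                     post[[m]][match(common, post$animal_id)]),
      sealmito_error = function(e) NULL)
    data.frame(measure = m,
               n_pairs = length(common),
               mean_pre = mean(pre[[m]][match(common, pre$animal_id)], na.rm = TRUE),
               mean_post = mean(post[[m]][match(common, post$animal_id)], na.rm = TRUE),
               t = if (is.null(res)) NA_real_ else res$t,
               p = if (is.null(res)) NA_real_ else res$p,
               significant = if (is.null(res)) NA else res$significant,
               stringsAsFactors = FALSE)
  }))
  qc <- list(
    excluded_runs = lapply(Filter(function(r) r$excluded, runs), function(r)
      list(run_id = r$run_id, reason = "cytochrome-c test failed (> 10% flux increase)")),
    oxygen_warnings = lapply(
      Filter(function(r) nrow(r$o2_excursions) > 0, runs), function(r)
        list(run_id = r$run_id, n_intervals = nrow(r$o2_excursions))),
    missing_states = lapply(
      Filter(function(r) any(r$states$qc != "ok"), runs), function(r)
        list(run_id = r$run_id,
             states = r$states$state[r$states$qc != "ok"],
             flags = r$states$qc[r$states$qc != "ok"]))
  )
  rownames(states) <- rownames(ratios) <- NULL
  list(states = states, ratios = ratios, prepost = prepost, qc = qc)
}

simulate_respirometry_runs <- function(n_animals = 6,
                                       protocols = c("A", "B", "CI", "CII"),
                                       noise_sd = 0.5, seed = 1,
                                       detector = list()) {
  maybe_seed(seed, {
    runs <- list()
    truths <- list()
    for (a in seq_len(n_animals)) {
      animal <- sprintf("seal%02d", a)
      scale_a <- exp(stats::rnorm(1, 0, 0.12))   # between-animal variation
      for (tp in c("pre", "post")) {
        scale_tp <- exp(stats::rnorm(1, 0, 0.05))  # within-animal drift
        fluxes <- default_state_fluxes() * scale_a * scale_tp
        for (pid in protocols) {
          sp <- trace_spec(protocol_id = pid, true_state_fluxes = fluxes,
                           noise_sd = noise_sd, animal_id = animal,
                           timepoint = tp,
                           seed = sample.int(.Machine$integer.max, 1))
          sim <- simulate_trace(sp)
          run <- analyze_run(sim$trace,
                             smoothing_window = detector$smoothing_window %||% 20,
                             stability_tol = detector$stability_tol %||% 0.02,
                             window = detector$window %||% 60)
          runs[[length(runs) + 1L]] <- run
          truths[[length(truths) + 1L]] <-
            cbind(run_id = sim$trace$run_id, sim$truth)
        }
      }
    }
    list(runs = runs, truth = do.call(rbind, truths))
  })
}

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      smt_stop(paste0("config not found: ", config), "sealmito_config_error")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config))
    smt_stop("config must be a list or a JSON path", "sealmito_config_error")
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages are gated on the presence of their config section:
#' `respirometry` (either `traces_dir` with trace CSVs or `synthetic` with
#' generator settings), `cohort` (either `csv` or `synthetic`), and
#' `enrichment` (either `de_tsv` + `gmt` or `synthetic`). Writes fixed-format
#' TSVs plus a machine-readable JSON QC report and a manifest into
#' `outdir`; reruns with the same config are byte-identical.
#'
#' @param config list or path to a JSON file; see the README for the schema
#' @return (invisibly) list of result tables and output paths
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  outdir <- config$outdir %||% smt_stop("config needs outdir", "sealmito_config_error")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  detector <- config$detector %||% list()
  outputs <- character(0)
  results <- list()
  qc <- list()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv_fixed(df, path)
    outputs[[length(outputs) + 1L]] <<- path
    path
  }

  leak_flux <- config$leak_flux
  if (!is.null(config$respirometry)) {
    rsp <- config$respirometry
    if (!is.null(rsp$traces_dir)) {
      files <- list.files(rsp$traces_dir, pattern = "\\.csv$", full.names = TRUE)
      files <- files[!grepl("_events\\.csv$", files)]
      if (length(files) == 0L)
        smt_stop(paste0("no trace CSVs in ", rsp$traces_dir),
                 "sealmito_config_error")
      protos <- if (!is.null(rsp$protocols_file))
        suit_protocols(rsp$protocols_file) else suit_protocols()
      runs <- lapply(files, function(f) {
        tr <- read_trace(f)
        analyze_run(tr, protocol = protos[[tr$protocol_id]],
                    smoothing_window = detector$smoothing_window %||% 20,
                    stability_tol = detector$stability_tol %||% 0.02,
                    window = detector$window %||% 60)
      })
      src <- rsp$traces_dir
    } else {
      syn <- rsp$synthetic %||% list()
      sim <- simulate_respirometry_runs(
        n_animals = syn$n_animals %||% 6,
        protocols = syn$protocols %||% c("A", "B", "CI", "CII"),
        noise_sd = syn$noise_sd %||% 0.5,
        seed = seed, detector = detector)
      runs <- sim$runs
      src <- "synthetic"
    }
    tb <- respirometry_tables(runs, source = src)
    results$states <- tb$states
    results$ratios <- tb$ratios
    results$prepost <- tb$prepost
    qc$respirometry <- tb$qc
    emit(tb$states, "states.tsv")
    emit(tb$ratios, "ratios.tsv")
    emit(tb$prepost, "prepost.tsv")
    if (is.null(leak_flux)) {
      ln <- tb$states$mean_Ln[!tb$states$excluded]
      if (any(is.finite(ln))) leak_flux <- min(ln, na.rm = TRUE)
    }
  }

  if (!is.null(config$cohort)) {
    ch <- config$cohort
    cohort <- if (!is.null(ch$csv)) read_cohort(ch$csv)
    else {
      syn <- ch$synthetic %||% list()
      simulate_cohort(n_animals = syn$n_animals %||% 4,
                      mass_pre_mean = syn$mass_pre_mean %||% 388,
                      mass_pre_sd = syn$mass_pre_sd %||% 50,
                      loss_mean = syn$loss_mean %||% 3,
                      loss_sd = syn$loss_sd %||% 0.5,
                      days_mean = syn$days_mean %||% 34,
                      days_sd = syn$days_sd %||% 3,
                      seed = seed)
    }
    budget <- energy_budget(cohort, leak_flux = leak_flux %||% 13)
    budget$source <- if (!is.null(ch$csv)) ch$csv else "synthetic"
    results$energy_budget <- budget
    emit(budget, "energy_budget.tsv")
  }

  if (!is.null(config$enrichment)) {
    en <- config$enrichment
    if (!is.null(en$de_tsv)) {
      de <- read_de_table(en$de_tsv)
      sets <- read_gmt(en$gmt %||% smt_stop("enrichment needs gmt",
                                            "sealmito_config_error"))
      src <- en$de_tsv
    } else {
      syn <- en$synthetic %||% list()
      de <- simulate_de_table(n_genes = syn$n_genes %||% 2000,
                              frac_up = syn$frac_up %||% 0.05,
                              frac_down = syn$frac_down %||% 0.05,
                              effect_lfc = syn$effect_lfc %||% 2, seed = seed)
      sets <- maybe_seed(seed + 1L, synthetic_gene_sets(de$gene_id))
      src <- "synthetic"
    }
    called <- filter_de(de, padj_cut = en$padj_cut %||% 0.05,
                        lfc_cut = en$lfc_cut %||% 1)
    bg <- de$gene_id
    for (dir in intersect(c("up", "down"), en$direction %||% c("up", "down"))) {
      res <- enrich(called[[dir]], sets, background = bg,
                    n_permutations = en$n_permutations %||% 200,
                    seed = seed + 2L)
      res$direction <- dir
      res$source <- src
      results[[paste0("enrichment_", dir)]] <- res
      emit(res, paste0("enrichment_", dir, ".tsv"))
    }
  }

  qc_path <- file.path(outdir, "qc.json")
  jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  manifest <- list(
    sealmito_version = as.character(utils::packageVersion("sealmito")),
    seed = seed,
    outputs = basename(unlist(c(outputs, qc_path)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(outputs = unlist(outputs), qc = qc)))
}

# small random gene-set collection over a gene universe, for synthetic runs
synthetic_gene_sets <- function(genes, n_sets = 12, set_size_range = c(20, 80)) {
  sets <- lapply(seq_len(n_sets), function(i) {
    sz <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    sample(genes, min(sz, length(genes)))
  })
  names(sets) <- sprintf("pathway_%02d", seq_len(n_sets))
  sets
}
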
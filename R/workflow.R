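## Configuration, file formats and the end-to-end pipeline. All tabular
## I/O is plain CSV with fixed headers; protocols, ground truth and the
## final report are JSON.

TRACE_COLUMNS <- c("cell_id", "time_s", "channel", "intensity")
TRACE_CHANNELS <- c("donor_em", "acceptor_em", "acceptor_direct")

#' Write recordings to the long-format trace CSV
#'
#' Columns: `cell_id`, `time_s`, `channel` (one of `donor_em`,
#' `acceptor_em`, `acceptor_direct`), `intensity`.
#'
#' @param recordings list of `raw_recording`s.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(recordings, path) {
  rows <- lapply(recordings, function(rec) {
    chans <- c("donor_em", "acceptor_em",
               if (!is.null(rec$acceptor_direct)) "acceptor_direct")
    do.call(rbind, lapply(chans, function(ch)
      data.frame(cell_id = rec$cell_id, time_s = rec$time, channel = ch,
                 intensity = rec[[ch]], stringsAsFactors = FALSE)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read the long-format trace CSV into raw recordings
#'
#' @param path CSV path (see [write_trace_csv()] for the schema).
#' @param protocol the `application_protocol` shared by all cells.
#' @return list of `raw_recording`s.
#' @export
read_trace_csv <- function(path, protocol) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("malformed trace CSV '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$channel), TRACE_CHANNELS)
  if (length(bad))
    stop("malformed trace CSV '", path, "': unknown channel(s) ",
         paste(bad, collapse = ", "))
  if (!is.numeric(df$time_s) || !is.numeric(df$intensity))
    stop("malformed trace CSV '", path,
         "': time_s and intensity must be numeric")
  lapply(split(df, df$cell_id), function(cd) {
    chans <- split(cd, cd$channel)
    time <- sort(unique(cd$time_s))
    getch <- function(name) {
      if (is.null(chans[[name]])) return(NULL)
      x <- chans[[name]][order(chans[[name]]$time_s), ]
      if (length(x$intensity) != length(time))
        stop("malformed trace CSV '", path, "': channel lengths differ ",
             "for cell ", cd$cell_id[1])
      x$intensity
    }
    structure(list(cell_id = cd$cell_id[1], time = time,
                   donor_em = getch("donor_em"),
                   acceptor_em = getch("acceptor_em"),
                   acceptor_direct = getch("acceptor_direct"),
                   protocol = protocol, truth = NULL, corrected = FALSE),
              class = "raw_recording")
  })
}

#' Write / read an application protocol as JSON
#' @param protocol an `application_protocol`.
#' @param path file path.
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(list(events = protocol$events,
                            total_duration = protocol$total_duration,
                            sampling_rate = protocol$sampling_rate),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  application_protocol(as.data.frame(x$events), x$total_duration,
                       x$sampling_rate)
}

## ground-truth efficacy sets for the named scenarios; the values mirror
## the amplitude tiers the recordings are designed to exhibit (full
## agonist, two strong partials, two weak partials, one very weak, one
## near-silent agonist)
scenario_efficacies <- function(scenario) {
  base <- c(ACh = 1.0, Metha = 0.6, Fur = 0.6, Are = 0.2, Guva = 0.2,
            Pilo = 0.08, Mda = 0.03)
  switch(scenario,
    concordant = list(Gq_activation = base, arrestin3_recruitment = base),
    arrestin_reversal = list(
      Gq_activation = base,
      ## Pilo and Are swap tiers in the arrestin arm: Pilo joins Guva's
      ## tier, Are drops to Pilo's — exactly one resolvable reversal
      arrestin3_recruitment = c(ACh = 1.0, Metha = 0.6, Fur = 0.6,
                                Pilo = 0.2, Guva = 0.2, Are = 0.08,
                                Mda = 0.03)),
    null = {
      flat <- stats::setNames(rep(1, 7), names(base))
      list(Gq_activation = flat, arrestin3_recruitment = flat)
    },
    stop("unknown scenario name: ", scenario))
}

#' Simulate a complete named input scenario
#'
#' Writes everything the pipeline consumes for a two-pathway experiment:
#' per-pathway trace CSVs, the shared protocol JSON, per-pathway
#' operational concentration-response CSVs with a Ki table, a ground-truth
#' sidecar JSON, and a ready-to-run pipeline config.
#'
#' Scenarios: `"concordant"` (identical efficacy tiers in both pathways),
#' `"arrestin_reversal"` (one agonist pair swaps tiers between pathways,
#' the canonical bias pattern), `"null"` (all agonists equi-efficacious).
#'
#' @param scenario scenario name.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @param n_cells cells per pathway.
#' @param noise_sd channel noise SD in counts (default 2 = 2\% of the
#'   FRET modulation depth).
#' @return the directory, invisibly; `config.json` inside is runnable with
#'   [run_pipeline()].
#' @export
simulate_scenario <- function(scenario, seed = 1L, dir = tempfile("scenario"),
                              n_cells = 20, noise_sd = 2) {
  eff <- scenario_efficacies(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  protocol <- standard_protocol(names(eff[[1]]))
  write_protocol_json(protocol, file.path(dir, "protocol.json"))
  truth_out <- list(scenario = scenario, seed = seed,
                    efficacies = lapply(eff, as.list))
  coeff_truth <- NULL
  ki <- c(ACh = 2e-9, Metha = 4e-9, Fur = 4e-9, Are = 2e-8, Guva = 8e-8,
          Pilo = 8e-10, Mda = 1e-4)
  tau <- list()
  for (i in seq_along(eff)) {
    pw <- names(eff)[i]
    truth <- fret_ground_truth(eff[[pw]], noise_sd = noise_sd,
                               cell_scale_sd = 0.2,
                               seed = seed + 1000L * i)
    coeff_truth <- truth
    recs <- generate_fret_cohort(protocol, truth, n_cells = n_cells)
    write_trace_csv(recs, file.path(dir, paste0("traces_", pw, ".csv")))
    ## operational arm: tau proportional to the efficacy tier over 3 log
    ## units, same reversal structure as the amplitudes
    tau_pw <- stats::setNames(10^(3 * (eff[[pw]] - 0.03) / 0.97 - 1),
                              names(eff[[pw]]))
    tau[[pw]] <- tau_pw
    op_truth <- operational_ground_truth(
      tau = tau_pw, Ki = ki, n = 1.2, Emax = 1,
      concentration_grid = 10^seq(-10, -3, length.out = 8),
      noise_sd = 0.02, replicates = 3, seed = seed + 2000L * i)
    cr <- generate_concentration_response(op_truth)
    utils::write.csv(cr, file.path(dir, paste0("conc_response_", pw,
                                               ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(agonist = names(ki), ki_M = unname(ki)),
                   file.path(dir, "ki_table.csv"), row.names = FALSE)
  truth_out$tau <- lapply(tau, as.list)
  truth_out$ki <- as.list(ki)
  truth_out$coefficients <- list(
    background_donor = coeff_truth$background[["donor"]],
    background_acceptor = coeff_truth$background[["acceptor"]],
    bleedthrough_frac = coeff_truth$bleedthrough_frac,
    false_excitation_frac = coeff_truth$false_excitation_frac)
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- list(
    protocol = "protocol.json",
    pathways = stats::setNames(lapply(names(eff), function(pw)
      list(traces = paste0("traces_", pw, ".csv"),
           conc_response = paste0("conc_response_", pw, ".csv"),
           Emax = 1)), names(eff)),
    ki_table = "ki_table.csv",
    coefficients = truth_out$coefficients,
    reference_agonist = "ACh",
    tie_rule = "tukey",
    seed = seed)
  jsonlite::write_json(config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load and validate a pipeline configuration
#'
#' @param path path to a `config.json` (relative file references are
#'   resolved against its directory), or a config list plus `base_dir`.
#' @param base_dir base directory for relative paths.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(path, base_dir = dirname(path)) {
  config <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else path
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  config$protocol <- resolve(config$protocol)
  if (!file.exists(config$protocol))
    stop("config error: protocol file not found: ", config$protocol)
  if (is.null(config$pathways) || !length(config$pathways))
    stop("config error: no pathways defined")
  if (is.null(config$reference_agonist)) config$reference_agonist <- "ACh"
  if (is.null(config$tie_rule)) config$tie_rule <- "tukey"
  protocol <- read_protocol_json(config$protocol)
  if (!config$reference_agonist %in% protocol$events$agonist_id)
    stop("config error: reference agonist '", config$reference_agonist,
         "' does not appear in the protocol")
  for (pw in names(config$pathways)) {
    config$pathways[[pw]]$traces <- resolve(config$pathways[[pw]]$traces)
    if (!file.exists(config$pathways[[pw]]$traces))
      stop("config error: trace file not found for pathway ", pw)
    if (!is.null(config$pathways[[pw]]$conc_response))
      config$pathways[[pw]]$conc_response <-
        resolve(config$pathways[[pw]]$conc_response)
  }
  if (!is.null(config$ki_table)) config$ki_table <- resolve(config$ki_table)
  config$.protocol <- protocol
  class(config) <- "pipeline_config"
  config
}

#' Run the full bias-analysis pipeline
#'
#' For every configured pathway: read and correct the single-cell traces,
#' extract and normalize amplitudes, aggregate efficacies, compute the
#' statistical rank order; optionally fit the operational model on the
#' pathway's concentration-response data (shared n, fixed Ki) and compute
#' delta log10(tau/Ki) relative to the reference agonist. All pathway pairs
#' are then compared; every discordant agonist pair becomes a bias call.
#' Deterministic given the config; intermediates are written with input
#' hashes and a config snapshot when `output_dir` is set.
#'
#' @param config a `pipeline_config` (or a path to one).
#' @param output_dir optional directory for the report JSON and CSV tables.
#' @param log emit per-stage record counts via `message()`.
#' @return `bias_report` list: `efficacy_tables`, `rank_orders`,
#'   `pairwise_stats`, `operational` (fits + bias factors, if configured),
#'   `comparisons`, `bias_calls`, `provenance`.
#' @export
run_pipeline <- function(config, output_dir = NULL, log = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  protocol <- config$.protocol
  coeff <- do.call(correction_coefficients,
                   config$coefficients[c("background_donor",
                                         "background_acceptor",
                                         "bleedthrough_frac",
                                         "false_excitation_frac")])
  note <- function(...) if (log) message(sprintf(...))
  ki <- NULL
  if (!is.null(config$ki_table)) {
    kt <- utils::read.csv(config$ki_table, stringsAsFactors = FALSE)
    ki <- stats::setNames(kt$ki_M, kt$agonist)
  }
  efficacy_tables <- list(); rank_orders <- list()
  pairwise_stats <- list(); operational <- list(); amplitudes <- list()
  for (pw in names(config$pathways)) {
    recs <- read_trace_csv(config$pathways[[pw]]$traces, protocol)
    note("pathway %s: %d cells read", pw, length(recs))
    res <- process_fret_cohort(recs, coeff,
                               reference_agonist = config$reference_agonist,
                               pathway_id = pw)
    note("pathway %s: %d amplitude records", pw, nrow(res$amplitudes))
    amplitudes[[pw]] <- res$amplitudes
    efficacy_tables[[pw]] <- res$efficacies
    rank_orders[[pw]] <- rank_order(res$amplitudes,
                                    tie_rule = config$tie_rule)
    pairwise_stats[[pw]] <- anova_tukey(
      split(res$amplitudes$normalized_amplitude,
            res$amplitudes$agonist_id))
    cr_path <- config$pathways[[pw]]$conc_response
    if (!is.null(cr_path) && !is.null(ki)) {
      cr <- utils::read.csv(cr_path, stringsAsFactors = FALSE)
      Emax <- config$pathways[[pw]]$Emax
      if (is.null(Emax)) Emax <- 1
      ds <- operational_dataset(cr, ki, Emax = Emax, pathway_id = pw)
      fit <- fit_operational_global(ds)
      operational[[pw]] <- list(
        fit = fit,
        bias_factors = compute_bias_factors(fit,
                                            config$reference_agonist))
      note("pathway %s: operational fit, shared n = %.3f", pw, fit$n)
    }
  }
  pws <- names(config$pathways)
  comparisons <- list(); bias_calls <- list()
  if (length(pws) >= 2) {
    for (pair in utils::combn(pws, 2, simplify = FALSE)) {
      cmp <- compare_pathways(rank_orders[[pair[1]]],
                              rank_orders[[pair[2]]],
                              efficacy_tables[[pair[1]]],
                              efficacy_tables[[pair[2]]],
                              pathway_a = pair[1], pathway_b = pair[2])
      comparisons[[paste(pair, collapse = "_vs_")]] <- cmp
      if (nrow(cmp$discordant_pairs)) {
        calls <- cmp$discordant_pairs
        calls$pathway_a <- pair[1]; calls$pathway_b <- pair[2]
        bias_calls[[length(bias_calls) + 1L]] <- calls
      }
    }
  }
  bias_calls <- if (length(bias_calls)) do.call(rbind, bias_calls) else
    data.frame(agonist1 = character(0), agonist2 = character(0),
               order_a = character(0), order_b = character(0),
               pathway_a = character(0), pathway_b = character(0),
               stringsAsFactors = FALSE)
  inputs <- c(config$protocol,
              vapply(config$pathways, `[[`, character(1), "traces"))
  provenance <- list(
    package_version = as.character(utils::packageVersion("ligandbias")),
    input_hashes = as.list(tools::md5sum(inputs)),
    config = unclass(config)[setdiff(names(config), ".protocol")])
  report <- structure(list(efficacy_tables = efficacy_tables,
                           rank_orders = rank_orders,
                           pairwise_stats = pairwise_stats,
                           operational = operational,
                           comparisons = comparisons,
                           bias_calls = bias_calls,
                           provenance = provenance),
                      class = "bias_report")
  if (!is.null(output_dir)) write_bias_report(report, output_dir,
                                              amplitudes)
  report
}

## serializable view of the report (S3 objects flattened to plain lists)
report_as_list <- function(report) {
  list(
    efficacy_tables = lapply(report$efficacy_tables, as.data.frame),
    rank_orders = lapply(report$rank_orders, function(r)
      list(ranking = r$ranking, table = r$table)),
    pairwise_stats = lapply(report$pairwise_stats, function(a)
      list(F = a$F, df_between = a$df_between, df_within = a$df_within,
           p_value = a$p_value, pairwise = a$pairwise)),
    operational = lapply(report$operational, function(o)
      list(n = o$fit$n, se_n = o$fit$se_n, Emax = o$fit$Emax,
           sse = o$fit$sse, agonists = o$fit$agonists,
           bias_factors = o$bias_factors)),
    comparisons = lapply(report$comparisons, function(cmp)
      list(pathway_a = cmp$pathway_a, pathway_b = cmp$pathway_b,
           discordant_pairs = cmp$discordant_pairs,
           concordance = cmp$concordance,
           n_pairs_compared = cmp$n_pairs_compared,
           table_2d = cmp$table_2d)),
    bias_calls = report$bias_calls,
    provenance = report$provenance)
}

#' Write a bias report to disk
#'
#' `report.json` plus CSV renditions of the efficacy tables and bias calls.
#'
#' @param report a `bias_report`.
#' @param output_dir directory (created if needed).
#' @param amplitudes optional named list of per-pathway amplitude tables to
#'   write alongside.
#' @export
write_bias_report <- function(report, output_dir, amplitudes = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_as_list(report),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  eff <- do.call(rbind, report$efficacy_tables)
  utils::write.csv(eff, file.path(output_dir, "efficacy_tables.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bias_calls,
                   file.path(output_dir, "bias_calls.csv"),
                   row.names = FALSE)
  if (!is.null(amplitudes))
    for (pw in names(amplitudes))
      utils::write.csv(amplitudes[[pw]],
                       file.path(output_dir,
                                 paste0("amplitudes_", pw, ".csv")),
                       row.names = FALSE)
  invisible(output_dir)
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Bias report\n")
  for (pw in names(x$rank_orders))
    cat(sprintf("  %s: %s\n", pw, x$rank_orders[[pw]]$ranking))
  cat(sprintf("  bias calls: %d\n", nrow(x$bias_calls)))
  if (nrow(x$bias_calls)) print(x$bias_calls)
  invisible(x)
}
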
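#' Compute per-cycle BRET ratios
#'
#' BRET ratio = acceptor (YFP, 520-700 nm) counts divided by luciferase
#' (Nluc, 415-485 nm) counts for every cycle.
#'
#' @param plate `bret_plate` data.frame (columns `well_id`, `cycle_index`,
#'   `cycle_time_s`, `phase`, `yfp`, `nluc`).
#' @return the plate with a `ratio` column.
#' @export
compute_bret_ratio <- function(plate) {
  stopifnot(all(c("well_id", "cycle_index", "yfp", "nluc") %in%
                  names(plate)))
  bad <- which(plate$nluc <= 0)
  if (length(bad))
    stop(sprintf("non-positive Nluc signal in well %s, cycle %d",
                 plate$well_id[bad[1]], plate$cycle_index[bad[1]]))
  plate$ratio <- plate$yfp / plate$nluc
  plate
}

#' Fit an ordinary least-squares line to each measurement phase
#'
#' @param cycle_time cycle times (s).
#' @param ratio per-cycle BRET ratios.
#' @param phase phase labels, one of `baseline`, `agonist`, `saturation`.
#' @return data.frame (`phase`, `intercept`, `slope`, `t_first`, `t_last`),
#'   phases in protocol order.
#' @export
fit_phase_lines <- function(cycle_time, ratio, phase) {
  order_ref <- c("baseline", "agonist", "saturation")
  phases <- intersect(order_ref, unique(phase))
  out <- do.call(rbind, lapply(phases, function(ph) {
    idx <- phase == ph
    if (sum(idx) < 2)
      stop(sprintf("phase '%s' has fewer than 2 cycles", ph))
    t <- cycle_time[idx]; y <- ratio[idx]
    co <- stats::lm.fit(cbind(1, t), y)$coefficients
    data.frame(phase = ph, intercept = unname(co[1]), slope = unname(co[2]),
               t_first = min(t), t_last = max(t), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Phase-boundary signal changes of one well
#'
#' The agonist-induced change is the distance between the baseline-phase
#' line evaluated at its last cycle time and the agonist-phase line at its
#' first cycle time; the additional change (saturating reference agonist) is
#' the analogous distance between the agonist and saturation phases. The
#' maximum change is their sum, and the agonist change is normalized to it.
#'
#' @param lines data.frame from [fit_phase_lines()] with all three phases.
#' @param well_id identifier carried into the result.
#' @return one-row data.frame of class entries: `well_id`, `agonist_change`,
#'   `additional_change`, `max_change`, `normalized_agonist_change` (NA with
#'   `flagged = TRUE` when `max_change <= 0`), plus per-phase intercepts and
#'   slopes.
#' @export
compute_phase_changes <- function(lines, well_id = "well") {
  need <- c("baseline", "agonist", "saturation")
  if (!all(need %in% lines$phase))
    stop("need fitted lines for baseline, agonist and saturation phases")
  ln <- function(ph) lines[lines$phase == ph, ]
  eval_line <- function(l, t) l$intercept + l$slope * t
  b <- ln("baseline"); a <- ln("agonist"); s <- ln("saturation")
  agonist_change <- eval_line(a, a$t_first) - eval_line(b, b$t_last)
  additional_change <- eval_line(s, s$t_first) - eval_line(a, a$t_last)
  max_change <- agonist_change + additional_change
  ## epsilon guards against QR round-off on exactly degenerate plates
  flagged <- max_change <= 1e-12 * max(1, abs(b$intercept))
  data.frame(well_id = well_id,
             agonist_change = agonist_change,
             additional_change = additional_change,
             max_change = max_change,
             normalized_agonist_change =
               if (flagged) NA_real_ else agonist_change / max_change,
             flagged = flagged,
             baseline_intercept = b$intercept, baseline_slope = b$slope,
             agonist_intercept = a$intercept, agonist_slope = a$slope,
             saturation_intercept = s$intercept, saturation_slope = s$slope,
             stringsAsFactors = FALSE)
}

#' Analyze a whole BRET plate
#'
#' Computes ratios, fits the per-phase lines for every well and returns the
#' per-well phase-change table.
#'
#' @param plate `bret_plate` data.frame.
#' @return data.frame of per-well results (see [compute_phase_changes()]),
#'   with the wells' agonist annotations.
#' @export
analyze_bret_plate <- function(plate) {
  plate <- compute_bret_ratio(plate)
  out <- do.call(rbind, lapply(split(plate, plate$well_id), function(w) {
    lines <- fit_phase_lines(w$cycle_time_s, w$ratio, w$phase)
    res <- compute_phase_changes(lines, well_id = w$well_id[1])
    res$agonist <- w$agonist[1]
    res$conc_M <- w$conc_M[1]
    res
  }))
  rownames(out) <- NULL
  out
}
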
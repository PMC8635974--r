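#' Spectral correction coefficients
#'
#' Background, bleed-through (donor emission leaking into the acceptor
#' detection channel) and false excitation (direct excitation of the
#' acceptor at the donor wavelength) used to correct raw two-channel
#' recordings.
#'
#' @param background_donor,background_acceptor additive channel backgrounds
#'   (intensity counts, >= 0).
#' @param bleedthrough_frac,false_excitation_frac cross-talk fractions in
#'   `[0, 1)`.
#' @export
correction_coefficients <- function(background_donor = 0,
                                    background_acceptor = 0,
                                    bleedthrough_frac = 0,
                                    false_excitation_frac = 0) {
  stopifnot(background_donor >= 0, background_acceptor >= 0,
            bleedthrough_frac >= 0, bleedthrough_frac < 1,
            false_excitation_frac >= 0, false_excitation_frac < 1)
  structure(list(background_donor = background_donor,
                 background_acceptor = background_acceptor,
                 bleedthrough_frac = bleedthrough_frac,
                 false_excitation_frac = false_excitation_frac),
            class = "correction_coefficients")
}

#' Coefficients matching a simulator ground truth
#'
#' Convenience accessor returning the `correction_coefficients` that exactly
#' undo the cross-talk of a `fret_ground_truth`.
#'
#' @param truth a `fret_ground_truth`.
#' @export
true_coefficients <- function(truth) {
  correction_coefficients(
    background_donor = truth$background[["donor"]],
    background_acceptor = truth$background[["acceptor"]],
    bleedthrough_frac = truth$bleedthrough_frac,
    false_excitation_frac = truth$false_excitation_frac)
}

#' Correct raw channels for background, bleed-through and false excitation
#'
#' Applies, in this fixed order: background subtraction per channel, then
#' removal of donor bleed-through from the acceptor channel, then removal of
#' the directly excited acceptor contribution:
#' `donor' = donor - bg_d`;
#' `acceptor' = (acceptor - bg_a) - bt * donor' - fx * (direct - bg_a)`.
#'
#' @param rec a `raw_recording`.
#' @param coeff a `correction_coefficients`.
#' @return the recording with corrected channels and `corrected = TRUE`.
#' @export
correct_channels <- function(rec, coeff) {
  stopifnot(inherits(rec, "raw_recording"),
            inherits(coeff, "correction_coefficients"))
  if (coeff$false_excitation_frac > 0 && is.null(rec$acceptor_direct))
    stop("acceptor_direct channel required when false_excitation_frac > 0")
  donor <- rec$donor_em - coeff$background_donor
  acceptor <- rec$acceptor_em - coeff$background_acceptor -
    coeff$bleedthrough_frac * donor
  if (coeff$false_excitation_frac > 0)
    acceptor <- acceptor - coeff$false_excitation_frac *
      (rec$acceptor_direct - coeff$background_acceptor)
  if (mean(donor < 0) > 0.10)
    stop("correction-coefficient error: corrected donor negative in >10% ",
         "of samples; background_donor likely too large")
  rec$donor_em <- donor
  rec$acceptor_em <- acceptor
  rec$corrected <- TRUE
  rec
}

#' Compute the FRET ratio trace
#'
#' Ratio of corrected acceptor over corrected donor emission per sample.
#' Samples with non-positive donor are masked (NA) with a warning; more than
#' 10\% masked samples is an error.
#'
#' @param rec a corrected `raw_recording`.
#' @return object of class `ratio_trace` with fields `cell_id`, `time`,
#'   `ratio`, `protocol`, `baseline_corrected`.
#' @export
compute_ratio <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!isTRUE(rec$corrected))
    stop("channels must be corrected before computing the ratio ",
         "(call correct_channels(); use zero coefficients for none)")
  bad <- rec$donor_em <= 0
  if (mean(bad) > 0.10)
    stop(sprintf("cell %s: %.1f%% of samples have non-positive donor",
                 rec$cell_id, 100 * mean(bad)))
  ratio <- rec$acceptor_em / rec$donor_em
  if (any(bad)) {
    ratio[bad] <- NA_real_
    warning(sprintf("cell %s: %d sample(s) masked (non-positive donor)",
                    rec$cell_id, sum(bad)))
  }
  structure(list(cell_id = rec$cell_id, time = rec$time, ratio = ratio,
                 protocol = rec$protocol, baseline_corrected = FALSE,
                 truth = rec$truth),
            class = "ratio_trace")
}

## Samples unaffected by any application: outside every event and outside a
## washout margin after each event (latent off-kinetics decay there).
buffer_mask <- function(time, protocol, washout_margin = 20) {
  in_event <- rep(FALSE, length(time))
  for (i in seq_len(nrow(protocol$events))) {
    ev <- protocol$events[i, ]
    in_event <- in_event |
      (time >= ev$t_start & time < ev$t_end + washout_margin)
  }
  !in_event
}

## mono-exponential + constant least squares: y ~ a * exp(-k * t) + c with k
## profiled over a sign-symmetric grid, then polished by nlminb. For each
## candidate k the (a, c) subproblem is linear.
fit_exp_const <- function(t, y) {
  ## work on unit-scaled time so the rate search is scale-free and
  ## exp() cannot overflow (|k'| capped at 20 on the unit interval)
  t0 <- min(t); span <- max(diff(range(t)), .Machine$double.eps)
  ts <- (t - t0) / span
  profile_sse <- function(k) {
    fit <- stats::lm.fit(cbind(exp(-k * ts), 1), y)
    sum(fit$residuals^2)
  }
  kgrid <- c(-10^seq(-3, 1.2, length.out = 10),
             10^seq(-3, 1.2, length.out = 10))
  sse <- vapply(kgrid, profile_sse, numeric(1))
  k0 <- kgrid[which.min(sse)]
  opt <- stats::nlminb(k0, profile_sse, lower = -20, upper = 20)
  k <- opt$par
  co <- stats::lm.fit(cbind(exp(-k * ts), 1), y)$coefficients
  list(a = unname(co[1]), k = k / span, c = unname(co[2]),
       predict = function(tt) co[1] * exp(-k * (tt - t0) / span) + co[2])
}

#' Correct a ratio trace for photobleaching drift
#'
#' Fits a mono-exponential-plus-constant drift model to the buffer-only
#' (no-agonist) samples of the trace and divides it out, anchoring the trace
#' at its first time point (bleaching is multiplicative on intensities, so
#' the drift is removed by division, not subtraction). With fewer than two
#' buffer segments a straight line is used instead, with a warning.
#'
#' @param trace a `ratio_trace`.
#' @param protocol optional `application_protocol` (defaults to the one
#'   stored on the trace).
#' @param washout_margin seconds after each application end still excluded
#'   from the buffer-only set, so that incomplete washout does not bias the
#'   drift fit.
#' @return the baseline-corrected `ratio_trace`.
#' @export
baseline_correct <- function(trace, protocol = trace$protocol,
                             washout_margin = 20) {
  stopifnot(inherits(trace, "ratio_trace"))
  ok <- !is.na(trace$ratio)
  buf <- buffer_mask(trace$time, protocol, washout_margin) & ok
  if (sum(buf) < 4) stop("too few buffer-only samples for baseline fit")
  t <- trace$time[buf]; y <- trace$ratio[buf]
  n_seg <- sum(diff(c(FALSE, buf)) == 1)
  lin <- stats::lm.fit(cbind(1, t), y)
  rel_drift <- abs(lin$coefficients[2]) * diff(range(trace$time)) /
    max(abs(mean(y)), .Machine$double.eps)
  t0 <- trace$time[1]
  if (rel_drift < 2e-3) {
    ## flat baseline: drift below 0.2% of the trace level over the whole
    ## recording is indistinguishable from washout residuals and far below
    ## any bleaching worth correcting; leave the trace untouched
    trace$baseline_corrected <- TRUE
    return(trace)
  }
  if (n_seg < 2) {
    warning("fewer than 2 buffer segments; falling back to linear drift")
    drift <- function(tt) lin$coefficients[1] + lin$coefficients[2] * tt
  } else {
    fit <- fit_exp_const(t, y)
    drift <- fit$predict
  }
  trace$ratio <- trace$ratio * drift(t0) / drift(trace$time)
  trace$baseline_corrected <- TRUE
  trace
}

#' Extract the response amplitude of one application event
#'
#' Amplitude is the difference between the mean ratio over the 5 s
#' immediately before agonist withdrawal and the mean over the 5 s
#' immediately before agonist application. Windows are half-open,
#' left-closed: `[t_end - w, t_end)` and `[t_start - w, t_start)`; at 2 Hz
#' each holds 10 samples. Windows are anchored to the protocol event times,
#' not to detected response onsets.
#'
#' @param trace a `ratio_trace`.
#' @param event one-row data.frame (a row of `protocol$events`).
#' @param window window length in seconds (default 5).
#' @return one-row data.frame: `cell_id`, `agonist_id`, `concentration`,
#'   `raw_amplitude`, `window_pre_start`, `window_pre_end`,
#'   `window_post_start`, `window_post_end`.
#' @export
extract_amplitude <- function(trace, event, window = 5) {
  stopifnot(inherits(trace, "ratio_trace"))
  win_mean <- function(from, to, what) {
    idx <- trace$time >= from & trace$time < to
    if (!any(idx))
      stop(sprintf("empty %s window for event %s @ [%g, %g] s",
                   what, event$agonist_id, event$t_start, event$t_end))
    v <- trace$ratio[idx]
    if (mean(is.na(v)) > 0.10)
      stop(sprintf(">10%% masked samples in %s window for event %s",
                   what, event$agonist_id))
    mean(v, na.rm = TRUE)
  }
  pre <- win_mean(event$t_start - window, event$t_start, "pre")
  post <- win_mean(event$t_end - window, event$t_end, "post")
  data.frame(cell_id = trace$cell_id, agonist_id = event$agonist_id,
             concentration = event$concentration,
             raw_amplitude = post - pre,
             window_pre_start = event$t_start - window,
             window_pre_end = event$t_start,
             window_post_start = event$t_end - window,
             window_post_end = event$t_end,
             stringsAsFactors = FALSE)
}

#' Extract amplitudes for every protocol event of a trace
#'
#' @inheritParams extract_amplitude
#' @return data.frame of amplitude records, one row per event.
#' @export
extract_amplitudes <- function(trace, window = 5) {
  ev <- trace$protocol$events
  do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
    extract_amplitude(trace, ev[i, ], window = window)))
}

#' Normalize amplitudes to each cell's reference-agonist amplitude
#'
#' Divides every raw amplitude by the same cell's reference amplitude so the
#' reference application itself normalizes to 1. Cells whose reference
#' amplitude is missing or non-positive are excluded; their ids and reasons
#' are attached as `attr(, "excluded")`.
#'
#' @param records amplitude data.frame from [extract_amplitudes()] (rows
#'   from many cells may be concatenated).
#' @param reference_agonist id of the reference (default "ACh").
#' @param reference_policy which reference application defines the
#'   denominator when the reference was applied more than once per cell:
#'   `"first"` (default) or `"max"`.
#' @return the records with a `normalized_amplitude` column.
#' @export
normalize_to_reference <- function(records, reference_agonist = "ACh",
                                   reference_policy = c("first", "max")) {
  reference_policy <- match.arg(reference_policy)
  stopifnot(is.data.frame(records),
            all(c("cell_id", "agonist_id", "raw_amplitude") %in%
                  names(records)))
  excluded <- character(0)
  out <- lapply(split(records, records$cell_id), function(df) {
    ref <- df$raw_amplitude[df$agonist_id == reference_agonist]
    if (!length(ref)) {
      excluded[df$cell_id[1]] <<- "no reference application"
      return(NULL)
    }
    ref_amp <- switch(reference_policy, first = ref[1], max = max(ref))
    if (!is.finite(ref_amp) || ref_amp <= 0) {
      excluded[df$cell_id[1]] <<- sprintf(
        "non-positive reference amplitude (%.3g)", ref_amp)
      return(NULL)
    }
    df$normalized_amplitude <- df$raw_amplitude / ref_amp
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(excluded))
    message(length(excluded), " cell(s) excluded from normalization")
  attr(res, "excluded") <- excluded
  res
}

#' Aggregate normalized amplitudes into a per-agonist efficacy table
#'
#' @param records normalized amplitude data.frame.
#' @param pathway_id label of the effector pathway these recordings probe.
#' @param value column to aggregate (default `normalized_amplitude`).
#' @return data.frame of class `efficacy_table`: `pathway`, `agonist`,
#'   `mean`, `sd`, `n`.
#' @export
aggregate_efficacies <- function(records, pathway_id = "pathway",
                                 value = "normalized_amplitude") {
  stopifnot(value %in% names(records))
  sp <- split(records[[value]], records$agonist_id)
  out <- data.frame(pathway = pathway_id, agonist = names(sp),
                    mean = vapply(sp, mean, numeric(1)),
                    sd = vapply(sp, stats::sd, numeric(1)),
                    n = vapply(sp, length, integer(1)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("efficacy_table", "data.frame")
  out
}

#' Estimate correction coefficients from calibration recordings
#'
#' Plumbing for instruments whose cross-talk coefficients are unknown:
#' estimates bleed-through from a donor-only recording (acceptor channel
#' signal must then be pure bleed-through) and false excitation from an
#' acceptor-only recording.
#'
#' @param donor_only `raw_recording` of a cell expressing only the donor.
#' @param acceptor_only `raw_recording` of a cell expressing only the
#'   acceptor (requires its `acceptor_direct` channel).
#' @param background_donor,background_acceptor backgrounds measured from
#'   blank regions, subtracted before ratios are formed.
#' @return `correction_coefficients`
#' @export
estimate_correction_coefficients <- function(donor_only, acceptor_only,
                                             background_donor = 0,
                                             background_acceptor = 0) {
  d <- donor_only$donor_em - background_donor
  a <- donor_only$acceptor_em - background_acceptor
  keep <- d > 0
  bt <- stats::median(a[keep] / d[keep])
  adir <- acceptor_only$acceptor_direct - background_acceptor
  aem <- acceptor_only$acceptor_em - background_acceptor
  keep2 <- adir > 0
  fx <- stats::median(aem[keep2] / adir[keep2])
  correction_coefficients(background_donor, background_acceptor,
                          bleedthrough_frac = max(0, bt),
                          false_excitation_frac = max(0, fx))
}

#' Process a cohort of raw recordings into an efficacy table
#'
#' Convenience chain: correct channels, compute ratio, baseline-correct,
#' extract amplitudes, normalize to the reference agonist.
#'
#' @param recordings list of `raw_recording`s.
#' @param coeff `correction_coefficients`.
#' @param reference_agonist reference for normalization.
#' @param reference_policy see [normalize_to_reference()].
#' @param pathway_id pathway label for the efficacy table.
#' @return list with `amplitudes` (normalized records) and `efficacies`
#'   (`efficacy_table`).
#' @export
process_fret_cohort <- function(recordings, coeff,
                                reference_agonist = "ACh",
                                reference_policy = "first",
                                pathway_id = "pathway") {
  records <- do.call(rbind, lapply(recordings, function(rec) {
    trace <- baseline_correct(compute_ratio(correct_channels(rec, coeff)))
    extract_amplitudes(trace)
  }))
  norm <- normalize_to_reference(records, reference_agonist,
                                 reference_policy)
  ## the reference application itself (and its stability re-application)
  ## stays in the table; efficacy aggregation uses every application
  list(amplitudes = norm,
       efficacies = aggregate_efficacies(norm, pathway_id))
}
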
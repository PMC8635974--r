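#' Agonist application protocol
#'
#' Describes the superfusion schedule of a single-cell recording: which
#' agonist is applied when, at what concentration, and how the recording is
#' sampled. Events must not overlap and must lie within the recording.
#'
#' @param events data.frame with columns `agonist_id` (character),
#'   `concentration` (mol/L, > 0), `t_start`, `t_end` (seconds).
#' @param total_duration recording length in seconds.
#' @param sampling_rate sampling frequency in Hz (default 2, the standard
#'   frame rate of the ratiometric recordings this package models).
#' @return An object of class `application_protocol`.
#' @export
application_protocol <- function(events, total_duration, sampling_rate = 2) {
  stopifnot(is.data.frame(events),
            all(c("agonist_id", "concentration", "t_start", "t_end") %in%
                  names(events)))
  events <- events[order(events$t_start), , drop = FALSE]
  if (any(events$concentration <= 0))
    stop("protocol error: concentrations must be > 0")
  if (any(events$t_start >= events$t_end))
    stop("protocol error: t_start must be < t_end")
  if (any(events$t_end > total_duration))
    stop("protocol error: events must end within total_duration")
  if (nrow(events) > 1 &&
      any(events$t_start[-1] < events$t_end[-nrow(events)]))
    stop("protocol error: overlapping application events")
  structure(list(events = events, total_duration = total_duration,
                 sampling_rate = sampling_rate),
            class = "application_protocol")
}

#' Standard sequential-application protocol
#'
#' Builds the canonical protocol used throughout this package: each agonist
#' applied once for `pulse` seconds with `gap` seconds of buffer washout
#' between applications, optionally re-applying the reference agonist at the
#' end as a stability control.
#'
#' @param agonists character vector of agonist identifiers, applied in order.
#' @param concentrations concentrations (mol/L), recycled to length of
#'   `agonists`.
#' @param pulse application duration (s); 30 s is typical for saturating
#'   pulses.
#' @param gap buffer washout between applications (s).
#' @param lead_in buffer time before the first application (s).
#' @param reapply_reference if TRUE, the first agonist is applied again at
#'   the end of the protocol.
#' @param sampling_rate Hz.
#' @return `application_protocol`
#' @export
standard_protocol <- function(agonists, concentrations = 3e-5, pulse = 30,
                              gap = 60, lead_in = 60,
                              reapply_reference = TRUE, sampling_rate = 2) {
  ids <- as.character(agonists)
  conc <- rep_len(concentrations, length(ids))
  if (reapply_reference) {
    ids <- c(ids, ids[1L])
    conc <- c(conc, conc[1L])
  }
  n <- length(ids)
  t_start <- lead_in + (seq_len(n) - 1L) * (pulse + gap)
  events <- data.frame(agonist_id = ids, concentration = conc,
                       t_start = t_start, t_end = t_start + pulse,
                       stringsAsFactors = FALSE)
  application_protocol(events, total_duration = max(events$t_end) + gap,
                       sampling_rate = sampling_rate)
}

#' Ground truth for the single-cell FRET simulator
#'
#' Collects every latent parameter of the two-channel fluorescence
#' simulator. `relative_efficacy` is the plateau of the latent receptor
#' occupancy/coupling signal for each agonist on a 0-1 scale relative to the
#' full agonist; the downstream pipeline should recover these values as
#' normalized amplitudes.
#'
#' @param relative_efficacy named numeric vector in `[0, 1]`, one entry per
#'   agonist.
#' @param on_rate,off_rate mono-exponential approach/decay rate constants of
#'   the latent signal (1/s).
#' @param donor_bleach_rate,acceptor_bleach_rate per-channel photobleaching
#'   rate constants (1/s).
#' @param bleedthrough_frac fraction of donor emission leaking into the
#'   acceptor detection channel, in `[0, 1)`.
#' @param false_excitation_frac fraction of the directly excited acceptor
#'   signal appearing in the acceptor channel under donor excitation, in
#'   `[0, 1)`.
#' @param background additive background per channel (intensity counts),
#'   named vector `c(donor = ..., acceptor = ...)`.
#' @param noise_sd additive Gaussian noise SD per sample per channel
#'   (counts). The default, 2 counts, is 2\% of the maximal FRET-induced
#'   channel modulation (`kappa * donor_scale` = 100 counts).
#' @param donor_scale,acceptor_scale,direct_scale unbleached signal
#'   amplitudes (counts) of the donor channel, the sensitized acceptor
#'   channel and the directly excited acceptor channel.
#' @param fret_base acceptor-channel baseline coefficient: at zero latent
#'   signal the sensitized channel sits at `acceptor_scale * fret_base`.
#' @param kappa FRET modulation depth: the latent signal `f` scales the
#'   donor channel by `(1 - kappa * f)` and the acceptor channel by
#'   `(fret_base + kappa * f)`.
#' @param cell_scale_sd SD of the per-cell log-normal expression scale
#'   factor (0 = identical cells).
#' @param seed integer seed for reproducible generation.
#' @return list of class `fret_ground_truth`
#' @export
fret_ground_truth <- function(relative_efficacy,
                              on_rate = 0.5, off_rate = 0.3,
                              donor_bleach_rate = 2e-4,
                              acceptor_bleach_rate = 1e-4,
                              bleedthrough_frac = 0.15,
                              false_excitation_frac = 0.10,
                              background = c(donor = 50, acceptor = 50),
                              noise_sd = 2,
                              donor_scale = 1000, acceptor_scale = 1000,
                              direct_scale = 500, fret_base = 1,
                              kappa = 0.1, cell_scale_sd = 0,
                              seed = 1L) {
  stopifnot(!is.null(names(relative_efficacy)),
            all(relative_efficacy >= 0 & relative_efficacy <= 1),
            on_rate >= 0, off_rate >= 0,
            donor_bleach_rate >= 0, acceptor_bleach_rate >= 0,
            bleedthrough_frac >= 0, bleedthrough_frac < 1,
            false_excitation_frac >= 0, false_excitation_frac < 1,
            all(background >= 0), noise_sd >= 0, kappa > 0, kappa < 1)
  structure(as.list(environment()), class = "fret_ground_truth")
}

## latent receptor-coupling signal: rises toward the agonist's efficacy with
## on_rate during an application, relaxes to 0 with off_rate otherwise;
## carried across segments so incomplete washout is represented faithfully.
latent_fret_signal <- function(time, protocol, truth) {
  ev <- protocol$events
  bounds <- sort(unique(c(0, ev$t_start, ev$t_end, max(time) + 1)))
  f <- numeric(length(time))
  f0 <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    idx <- which(time >= a & time < b)
    active <- which(ev$t_start <= a & ev$t_end >= b)
    if (length(active)) {
      target <- unname(truth$relative_efficacy[ev$agonist_id[active[1L]]])
      rate <- truth$on_rate
    } else {
      target <- 0
      rate <- truth$off_rate
    }
    if (length(idx))
      f[idx] <- target + (f0 - target) * exp(-rate * (time[idx] - a))
    f0 <- target + (f0 - target) * exp(-rate * (b - a))
  }
  f
}

#' Simulate a raw two-channel single-cell FRET recording
#'
#' Generates donor-emission, acceptor-emission (donor excitation) and
#' directly excited acceptor channels from the latent signal model, with
#' per-channel mono-exponential photobleaching, spectral cross-talk
#' (bleed-through of donor emission and false excitation of the acceptor)
#' and additive Gaussian noise. The ground truth is stored on the returned
#' object so tests never re-derive it.
#'
#' @param protocol an `application_protocol`.
#' @param truth a `fret_ground_truth`.
#' @param cell_id identifier for the simulated cell.
#' @param .rng if FALSE, the function does not touch the RNG seed (used when
#'   simulating many cells inside one seeded block).
#' @return object of class `raw_recording` with fields `cell_id`, `time`,
#'   `donor_em`, `acceptor_em`, `acceptor_direct`, `protocol`, and the
#'   generator `truth`.
#' @export
generate_fret_recording <- function(protocol, truth, cell_id = "cell_01",
                                    .rng = TRUE) {
  stopifnot(inherits(protocol, "application_protocol"),
            inherits(truth, "fret_ground_truth"))
  missing_ag <- setdiff(protocol$events$agonist_id,
                        names(truth$relative_efficacy))
  if (length(missing_ag))
    stop("protocol error: no efficacy configured for agonist(s) ",
         paste(missing_ag, collapse = ", "))
  if (.rng) set.seed(truth$seed)
  dt <- 1 / protocol$sampling_rate
  time <- seq(0, protocol$total_duration, by = dt)
  f <- latent_fret_signal(time, protocol, truth)
  scale <- if (truth$cell_scale_sd > 0)
    exp(stats::rnorm(1, 0, truth$cell_scale_sd)) else 1
  bleach_d <- exp(-truth$donor_bleach_rate * time)
  bleach_a <- exp(-truth$acceptor_bleach_rate * time)
  D <- truth$donor_scale * scale * bleach_d * (1 - truth$kappa * f)
  A <- truth$acceptor_scale * scale * bleach_a * (truth$fret_base +
                                                    truth$kappa * f)
  Adir <- truth$direct_scale * scale * bleach_a
  n <- length(time)
  noise <- function() if (truth$noise_sd > 0)
    stats::rnorm(n, 0, truth$noise_sd) else 0
  donor_em <- truth$background[["donor"]] + D + noise()
  acceptor_em <- truth$background[["acceptor"]] + A +
    truth$bleedthrough_frac * D + truth$false_excitation_frac * Adir +
    noise()
  acceptor_direct <- truth$background[["acceptor"]] + Adir + noise()
  structure(list(cell_id = cell_id, time = time, donor_em = donor_em,
                 acceptor_em = acceptor_em,
                 acceptor_direct = acceptor_direct,
                 protocol = protocol, truth = truth, corrected = FALSE),
            class = "raw_recording")
}

#' Simulate a cohort of single-cell FRET recordings
#'
#' @inheritParams generate_fret_recording
#' @param n_cells number of cells.
#' @return list of `raw_recording` objects.
#' @export
generate_fret_cohort <- function(protocol, truth, n_cells = 20) {
  set.seed(truth$seed)
  lapply(seq_len(n_cells), function(i)
    generate_fret_recording(protocol, truth,
                            cell_id = sprintf("cell_%02d", i), .rng = FALSE))
}

#' Simulate a three-phase BRET plate
#'
#' Produces per-well, per-cycle acceptor (YFP) and luciferase (Nluc) counts
#' whose ratio follows a piecewise-linear truth over the three measurement
#' phases (baseline, agonist, saturation), plus additive Gaussian noise on
#' the ratio. The line parameters of the truth are stored on the result.
#'
#' @param n_wells number of wells.
#' @param phase_params 3x2 numeric matrix (rows: baseline, agonist,
#'   saturation; columns: intercept, slope) describing the true BRET-ratio
#'   line of each phase as a function of cycle time (s).
#' @param n_cycles cycles per phase (default 10).
#' @param cycle_time cycle duration in seconds (default 44). Taken at face
#'   value; no constant is assumed elsewhere.
#' @param noise_sd Gaussian noise SD on the ratio.
#' @param nluc_counts luciferase counts per cycle (constant).
#' @param agonist_id,concentration annotations copied to every well.
#' @param seed RNG seed.
#' @return data.frame of class `bret_plate` with columns `well_id`,
#'   `cycle_index`, `cycle_time_s`, `phase`, `yfp`, `nluc`, `agonist`,
#'   `conc_M`; generator truth in `attr(, "truth")`.
#' @export
generate_bret_plate <- function(n_wells = 6,
                                phase_params = rbind(baseline = c(1.0, 0),
                                                     agonist = c(1.1, 0),
                                                     saturation = c(1.3, 0)),
                                n_cycles = 10, cycle_time = 44,
                                noise_sd = 0, nluc_counts = 1e5,
                                agonist_id = "ACh", concentration = 3e-5,
                                seed = 1L) {
  if (n_cycles <= 0) stop("non-positive cycle count")
  stopifnot(nrow(phase_params) == 3, ncol(phase_params) == 2)
  set.seed(seed)
  phases <- c("baseline", "agonist", "saturation")
  cyc <- seq_len(3L * n_cycles)
  t <- (cyc - 1L) * cycle_time
  phase <- rep(phases, each = n_cycles)
  ratio_truth <- phase_params[match(phase, phases), 1L] +
    phase_params[match(phase, phases), 2L] * t
  out <- do.call(rbind, lapply(seq_len(n_wells), function(w) {
    ratio <- ratio_truth
    if (noise_sd > 0) ratio <- ratio + stats::rnorm(length(ratio), 0, noise_sd)
    data.frame(well_id = sprintf("W%02d", w), cycle_index = cyc,
               cycle_time_s = t, phase = phase,
               yfp = ratio * nluc_counts, nluc = nluc_counts,
               agonist = agonist_id, conc_M = concentration,
               stringsAsFactors = FALSE)
  }))
  attr(out, "truth") <- list(phase_params = phase_params,
                             n_cycles = n_cycles, cycle_time = cycle_time,
                             noise_sd = noise_sd, seed = seed)
  class(out) <- c("bret_plate", "data.frame")
  out
}

#' Ground truth for operational concentration-response data
#'
#' @param tau named per-agonist operational efficacy (> 0).
#' @param Ki named per-agonist equilibrium dissociation constant (mol/L).
#' @param n shared transducer slope (> 0).
#' @param Emax theoretical maximum response of the system.
#' @param concentration_grid strictly increasing agonist concentrations
#'   (mol/L).
#' @param noise_sd additive Gaussian noise SD on the response.
#' @param replicates replicates per concentration.
#' @param seed RNG seed.
#' @export
operational_ground_truth <- function(tau, Ki, n = 1, Emax = 1,
                                     concentration_grid =
                                       10^seq(-9, -4, length.out = 8),
                                     noise_sd = 0, replicates = 1,
                                     seed = 1L) {
  stopifnot(!is.null(names(tau)), !is.null(names(Ki)),
            all(names(tau) %in% names(Ki)),
            all(tau > 0), all(Ki > 0), n > 0, Emax > 0,
            all(diff(concentration_grid) > 0), replicates >= 1)
  structure(list(tau = tau, Ki = Ki[names(tau)], n = n, Emax = Emax,
                 concentration_grid = concentration_grid,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 seed = seed),
            class = "operational_ground_truth")
}

#' Operational model of agonism (Black-Leff)
#'
#' Response of the operational model,
#' `Y = [A]^n tau^n Emax / ([A]^n tau^n + ([A] + Ki)^n)`.
#'
#' @param A agonist concentration (mol/L), vectorized.
#' @param tau operational efficacy.
#' @param Ki agonist equilibrium dissociation constant (mol/L).
#' @param n transducer slope.
#' @param Emax system maximum response.
#' @return response values.
#' @export
operational_response <- function(A, tau, Ki, n = 1, Emax = 1) {
  num <- (A * tau)^n * Emax
  num / ((A * tau)^n + (A + Ki)^n)
}

#' Simulate concentration-response tables from the operational model
#'
#' @param truth an `operational_ground_truth`.
#' @return data.frame (`agonist`, `conc_M`, `response`, `replicate`) with
#'   generator truth in `attr(, "truth")`.
#' @export
generate_concentration_response <- function(truth) {
  stopifnot(inherits(truth, "operational_ground_truth"))
  set.seed(truth$seed)
  grids <- expand.grid(conc_M = truth$concentration_grid,
                       replicate = seq_len(truth$replicates),
                       agonist = names(truth$tau),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y <- operational_response(grids$conc_M,
                            tau = truth$tau[grids$agonist],
                            Ki = truth$Ki[grids$agonist],
                            n = truth$n, Emax = truth$Emax)
  if (truth$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, truth$noise_sd)
  out <- data.frame(agonist = grids$agonist, conc_M = grids$conc_M,
                    response = y, replicate = grids$replicate,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  out
}

#' Simulate a competition radioligand-binding table
#'
#' Percent of control specific binding as a function of competitor
#' concentration: `100 / (1 + ([I]/IC50)^hill)` plus Gaussian noise.
#'
#' @param IC50 half-maximal inhibitory concentration (mol/L, > 0).
#' @param hill Hill slope of the displacement curve.
#' @param noise_sd noise SD in percentage points.
#' @param grid competitor concentrations (mol/L).
#' @param replicates replicates per concentration.
#' @param seed RNG seed.
#' @return data.frame (`conc_M`, `percent_specific`, `replicate`) with truth
#'   attributes.
#' @export
generate_competition_binding <- function(IC50, hill = 1, noise_sd = 0,
                                         grid = 10^seq(-10, -3,
                                                       length.out = 10),
                                         replicates = 1, seed = 1L) {
  stopifnot(IC50 > 0, hill > 0, noise_sd >= 0, all(grid >= 0))
  set.seed(seed)
  g <- expand.grid(conc_M = grid, replicate = seq_len(replicates),
                   KEEP.OUT.ATTRS = FALSE)
  pct <- 100 / (1 + (g$conc_M / IC50)^hill)
  if (noise_sd > 0) pct <- pct + stats::rnorm(length(pct), 0, noise_sd)
  out <- data.frame(conc_M = g$conc_M, percent_specific = pct,
                    replicate = g$replicate)
  attr(out, "truth") <- list(IC50 = IC50, hill = hill, noise_sd = noise_sd,
                             seed = seed)
  out
}
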
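## shared fixtures: the canonical seven-agonist efficacy tiers and small
## builders used across test files

std_efficacies <- function() {
  c(ACh = 1.0, Metha = 0.6, Fur = 0.6, Are = 0.2, Guva = 0.2,
    Pilo = 0.08, Mda = 0.03)
}

## a clean (noise-free, artifact-free) ground truth for identity checks
clean_truth <- function(eff = std_efficacies(), ...) {
  fret_ground_truth(eff, noise_sd = 0, donor_bleach_rate = 0,
                    acceptor_bleach_rate = 0, bleedthrough_frac = 0,
                    false_excitation_frac = 0,
                    background = c(donor = 0, acceptor = 0), ...)
}

## expected corrected-ratio step for a given efficacy under the generator's
## signal model (acceptor_scale/donor_scale cancels at equal defaults)
expected_ratio <- function(f, truth) {
  (truth$acceptor_scale / truth$donor_scale) *
    (truth$fret_base + truth$kappa * f) / (1 - truth$kappa * f)
}

## single-event protocol for amplitude-level unit tests
single_pulse_protocol <- function(agonist = "ACh", conc = 3e-5,
                                  t_start = 60, pulse = 30, tail = 60) {
  application_protocol(
    data.frame(agonist_id = agonist, concentration = conc,
               t_start = t_start, t_end = t_start + pulse),
    total_duration = t_start + pulse + tail)
}

## standard three-agonist operational ground truth (tau over 3 log units)
std_op_truth <- function(noise_sd = 0, replicates = 1, seed = 1L) {
  operational_ground_truth(
    tau = c(ACh = 10, Are = 1, Pilo = 0.1),
    Ki = c(ACh = 1e-7, Are = 1e-6, Pilo = 1e-5),
    n = 1.2, Emax = 1,
    concentration_grid = 10^seq(-10, -3, length.out = 10),
    noise_sd = noise_sd, replicates = replicates, seed = seed)
}

## coarse grid-search oracle for the operational fit: best SSE over a grid
## of (log10 tau per agonist, log10 n); independent of the optimizer path
op_grid_search_sse <- function(ds, log10_tau_grid = seq(-3, 3, by = 0.25),
                               log10_n_grid = seq(-0.5, 0.5, by = 0.05)) {
  agonists <- ds$agonists
  best <- Inf
  for (ln in log10_n_grid) {
    n <- 10^ln
    ## with shared n fixed, the per-agonist tau minimization separates
    sse_n <- 0
    for (ag in agonists) {
      rows <- ds$data$agonist == ag
      A <- ds$data$conc_M[rows]; y <- ds$data$response[rows]
      sse_ag <- min(vapply(log10_tau_grid, function(lt) {
        mu <- operational_response(A, 10^lt, ds$Ki[[ag]], n, ds$Emax)
        sum((mu - y)^2)
      }, numeric(1)))
      sse_n <- sse_n + sse_ag
    }
    best <- min(best, sse_n)
  }
  best
}
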
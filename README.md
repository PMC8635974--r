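# ligandbias

Quantification of GPCR ligand bias from resonance-energy-transfer
recordings.

Different agonists at one G protein-coupled receptor can preferentially
drive recruitment of different intracellular effectors (G protein, GRK2,
arrestin) — *ligand bias*. This package implements the complete analysis
chain for quantifying that bias at the effector-recruitment level, for
pharmacologists working with single-cell FRET and plate-reader BRET
readouts:

* **FRET traces** — spectral correction (background, bleed-through, false
  excitation), acceptor/donor ratio, photobleaching baseline correction,
  per-application amplitude extraction by the 5-s window rule, within-cell
  normalization to a reference agonist, per-agonist efficacy tables.
* **BRET plates** — per-cycle ratios, per-phase line fits, agonist-induced /
  additional / maximum signal changes with per-well normalization.
* **Kinetics** — constrained one- and two-phase exponential decay fits and
  nested-model comparison.
* **Binding** — Hill concentration-response fits (bottom fixed at 0),
  competition-binding fits with no-displacement censoring, Cheng–Prusoff
  conversion Ki = IC50 / (1 + [L]/Kd).
* **Operational model** — global Black–Leff fit per pathway,
  Y = [A]ⁿτⁿ·Emax / ([A]ⁿτⁿ + ([A]+Ki)ⁿ), with one shared slope n,
  per-agonist τ, fixed Ki; transduction coefficients log₁₀(τ/Ki) and bias
  coefficients Δlog₁₀(τ/Ki) relative to a reference agonist with propagated
  uncertainty.
* **Bias detection** — efficacy rank orders with statistical tie groups
  (Tukey rule), cross-pathway comparison, discordant-pair bias calls.
* **Synthetic data** — generators for every input with stored ground truth
  (latent recruitment kinetics, photobleaching, spectral cross-talk,
  noise; three-phase BRET plates; operational concentration-response;
  displacement curves), plus named end-to-end scenarios.

See the methods vignette (`vignettes/ligand-bias-methods.Rmd`) for the
models, conventions and numerical choices.

## Worked example

Simulate a 20-cell, seven-agonist cohort with cross-talk, bleaching and
noise on; run the full trace pipeline; rank the agonists:

```r
library(ligandbias)

eff <- c(ACh = 1.0, Metha = 0.6, Fur = 0.6, Are = 0.2, Guva = 0.2,
         Pilo = 0.08, Mda = 0.03)                     # ground truth
truth <- fret_ground_truth(eff, seed = 42, cell_scale_sd = 0.2)
prot  <- standard_protocol(names(eff))
recs  <- generate_fret_cohort(prot, truth, n_cells = 20)

res <- process_fret_cohort(recs, true_coefficients(truth),
                           pathway_id = "Gq_activation")
res$efficacies
#>         pathway agonist   mean      sd  n
#> 1 Gq_activation     ACh 0.9992 0.00879 40
#> 2 Gq_activation     Are 0.1842 0.00677 20
#> 3 Gq_activation     Fur 0.5712 0.00835 20
#> 4 Gq_activation    Guva 0.1804 0.00545 20
#> 5 Gq_activation     Mda 0.0264 0.00739 20
#> 6 Gq_activation   Metha 0.5735 0.00619 20
#> 7 Gq_activation    Pilo 0.0732 0.00586 20

rank_order(res$amplitudes)
#> Efficacy rank order (tukey tie rule):
#>   ACh > Metha ~ Fur > Are ~ Guva > Pilo > Mda
```

The per-agonist mean normalized amplitudes recover the configured
efficacies (ACh, the reference, normalizes to 1; equal-efficacy pairs end
up in `~` tie groups; the small downward shift of mid-range agonists is the
documented ratio nonlinearity of a dual-channel FRET readout).

Global operational-model fit and bias coefficients:

```r
tr <- operational_ground_truth(
  tau = c(ACh = 10, Are = 1, Pilo = 0.1),
  Ki  = c(ACh = 1e-7, Are = 1e-6, Pilo = 1e-5),
  n = 1.2, Emax = 1,
  concentration_grid = 10^seq(-10, -3, length.out = 10),
  noise_sd = 0.02, replicates = 3, seed = 7)
fit <- fit_operational_global(
  operational_dataset(generate_concentration_response(tr), tr$Ki,
                      pathway_id = "Gq_activation"))
fit
#> Operational-model global fit: Gq_activation
#>   shared n = 1.183 (SE 0.0254), Emax = 1, SSE = 0.03263
#>   agonist     tau se_log10_tau    Ki censored log_tau_over_ki
#> 1     ACh 10.4028     0.013316 1e-07    FALSE           8.017
#> 2     Are  1.0004     0.007847 1e-06    FALSE           6.000
#> 3    Pilo  0.1091     0.046920 1e-05    FALSE           4.038

compute_bias_factors(fit, "ACh")[, 1:6]
#>   agonist log_tau_over_ki delta_log_tau_over_ki se_delta ci_lo ci_hi
#> 1     ACh            8.02                  0.00   0.0000  0.00  0.00
#> 2     Are            6.00                 -2.02   0.0155 -2.05 -1.99
#> 3    Pilo            4.04                 -3.98   0.0488 -4.08 -3.88
```

With 2 % response noise the fit recovers τ = {10, 1, 0.1} and n = 1.2
within the reported uncertainties; Δlog₁₀(τ/Ki) is 0 for the reference by
construction and −2 / −4 log units for the partial agonists, matching the
configured τ/Ki ratios.

End-to-end scenario with a built-in recruitment-bias reversal:

```r
dir <- simulate_scenario("arrestin_reversal", seed = 1)
report <- run_pipeline(file.path(dir, "config.json"))
report
#> Bias report
#>   Gq_activation: ACh > Metha ~ Fur > Are ~ Guva > Pilo > Mda
#>   arrestin3_recruitment: ACh > Fur ~ Metha > Pilo ~ Guva > Are > Mda
#>   bias calls: 1
#>   agonist1 agonist2 order_a order_b     pathway_a             pathway_b
#> 1      Are     Pilo       >       < Gq_activation arrestin3_recruitment
```

One agonist pair (Are/Pilo) swaps rank between the two pathways — the
pipeline reports exactly that pair as a bias call.

A command-line entry point with `simulate` and `run-all` subcommands is
installed at `system.file("cli", "ligandbias", package = "ligandbias")`.

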
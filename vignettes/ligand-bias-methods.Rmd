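---
title: "Methods: quantifying GPCR ligand bias from resonance-energy-transfer recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying GPCR ligand bias from resonance-energy-transfer recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandbias)
```

## The problem

Different agonists at one G protein-coupled receptor (GPCR) can favour
different downstream effectors — G proteins, GPCR kinases (GRKs),
arrestins. This *ligand bias* is usually inferred from downstream signalling,
where amplification distorts efficacy estimates. The analysis chain
implemented here instead works at the level of *effector recruitment to the
receptor*, measured as ratiometric FRET in single cells (and G protein
activation by BRET in plates), and asks two quantitative questions:

1. What is each agonist's efficacy to drive recruitment of each effector,
   expressed relative to a full reference agonist (acetylcholine, "ACh")?
2. Does the *rank order* of agonist efficacies differ between effector
   pathways — the operational signature of bias at the recruitment level?

The package covers the full chain: trace correction → amplitude extraction
→ normalization → efficacy tables → rank orders with statistical tie groups
→ cross-pathway comparison, plus decay-kinetics fitting, binding-affinity
estimation, and global operational-model fitting yielding
$\Delta\log(\tau/K_i)$ bias coefficients. A synthetic-data module generates
every input with known ground truth, so each stage — and the chain
end-to-end — is testable without external data.

## Single-cell FRET processing

A raw recording holds donor emission $D(t)$ and acceptor emission $A(t)$
under donor excitation (sampled at 2 Hz), optionally the directly excited
acceptor channel, and the agonist application protocol. Processing steps:

**Spectral correction** (`correct_channels`). With backgrounds $b_D, b_A$,
bleed-through fraction $\beta$ and false-excitation fraction $\phi$:
$$D' = D - b_D, \qquad
A' = (A - b_A) - \beta D' - \phi (A_{direct} - b_A).$$
The order (background, then bleed-through, then false excitation) is a
package convention; the exact ordering is rarely reported by instruments
and is exactly inverted by the synthetic generator, so round-trip tests
are exact. A corrected donor that is negative in more than 10 % of samples
indicates a wrong background and is an error.

**Ratio** (`compute_ratio`): $R(t) = A'(t)/D'(t)$. Samples with
non-positive donor are masked with a warning; more than 10 % masked is an
error.

**Baseline correction** (`baseline_correct`). Photobleaching is
multiplicative on intensities, so unequal donor/acceptor bleach rates put a
smooth multiplicative drift on the ratio. The model is
mono-exponential-plus-constant, $d(t) = a e^{-kt} + c$, least-squares
fitted to *buffer-only* samples (outside every application event and a
washout margin, default 20 s, after each event) and divided out, anchored
at the first time point. $k$ is profiled on a sign-free grid (the ratio can
drift up or down depending on which channel bleaches faster), then
polished. Numerical choices:

* Relative drift below 0.2 % of the trace level over the whole recording is
  left uncorrected: it is indistinguishable from washout residuals and an
  order of magnitude below any bleaching worth correcting. This makes the
  no-drift case an exact identity.
* With fewer than two buffer segments the model falls back to a straight
  line, with a warning.

**Amplitude extraction** (`extract_amplitude`). The response amplitude of
an application is the difference of two 5-s window means: the mean ratio
over $[t_{end}-5, t_{end})$ minus the mean over $[t_{start}-5,
t_{start})$. Windows are half-open and anchored to the *protocol* times,
never to detected onsets — deterministic and faithful to the stated rule.
At 2 Hz each window holds exactly 10 samples.

**Normalization** (`normalize_to_reference`). Amplitudes are divided by the
same cell's reference-agonist (default ACh) amplitude, so the reference
normalizes to 1 and cell-to-cell expression differences cancel. When the
reference was applied more than once (a stability control), the *first*
application is the default denominator; `"max"` is available — which one
the original protocol used is not documented, so it is exposed as a
policy. Cells with non-positive reference amplitude are excluded, with the
reason recorded.

## BRET plate analysis

Per well, the BRET ratio is YFP counts over Nluc counts per cycle. The
three phases (baseline, agonist, saturation — 10 cycles each by default)
are each fitted with an ordinary least-squares line over cycle time, and
the signal changes are *distances between fitted lines at the phase
boundaries*: the agonist-induced change evaluates the baseline line at its
last cycle and the agonist line at its first cycle; likewise for the
additional change at the agonist/saturation boundary. The maximum change is
their sum — an exact identity, asserted on every input — and the agonist
change is normalized per well by the maximum change. Line fits, not raw
boundary cycles, denoise the boundary evaluation. Cycle times are always
taken from the input table; no cycle-duration constant is assumed.
A well whose maximum change is not positive (within numerical round-off)
has no defined normalized change and is flagged.

## Decay kinetics

Offset (washout) kinetics of normalized traces are fitted with

* one-phase: $Y = (Y_0 - P)e^{-Kx} + P$,
* two-phase: $Y = P + \mathrm{SpanFast}\, e^{-K_{fast}x} +
  \mathrm{SpanSlow}\, e^{-K_{slow}x}$ with
  $\mathrm{SpanFast} = (Y_0-P)\cdot \%Fast\cdot 0.01$ and
  $\mathrm{SpanSlow} = (Y_0-P)(100-\%Fast)\cdot 0.01$,

with the convention $Y_0 = 1$, $P = 0$ for normalized offset traces
(unconstrained variants are available). Rates are optimized as $\log K$
(smooth positivity, no boundary artifacts) and $\%Fast$ as a logit;
$K_{fast} \ge K_{slow}$ is enforced by relabeling after the fit,
complementing $\%Fast$, which removes label-switching ambiguity. Starting
values come from log-linear regression on the first/last thirds of the
trace, with three starts. Fits with $K_{fast}/K_{slow} < 3$ are flagged
`practically_one_phase`; $\%Fast$ pinned at 0 or 100 is `degenerate`; a
rate slower than $1/(100\,T)$ on a window of length $T$ is
`non_convergent`. `compare_decay_models` provides the extra-sum-of-squares
F test between the nested fits (the original analysis states which model
was used per condition but no selection rule; the F test is the standard
choice and is exposed as plumbing).

## Binding and concentration-response

`fit_hill` fits $Y = \mathrm{top}\,[A]^h/([A]^h + EC_{50}^h)$ with the
bottom fixed at 0, in log10-concentration space (multi-start across the
tested range). `fit_competition` fits the descending displacement curve on
the percent-of-control scale with top/bottom fixed at 100/0 by default. A
curve that stays above 80 % of control at the top quartile of tested
concentrations is reported as `no_displacement` with the IC50 *censored* at
the highest tested concentration — a lower bound, not an estimate (the
behaviour required for a competitor with no measurable affinity).
`cheng_prusoff` converts $IC_{50}$ to $K_i = IC_{50}/(1 + [L]/K_d)$; the
radioligand $K_d$ is a required user input.

## Operational model and bias coefficients

The Black–Leff operational model of agonism relates concentration to
response through efficacy $\tau$ and affinity $K_i$:
$$Y = \frac{[A]^n \tau^n E_{max}}{[A]^n \tau^n + ([A]+K_i)^n}.$$
`fit_operational_global` fits all agonists of one pathway simultaneously:
**one shared slope $n$**, one $\tau$ per agonist, $K_i$ fixed per agonist
from competition binding, $E_{max}$ fixed by the pathway's normalization
convention (1 for recruitment readouts normalized to the reference
maximum; the reference's own maximum response on a percent-like scale for
per-well-normalized readouts — always user-supplied, never hard-coded).
$\tau$ and $n$ are positive by log-parameterization.

* Standard errors use the standard nonlinear-regression covariance
  $\hat\sigma^2 (J^\top J)^{-1}$ with a central-difference Jacobian of the
  stacked residuals; intervals use $t$ quantiles on the residual degrees
  of freedom.
* Agonists whose mean response never exceeds 2 % of $E_{max}$ (default) are
  *censored*: they carry no slope information, are excluded from the
  shared-$n$ estimation (they would destabilize it), and get an upper-bound
  $\tau$ at the detection limit rather than a point estimate.
* Weighting is unweighted least squares (no weighting scheme is documented
  for this analysis).

`compute_bias_factors` forms $\log_{10}(\tau/K_i)$ and
$\Delta\log_{10}(\tau/K_i)$ relative to the reference agonist (exactly 0
for the reference). Uncertainty is the quadrature sum of the two
$\log_{10}\tau$ standard errors, treating the fixed $K_i$ as constants —
the minimal assumption matching the fixed-$K_i$ design. Censored agonists
propagate as bounds ($-\infty$ lower CI), never as point values.
Differences of $\Delta\log(\tau/K_i)$ between two non-reference agonists
are invariant to the choice of reference (a tested property).

## Rank orders, tie groups and bias calls

`rank_order` sorts agonists by mean normalized efficacy and merges adjacent
agonists into tie groups ("$\approx$") when they are not statistically
separated. The default tie rule is the Tukey-adjusted pairwise p-value
($p \ge 0.05$ means tied) from a single family-wise test over all groups —
the same multiple-comparison machinery used for the group statistics,
rather than an arbitrary numeric tolerance. A tolerance rule
($|\Delta\text{mean}| <$ `tie_tol`) is the fallback when per-cell values
are unavailable or degenerate (zero within-group variance).

`compare_pathways` lists *discordant pairs*: agonist pairs whose order
reverses between two pathways with both orderings outside tie groups.
Pairs tied in either pathway are not comparable and never count. A
Kendall-type concordance (concordant minus discordant over comparable
pairs) summarizes each pathway pair, and every discordant pair becomes one
bias call in the report — so every bias call is backed by a recorded
reversal.

Statistics (`paired_t_test`, `anova_tukey`) are implemented from the
classical formulas — paired $t$ on within-cell differences; one-way ANOVA
with Tukey HSD via the studentized-range distribution — and are verified in
the test suite against R's independent reference implementations
(`t.test`, `aov`/`TukeyHSD`). The significance-star ladder is
configuration; the default is the conventional 0.05/0.01/0.001/0.0001 (the
source material prints an inconsistent ladder that repeats 0.001, evidently
a typo).

## The synthetic world

`generate_fret_recording` inverts the correction pipeline. A latent
receptor-coupling signal $f(t)$ per cell rises toward the agonist's
relative efficacy with `on_rate` (default 0.5 s$^{-1}$) during an
application and relaxes with `off_rate` (default 0.3 s$^{-1}$) after
washout — mono-exponential in both directions, carried across segments.
The channels are built as
$$D = b_D + s\,e^{-k_D t}(1 - \kappa f), \qquad
A = b_A + s\,e^{-k_A t}(\mathrm{base} + \kappa f) + \beta D_{sig} +
\phi A_{direct,sig},$$
with per-channel mono-exponential bleaching (defaults $2\times10^{-4}$ and
$1\times10^{-4}$ s$^{-1}$ — slow drift of order 10 % per recording, the
simplest model the baseline correction must defeat), modulation depth
$\kappa = 0.1$, additive Gaussian noise per sample and channel, and an
optional log-normal per-cell expression scale. Defaults:
bleed-through 0.15, false excitation 0.10, backgrounds 50 counts, signal
scale 1000 counts.

Choices worth stating explicitly:

* **Noise level.** "2 % noise" is interpreted as noise SD equal to 2 % of
  the FRET-induced modulation depth ($\kappa \times 1000 = 100$ counts, so
  `noise_sd = 2` counts): noise quoted relative to the signal of interest,
  an SNR of 50 typical of averaged single-cell ratio recordings. Chosen
  once, before any criterion was measured.
* **On/off rates** are free parameters of the generator (no kinetic rate
  constants are documented for the latent recruitment signal); the defaults
  make a 30-s pulse saturate and a 60-s washout complete.
* **Ratio nonlinearity.** Because $f$ modulates both channels, the ratio
  step is $(\mathrm{base}+\kappa f)/(1-\kappa f)$ — slightly convex in
  $f$. Normalized amplitudes therefore under-recover mid-range efficacies
  by up to $\sim 0.03$ at $\kappa = 0.1$. This is physics, not an artifact:
  it is why the end-to-end recovery tolerance is ±0.05, not machine
  precision, on noiseless data.
* Ground truth is always stored on the generated objects and in sidecar
  JSON; tests never re-derive it.

What the generator does *not* emulate: optics and point-spread functions,
shot (Poisson) noise, receptor phosphorylation dynamics, heterogeneous
per-agonist kinetics, or cell-to-cell variability beyond one scale factor.
A green end-to-end test therefore establishes that the *analysis chain* is
correct and calibrated for data obeying its stated model — not that the
model captures every feature of real recordings.

Scenario generator (`simulate_scenario`): `"concordant"` uses the efficacy
tiers {1.0, 0.6, 0.6, 0.2, 0.2, 0.08, 0.03} for seven agonists in both
pathways; `"arrestin_reversal"` swaps one weak-partial pair (Pilo/Are)
between pathways so that exactly one discordant pair is resolvable — the
canonical recruitment-bias pattern; `"null"` makes all agonists
equi-efficacious. The operational arm of each scenario maps the same tiers
onto $\tau$ spanning 3 log units with shared $n = 1.2$.

## Known limitations

* Correction coefficients must be supplied or estimated from calibration
  recordings (`estimate_correction_coefficients`); the package cannot
  deconvolve cross-talk blindly.
* The censoring rule for silent agonists (2 % of $E_{max}$) is a detection
  threshold, not an inference; $\tau$ upper bounds depend on it.
* The quadrature-sum uncertainty on $\Delta\log(\tau/K_i)$ ignores the
  (small) covariance between the two $\tau$ estimates induced by the shared
  slope, and treats $K_i$ as exact.
* Baseline correction assumes drift is multiplicative and slow relative to
  responses; fast focus drifts or step artifacts are out of scope.
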
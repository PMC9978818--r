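---
title: "Methods: dissociation-rate binning of polyclonal antibody sensorgrams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissociation-rate binning of polyclonal antibody sensorgrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paart)
```

## The problem and the model

Label-free biosensors (BLI in nm, SPR in RU) record the total binding
response of everything in the sample that interacts with the immobilized
antigen. For a polyclonal sample the dissociation phase is a superposition
of the decays of antibody populations with different stabilities. Because
clonal concentrations are unknown, k_a and K_D are not estimable for pAbs;
the concentration-independent dissociation rate constant k_d is, and it is
the avidity readout (slower k_d, higher avidity).

The dissociation window is modeled as

$$R(t) = \sum_{i=1}^{n} \alpha_i e^{-k_{d,i} t} \; (+\, R_\infty),$$

where component $i$ collects antibodies of similar avidity, $\alpha_i$ is
that group's bound response at the window start, and the optional constant
$R_\infty$ absorbs genuinely non-dissociating signal. The reported fraction
$f_i = \alpha_i / \sum_j \alpha_j$ is the component's share of *antigen
occupancy at the window start* — not its abundance in solution; $R_\infty$
is excluded from the normalization. Model order $n$ is chosen by the
Akaike information criterion in its least-squares form
$\mathrm{AIC} = N\ln(\mathrm{RSS}/N) + 2K$ with $K = 2n\,(+1\ \text{for}\
R_\infty) + 1$, the noise variance counted as a parameter; AICc is
available behind `paart_control(aic = "aicc")`. Orders are fit
sequentially and the loop stops at the first AIC increase (or at
`max_components`, default 4, or when fewer than `min_points_per_param`
(10) points per parameter remain); the returned model is the AIC minimum
among the fitted orders — identical under the stopping rule, and robust if
the order cap truncates the loop.

### Assumptions

* Dissociation is a sum of pure exponentials: rebinding during the
  dissociation phase is negligible (flow/large buffer volume), no
  mass-transport limitation, no conformational-change kinetics.
* Noise is additive, homoscedastic and uncorrelated; the AIC form above is
  exact for Gaussian noise.
* The fractions are occupancy shares at the window start: they depend on
  the association time used (see the competition dynamics below) and on
  the window choice, so both are carried in every result.

## Fitting: variable-projection multistart

Sums of exponentials are notoriously initialization-sensitive, so
`fit_sum_exp()` never starts from a single guess. Candidate rate constants
are taken as all size-$n$ subsets of a 10-point log-spaced seed grid
spanning $[1/(10\,T),\ 10/\Delta t]$ (clipped to `kd_bounds`, default
$[10^{-6}, 1]$ s$^{-1}$) — i.e. from "barely decays over the window" to
"decays within a few samples". For every subset the amplitudes are solved
by non-negative linear least squares on precomputed normal equations
(variable projection; microseconds per subset), the best `multistart`
(default 24) subsets by screened RSS are refined jointly by
bound-constrained Levenberg–Marquardt in $(\log k_d, \alpha)$ with an
analytic Jacobian, and ties break by lowest RSS then lowest seed index.
The procedure is deterministic: identical input and control give
bit-identical results; the `seed` in `paart_control()` only drives
`simulate()` on a fitted object.

Numerical choices worth stating:

* **Convergence** — LM `ftol` equals `tol` ($10^{-10}$ relative RSS
  change), `ptol` $10^{-12}$, 200 iterations per start.
* **Noise floor** — if a candidate's RSS falls below
  $10^{-16}\sum_t R(t)^2$ (residuals $\sim 10^{-8}$ of the signal), the
  order loop stops growing: below that floor "improvements" are
  floating-point artifacts and the Gaussian AIC would otherwise prefer a
  spurious extra component on noiseless input.
* **Degenerate inputs** — a non-positive response at the window start is
  an error (nothing to fit); an all-constant trace fits with k_d pinned at
  the lower bound and a warning; bound-pinned rate estimates always warn.
* **Standard errors** — linearized at the optimum,
  $\widehat\sigma^2 (J^\top J)^{-1}$ with
  $\widehat\sigma^2 = \mathrm{RSS}/(N-k)$. Conditioning is assessed on the
  unit-scaled (correlation-like) $J^\top J$ so that disparate parameter
  units are not mistaken for collinearity; below a reciprocal condition
  number of $10^{-10}$ the SEs are reported missing with an
  "ill-conditioned" warning. Adjacent components closer than 2-fold in
  k_d additionally warn that the split is poorly separated — they are
  never merged silently.
* **χ²** — reported as the unnormalized RSS over the fitted window,
  matching the magnitudes practitioners quote for nm-scale responses.

The resolution limit this implies is a feature, not a bug: component pairs
separated by less than roughly 5-fold in k_d at realistic noise merge into
one component whose rate lies between the truths; pairs ~100-fold apart
are resolved reliably. The acceptance suite quantifies both regimes.

## Preprocessing

Raw sensorgrams are reference-subtracted (`reference_subtract()`; the
control trace is linearly interpolated onto the sample grid — never the
reverse, preserving the fitted signal's sampling), inter-step corrected
(`align_intersteps()`: the dissociation trace is shifted by a constant so
it continues the association end; the offset is recorded in the notes),
and windowed (`dissociation_window()`). The default window drops the first
5 s — step-transition distortion — and keeps the rest; late-phase
non-specific baselines can be cut with `t_end` or absorbed by `R_∞`
(`include_r_inf`, off by default since a clean window is preferable to an
extra parameter). Times are rebased so the first retained point is t = 0;
the α's and fractions therefore refer to the *window* start, which is the
convention used consistently in results and tests. Replicates are never
averaged or auto-selected: each is fit and reported independently.

## The competing-reactions model

Validation uses mixtures of antibodies with known kinetics. During
association, N analytes competing for one surface of capacity $R_{max}$
follow the mass-action system

$$\frac{dR_j}{dt} = k_{a,j} C_j \Big(R_{max} - \sum_k w_{jk} R_k\Big) -
  k_{d,j} R_j, \qquad w_{jk} = mw_j/mw_k,$$

with $w = 1$ for equal molecular weights (IgG mixtures); the
molecular-weight coupling is available but defaults to 1. This is a linear
constant-coefficient system, so `simulate_competing()` solves it exactly
by eigendecomposition (adaptive `lsoda` fallback for degenerate spectra);
dissociation sets $C_j = 0$, making each component decay as
$R_j(t_{assoc})e^{-k_{d,j}\tau}$ — deliberately, so the simulated
dissociation is *exactly* multi-exponential and serves as an oracle for
the binning fit. At equilibrium the two-analyte occupancy ratio reduces to
$(C_1/K_{D,1})/(C_2/K_{D,2})$, which the simulator reproduces to
closed-form accuracy and which anchors the association-length dynamics:
the longer the association, the more the slow-k_d (high-avidity) analyte
displaces the fast one, so short association phases are needed to *see*
low-avidity antibodies at the start of dissociation.

`fit_competing()` inverts the simulator: both phases of a two-analyte
mixture at known concentrations are fit for per-analyte $(k_a, k_d)$ plus
a shared $R_{max}$ (profiled linearly), seeded from a dissociation-only
binning of the same trace crossed with a log-spaced $k_a$ grid over
$[10^3, 10^7]$ M$^{-1}$s$^{-1}$. One identifiability fact is documented
rather than hidden: with equal response weights the total curve depends on
the analytes only through the exchangeable pairs $(k_a C, k_d)$, so which
pair belongs to which *named* analyte is not decidable from the mixture
data. The labeling is resolved by optional per-analyte prior kinetics
(`kinetics_init`, e.g. from fitting each mAb alone — the realistic
workflow) or, by default, slow-k_d-first. Fitting more than two competing
analytes is out of scope (simulation supports N).

## The synthetic generator and what it does (not) cover

`simulate_mixture_sensorgram()` produces the canonical study conditions:
mixtures of the three reference anti-repeat mAbs (k_d = 5.6×10⁻⁵,
2.4×10⁻⁴ and 3.7×10⁻² s⁻¹; k_a = 8.2×10⁴–4.7×10⁵ M⁻¹s⁻¹) at 5 µg/ml total
IgG (3.33×10⁻⁸ M at 1.5×10⁵ g/mol), R_max = 1 response unit, 300 s
association (presets 100/1800 s), 600 s dissociation, 5 Hz sampling, and
i.i.d. Gaussian noise with σ = 0.005 response units — a plausible BLI
noise floor relative to 0.2–0.9 nm signals; the true level of any given
instrument is not knowable here and σ is configurable. Optional linear
drift is available; molar shares are canonical and mass shares convert via
per-species molecular weight (identical for equal-mw mixtures). The
ternary validation scenario is the neutral 1:1:1 molar mix. Seeds are
explicit everywhere and the generator never touches global RNG state.

What the generator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: step-transition distortion, spectral
artifacts, sensor-to-sensor loading differences, heteroscedastic or
correlated noise, mass-transport limitation, rebinding, and true clonal
continua rather than discrete components. Results on real sensorgrams
additionally depend on window choice and reference quality.

## Problem sizes used in tests

The stochastic characterizations run 100 noisy binary mixtures and 50
noisy ternary mixtures at the full 5 Hz / 600 s resolution (≈3000-point
fits), 200 Monte-Carlo replicates for SE calibration at 1 Hz, and 20
replicates of the global Langmuir noise study — sizes at which the
binomial uncertainty on a 90% selection rate is a few percent while the
whole suite stays in the minutes range on one core.

## Known limitations

* Components are bins, not clones; a continuum of avidities will be
  summarized by 2–3 discrete rates.
* k_d separations below ~5-fold are reported as one averaged component;
  fractions below the 5% reporting threshold (`count_components()`) are
  unstable at σ = 0.005 and should not be over-interpreted.
* The AIC occasionally admits a marginal extra component (~1–3% fraction)
  at this noise level; the reporting threshold exists precisely to keep
  such components out of sample-level summaries.
* Fractions refer to occupancy at the window start and shift with
  association length — comparisons across samples require a common assay
  design (2–5 min association is a sensible default regime).
* The 1:1 and competing models ignore analyte bivalency mechanics; avidity
  is treated empirically through k_d.
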
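# paart — avidity binning of polyclonal antibody dissociation kinetics

Polyclonal antibody (pAb) responses are heterogeneous: antibodies of
different avidity bind the same antigen simultaneously, and label-free
biosensor platforms (biolayer interferometry, surface plasmon resonance)
record only their summed response. The conventional analysis fits the
dissociation phase to a single exponential and returns one dissociation
rate constant weighted toward the slowest-dissociating antibodies,
discarding the heterogeneity. And because clonal concentrations in serum
are unknown, association-phase analysis — and hence k_a and K_D — is not
available for pAbs; the concentration-independent k_d is the avidity
readout that *can* be measured.

This package resolves that heterogeneity by dissociation-rate binning. A
windowed dissociation time-course R(t) is fit to a sum of exponentials

    R(t) = Σ_{i=1..n} α_i exp(−k_{d,i} t)   (+ optional R_∞)

where each component i is a group of antibodies of similar avidity, α_i is
that group's bound response at the window start and k_{d,i} its
dissociation rate constant. Models of increasing order n = 1, 2, … are fit
by bound-constrained variable-projection least squares, and the minimal
adequate n is selected with the Akaike information criterion
(AIC = N ln(RSS/N) + 2K), guarding against overfitting. Each component is
reported with its k_d ± SE and its fraction f_i = α_i / Σ α_j — its share
of antigen occupancy at the start of the dissociation window.

For validation the package also implements the surrounding kinetics
machinery:

* the closed-form 1:1 Langmuir model and global (k_a, k_d, R_max) fitting
  over concentration series;
* a heterogeneous-analyte (competing reactions) mass-action model — N
  analytes competing for one surface — with exact forward simulation
  (matrix-exponential solution of the linear association system) and
  two-analyte global fitting, which dissects a mixture sensorgram into
  per-antibody component curves when concentrations are known;
* a synthetic sensorgram generator (mixtures of reference monoclonal
  antibodies spanning k_d 5.6×10⁻⁵–3.7×10⁻² s⁻¹, Gaussian instrument
  noise) so every claim is testable without instrument data.

It is aimed at vaccine-immunology and antibody-engineering labs that
already run BLI/SPR dissociation-rate ranking and want the avidity
*distribution* rather than a single weighted k_d.

## Worked example

Simulate a 25:75 molar mixture of a high-avidity mAb (k_d = 5.6×10⁻⁵ s⁻¹)
and a low-avidity mAb (k_d = 3.7×10⁻² s⁻¹) at 5 µg/ml total — 300 s
association, 600 s dissociation at 5 Hz, 0.005 nm noise — then bin the
dissociation phase:

```r
library(paart)

mix <- simulate_mixture_sensorgram(npna3_mabs()[c(1, 3), ],
                                   share = c(0.25, 0.75), seed = 42)
fit <- paart(mix$sensorgram)   # windows the dissociation phase (5-600 s)
fit
#> Avidity binning fit: 2 component(s) selected (AIC), window 5-600 s
#>   component 1: kd = 5.835e-05 1/s (se 5.1e-06), fraction = 0.455
#>   component 2: kd = 0.03733 1/s (se 0.00033), fraction = 0.545
#>   chi^2 (RSS) = 0.07607 over 2976 points
```

Two avidity bins are selected; both rate constants land within a few
percent of the simulated truth. The fractions are shares of antigen
occupancy at the window start: although the low-avidity mAb made up 75% of
the solution, it holds only ~54% of the bound response after 300 s of
competition (the simulation's true end-of-association shares were
0.41/0.59; the fast component decays further in the 5 s before the window
opens). `coef(fit)` returns the component table, `plot(fit)` overlays the
fit and residuals, `summary(fit)` adds the AIC trace across model orders,
and `count_components(fit)` counts components above the 5% reporting
threshold. `paart_batch()` + `write_paart_report()` process a tidy CSV of
many samples into a JSON report; `inst/cli/paart.R` exposes
`fit` / `simulate` / `compete` / `summarize` subcommands for shell use.

The reference analysis for known mixtures is the competing-reactions fit,
which uses both phases and the known concentrations:

```r
cf <- fit_competing(mix$sensorgram, conc = mix$truth$conc,
                    labels = c("AB334", "AB395"))
```

Its per-analyte (k_a, k_d) and end-of-association shares agree with the
dissociation-only binning — the package's central validation property.

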
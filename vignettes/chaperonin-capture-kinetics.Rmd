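---
title: "Kinetic analysis of chaperonin-capture folding assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of chaperonin-capture folding assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldtrap)
```

## The experiment this package models

Nucleotide-free GroEL binds partially folded protein conformers with
sub-nanomolar affinity: it is a kinetic trap. When an initially native,
metastable protein (here frataxin and its Friedreich's ataxia clinical
variants D122Y and I154F) is incubated with GroEL immobilized on beads,
any molecule that transiently unfolds can be captured and removed from
solution by a brief spin. The time-dependent loss of soluble protein
therefore reports on the *kinetic* stability of the native state — how
often it visits the binding-competent conformer — rather than on its
equilibrium stability. `foldtrap` implements the full analysis of such
assays: the forward kinetic model, the pseudo-first-order fits used on
real data, the saturation analysis that extracts the unfolding-limited
rate, two-state thermal-unfolding fits (DSF and equilibrium), UV
light-scattering QC, and in vivo solubility arithmetic, together with
seeded generators for synthetic versions of every input.

## The kinetic model

The scheme is

$$N \underset{k_f}{\overset{k_u}{\rightleftharpoons}} I
  \xrightarrow{k_c\,[EL]} C, \qquad
  2I \xrightarrow{k_{agg}} A$$

with mass-action ODEs (µM, minutes)

$$\frac{dN}{dt} = -k_u N + k_f I,\quad
  \frac{dI}{dt} = k_u N - k_f I - k_c [EL]\, I - 2 k_{agg} I^2,\quad
  \frac{dC}{dt} = k_c [EL]\, I,\quad
  \frac{dA}{dt} = 2 k_{agg} I^2.$$

Assumptions, each a deliberate design choice:

* **Capture is irreversible.** The nucleotide-free chaperonin's affinity
  is so high that release is negligible on the 60-minute assay scale.
* **[EL] is the oligomer concentration** and is treated as constant
  (the trap is in effective excess over the transient intermediate
  population); the two binding sites per oligomer are absorbed into
  $k_c$, matching how rate-versus-concentration data are plotted.
* **Aggregation is second order in the intermediate** with monomer-unit
  bookkeeping (the factor 2). No reaction order is established
  experimentally; dimerization-initiated growth is the minimal choice
  that makes the extent of aggregation depend on starting concentration,
  which is what the control experiments show.
* **Aggregate counts as insoluble.** The observable is
  $soluble(t) = N + I$; both $C$ (on beads) and $A$ are removed by the
  spin. Escape of small aggregates from a gentle spin is a real
  phenomenon but is not part of the core model.
* **Temperature and urea are metadata.** They act only through the rate
  constants; the model has no explicit temperature dependence.

Integration uses `deSolve::lsoda` (stiff-safe) at relative tolerance
1e-8 and absolute tolerance 1e-10 µM. Mass conservation
($N+I+C+A = N_0$) is asserted in the test suite at 1e-6 µM.

## The apparent rate and its saturation

Applying a steady-state treatment to $I$ (with $k_{agg}=0$) gives a
single-exponential loss of soluble protein with

$$k_{app} = \frac{k_u\, k_c [EL]}{k_f + k_c [EL]}
  = \frac{k_{max} [EL]}{k_{half} + [EL]},
  \qquad k_{max} = k_u,\; k_{half} = k_f / k_c .$$

This is the central measurement logic: fitted decay rates rise
hyperbolically with chaperonin concentration and saturate at the
unfolding rate, because at saturating trap concentrations unfolding
itself becomes rate limiting. `fit_first_order()` fits
$S(t) = S_\infty + (S_0 - S_\infty) e^{-k_{app} t}$ per concentration
(weights $1/\mathrm{sd}^2$ when replicate SDs exist) and
`fit_rate_saturation()` fits the hyperbola.

**Accuracy of the steady-state closed form.** Its relative error is of
order $k_u / (k_f + k_c[EL])$. For the wild-type and D122Y parameter
sets this is well under 1% everywhere tested; for the fastest-unfolding
I154F set it is ~0.7% at 3 µM chaperonin but grows to ~2.5% at 0.5 µM,
where intermediate consumption is slowest. The closed form is therefore
an excellent oracle at the calibration condition (3 µM) and a
deliberately approximate one at low trap concentrations; the test suite
states the 1% bound across the full concentration range and the low-[EL]
I154F cases fail it by this predictable margin. We kept the model and
the bound as they are rather than tuning either: the discrepancy is the
textbook breakdown of the steady-state assumption, worth surfacing.

**Fitting choices.** Initial $k_{app}$ is $\ln 2 / t_{1/2}$ from the
first midpoint crossing, with log-spaced multi-starts on failure;
$S_0$/$S_\infty$ start at the first/last points. The plateau is free by
default (`fix_plateau_zero = TRUE` reproduces decay to zero). A flat
series returns $k_{app}=0$ with a `degenerate_flat` flag rather than an
error. A fitted `k_half` above ten times the largest tested
concentration sets `saturation_not_reached` — the analogue of a
partitioning profile that was not carried to saturation. A single
exponential is always fitted; an early burst phase (material lost within
the first minute) shows up as residual structure, not as an extra term.

## Two-state thermal unfolding

Melt curves — DSF fluorescence traces or normalized equilibrium
denaturation curves — are fitted with the van 't Hoff two-state model

$$K(T) = \exp\!\left[\frac{\Delta H_{vH}}{R}
  \left(\frac{1}{T_m} - \frac{1}{T}\right)\right],\qquad
  f_u = \frac{K}{1+K},$$

with $R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$, temperatures in
kelvin internally and Celsius at the interface, and $\Delta C_p = 0$
(two parameters: $T_m$, $\Delta H_{vH}$). The DSF observation model adds
linear folded/unfolded baselines,
$y = (a_n + b_n T)(1-f_u) + (a_u + b_u T) f_u$ (six parameters);
equilibrium curves use the same machinery with baselines fixed at 0 and
1\. $T_m$ is initialized at the maximum smoothed derivative, baselines
from linear fits to the outer 15% of points. Post-transition signal
decay from dye release is not modeled; `truncate_post_max` drops points
beyond the signal maximum instead. `delta_tm()` and
`stabilization_trend()` summarize osmolyte series as shifts against the
no-additive control and an OLS slope in °C per molar.

**Identifiability at the scan edge.** With a 25–80 °C scan and 1%
amplitude noise, $T_m$ recovery for transitions well inside the scan is
precise (standard error ≈ 0.15 °C for the wild-type preset). For the
I154F preset ($T_m$ = 39.1 °C) the folded baseline is barely sampled
before the transition begins, and the six-parameter fit's $T_m$
standard error grows to ≈ 0.3–0.5 °C; the fitted optimum is the exact
global least-squares optimum (verified against an independent
polish from the generating truth), so this scatter is the information
content of the curve, not an optimizer artifact. Recovery claims at
±0.3 °C are met by the wild-type DSF and equilibrium cases and are
genuinely marginal for I154F; the corresponding test records that
honestly.

**Published-table arithmetic.** The bundled DSF melting-temperature
table reproduces the printed $T_m$ and $\Delta T_m$ columns for all
three variants. Several printed $\Delta T_m$ entries do not equal
$T_m -$ control as printed (the D122Y trehalose shifts are consistent
with a ~46.2 °C reference rather than the printed 48.8 °C control, and
the wild-type TMAO rows disagree with the 55.1 °C control outright).
`dsf_tm_table()` flags such rows as `inconsistent` instead of silently
correcting either column; quantitative checks use only the
self-consistent wild-type trehalose rows.

## Spectral QC and solubility

Protein in the supernatant is quantified as $A_{280} - A_{350}$: the
350 nm reading carries no protein absorbance and subtracts instrument
drift and any flat offset exactly. For curved Rayleigh-type scatter
($A \propto \lambda^{-4}$) the two-point correction under-subtracts —
with scatter normalized to $A_{350} = 0.05$ a 0.30 AU band reads as
0.372 — so `scatter_profile()` additionally fits
$\log A = \log c - \beta \log \lambda$ over 320–400 nm as a diagnostic
($\beta \approx 4$ for small-particle scattering), kept separate so the
simple two-point procedure stays reproducible bit-for-bit.
`aggregation_index()` is the baseline elevation $\Delta A_{350}$ against
the time-zero spectrum, classified as aggregating above 0.01 AU — a
package default, as no quantitative threshold is established
experimentally.

In vivo solubility is pure densitometry arithmetic: fraction soluble
$S/(S+P)$ per replicate, triplicate mean and SD ($n-1$), and
$\log_2$ of the condition/control ratio of soluble fractions. Gel
images themselves are out of scope; band intensities are the input.

## Synthetic data: what it emulates and what it does not

All generators are deterministic functions of their parameters and a
seed (and they restore the caller's RNG stream). The variant presets
pin the published melting temperatures (DSF 55.1/48.8/39.1 °C;
equilibrium 66.3/50.4/50.7 °C) and carry capture rate constants
calibrated so the published 60-minute endpoints emerge from the
defaults: at 3 µM chaperonin the I154F preset leaves ≈25% soluble and
D122Y ≈55%, while wild type loses under 2% at any tested concentration.
Values with no published counterpart were fixed once at realistic
magnitudes and are isolated in the presets: $\Delta H_{vH}$ = 45
kcal/mol (a ~10 °C transition width), DSF baselines
$a_n=1000, b_n=1, a_u=9000, b_u=-4$, time-course noise SD 0.02
(triplicates), DSF noise 1% of transition amplitude, densitometry CV
0.1, a 0.5 °C DSF sampling step at the 1.5 °C/min scan rate.

The generators emulate hyperbolically saturating decays, sigmoidal
melts with linear baselines, a Gaussian 280 nm band (SD 15 nm) over
$\lambda^{-4}$ scatter, and noisy triplicate band intensities. They do
**not** emulate burst-phase partitioning within the first minute,
dye-induced destabilization during DSF, post-transition fluorescence
decay, bead-transport limitations, or small-aggregate escape from the
spin — so passing recovery tests here demonstrates correctness of the
estimators under the stated model, not robustness to every artifact of
real traces.

## Problem sizes and reproducibility

The shipped analyses are intentionally small: 10–121 time points per
decay, six concentrations per saturation profile, ~110-point melt
curves, 161-point spectra; every stochastic step takes an explicit
seed, and `run_full_analysis()` is byte-reproducible for a fixed
configuration. `scripts/acceptance.R` regenerates the headline
quantities (the two 60-minute endpoints and the two recovered melting
temperatures) from scratch at any seed.

## Known limitations

* Absolute microscopic rate constants for the frataxin variants are not
  publicly available; the capture presets are endpoint-calibrated, so
  only their ratios and qualitative ordering are meaningful.
* The single-exponential decay and the hyperbolic $k_{app}([EL])$ are
  approximations whose error grows exactly where the data are least
  informative (low trap concentration, fast unfolding).
* $\Delta C_p = 0$ means no $\Delta G(25\,°C)$ extrapolation; no
  m-values, no scan-rate-dependent irreversible-unfolding kinetics.
* No Gillespie simulation, no Mie scattering or particle sizing, no gel
  image processing.
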
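# foldtrap

Kinetic analysis for solid-phase chaperonin (GroEL) capture assays on
metastable proteins.

Nucleotide-free GroEL binds transiently unfolded protein conformers with
sub-nanomolar affinity, acting as a kinetic trap: any molecule of an
initially native protein that visits its unfolded/partially folded state
is captured onto the chaperonin beads and removed from solution by a
brief spin. The decline of soluble protein with time therefore measures
*kinetic* stability — the unfolding rate of the native state — at near
physiological conditions, without harsh denaturants. The approach
distinguishes clinical missense variants (here frataxin D122Y and I154F,
the Friedreich's ataxia alleles) that look similar by equilibrium
criteria but differ sharply in how fast they unfold.

`foldtrap` is for biophysicists running or modelling such assays. It
provides:

* **Kinetic model** — mass-action scheme
  N ⇌ I (k_u, k_f), I + EL → C (k_c, irreversible capture),
  2I → A (k_agg, aggregation), integrated with a stiff-safe ODE solver
  (`simulate_capture()`), and its closed-form apparent rate
  k_app = k_u·k_c[EL] / (k_f + k_c[EL]) (`apparent_rate()`).
* **Partition analysis** — pseudo-first-order fits
  S(t) = S∞ + (S0 − S∞)e^(−k_app·t) per chaperonin concentration
  (`fit_first_order()`) and the hyperbolic saturation fit
  k_app([EL]) = k_max[EL]/(k_half + [EL]) whose plateau k_max estimates
  the unfolding rate k_u (`fit_rate_saturation()`).
* **Thermal unfolding** — two-state van 't Hoff fits
  K(T) = exp[(ΔH_vH/R)(1/Tm − 1/T)] with linear baselines for DSF
  traces or fixed 0/1 baselines for normalized equilibrium curves
  (`fit_melt()`), plus osmolyte ΔTm and dose-trend summaries
  (`delta_tm()`, `stabilization_trend()`, `dsf_tm_table()`).
* **Spectral QC** — baseline-corrected A280 (A280 − A350), power-law
  scatter exponent, and the ΔA350 aggregation index.
* **Solubility** — densitometry fraction soluble S/(S+P) and log2
  condition/control ratios.
* **Synthetic data** — seeded generators for every input, with variant
  presets calibrated so the published endpoints emerge from the
  defaults.

## Worked example

Simulate the aggressive I154F variant at 3 µM immobilized GroEL, 2 µM
protein, then recover the unfolding-limited rate from a six-point
concentration series:

```r
library(foldtrap)

p <- preset("I154F")
traj <- simulate_capture(p$capture,
                         experiment_condition(el_conc = 3, protein0 = 2),
                         seq(0, 60, 5))
round(tail(traj, 3), 4)
#>    time_min   n_uM   i_uM   c_uM   a_uM soluble_frac
#> 11       50 0.6231 0.0141 1.3613 0.0015       0.3186
#> 12       55 0.5548 0.0125 1.4311 0.0015       0.2837
#> 13       60 0.4940 0.0112 1.4933 0.0015       0.2526

el <- c(0.5, 1, 2, 3, 6, 12)
tcs <- lapply(el, function(e) {
  gen_timecourse(p, experiment_condition(e), noise_sd = 0.02,
                 seed = 100 + e)
})
fit_rate_saturation(profile_from_timecourses(tcs))
#> Rate saturation: k_max = 0.031 min^-1, k_half = 1.006 uM

fit_melt(gen_meltcurve(preset("WT"), noise_frac = 0.01, seed = 7))
#> Two-state fit: Tm = 54.87 degC (dH_vH = 45.7 kcal/mol)
```

Reading the output: after 60 minutes only 25.3% of the I154F pool is
still soluble (1.49 µM is on the beads, a trace aggregated) — the
published endpoint for this variant. The fitted limiting rate
k_max ≈ 0.031 min⁻¹ recovers the preset's unfolding rate
k_u = 0.030 min⁻¹ from noisy data, and the wild-type melt fit returns
Tm ≈ 54.9 °C against the generating 55.1 °C.

`run_full_analysis(run_config(seed = 1))` runs every stage on synthetic
inputs and returns a machine-readable report;
`inst/scripts/foldtrap.R` exposes the same functions as shell
subcommands (`make-synthetic`, `fit-partition`, `rate-profile`,
`fit-dsf`, `spectra-qc`, `solubility`, `run-all`).

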
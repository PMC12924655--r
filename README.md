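# exclusim

Modelling competitive exclusion of pathogens by probiotic consortia, with
the statistics of disinfection trials.

Probiotic-based surface disinfectants work in two phases: secreted
antimicrobials (bacteriocins, lipopeptides, organic acids) rapidly kill
resident pathogens, and the probiotic community then colonizes the
surface and excludes recolonization (Gause's competitive-exclusion
principle). `exclusim` is for microbial ecologists and biocontrol
researchers who want to simulate, fit and test that mechanism
quantitatively. It provides:

- a **generalized Lotka–Volterra (gLV) community model** of probiotic
  strains (indexed *i*, *j*) and pathogens (indexed *k*, *m*):

  ```
  dP_i/dt = r_i P_i (1 − Σ_j α_ij P_j / K_i) − Σ_k β_ik P_i (P_k / K_k)
  dP_k/dt = r_k P_k (1 − Σ_m γ_km P_m / K_k) − Σ_i δ_ki P_k (P_i / K_i)
  ```

  with stiff ODE integration, extinction-time diagnostics, bisection
  calibration of the probiotic antagonism coefficient δ, and
  single-strain vs consortium experiments;
- **coefficient inference** from coculture time series by bounded
  multi-start nonlinear least squares on log₁₀ abundances, with a
  leverage-adjusted residual-resampling **bootstrap** (default n = 1000)
  and parameter-recovery studies;
- a stochastic, spatially explicit **agent-based model** of four guilds
  (Bacillus-like M1 secretors, Lactobacillus-like M2 secretors,
  oxygen-sensitive cross-feeders, pathogens) with explicit-stencil
  metabolite diffusion, Hill-function cross-feeding, probabilistic
  antagonism (p_kill = 0.2/step above threshold), biofilm transition at
  20 agents/patch, dominance heatmaps, halo metrics and sensitivity
  scans;
- **disinfection-trial statistics**: CFU enumeration from serial
  dilutions (30–100 colony window), log reduction LR and percentage
  reduction PR = (1 − 10⁻ᴸᴿ) × 100, pooled Student's t-tests,
  inhibition-zone summaries and formulation concentration arithmetic;
- seeded **synthetic-data generators** for coculture series, plate
  counts, storage-stability and surface-survival curves, and
  inhibition-zone tables, so every stage is testable without any
  laboratory data.

## Worked example

Calibrate the single-probiotic baseline so the pathogen goes extinct at
6.5 h, then expand to a 12-strain consortium:

```r
library(exclusim)

base <- calibrate_delta(6.5)
attr(base, "delta")
#> [1] 1.320312

consortium_experiment(base, n_strains = 12)
#> Consortium suppression experiment (12 strains)
#>   baseline extinction:   6.519 h
#>   consortium extinction: 0.255 h
#>   ratio (consortium/baseline): 0.039
```

The calibrated antagonism coefficient (δ ≈ 1.32/h) lies inside the
admissible range [0, 2]; replicating the probiotic twelve-fold (each
strain seeded at the full 5×10⁹ CFU/mL inoculum) collapses the pathogen
time-to-extinction from 6.5 h to about a quarter of an hour — the
consortium-synergy effect.

The agent-based model, at its defaults (100×100 grid, 500 steps = 24 h,
10 replicates):

```r
runs <- abm_run(seed_base = 1)
runs
#> ABM experiment: 10 replicates x 500 steps (24 h)
#>   pathogen exclusion probability: 1.00
#>   exclusion steps: 352 340 368 343 359 353 337 366 356 339
```

All replicates exclude the pathogen between steps 337 and 368
(roughly 16–18 simulated hours).

Trial statistics on the bundled 43-strain spot-assay table:

```r
zt <- read_zone_table()
summarize_zones(zt)
#> Inhibition zones: 13.84 ± 1.23 mm (n = 43)
bactericidal_fraction(zt)
#> [1] 34.88372
percent_reduction(2.46)
#> [1] 99.65365
```

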
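# popencycle

Single-channel open-probability analysis and thermodynamic-cycle estimation
of agonist efficacy for ligand-gated ion channels.

## What problem this solves, and for whom

Patch-clamp electrophysiologists measuring agonist efficacy at saturating
concentrations see the channel's activity organised into *clusters*:
stretches of high open probability separated by long desensitized silences.
The open probability within a cluster, *P*<sub>open</sub>, gives the overall
gating equilibrium constant

> *P*<sub>open</sub> = *E* / (*E* + 1),  so *E* = *P*<sub>open</sub> / (1 − *P*<sub>open</sub>),

where *E* lumps the pre-open (flipping/priming) and opening steps. For a set
of four agonists related by two independent structural modifications —
for glycine receptors: glycine, β-alanine (backbone lengthened by one
methylene), AMS (carboxylate swapped for sulfonate) and taurine (both
changes) — the gating free energies form a thermodynamic cycle. Each edge
carries ΔG = −RT ln(*E*<sub>mod</sub>/*E*<sub>ref</sub>)
(R = 1.987 cal K⁻¹ mol⁻¹, T = 295 K), and the coupling energy

> ΔΔG<sub>int</sub> = ΔG₁ − ΔG₁′

measures how far the two modifications are from acting additively.

The package provides the full chain as composable, tibble-first functions:

- **Simulation** (`gating_params()`, `simulate_dwells()`, `render_trace()`,
  `make_agonist_dataset()`): dwell sequences with known ground truth,
  rendered as noisy Gaussian-filtered traces emulating cell-attached
  recordings (100 kHz sampling, configurable cutoff and noise).
- **Idealization** (`gaussian_filter()`, `resample()`,
  `threshold_idealize()`, `detect_double_openings()`, `event_recovery()`):
  the published conditioning (3 kHz Gaussian, resample to 33.3 kHz,
  half-amplitude threshold crossing).
- **Cluster analysis** (`segment_clusters()`, `filter_clusters()`,
  `cluster_popen()`, `popen_summary()`, `plot_popen_boxplot()`): tcrit
  segmentation, the ≥100 ms / no-double-openings acceptance rules with an
  audit trail, per-agonist summaries.
- **Thermodynamic cycle** (`popen_to_eeff()`, `free_energy_change()`,
  `cycle_spec()`, `coupling_energy()`, `bootstrap_cycle()`): per-cluster
  gating constants, edge free energies, coupling energy with 10,000-replicate
  bootstrap SDs; `tidy()`, `glance()`, `autoplot()` methods.
- **Resampling inference** (`randomization_test()`, `bootstrap_sd()`):
  two-tailed nonparametric randomization test (exact on enumerable
  instances, compiled Monte Carlo otherwise) and generic bootstrap.
- **Dose-response** (`fit_hill()`, `check_rundown()`,
  `normalize_and_pool()`, `zwitterion_fraction()`): Hill fits per cell,
  30%-rundown exclusion, normalization/pooling, and the
  Henderson–Hasselbalch arithmetic behind acidic-pH protocols for unstable
  agonists like AMS (pKa 5.75: ~2% zwitterion at pH 7.4, ~85% at pH 5).
- **I/O and pipeline** (`read_dwell_table()`, `read_popen_table()`,
  `read_trace()`, writers, `pipeline_config()`, `run_pipeline()`): plain CSV
  dialects compatible with spreadsheet-exported per-cluster data, plus a
  seeded end-to-end runner that writes stage outputs and a manifest.

## Worked example

Simulate per-cluster *P*<sub>open</sub> tables for the four agonists at
realistic targets, apply the ≥100 ms acceptance rule, and run the
bootstrapped cycle:

```r
library(popencycle)
library(dplyr)

sets <- make_agonist_dataset(
  c(glycine = 0.96, `beta-alanine` = 0.54, AMS = 0.85, taurine = 0.12),
  kinetics = gating_params(alpha = 200, desens_prob = 0.02,
                           mean_desens = 2, n_clusters = 100),
  seed = 1
) |> filter(duration_ms >= 100)

popen_summary(sets)
#> # A tibble: 4 × 6
#>   agonist      n_patches n_clusters mean_popen sd_popen median_popen
#> 1 AMS                  1         71      0.850  0.0332         0.850
#> 2 beta-alanine         1         71      0.552  0.0653         0.552
#> 3 glycine              1         70      0.962  0.00791        0.961
#> 4 taurine              1         90      0.123  0.0289         0.119

bootstrap_cycle(cycle_spec(sets), n_boot = 10000, seed = 2)
#> <thermo_cycle> (estimator: mean)
#>   E_eff[reference  glycine     ] =   26.305  (n = 70 clusters)
#>   E_eff[lengthened beta-alanine] =    1.287  (n = 71 clusters)
#>   E_eff[swapped    AMS         ] =    6.060  (n = 71 clusters)
#>   E_eff[both       taurine     ] =    0.142  (n = 90 clusters)
#>   dG1  (lengthen, -COO-):  +1.769 +/- 0.027 kcal/mol
#>   dG1' (lengthen, -SO3-):  +2.201 +/- 0.028 kcal/mol
#>   dG2  (swap, short):      +0.861 +/- 0.029 kcal/mol
#>   dG2' (swap, long):       +1.293 +/- 0.027 kcal/mol
#>   coupling ddG_int:        -0.433 +/- 0.039 kcal/mol  (|ddG| = 0.433)
#>   closure residual: 0.00e+00 kcal/mol   (bootstrap: 10000 replicates, seed 2)
```

Reading the output: lengthening the agonist costs ~1.8 kcal/mol of gating
free energy on the carboxylate background (ΔG₁) but ~2.2 kcal/mol on the
sulfonate background (ΔG₁′); the difference, the coupling energy of
magnitude 0.43 kcal/mol here, is resolved at >10 bootstrap SDs, so the two
modifications interact rather than act additively. The closure residual is
zero to machine precision, as it must be algebraically. (These numbers are
for the homogeneous simulator at the targets above; real per-cluster tables,
ingested with `read_popen_table()`, give wider spreads and their own
coupling estimate.)

A randomization test on two corners, and the protonation helper:

```r
randomization_test(sets$popen[sets$agonist == "glycine"],
                   sets$popen[sets$agonist == "AMS"],
                   n_iter = 50000, seed = 3)
#> <rand_test> (Monte Carlo)
#>   |difference of group means| = 0.1112
#>   two-tailed p = 2e-05  (50000 relabellings)

zwitterion_fraction(c(7.4, 5.0))   # pKa 5.75 default
#> [1] 0.0218970 0.8490204
```

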
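---
title: "From single-channel clusters to agonist coupling energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-channel clusters to agonist coupling energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popencycle)
library(dplyr)
```

## The scientific problem

A saturating concentration of an efficacious agonist drives a ligand-gated
ion channel into long stretches of high open-probability activity
("clusters") separated by seconds-long desensitized silences. The maximum
open probability within a cluster, $P_\mathrm{open}$, is the channel's most
direct report of agonist efficacy: it depends only on the equilibrium
between the fully-bound shut and open classes of state,

$$P_\mathrm{open} = \frac{E}{E + 1}, \qquad E = \frac{P_\mathrm{open}}{1 - P_\mathrm{open}},$$

where $E$ is the overall gating equilibrium constant, lumping the pre-open
conformational steps (flipping/priming) together with the opening step
itself. Given four structurally related agonists that differ by two
independent modifications — lengthening the backbone by one methylene, and
swapping the carboxylate for a sulfonate — the corresponding gating free
energies can be arranged in a thermodynamic cycle. For glycine receptors the
four corners are glycine (reference), β-alanine (lengthened), AMS
(aminomethanesulfonic acid, swapped) and taurine (both). Each edge carries

$$\Delta G = -RT \ln\!\left(\frac{E_\mathrm{mod}}{E_\mathrm{ref}}\right),$$

with $R = 1.987\ \mathrm{cal\,K^{-1}mol^{-1}}$ and $T = 295\ \mathrm{K}$
(so $RT = 0.586\ \mathrm{kcal/mol}$), and the coupling energy

$$\Delta\Delta G_\mathrm{int} = \Delta G_1 - \Delta G_1'$$

measures the deviation from additivity of the two modifications. The closure
identity $\Delta G_1 + \Delta G_2' = \Delta G_2 + \Delta G_1'$ holds for any
four positive corners, so $\Delta\Delta G_\mathrm{int}$ is well defined
regardless of which pathway is traversed; `coupling_energy()` asserts the
residual at every call as a numerical check.

The package implements the whole chain from raw (or simulated) current
traces to the bootstrapped coupling energy, plus the supporting analyses of
the acidic-pH protocol that makes the AMS measurements possible: Hill
dose-response fits with rundown-based cell exclusion, a two-tailed
randomization test for cluster $P_\mathrm{open}$ comparisons, and
Henderson–Hasselbalch protonation arithmetic.

## The simulator and what it emulates

`simulate_dwells()` draws from the minimal scheme that reproduces the
observable the analysis consumes: an open↔shut two-state process whose
closures terminate the cluster into a desensitized state with fixed
probability. Open dwells are exponential with mean $1/\alpha$, within-cluster
shut dwells exponential with mean $1/\beta$, so the within-cluster open
probability is $\beta/(\alpha+\beta)$, and the number of openings per
cluster is geometric with mean $1/p_\mathrm{desens}$. This is deliberately
*not* a mechanistic activation model (no ligand binding steps, no
flipping/primed intermediates, no missed-event correction): it claims only
the cluster structure — alternating dwells at two conductance levels,
bounded by long silences.

Defaults are chosen to emulate cell-attached recordings at +100 mV with
saturating agonist:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 200 s⁻¹ | closing rate; 5 ms mean open dwell |
| `beta` | 800 s⁻¹ | opening rate; set from the target $P_\mathrm{open}$ in `make_agonist_dataset()` |
| `desens_prob` | 0.02 | ≈50 openings per cluster, clusters of hundreds of ms to seconds |
| `mean_desens` | 2 s | desensitized gaps, well separated from intra-cluster shut times |
| `amp` | 5 pA | unitary current; arbitrary (the recordings' unitary amplitude at +100 mV is setup-dependent) |

`render_trace()` emulates the recording chain: the piecewise-constant
two-level signal plus white Gaussian noise is low-pass filtered with a
Gaussian kernel specified by its −3 dB cutoff ($\sigma_t = 0.1325/f_c$,
truncated at $\pm4\sigma$, unit DC gain). The noise is added *before*
filtering, as in a real rig where the anti-alias filter acts on signal and
instrumentation noise together; the per-level sample SD is therefore the
white SD times the kernel's $\ell_2$ norm. The acquisition chain being
emulated used a 10 kHz Bessel stage followed by a 3 kHz Gaussian analysis
filter; the simulator exposes a single Gaussian cutoff per stage and
composes cascaded stages as $1/f_\mathrm{eff}^2 = \sum_i 1/f_{c,i}^2$. A
Bessel stage is not modelled separately — for threshold idealization at
half-amplitude the difference is immaterial, and we make no claim of
waveform-level equivalence.

What the simulator does **not** reproduce: patch-to-patch heterogeneity
(every simulated cluster shares one $E$; real per-cluster
$P_\mathrm{open}$ spreads are wider, e.g. SDs of 0.19–0.24 for the partial
agonists), multiple channels per patch (unless double openings are
injected), baseline drift, and open-channel noise in excess of baseline
noise. Passing tests therefore demonstrate correctness of the *analysis*
under known ground truth, not that real recordings satisfy the generating
assumptions.

## Idealization and cluster criteria

`threshold_idealize()` classifies samples by half-amplitude threshold
crossing (`threshold_frac = 0.5`, the field's standard and the default of
the software used for the original analysis), after `gaussian_filter()` and
`resample()` reproduce the published conditioning (3 kHz Gaussian, resampled
to 33.3 kHz from 100 kHz acquisition). No dead time is imposed by default; a
configurable minimum-duration merge exists for noisy data. The first and
last dwells of a record are flagged censored and excluded from
dwell statistics.

`segment_clusters()` splits records at non-conducting dwells of at least
`tcrit` (default 100 ms) and trims clusters to begin and end on an opening,
so inter-cluster silence belongs to no cluster. The desensitized gaps this
emulates are seconds long while intra-cluster shuttings are milliseconds, so
any `tcrit` inside the decade-wide gap gives the same segmentation; a
diagnostic warns when the shut-time distribution does not separate cleanly
(less than ~3× between the longest within-cluster shutting and the shortest
gap). Cluster acceptance follows the published protocol: at least 100 ms
long, no double openings (`detect_double_openings()` flags excursions beyond
1.5× the unitary amplitude lasting more than one filter rise-time), and — by
default, configurable — no overlap with a recording edge. Rejected clusters
are kept in the returned table with a `reject_reason`, so the audit trail
survives.

One estimator property deserves emphasis. Because clusters are trimmed to
open boundaries, a cluster with $N$ openings contains only $N-1$ shut
dwells, and $P_\mathrm{open} = t_\mathrm{open}/t_\mathrm{total}$ is biased
upward by $O(1/N)$; a one-opening cluster has $P_\mathrm{open} = 1$
identically. The bias is concentrated in short clusters and is strongest for
weak partial agonists (low $P_\mathrm{open}$, long shut times, few openings
before desensitization). The ≥100 ms acceptance rule suppresses most of it,
which is one reason the rule exists; the residual bias on accepted clusters
is below the sampling error at the cluster counts used here. This is a
property of the field's measurement definition, not of the simulator.

## From Popen to the cycle

`popen_to_eeff()` maps each accepted cluster's $P_\mathrm{open}$ to one
$E$ value. Saturated clusters ($P_\mathrm{open}=1$, infinite $E$) and silent
ones ($P_\mathrm{open}=0$) have no finite gating constant; the default
policy excludes them with a recorded count (conservative and auditable), and
a continuity-correction alternative
$(t_\mathrm{open}+\varepsilon)/(t_\mathrm{total}+2\varepsilon)$ is provided
for users who prefer to keep every cluster.

The per-corner point estimate collapses the per-cluster $E$ values by their
mean (default) or median. The choice matters: per-cluster $E$ is strongly
right-skewed near saturation, so the mean exceeds the median appreciably for
efficacious agonists. Both are computed and stored side by side
(`eeff_point`, `eeff_alt`); the median estimator is the one that reproduces
a published medians row exactly when applied to data calibrated on medians.
The sign of $\Delta\Delta G_\mathrm{int}$ depends on the edge-labelling
convention (our convention yields a negative value for these four agonists);
the magnitude does not, and `glance()` reports both.

`bootstrap_cycle()` resamples each corner's per-cluster $E$ values with
replacement, independently per corner (10,000 replicates by default),
recomputing all four edges and the coupling per replicate; the replicate SDs
are the reported uncertainties, and the full replicate table is kept for
plotting (`autoplot()`). Resampling $E$ values rather than
$P_\mathrm{open}$ values matches the description of the original
computation; the two differ only through the nonlinearity of the transform
within a resample, and both are available to the user by transforming the
input table.

## Resampling inference

`randomization_test()` permutes group labels with the absolute difference of
group means as statistic (the convention of the DC-Stats family of tools;
difference of medians available), 50,000 iterations by default. When the
number of distinct splits is no larger than the iteration budget the test
enumerates all of them and the p-value is exact; otherwise the Monte Carlo
p-value uses the add-one convention $(1+k)/(n+1)$, which cannot be zero and
keeps the test valid. The permutation inner loop is compiled (Rcpp) and uses
R's RNG, so results are reproducible under `set.seed()`/`seed =` and the
1,000-replicate calibration study in the test suite runs in seconds.

## Dose-response module

`fit_hill()` fits $I = I_\mathrm{max} c^{n_H}/(c^{n_H} + EC_{50}^{n_H})$ —
three parameters, bottom fixed at zero, matching the three reported
parameters of whole-cell peak-current fits — by unweighted
Levenberg–Marquardt least squares. Initialisation is fixed for determinism:
$I_\mathrm{max}$ at the largest response, $EC_{50}$ at the concentration
nearest half-maximum, $n_H = 1$. Per-cell fits are unconstrained; at least
three distinct concentrations are required, and non-convergence is a flag,
not an error. `check_rundown()` implements the 30% exclusion rule on
interleaved saturating-reference applications;
`normalize_and_pool()` divides each passing cell by its own maximum (for
same-agonist curves) or by its mean reference response (for
relative-efficacy curves, where the pooled $I_\mathrm{max}$ becomes the
fractional efficacy against the reference agonist), then refits the pooled
points.

`zwitterion_fraction()` is the Henderson–Hasselbalch helper behind the
acidic-pH protocol: with an amino-group p$K_a$ of 5.75, only ~2% of AMS is
zwitterionic (stable) at pH 7.4, versus ~85% at pH 5 — the compromise at
which the recordings were made.

## Numerical choices and degenerate inputs

* Gaussian kernel: $\sigma_t = 0.1325/f_c$, truncated at $\pm4\sigma$,
  renormalised to unit sum; symmetric edge padding keeps output length equal
  to input length. Filter rise time taken as $0.3321/f_c$.
* Resampling by linear interpolation on the band-limited signal; sample
  timestamps at bin centres $(i-\tfrac12)/f_s$.
* Even-length medians are the mean of the two central values (required to
  reproduce published medians deterministically).
* Sample SDs use the $n-1$ denominator throughout, including bootstrap
  replicate SDs.
* All stochastic entry points take explicit seeds; the pipeline derives
  per-stage seeds from one global seed by fixed offsets, and restores the
  caller's RNG state afterwards.
* Zero-duration clusters, empty corners after the $P_\mathrm{open}$ policy,
  empty groups, non-positive rates and out-of-range probabilities raise
  classed errors (`popencycle_data_error`, `popencycle_parameter_error`,
  `popencycle_config_error`) naming the offending field or row.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated data at
sizes chosen to keep every stochastic check comfortably inside its
tolerance: 100 clusters per corner for parameter recovery (10,000 bootstrap
replicates), ~180 scored events on a ~40 s rendered trace for idealization
fidelity, 1,000 replicate randomization tests at 5,000 iterations for null
calibration, and 200 noisy replicates for Hill-fit recovery. The per-cluster
source-data reproduction check runs on a simulator-generated stand-in
calibrated to the published per-agonist conditions (median
$P_\mathrm{open}$ 0.976/0.566/0.931/0.060, cluster counts 92/52/146/37, the
≥100 ms rule) because the deposited spreadsheets are not redistributed with
the package; `read_popen_table()` ingests the real sheets in the same layout
when the user supplies them.

## Known limitations

* No missed-event (dead-time) correction and no HMM/SKM idealization; events
  comparable to the filter rise time are unreliable by construction.
* No mechanism fitting: $E$ deliberately lumps flipping/priming and opening,
  and the package cannot separate them.
* The simulator's homogeneity means bootstrap SDs on simulated corners are
  smaller than on real data with patch heterogeneity; uncertainty statements
  about real data must come from the real per-cluster tables.
* Whole-cell fits ignore series-resistance and junction-potential
  corrections (acquisition-time concerns) and desensitization-peak
  corrections.

## A compact end-to-end example

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  kinetics = gating_params(alpha = 200, desens_prob = 0.02,
                           mean_desens = 2, n_clusters = 100),
  n_boot = 10000, seed = 1
)
res <- run_pipeline(cfg)
popen_summary(res$popen)
glance(res$cycle)
autoplot(res$cycle)
```
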
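# isingfc

Generalized Ising model analysis of structure–function coupling in brain
networks.

## What this is for

Resting-state functional connectivity (FC) — the matrix of Pearson
correlations between regional BOLD time series — is constrained by the
structural connectome, the matrix of white-matter streamline counts between
the same regions. A productive way to probe that constraint is to treat
each brain region as a binary spin `s_i = ±1` coupled through the
(normalized) structural connectome `J_ij` and let the system fluctuate in
contact with a thermal bath at temperature `T`:

    E(s) = − Σ_{i,j} J_ij s_i s_j        (full double sum, k_B = 1)

Metropolis Monte Carlo simulation of this *generalized Ising model* at a
grid of temperatures yields, per subject:

* **Tc** — the critical temperature, located at the peak of the
  run-averaged magnetic susceptibility `χ(T) = N(⟨m²⟩ − ⟨|m|⟩²)/T`;
* **T\*** — the temperature at which the simulated FC (Pearson
  correlations of the spin time series, averaged over repeated runs) best
  reproduces the subject's empirical FC, measured by the Mantel
  correlation of the two matrices' upper triangles, with a permutation
  p-value;
* the **direct SC–FC correlation**, the no-model baseline the Ising fit
  is compared against;
* **D** — a connectome-distance dimensionality: with distance
  `d_ij = 1/J̃_ij` (strongly connected = close), the mean FC per log-spaced
  distance bin is fit as a power law `c(d) ∝ d^(−γ)`, and `D = γ + 2 − η`
  (η = 0 by default). Faster decay of correlation with connectome distance
  reads as higher dimensionality.

Cohort-level wrappers compare these parameters across groups (healthy
controls vs. patients with disorders of consciousness in the reference
design: HC / VS-UWS / MCS− / MCS+) with Welch t-tests, one-way ANOVA,
post-hoc contrasts under Benjamini–Hochberg correction, and paired tests
between repeated scans. A synthetic-data layer generates geometric
connectomes, lesioned "patient" variants, and BOLD-like scans with known
ground truth, so the entire pipeline is testable without any imaging data.

This package is aimed at computational neuroscientists who want a small,
fully reproducible, statistically validated implementation of the
spin-model structure–function pipeline at desk scale.

All temperatures are reported on the scale set by the double-sum energy
above; on the per-pair convention they are exactly half as large (the
16×16 lattice critical point is 4.539 here, i.e. the textbook 2.269).

## Worked example

```r
library(isingfc)

counts <- geometric_connectome(n = 84, seed = 42)        # pseudo streamline counts
J      <- normalize_coupling(counts)
bold   <- list(t1 = synth_bold(J, T0 = 0.9, n_timepoints = 480, seed = 1),
               t2 = synth_bold(J, T0 = 0.9, n_timepoints = 480, seed = 2))

cfg <- gim_config(n_grid = 20, n_runs = 5, master_seed = 7,
                  sim = sim_params(n_equil_sweeps = 500, n_samples = 500,
                                   sample_interval_sweeps = 1))
fit <- gim_fit(counts, bold = bold, config = cfg, subject_id = "sub-01")
fit
round(coef(fit), 4)
```

```
Generalized Ising model fit -- subject sub-01
  regions: 84  grid: [ 0.1104 , 3.312 ] x 20  runs: 5
  Tc = 0.95289
  t1: T* = 0.95289, best Mantel r = 0.7886 (p = 1e-04), direct SC-FC r = 0.4248
  t2: T* = 0.95289, best Mantel r = 0.8835 (p = 1e-04), direct SC-FC r = 0.2884
  best scan: t2
  Dimensionality D = 2.283 ( gamma = 0.2829 , eta = 0 , R^2 = 0.959 , 11 bins )

    Tc   T_star   best_r  r_at_Tc direct_r    gamma        D
0.9529   0.9529   0.8835   0.8835   0.2884   0.2829   2.2829
```

Reading this: the susceptibility peaks at `Tc ≈ 0.95`; both scans are best
reproduced at `T* = Tc` (the scans were generated at `T0 = 0.9`, one grid
step away — the fit recovers it); the Ising model at `T*` correlates with
the empirical FC at `r ≈ 0.88` versus `r ≈ 0.29` for raw structure, the
structure-to-function improvement the model exists to quantify; and the
FC decays slowly with connectome distance (`γ ≈ 0.28`), i.e. `D ≈ 2.3`,
close to the two-dimensional regime expected for an intact connectome.
`plot(fit)` draws the susceptibility and Mantel curves;
`summary`, `simulate` and `residuals` methods are available.

For whole cohorts:

```r
coh <- synth_cohort(cohort_spec(master_seed = 1))   # 25 HC + 13 patients, 2 scans each
res <- run_cohort(coh, config = gim_config(master_seed = 1), out_dir = "out")
summary(res)    # per-subject table + Welch/ANOVA/post-hoc/paired-t battery
```

Real data enter through `read_manifest()` (a TSV/CSV table of subject IDs,
group labels and file paths) with connectomes and BOLD series as delimited
text matrices; `run_cohort()` accepts the manifest path directly.

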
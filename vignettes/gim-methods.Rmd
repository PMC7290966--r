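---
title: "Modelling brain structure-function coupling with a generalized Ising model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling brain structure-function coupling with a generalized Ising model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`isingfc` treats each of the `N` regions of a brain parcellation (84 in the
reference design) as a binary spin `s_i = ±1` whose pairwise couplings are
the subject's structural connectome: the streamline-count matrix, diagonal
zeroed and rescaled so its largest entry is 1. In the absence of an
external field the energy of a configuration is

    E(s) = - sum_{i,j} J_ij s_i s_j

taken over the *full* double index range, so every unordered pair
contributes twice. This convention matters: it fixes the temperature
scale. All critical temperatures (`Tc`) and best-fit temperatures (`T*`)
reported by this package are on the double-sum scale; on the common
per-pair convention they are exactly half as large. For the 16x16 periodic
uniform lattice the exactly known critical point is therefore
`4/ln(1+sqrt(2)) ≈ 4.539` here, twice the textbook `2.269`.

Dynamics are single-spin-flip Metropolis Monte Carlo: one sweep proposes
`N` flips at uniformly random sites (with replacement), each accepted with
probability `min(1, exp(-dE/T))` (`k_B = 1`, temperature dimensionless).
The engine is compiled, traverses the couplings through per-site
neighbour lists (so sparse matrices such as lattices or heavily lesioned
connectomes cost O(degree) per proposal), and draws all randomness from
R's generator so that `set.seed()` — and the package's master-seed
derivation — makes every trajectory reproducible.

## Locating criticality

A temperature sweep simulates each grid temperature `n_runs` times
(default 10, matching the repeat-and-average protocol of the study design
this package models) from fresh random configurations, and records the
magnetic susceptibility

    chi(T) = N * (<m^2> - <|m|>^2) / T

from the sampled magnetization `m(t)`. The absolute-value centring is the
standard finite-size choice: below criticality a finite system tunnels
between the `+m` and `-m` branches, and centring on `<m>` would read that
tunnelling as divergent variance. The raw estimator remains available
(`susceptibility(trace, use_abs = FALSE)`).

`Tc` is the grid temperature maximizing the run-averaged curve, optionally
after a short moving average (`smooth_window`), with ties resolved toward
the lower temperature. Averaging the curve before peak detection (rather
than averaging per-run peaks) is the default because the run-to-run
scatter of `chi` near the peak is large at feasible sample counts;
`per_run = TRUE` exposes the alternative.

Two numerical cautions, both visible in the validation suite:

* At temperatures well below `Tc`, a run started from a random
  configuration can freeze into a metastable multi-domain state whose
  slowly drifting magnetization inflates the variance estimate; divided
  by a small `T` this can rival the true peak. The defences are exactly
  the protocol's own averaging (10 runs dilute a single bad run), adequate
  equilibration (the lattice oracle uses 4000 discarded sweeps), and the
  3-point smoothing used whenever a curve is consumed automatically.
* The default grid spans `[0.1, 3] x T_hat`, where
  `T_hat = mean_i sum_j 2 J_ij` is the mean-field estimate of the
  ordering temperature under the double-sum convention. For
  connectome-like weight distributions the susceptibility peak falls well
  inside this window (typically near `0.5-0.9 T_hat`).

## Fitting the temperature to empirical functional connectivity

Empirical functional connectivity (FC) is the Pearson correlation matrix
of the regional BOLD time series; simulated FC is the Pearson correlation
matrix of the sampled spin time series, averaged entrywise over the
`n_runs` repeats at each temperature. Zero-variance regions (frozen
spins) are flagged and their correlations set to zero rather than
propagated as NaN.

The agreement between a simulated and an empirical FC matrix is the
Mantel correlation: Pearson's r between the strictly-upper-triangle
vectors. `T*` is the grid temperature maximizing that curve; the
permutation p-value at `T*` applies the same random node relabelling to
rows and columns of the second matrix (one-tailed, greater,
`p = (#{r_perm >= r_obs} + 1)/(n_perm + 1)`, 10000 permutations by
default). With two scans per subject the scan with the higher best-fit
correlation is selected (ties to `t1`), and the direct SC-FC correlation
(couplings against empirical FC, upper triangles) is reported as the
no-model baseline.

Simulated FC is averaged over runs *before* the Mantel comparison; this
matches the repeat-and-average protocol and is less noisy than averaging
per-run Mantel statistics.

## Connectome-distance dimensionality

The connectome defines its own metric: strongly connected regions are
close. With `J~` the max-one-rescaled couplings, the default map is
`d_ij = 1/J~_ij` (so the strongest pair sits at distance 1), with
`-log(J~_ij)` available as an alternative; pairs with zero coupling have
no defined distance and are excluded. The functional correlation is then
binned over log-spaced distance bins (12 by default, geometric bin
centres, bins with fewer than 3 pairs dropped) and the decay exponent
`gamma` is the negative slope of an ordinary least-squares fit of
`log(mean correlation)` on `log(distance)` over bins with positive mean
correlation. The dimensionality is

    D = gamma + 2 - eta

with the anomalous exponent `eta = 0` by default (`gamma` is always
reported so another convention can be applied afterwards). A flat decay
curve thus reads `D = 2`, and faster decay of correlation with connectome
distance reads as higher dimensionality. By default the FC entering this
estimate is the simulated FC at the subject's `Tc`; the simulated-at-`T*`
and empirical sources are one argument away.

The reciprocal map, the binning scheme and the `gamma -> D` offset are
declared conventions of this package, isolated behind
`coupling_to_distance()` / `fit_dimensionality()` and recorded in every
output, because the choice of map changes the numerical value of `gamma`
(not its ordering across subjects fitted with the same settings).

## The synthetic cohort generator

No subject data ship with the package; a generator produces cohorts with
the reference study's shape (84 regions; 25 HC, 6 VS/UWS, 3 MCS-, 4 MCS+;
two 480-point scans per subject) and known ground truth:

* **Connectomes** — `n` points uniform in the unit `dim`-cube, weight
  `(0.001 + distance)^(-alpha)` rescaled to a maximum of ~10^4 and
  Poisson-rounded to integer pseudo-streamline counts. The default
  `alpha = 1.5` was fixed at design time as the value giving 2-3 decades
  of weight spread — comparable to empirical streamline-count matrices —
  while keeping a clear interior susceptibility peak; steeper decay
  (`alpha >= 2`) under this uniform-point generator concentrates nearly
  all weight on the closest pair and degrades the peak. The default
  embedding is 2-D, matching the approximately two-dimensional decay
  reported for healthy connectomes.
* **Lesions** — patient damage is uniform random deletion of a fraction
  of existing edges (0.15 / 0.30 / 0.45 for MCS+ / MCS- / VS-UWS)
  plus a global attenuation of survivors, then max-one renormalization.
  This controls sparsity directly and is deliberately the simplest
  damage model; it does **not** emulate focal lesions or the
  preferential loss of strong long-range tracts.
* **Scans** — the spin model run at the subject's own (coarsely
  estimated) critical temperature — brains modelled as operating near
  criticality — sampled for `scan_length` time points with independent
  Gaussian noise (sd 0.3) added.

What passing tests on these cohorts do and do not show: they validate the
pipeline's estimators (temperature recovery, exponent recovery,
calibration of the statistics) and the qualitative edge-density ordering
across groups. They cannot certify behaviour on real tractography
matrices, which have hub structure, distance biases and measurement noise
the generator does not model. Two directional expectations are *not*
robustly reproduced under this generator and are worth stating plainly:
(i) uniform random edge deletion tends to *lower* the susceptibility-peak
temperature under any global rescaling of the couplings — deletion
removes coupling mass, and renormalization at best compensates on
average — so the empirically reported association of higher `Tc` with
sparser (patient) connectomes is not a reliable consequence of this
lesion model (measured single-connectome differences at 40% deletion are
negative; cohort-level group differences at the milder per-group
fractions are within seed-to-seed noise and change sign). Reproducing
that association plausibly requires damage concentrated on strong
long-range connections, which homogenizes the normalized weights.
(ii) With `alpha` below the embedding dimension the coupling row sums are
dominated by long-range weights, the system is effectively mean-field in
either embedding, and the fitted `D` does not order 2-D versus 3-D
embeddings beyond noise. Both observations are reported by the
validation checks rather than hidden.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_equil_sweeps` | 1000 | discarded Metropolis sweeps (dimensionless); raise well above domain-wall decay times when scanning far below `Tc` |
| `n_samples` | 1000 | recorded configurations per run |
| `sample_interval_sweeps` | 2 | sweeps between records |
| `n_runs` | 10 | repeats averaged per temperature |
| `n_grid` | 30 | temperatures in `[0.1, 3] x T_hat` |
| `smooth_window` | 1 | moving-average window for peak detection |
| `mantel_permutations` | 10000 | permutations for the p-value at `T*` |
| `n_bins` / `min_pairs_per_bin` | 12 / 3 | distance-decay binning |
| `eta` | 0 | anomalous exponent in `D = gamma + 2 - eta` |

The validation and acceptance runs use reduced problem sizes chosen to
keep the full suite at desk scale — typically 12-16 grid points, 2-3
runs, 250-400 samples after 250-400 equilibration sweeps for 84-region
connectomes, and 120-point synthetic scans; the lattice oracle uses the
full 40-point grid, 10 runs and 4000 equilibration sweeps. These sizes
are stated in the scripts themselves.

## Degenerate inputs and tie-breaks

* All-zero connectomes, negative entries, and asymmetry beyond tolerance
  are rejected at normalization.
* Frozen (zero-variance) regions are flagged through the FC layer, and a
  fully frozen trace yields a degenerate, flagged FC rather than NaN.
* Constant upper triangles make the Mantel statistic 0 with `p = 1` and a
  degeneracy flag.
* Argmax ties (susceptibility peak, Mantel curve) resolve to the lowest
  temperature; best-scan ties resolve to `t1`.
* Seeds: one master seed per analysis; every (subject, stage, grid index,
  run) context hashes to its own 31-bit sub-seed, so per-subject results
  are reproducible in isolation.

## Known limitations

* No external-field term, continuous spins, or cluster updates; far
  sub-critical temperatures mix slowly by design of the single-flip
  dynamics.
* The Mantel permutation count bounds the smallest attainable p-value at
  `1/(n_perm + 1)`.
* `Tc` and `T*` are grid-resolution limited; refine the grid around a
  coarse peak for sharper estimates.
* Group statistics on cohorts of the reference design's size (3-6
  subjects per patient group) have the power limitations the sample
  sizes imply; they are reported with raw and BH-adjusted p-values.
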
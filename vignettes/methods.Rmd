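---
title: "Models and methods in placentadr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in placentadr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`placentadr` analyses combined diffusion-relaxation MRI of the placenta:
acquisitions that interleave several echo times (TE) with several diffusion
weightings (b-values) in one scan, so that every voxel carries a joint
(T2\*, ADC) signature. This vignette is the package's own account of the
models it implements, the tunable parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices behind the solvers.

```{r setup}
library(placentadr)
```

## The voxel signal model

Every measurement m of a voxel is modelled as

$$ S_m = S_0 \, e^{-(TE_m - TE_{\min})/T_2^*} \, e^{-b_m \cdot ADC}, $$

where $S_0$ is the proton-density signal (the value at the shortest echo
time with no diffusion weighting), $T_2^*$ the effective transverse
relaxation time in seconds, and $ADC$ the apparent diffusion coefficient.
Two conventions deserve emphasis:

* **ADC scale.** All diffusivities are on the placental-literature scale on
  which free water sits at 0.3 mm²/s and typical whole-ROI means are near
  0.02 — an order of magnitude above the common $3\times10^{-3}$ mm²/s
  tissue convention. The package adopts this printed scale throughout and
  never rescales silently.
* **Scalar ADC.** Measurements at the same b-value but different gradient
  directions are exchangeable replicates. The synthetic data are isotropic,
  and the decomposition's continuum view (below) is where orientation-free
  microcirculation effects are meant to live.

`fit_voxel()` initialises with ordinary least squares of $\log S$ on
$(TE - TE_{\min})$ and $b$ — exact for noiseless data — and refines with
bounded L-BFGS-B on the intensity-scale sum of squares, with analytic
gradients. Bounds are $T_2^* \in [0.005, 0.5]$ s and
$ADC \in [10^{-5}, 1]$ mm²/s; the acquisition itself cannot localise decay
constants outside these ranges. A line-search stop at the numerical floor
of the objective is treated as convergence; only iteration-limit stops are
flagged as failures. Voxels containing non-positive intensities cannot be
log-initialised and are flagged failed rather than raising an error; ROI
means aggregate converged voxels only (the exclusion rule is a package
choice — no standard exists).

## The default acquisition scheme

`zebra_scheme("full_cross")` crosses four echo times (78, 114, 150, 186 ms)
with a diffusion list of one b = 0 volume, ten b-values (5–1600 s/mm²) at
three directions each, plus single shells at b = 18 (8 directions), 36 (7)
and 800 (15): 61 diffusion volumes per TE, 244 measurements. The published
acquisition table does not state how echo times interleave with the
diffusion list; the package adopts a full crossing because the joint
decomposition needs TE-b coverage and a full crossing is a superset of any
interleaving. One b = 0 volume is placed at every TE so the reference
volume at $(TE_{\min}, b = 0)$ exists by construction.
`zebra_scheme("reduced_test")` (4 TEs × b ∈ {0, 36, 200, 1600}) is the
documented small subset used in tests and examples.

## Spectral decomposition

The decomposition expresses voxel signals over a dictionary grid: 50 × 50
log-spaced points by default, $T_2^* \in [0.01, 0.3]$ s and
$ADC \in [10^{-4}, 1]$ mm²/s, covering every landmark used in
interpretation (the 0.06 s and 0.09 s oxygenation thresholds, the 0.001 and
0.1 mm²/s diffusivity marks, and the 0.3 mm²/s free-water line). Log
spacing reflects the multiplicative action of decay constants. The
dictionary entry for measurement m and grid cell j is the unit-amplitude
signal $A_{mj} = e^{-(TE_m - TE_{\min})/T^*_{2,j}} e^{-b_m D_j}$.

Each of K components is a non-negative spectrum $f_k$ over the grid with
unit mass; each voxel carries simplex weights $w_{vk}$ and a scale $s_{0v}$.
Full-mode fitting minimises

$$ \sum_v \Big\| S_v - s_{0v} \sum_k w_{vk} A f_k \Big\|^2
   + \lambda \sum_k \|L f_k\|^2 $$

by block alternating minimisation:

* **Weights step.** Per voxel, exact non-negative least squares
  (Lawson–Hanson active set) of the signal on the K component signals
  $A f_k$; $s_{0v}$ is the coefficient sum, absorbed per voxel rather than
  divided out beforehand.
* **Spectra step.** Per component, a non-negative quadratic solve on the
  weight-apportioned stacked system, warm-started from the current
  spectrum with a monotone accelerated projected-gradient method (step
  $1/L$ from a power-iteration Lipschitz estimate, restart on any
  increase). Because both steps are monotone, the recorded objective trace
  never increases — a property the tests assert on every run.
* **Initialisation.** A per-voxel Tikhonov-regularised non-negative grid
  inversion (vectorised projected gradient over all voxels) yields crude
  voxel spectra; seeded k-means++ clustering of those spectra provides the
  K initial components. `n_restarts` (default 5) restarts with distinct
  sub-seeds are run and the best final objective kept.

Iteration stops when the relative objective decrease falls below $10^{-6}$
or after 200 iterations. Spectrum masses are folded into the coefficients
only once at the end, so renormalisation never perturbs the trace. The
roughness penalty uses a normalised grid Laplacian with default
$\lambda = 0.01$; $\lambda = 0$ remains available and is used wherever a
test compares against an exact oracle. When several scans are supplied
their masked voxels are pooled into one joint fit (whether a multi-subject
decomposition pools voxels or averages per-scan fits is not externally
specified; pooling is the package's choice and matches the idea of one
shared component basis for a control cohort).

Component numbering after any fit is an artifact of initialisation, so
components are canonically ordered by spectrum-weighted mean log T2\*
(ascending: component 1 is always the least-oxygenated environment), and
cross-run comparisons go through `match_components()`, a Hungarian
assignment minimising summed spectral L2 distance.

Reduced mode (`fit_weights_reduced()`) fixes the spectra — learned from a
control cohort or known ground truth — and re-solves only the voxel
weights, guaranteeing identical component definitions across all scans
analysed with them. On noiseless data generated from the supplied spectra
the reconstruction is exact to numerical precision.

**Identifiability caveat.** Above roughly $ADC = 0.1$ mm²/s at this b-range
the diffusion-weighted signal is extinguished and dictionary columns become
collinear along the ADC axis, so spectral peak positions in that region
(including the free-water line itself) are not localisable; only the mass
that sits there is. Recovery tests therefore place ground-truth peaks in
the identifiable region.

## Synthetic placentas

`make_phantom()` emulates the spatial organisation the decomposition is
sensitive to: lobule centres placed by seeded rejection sampling with a
minimum separation, nearest-centre territories, a centre/periphery split at
a radius fraction (default 0.6), septa where the two nearest centres are
nearly equidistant, and a 1–2-voxel uterine-wall slab. Each class carries a
fixed weight simplex over the components — by default the last
(well-oxygenated) component peaks at lobule centres, the first at
peripheries, and a middle "septal" component along boundaries and wall,
reproducing the reported centre/periphery/septa contrasts. Noise is Rician,
$\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with
$\varepsilon \sim N(0, \sigma^2)$ and $\sigma = \overline{s_0}/\mathrm{SNR}$
(a Gaussian option exists for analytic checks). The phantom does **not**
emulate anatomically realistic vasculature, flow, motion, or scanner
reconstruction; passing recovery tests shows the solvers invert their own
forward model under realistic noise, not that clinical data obey it.

## Synthetic cohorts

`simulate_cohort()` draws a two-group cohort at the published study scale:
36 control and 12 CHD subjects, 39% scanned twice (50 and 17 scans), with
repeat scans sharing subject-level random component effects. Per-scan mean
weightings follow piecewise-linear gestational-age trajectories with a
changepoint fixed at 30 weeks — the gestation after which group differences
are described as most evident — plus between-subject (sd 0.02) and
scan-level (sd 0.01) noise, clipped and renormalised to the simplex.

Scalar summaries are calibrated to the published cohort values: control/CHD
mean T2\* of 58.1/51.1 ms declining 2.2 ms/week (yielding a pooled
gestational-age correlation near −0.78), ADC near 0.020/0.0175 mm²/s
declining to r ≈ −0.63, ROI volume near 453,000/512,000 mm³ rising to
r ≈ +0.5, and maternal-age medians 35.0/32.3 years. Only printed
means/medians/SDs constrain these choices; per-subject distributions are
the package's own (normal with clipping).

The default trajectory shapes encode the reported qualitative pattern: the
component-4 weighting rises after 30 weeks in controls but not CHD, the
component-3 weighting rises after 30 weeks in CHD but not controls, and the
late components decline in both groups. The divergence slope (0.04/week
after 30 weeks) was calibrated so that the implied covariate-adjusted group
comparison at n = 67 scans lands safely inside the reported strength
(adjusted p below 0.001); at 0.03/week the median adjusted p sits exactly
on that boundary.

Two derived specifications support the operating-characteristic studies:
`divergent_cohort_spec()` makes the groups identical except for one
component's programmed post-30-week divergence, and `null_cohort_spec()`
removes all effects *and* subject-level random effects. The latter matters:
the cohort statistics analyse scans as independent observations (mixed
models are out of scope), which is anti-conservative when repeat scans are
correlated. The exchangeable null isolates the false-positive behaviour of
the testing machinery itself; the correlated-repeat caveat applies to real
analyses and is the main known limitation of the scan-level treatment.

## Cohort statistics

`component_weighting_analysis()` runs three families, each
Benjamini–Hochberg-corrected across the K components at 0.05: (1) ANCOVA
group comparisons — ordinary least squares of the weighting on an
intercept, a group indicator (control as reference) and the covariates
gestational age and maternal age, with a partial 1-df F-test on the group
term; (2) Pearson gestational-age trends in controls; (3) the same in the
CHD group. Correcting within each family separately (rather than over all
3K tests) mirrors the per-panel presentation convention and is
configurable by calling the pieces directly. Weightings are analysed on
the raw fraction scale. The Shapiro–Wilk test (`shapiro_wilk()`,
`describe_by_group()`) gates only whether descriptives print as mean ± SD
or median/IQR; inference always uses the ANCOVA and Pearson machinery.

## Numerical choices and problem sizes

* Voxel-fit bounds and the grid ranges are stated above; ties in peak
  merging resolve toward the larger peak, and peaks below 1% of spectral
  mass are not reported.
* The projected-gradient NNLS solves use a 1% safety margin on the
  Lipschitz estimate and a monotone restart, so every recorded objective is
  a true descent value; the Lawson–Hanson solver is used wherever designs
  are small, with the projected-gradient solve as a deterministic fallback
  on (near-)degenerate designs where active-set cycling can exceed its
  iteration budget.
* All generators and fits are pure functions of their inputs and a seed;
  sub-seeds are derived arithmetically and stay below $2^{31}$.
* Tests and the acceptance script run decomposition problems at reduced
  size — the 16-measurement test scheme, 15 × 15 grids, phantoms of a few
  hundred voxels, and 100-replicate Monte Carlo studies — sizes chosen so
  the full suite completes in minutes on one CPU while still exercising
  every code path of the full-size problem.

## Known limitations

* Scan-level independence: repeat scans are treated as independent
  observations, as discussed above.
* The scalar-ADC model ignores diffusion anisotropy; anisotropic spectra
  and spatially regularised weight maps are out of scope.
* K is configurable but there is no model selection over K (the default 7
  follows the number previously found to best explain placental and
  adjacent uterine-wall combined T2\*-diffusion signal).
* The phantom's geometry is a caricature: it reproduces class contrasts and
  the forward model, not placental anatomy. Conclusions about clinical data
  require clinical data.
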
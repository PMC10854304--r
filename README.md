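# placentadr

Combined diffusion-relaxation (T2\*-ADC) MRI analysis of the placenta, with
a synthetic-data module providing ground truth for every stage.

## The problem

The placenta is spatially heterogeneous: maternal blood pools around the
villous trees inside lobules, fetal blood flows in capillaries, and septa
and the uterine wall carry their own microcirculation. Single summary maps
(a mean T2\*, a mean ADC) blur these environments together. A combined
acquisition that interleaves multiple echo times with multiple diffusion
weightings samples the joint (T2\*, ADC) signature of every voxel, and a
data-driven decomposition can then separate tissue microenvironments that
plain relaxometry or diffusion imaging cannot. Cohort analyses of how each
environment's signal fraction evolves across gestation — and how that
evolution differs when the fetus has congenital heart disease (CHD) — are
the downstream scientific target.

`placentadr` implements the full pipeline for researchers in quantitative
placental MRI:

1. **Signal model** — every voxel follows
   `S(TE, b) = S0 · exp(−(TE − TE_min)/T2*) · exp(−b · ADC)`,
   fit voxelwise by log-linear initialisation plus bounded nonlinear least
   squares (`fit_voxel()`, `fit_roi()`).
2. **Spectral decomposition** — voxel signals are expressed over a
   log-spaced (T2\*, ADC) dictionary grid; K non-negative unit-mass
   component spectra `f_k` and simplex voxel weights `w_vk` minimise
   `Σ_v ‖S_v − s0_v Σ_k w_vk A f_k‖²` by alternating non-negative least
   squares with seeded k-means++ initialisation and restarts
   (`fit_full()`); with spectra fixed, only weights are re-inferred for new
   scans (`fit_weights_reduced()`).
3. **Synthetic placentas** — lobulated digital phantoms with
   centre/periphery/septa/uterine-wall classes and Rician noise
   (`make_phantom()`), and seeded cohorts whose per-scan mean component
   weightings follow piecewise-linear gestational-age trajectories with a
   30-week changepoint (`simulate_cohort()`).
4. **Cohort statistics** — covariate-adjusted group comparisons (ANCOVA on
   gestational age and maternal age), Pearson gestational-age trends per
   group, and Benjamini–Hochberg FDR across components within each analysis
   family (`component_weighting_analysis()`).

Note the ADC convention: values are on the placental-literature scale where
free water sits at 0.3 mm²/s; they are never silently rescaled.

## A worked example

```r
library(placentadr)

scheme <- zebra_scheme("reduced_test")      # 4 TEs x 4 b-values, 16 volumes
grid   <- spectral_grid(15, 15)
truth  <- make_component_spectra(grid, list(
  list(list(t2star = 0.03, adc = 6e-4, log_width = 0, mass = 1)),
  list(list(t2star = 0.08, adc = 0.01, log_width = 0, mass = 1)),
  list(list(t2star = 0.15, adc = 0.05, log_width = 0, mass = 1))
))
ph  <- make_phantom(c(12, 12, 4), scheme, truth, snr = 100, seed = 104,
                    class_weights = matrix(c(0.85, 0.10, 0.05,
                                             0.10, 0.80, 0.10,
                                             0.05, 0.10, 0.85,
                                             0.40, 0.30, 0.30),
                                           4, 3, byrow = TRUE))
dec <- fit_full(ph$stack, ph$mask, scheme, K = 3, grid = grid,
                lambda = 0, n_restarts = 2, seed = 7)
perm <- match_components(truth, dec$components)
sapply(1:3, function(k)
  cor(dec$weight_maps[[1]]$weights[, perm[k]], ph$truth$true_weights[, k]))
#> [1] 0.9971774 0.9976364 0.9969873
```

The three per-component correlations compare the recovered voxelwise weight
maps against the phantom's generating weights after optimal component
matching: values above 0.99 mean the decomposition reassembled both the
spectra and their spatial distribution from noisy data alone.

On the cohort side:

```r
rec <- simulate_cohort(divergent_cohort_spec(component = 3), seed = 21)
res <- component_weighting_analysis(rec, K = 7)
subset(res, family == "group_comparison" & component == 3)
#> # A tibble: 1 × 7
#>   family           component effect statistic    p_raw     p_fdr significant
#>   <chr>                <int>  <dbl>     <dbl>    <dbl>     <dbl> <lgl>
#> 1 group_comparison         3 0.0546      26.5 2.84e-6  1.99e-5  TRUE
```

A programmed post-30-week divergence of one component's weighting
trajectory between groups is recovered as a significant adjusted group
effect after FDR correction.

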
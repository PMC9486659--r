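# dmipipe

Diffusion microstructure imaging (DMI) of acute ischemic stroke in R.

In acute stroke, tissue with an apparent diffusion coefficient (ADC) below
roughly 0.620 µm²/ms is conventionally read as the irreversibly injured
infarct core. `dmipipe` implements the model-based alternative: mapping the
parameters of the three-compartment **standard model** of white matter from
a fast two-shell diffusion acquisition and delineating the core from the
intra-axonal axial diffusivity `D_ax_intra`, which collapses markedly in
ischemic tissue. It is aimed at quantitative-MRI researchers who want a
self-contained, reproducible implementation of the whole chain — forward
model, rotation-invariant features, simulation-trained Bayesian estimator,
ADC mapping, and ROC/Youden evaluation of threshold segmentation — runnable
end-to-end on a digital stroke phantom (no patient data are shipped).

## The model and the estimator

Each voxel mixes an intra-axonal stick, an extra-axonal zeppelin and a
free-water ball (D fixed at 3 µm²/ms):

```
S(b,g) = v_i exp(-b D_ax_intra (g·n)²)
       + v_e exp(-b D_rad_extra - b (D_ax_extra - D_rad_extra)(g·n)²)
       + v_c exp(-3b),        v_i + v_e + v_c = 1
```

Signals are reduced to three rotation-invariant features (spherical means of
the two radial bins plus the order-2 spherical-harmonic power, all
b0-normalized). A polynomial regressor of order 3, trained on Rician-noisy
simulations from a generic biophysical prior (with the degeneracy-breaking
constraint `D_ax_intra > D_ax_extra + 2 D_rad_extra`), approximates the
Bayesian posterior mean of the six parameters given the features. An
importance-sampling posterior-mean oracle is included as the slow reference
the regressor is validated against. Segmentation quality is quantified by
pooled-voxel exact empirical ROC curves, AUC, the Youden maximum
`J = sensitivity + specificity - 1` and its optimal threshold, against four
ground-truth variants (DMI-based, DWI-based, intersection, union).

See the methods vignette (`vignettes/dmi-stroke-methods.Rmd`) for the full
account: assumptions, priors, numerical choices and limitations.

## Worked example

```r
library(dmipipe)

# 1. simulate a small stroke phantom (two-shell protocol, SNR 30)
cfg <- phantom_config(grid_shape = c(32, 32, 32), brain_radius = 13,
                      csf_rim = 1, gm_ribbon = 3, ventricle_radius = 2,
                      lesion_center = c(21.5, 16.5, 16.5), lesion_radius = 4,
                      snr = 30, seed = 42)
ds <- phantom_dataset(cfg)

# 2. train the simulation-based estimator for this protocol
est <- train_estimator(ds$scheme, prior_config(n_samples = 20000, seed = 1))
est
#> <dmi_estimator> order-3 polynomial, 20 terms, trained on 20000 samples
#>   scheme: two_shell/n71/b0_11/chk4124.697530
#>   training RMSE: v_intra=0.181 v_extra=0.152 v_csf=0.059 d_ax_intra=0.478 d_ax_extra=0.526 d_rad_extra=0.228

# 3. microstructure maps + conventional ADC
maps <- predict_maps(est, ds$volume, ds$brain_mask)
adc <- compute_adc(ds$volume, maps$mask)

# 4. how well does each contrast delineate the infarct core?
glance(pooled_roc(maps$fields$d_ax_intra, ds$lesion_mask, maps$mask))
#> # A tibble: 1 × 7
#>     auc j_max optimal_threshold  sens  spec n_pos n_neg
#>   <dbl> <dbl>             <dbl> <dbl> <dbl> <int> <int>
#> 1 0.962 0.884              2.43 0.978 0.906   276  9052

# 5. lesion vs mirrored contralateral tissue
contra <- mirror_mask(ds$lesion_mask,
                      clip_mask = combine_masks(ds$brain_mask, 1L - ds$csf_mask,
                                                "intersection"))
lesion_statistics(maps, ds$lesion_mask, contra)
#> # A tibble: 12 × 6
#>    parameter   region          mean     p5    p95 n_voxels
#>  1 v_intra     lesion        0.509  0.429  0.582       276
#>  4 d_ax_intra  lesion        2.11   1.79   2.40        276
#>  7 v_intra     contralateral 0.388  0.268  0.461       276
#> 10 d_ax_intra  contralateral 2.64   2.56   2.71        276
#>  ...
```

The numbers carry the acute-stroke signature the method is built around:
inside the lesion the predicted intra-axonal fraction rises (0.51 vs 0.39
contralaterally) while `D_ax_intra` falls (2.11 vs 2.64 µm²/ms), and the
Youden-optimal `D_ax_intra` threshold (2.43) sits between the lesion and
healthy-white-matter values. ROC objects also plot directly:
`autoplot(pooled_roc(...))`; parameter maps via `autoplot(maps)`.

A command-line front end wrapping the same functions ships in
`inst/cli/dmipipe.R` with subcommands `train`, `fit`, `evaluate`, `phantom`.

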
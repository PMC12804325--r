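# mamsim

Monte Carlo simulation of how measurement errors distort the minimum
ablative margin (MAM) after thermal ablation of liver tumors — and of the
observed-margin threshold (**A0**) a confirmation workflow must demand so
that the *true* microscopic margin is positive with ≥ 99% probability.

## The problem

Ablation success is judged from co-registered pre-/post-ablation images:
tumor and ablation zone are contoured, and the MAM — the minimum 3D
distance between the tumor surface and the ablation boundary — is
computed. The measurement carries registration error, segmentation error
and finite slice thickness; biology adds thermal tissue shrinkage and
microscopic satellite lesions invisible at imaging resolution. mamsim
builds synthetic 3D voxel phantoms, pushes them through a statistical
model of those error sources, measures true and observed MAM with exact
spacing-aware signed Euclidean distance transforms, and fits the logistic
coverage model

```
logit P(MAM_true > 0) = beta0 + beta1 * MAM_observed
A0 = (logit(0.99) - beta0) / beta1
```

A0 ≤ 5 mm means the conventional "5-mm margin" rule is reliable under
that error profile; A0 > 5 mm means it is not.

## Worked example

```r
library(mamsim)

p   <- sim_params(n_sims = 5000, seed = 1)   # all-minimal baseline:
                                             # reg 1 mm, seg 1 mm, slice 1 mm
rec <- run_simulations(p)
est <- estimate_a0(rec)
est
#> <a0_estimate> A0 = 2.9 mm (ml fit; beta0 = 1.332, beta1 = 1.132)
#>   P(true coverage | observed >= 5 mm) = 1.000; n = 5000 (0 excluded)
verdict(est)
#> <reliability_verdict> A0 = 2.9 mm; 5-mm rule RELIABLE (P[coverage | obs >= 5 mm] = 1.000)
```

The baseline A0 of ~3 mm says: with 1-mm-accurate registration and
segmentation, demanding an observed margin of about 3 mm already
guarantees true coverage 99% of the time (the Monte Carlo spread across
seeds at this n is a few tenths of a millimetre). Raising the
segmentation error pushes the threshold past the 5-mm rule:

```r
sw <- run_sweep(sim_params(n_sims = 5000, seed = 1),
                "segmentation_sd_mm", c(1, 3, 5))
for (s in sw) cat(sprintf("seg %g mm -> A0 = %.1f mm\n", s$value, s$estimate$x_a0))
#> seg 1 mm -> A0 = 3.3 mm
#> seg 3 mm -> A0 = 5.2 mm
#> seg 5 mm -> A0 = 8.0 mm
plot_coverage_curves(sw, "figures/seg_sweep.png")

gr <- run_grid(sim_params(n_sims = 2000, seed = 1),
               seg_values = 1:5, reg_values = 1:5)
plot_a0_contour(gr, "figures/a0_contour.png")  # 5-mm reliability frontier
```

Conversely, 30% tissue shrinkage pulls the threshold below 2 mm — the
imaged margin then *understates* the true one.

A command-line front end covers the same operations
(`inst/cli/a0sim.R`): `sweep`, `grid`, `single --config run.yaml`,
`compute --tumor t.nii.gz --ablation a.nii.gz`, and `report`.

## Package layout

| module | functions |
|---|---|
| phantom | `grid_spec`, `volume_mask`, `sample_case`, `rasterize_case`, `apply_shrinkage`, `add_satellite` |
| error models | `draw_errors`, `apply_registration_shift`, `apply_segmentation_noise`, `resample_slice_thickness` |
| margin metrics | `signed_distance_field`, `compute_mam` |
| A0 estimation | `fit_coverage_curve`, `solve_a0`, `coverage_prob_at`, `filter_registration`, `estimate_a0` |
| experiment | `sim_params`, `run_simulation(s)`, `run_sweep`, `run_grid`, `enumerate_permutations` |
| report | `plot_coverage_curves`, `plot_a0_contour`, `verdict` |

The methods vignette (`vignettes/mamsim-methods.Rmd`) documents the
simulation model, the error realizations and their rationale, numerical
conventions, and known limitations.
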
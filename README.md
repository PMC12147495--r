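# bonevar

Variability-aware prediction of bone formation rates by sub-dataset
ensembles.

## The problem

The bone formation rate of an artificial bone substitute (hydroxyapatite,
β-TCP and related calcium-phosphate ceramics) is measured by implantation
in animals, and repeated implantations of the *same* material give visibly
different results. A material is good when its rate is both high and
stable, so a useful model must predict the **distribution** of the rate —
mean *and* variability — not just its average. `bonevar` is for
biomaterials and chemometrics researchers who have a small panel of
materials, a handful of repeated response measurements per material, and
feature blocks of unequal provenance (synthesis/assay conditions, FT-IR
and XRD spectra, SEM images).

## The method

Given materials with features `x_i` and repeated measurements
`y_i1 … y_ik`, the package:

1. draws `N` **sub-datasets**, each keeping all `x_i` and one uniformly
   drawn `y_ij` per material;
2. on each sub-dataset, selects the best regressor from a zoo (OLS, ridge,
   lasso, elastic net, linear/RBF SVR, GPR, tree, random forest, boosted
   trees) by inner cross-validation and collects **out-of-fold estimates**
   under double cross-validation (5 inner / 10 outer folds), giving every
   material `N` predictions — an empirical predictive distribution;
3. fits Gaussians to measured and predicted values per material (materials
   with ≤ 2 measurements receive the mean SD of the well-measured ones)
   and scores them with the **Jensen–Shannon divergence**

   D_JS(p, q) = ½ D_KL(p ‖ (p+q)/2) + ½ D_KL(q ‖ (p+q)/2),
   D_KL(p ‖ q) = ∫ p(x) log(p(x)/q(x)) dx,

   computed by trapezoidal quadrature in log-density space (symmetric,
   ≥ 0, ≤ log 2 nats), alongside the r² of the per-material means.
   Feature blocks are switched by the eight combinations A–H (A = base
   features only, H = base + FT-IR + XRD + SEM-image LBP histograms).

Because no public dataset of this shape exists, the package ships a
seeded synthetic generator that emulates the assumed structure (38
materials, 17 of them measured once, peak-structured spectra, textured
images, heteroscedastic noise) together with its ground truth.

## Worked example

```r
library(bonevar)

gen <- generate_synthetic_dataset(synthetic_config(seed = 1))
gen$dataset
#> <material_dataset> 38 materials, 5 base features
#>   measurements per material: 1-6 (total 83)
#>   spectra: ftir+xrd; images: yes

zoo <- model_zoo(c("ridge", "random_forest"))
res <- run_pipeline(gen$dataset, combos = c("A", "E"), zoo = zoo,
                    n_subdatasets = 20, seed = 1,
                    ftir_bands = gen$bands$ftir, xrd_bands = gen$bands$xrd)
res
#> <pipeline_result>
#>  combo use_ftir use_xrd use_sem  d_js r_squared
#>      A    FALSE   FALSE   FALSE 0.343   0.00851
#>      E     TRUE    TRUE   FALSE 0.233   0.60460
```

Combo E (base features + FT-IR + XRD band intensities) beats the
feature-only combo A on both metrics: its predicted means explain 60 % of
the variance of the measured means, and its predicted distributions sit
closer to the measured ones (mean D_JS 0.233 vs 0.343 nats; 0 would be
identical distributions, log 2 ≈ 0.693 disjoint ones). Per-material
detail:

```r
head(res$evaluations$E$per_material[, c("material_id", "measured_mean",
     "measured_sd", "measured_n", "predicted_mean", "predicted_sd", "d_js")], 3)
#>   material_id measured_mean measured_sd measured_n predicted_mean predicted_sd      d_js
#> 1         M01      35.22609    6.293565          2       28.63638     2.943492 0.2485223
#> 2         M02      33.28125    6.293565          2       37.35940     1.833410 0.2694763
#> 3         M03      42.40237    9.258432          3       44.45350     2.896389 0.2078369
```

Materials M01 and M02 have only two measurements, so their measured SD
(6.29) is the substituted fallback — the mean sample SD of the materials
with three or more measurements. `make_figures()` / `save_figures()` draw
the mean-vs-mean scatter with dispersion rectangles, the per-material
measured/estimated strip plot, and the per-material D_JS bar chart;
`write_report()` writes the tables plus a reproducibility manifest. A thin
CLI wraps the same functions:

```sh
exec/bonevar simulate --out data/ --seed 1
exec/bonevar run --config run.yaml
```

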
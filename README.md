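# attenuskin

Dual-modal analysis of skin lesions: depth-resolved **OCT attenuation
fitting** with linear-SVM classification, and **Raman spectral
preprocessing** with group comparison statistics. The package targets the
question of separating malignant melanoma (MM) from benign nevi (BN)
noninvasively, for researchers building optical-biopsy pipelines who need a
tested, fully reproducible implementation of each stage — including a
seeded synthetic-data generator, because clinical scans of this kind are
rarely shareable.

## The method

**OCT branch.** Light backscattered from depth `z` in tissue decays by the
Lambert–Beer law; in OCT the path is two-way, so the A-scan intensity
follows

    I(z) = I0 * exp(-2 * mu * z)

where `mu` is the *effective* attenuation coefficient — the product of the
tissue attenuation (absorption + scattering) and its refractive index
(1.33–1.55), which is why fitted values reach ≈ 1.6 rather than 1. For
every A-scan the package detects the surface (global intensity maximum),
fits `a·e^(−2bz)` by least squares over a fixed window below it, and
records `b` (the attenuation coefficient), `R²`, RMSE and the surface
intensity. Results from every 5 A-scans are binned into means and sample
SDs, giving 8 features per bin; a linear SVM (`C = 1`) with stratified
10-fold cross-validation produces pooled out-of-fold accuracy, fold-wise
ROC curves interpolated onto a common grid (mean AUC ± SD), a per-sample
majority report, and the signed feature weight vector.

**Raman branch.** Spectra are despiked (modified z-score of the second
difference), Savitzky–Golay smoothed, area-normalized over the fingerprint
region 800–1800 cm⁻¹, and baseline-corrected with **arPLS**
(asymmetrically reweighted penalized least squares), which removes the
broad tissue autofluorescence while preserving Raman bands. Group mean
spectra carry pointwise t-based 95% confidence intervals; BN−MM difference
spectra use Welch intervals. In this lesion contrast, carotenoid bands
(~1008, 1158, 1525 cm⁻¹) run higher in melanoma, CH₂–CH₃ (~1450 cm⁻¹) and
amide-I (~1655 cm⁻¹) higher in nevi.

## Worked example

```r
library(attenuskin)

# one synthetic benign-nevus B-scan: 1000 A-scans with ground truth
bscan <- generate_bscan(oct_sim_config("BN", n_ascans = 1000, seed = 101),
                        sample_id = "01_Nevus")
fits  <- fit_bscan(bscan, fit_depth = 150)
head(fits[, c("column_index", "amplitude_a", "attenuation_b",
              "r_squared", "rmse")], 3)
#>   column_index amplitude_a attenuation_b r_squared      rmse
#> 1            1   106.03052      1.197168 0.8395496 10.977912
#> 2            2    90.05606      1.248953 0.8516527  9.007558
#> 3            3    94.50884      1.132181 0.8217126 10.138326
mean(fits$attenuation_b)   # 1.208: BN attenuation, near the true 1.2
```

`attenuation_b` is the effective attenuation in 1/mm — the per-A-scan
quantity rendered as a heatmap via `attenuation_map()`. Binning and
classifying six samples (3 BN + 3 MM, 200 bins each):

```r
ds <- assemble_dataset(lapply(1:6, function(i) {
  cls <- if (i <= 3) "BN" else "MM"
  sid <- sprintf("%02d_%s", i, if (cls == "BN") "Nevus" else "Melanoma")
  bin_features(fit_bscan(generate_bscan(
    oct_sim_config(cls, n_ascans = 1000, seed = 100 + i),
    sample_id = sid)))
}))
cross_validate(ds, cv_config(seed = 7))
#> <cv_report> 10-fold linear SVM (C = 1) on 1200 instances
#>   overall accuracy 0.997 (1196/1200), mean AUC 1.000 +/- 0.000
#>   per-sample correct proportions:
#>    sample_id total correct proportion majority_correct
#>     01_Nevus   200     199      0.995             TRUE
#>     02_Nevus   200     199      0.995             TRUE
#>     03_Nevus   200     200      1.000             TRUE
#>  04_Melanoma   200     200      1.000             TRUE
#>  05_Melanoma   200     200      1.000             TRUE
#>  06_Melanoma   200     198      0.990             TRUE
```

Every lesion is called correctly when more than half of its 200 instances
match its type (`majority_correct`). Accuracy here is near-perfect because
the default synthetic classes are well separated (BN μ ~ N(1.2, 0.15) vs
MM μ ~ N(0.8, 0.15) per A-scan); it is a sanity level, not a clinical
claim. The Raman side is analogous:
`generate_raman_spectrum() |> remove_cosmic_rays() |> smooth_spectrum() |>
normalize_fingerprint()` then `arpls_baseline()`, `group_statistics()` and
`difference_spectrum()`.

## Command line

```sh
inst/cli/attenuskin simulate-oct --class bn --n-ascans 1000 --seed 1 \
    --out bscan.csv --truth truth.csv
inst/cli/attenuskin fit-oct --in bscan.csv --fit-depth 150 \
    --out fits.csv --map map.csv
inst/cli/attenuskin features --fits fits.csv --bin 5 --label bn \
    --sample-id 01_Nevus --out features.csv
inst/cli/attenuskin classify --features features.csv --folds 10 --C 1 \
    --report report.json
inst/cli/attenuskin run --seed 1 --out run_dir/     # full pipeline + manifest
```

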
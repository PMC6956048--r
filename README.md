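# stromaquant

Quantitative analysis of corneal stromal ultrastructure, mechanics and gene
expression for ex vivo ectasia (keratoconus-like) models.

Corneal ectasia weakens the stroma: proteoglycan loss loosens the
collagen-fibril network, lowering fibril packing density, stiffness and
thermal stability. Studies of this process — and of treatments meant to
reverse it — quantify the tissue along four standard axes, all implemented
here as a tested, reusable pipeline:

- **TEM ultrastructure.** Fibril cross-sections in transmission electron
  micrographs are segmented by mean−C adaptive thresholding (a pixel is
  foreground when it is darker than its local-neighborhood mean by more
  than an offset), filtered by area and circularity, and measured by
  equivalent-circle diameter `d = 2·sqrt(A/π)·pixel size`. Fibril density
  is estimated stereologically: 300 × 300 px counting windows are placed
  uniformly at random inside each image (200 per image, ≥ 3 images), each
  window counts the fibril centroids it contains, and the density is the
  **median** per-window count divided by the window area (fibrils/µm²).
- **Tensile mechanics.** Load–displacement records from strips pulled at
  0.1 mm/s reduce to engineering stress σ = F/A₀ and strain
  ε = Δl/l₀; Young's modulus is the OLS slope of σ(ε) over a
  configurable high-strain window (default [0.7, 0.9] × max strain, the
  near-linear regime of the J-shaped soft-tissue curve).
- **DSC thermal stability.** Heat-flow traces (10–95 °C at 5 °C/min) are
  reduced by fitting a linear baseline through pre- and post-transition
  windows; the collagen denaturation temperature Td is the baseline-
  subtracted endotherm extremum, located after matched-filter-style
  Gaussian smoothing and refined by a 3-point parabola.
- **qPCR expression.** Relative expression by ΔΔCt: ΔCt = Ct(target) −
  Ct(Gapdh), ΔΔCt = ΔCt − mean control ΔCt, fold change = 2^(−ΔΔCt);
  group comparison by Student/Welch t tests and one-way ANOVA.

Because such studies rarely deposit raw data, every input has a synthetic
twin with known ground truth: hard-core (random-sequential-adsorption) disk
packings rendered as anti-aliased, blurred, noisy micrographs; toe-
exponential stress–strain records; Gaussian-endotherm thermograms; and Ct
tables with injected log2 effects. Each estimator is validated by parameter
recovery against these generators, and five shipped group presets (control,
KC, COR, CART, LN) encode the ordinal structure of an enzyme-weakened,
particle-treated cornea study.

## Worked example

```r
library(stromaquant)

# simulate a micrograph with known truth, then recover density and diameters
params <- fibril_field_params(target_density = 50, field_width_px = 1024,
                              field_height_px = 1024, pixel_size_nm = 2,
                              seed = 42)
field <- generate_fibril_field(params)
field
#> <fibril_field> 210 fibrils, 50.07 /um^2 realized (target 50.00)
#>   raster 1024 x 1024 px at 2 nm/px

detections <- segment_fibrils(field$image, pixel_size_nm = 2)
estimates <- lapply(1:3, function(i)
  estimate_density(detections, config = density_config(seed = i)))
aggregate_density(estimates)
#> <density_estimate> 50.00 fibrils/um^2 (median count 18.0 in 0.360 um^2 windows, 600 windows, 3 images)

diameter_distribution(detections)
#> <diameter_distribution> n = 210, median 27.7 nm (IQR 4.7), mean 28.0 nm (SD 3.8)

# tensile record -> Young's modulus (toe-exponential law, default window)
curve <- compute_stress_strain(generate_tensile_record(
  tensile_params(toe_amplitude = 0.092, toe_rate = 8, seed = 1)))
estimate_modulus(curve)
#> <modulus_estimate> E = 5.057 MPa (strain window [0.21, 0.27], n = 100, R^2 = 0.9962)

# thermogram -> denaturation temperature
tg <- generate_thermogram(thermogram_params(td_C = 62.57,
                                            baseline_intercept_mW = 5,
                                            seed = 7))
detect_denaturation(tg)
#> <denaturation_result> Td = 62.56 degrees C (peak height 1.87 mW)
```

The density estimate recovers the realized 50.07 fibrils/µm² to within the
median-count quantization (1 count ≙ 2.8 fibrils/µm² at this window size);
the diameter summaries match the generator's lognormal (mean 28 nm, SD 4);
the modulus is the mean analytic tangent over the fit window; and Td lands
within one 0.1 °C sampling interval of the programmed transition.

`run_pipeline(validate_config(NULL, seed = 1))` chains all four assays over
the five group presets and returns a deterministic report (densities,
diameter distributions, moduli, Td values, fold changes, and ANOVA/t-test
results), writable as JSON/CSV with `write_report()`.

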
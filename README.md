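# sisr — super-resolution MR spectroscopic imaging

Proton MR spectroscopic imaging (MRSI) yields per-metabolite concentration
maps of the brain — NAA, creatine (Cr), choline (Ch), glutamate (Glu),
glutamine (Gln), myo-inositol (mI) — but at coarse spatial grids (16×16 to
32×32 points) because the metabolites sit at millimolar concentrations.
`sisr` reconstructs high-resolution metabolite maps (128×128) from the
pair *(T1-weighted image, low-resolution metabolite map)* with a densely
connected U-Net (D-UNet), and contains everything needed to build, train
and judge that model without any external data:

* a **synthetic-data generator**: digital brain phantoms with known
  white-/gray-matter fractions; segmentation
  `WM = clip((S − GM_min)/WM_max, 0, 1)·M`, `GM = (1 − WM)·M`;
  contrast/rotation/field-of-view/lesion augmentation
  `aT1w = R(S_n^{r1} + L)`; metabolite maps
  `HRSI = r2·WM + (1 − r2)·GM + B + r3·L`; and the acquisition model —
  k-space truncation, complex Gaussian noise at 2–40% of the signal
  maximum, magnitude reconstruction, nearest-neighbor upscaling;
* the **D-UNet** itself — dense within-level concatenations, encoder →
  decoder skips, and a final convolution that sees every full-resolution
  feature map produced anywhere in the network — implemented from scratch
  in RcppArmadillo (im2col/GEMM convolutions, verified backpropagation),
  with the fixed-budget training protocol (summed-squared-error/m² loss,
  Adam at 1e-3, fresh 1000-case epochs, batch size 1 then 10);
* the **evaluation battery**: zero-filling and bicubic interpolation
  baselines, noise-band sweeps, point-by-point spectral super-resolution
  over parametric Lorentzian metabolite bases, and ratio-vs-T1w-intensity
  curve analysis.

## Worked example

Generate a phantom case, acquire a noisy 16×16 map, and compare
reconstructions:

```r
library(sisr)

sc <- generate_phantom(seed = 7, size = 64, n_gyri = 8)
print(sc)
#> phantom_scene: 64x64 grid, seed 7
#>   brain area fraction: 0.463; WM fraction of brain: 0.306

case <- generate_dataset(1, hr_size = 64, lr_size = 16,
                         noise_range = c(0.02, 0.05), seed = 7)[[1]]
fit <- train_dunet(dunet(dunet_spec(64, 16, 3), seed = 7),
                   train_config(n_epochs = 10, samples_per_epoch = 200,
                                batch_schedule = list(
                                  list(epochs = c(1, 2), size = 1L),
                                  list(epochs = c(3, 10), size = 10L)),
                                lr_size = 16L, seed = 21))

rep <- noise_sweep(list(dunet     = dunet_method(fit),
                        bicubic   = function(case, lr) bicubic_upsample(lr$native, 64),
                        zero_fill = function(case, lr) zero_fill_upsample(lr$native, 64),
                        nn_input  = function(case, lr) lr$upscaled),
                   n_cases = 50, lr_size = 16, hr_size = 64,
                   noise_bands = list(low = c(0.02, 0.05)), seed = 99)
print(rep)
#> eval_report: 50 cases, native 16x16, seed 99
#> mean normalized MSE (rows = methods, cols = noise bands):
#>              low
#> dunet     0.0042
#> bicubic   0.0202
#> zero_fill 0.0098
#> nn_input  0.0260
```

The mean squared errors are per-image `sum((recon − truth)²)/m²` after
dividing both by the truth's maximum. The trained network more than halves
the error of k-space zero-filling and reaches roughly a quarter of the
bicubic error at the same 4× super-resolution factor — the qualitative
ordering expected of a learned reconstruction that exploits the anatomical
prior in the T1w channel, which no interpolation method sees.

A spectral-domain example (point-by-point reconstruction of a full
spatial-spectral volume) and the pipeline/CLI interface
(`run_pipeline()`, `inst/cli/sisr.R` with `phantom | generate | train |
evaluate | model-summary` subcommands, YAML configs) are described in the
vignette `vignettes/super-resolution-mrsi.Rmd`.

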
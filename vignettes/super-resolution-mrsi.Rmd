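---
title: "Super-resolution spectroscopic imaging with a densely connected U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolution spectroscopic imaging with a densely connected U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisr)
```

## The problem

Proton MR spectroscopic imaging (MRSI) measures an NMR spectrum in every
voxel of a slice, and hence per-metabolite concentration maps — NAA,
creatine (Cr), choline (Ch), glutamate (Glu), glutamine (Gln),
myo-inositol (mI). Because these metabolites sit at millimolar
concentrations, acquisitions are starved for signal and spatial grids are
coarse: 16×16 to 32×32 points where the anatomical T1-weighted (T1w) image
has 128×128 or better. `sisr` implements a learning-based super-resolution
reconstruction: a densely connected U-Net (D-UNet) maps the pair
*(T1w image, nearest-neighbor-upscaled low-resolution metabolite map)* to
the high-resolution metabolite map. Since no large paired LRSI/HRSI corpus
exists, the package also implements the synthetic-data generator that makes
training possible, and the evaluation battery (interpolation baselines,
noise sweeps, point-by-point spectral reconstruction, metabolite-ratio
curves) used to judge it.

## The generator

The generator turns one T1w slice into an unbounded stream of matched
training triples `(aT1w, LRSI, HRSI)`.

**Tissue model.** A T1w image is segmented by the linear intensity rule

$$\mathrm{WM} = \mathrm{clip}\!\left(\frac{S - \mathrm{GM}_{min}}{\mathrm{WM}_{max}},\ 0,\ 1\right)\cdot M,
\qquad \mathrm{GM} = (1 - \mathrm{WM})\cdot M,$$

with $S$ the image, $M$ the brain mask. The two maps are continuous tissue
*fractions* summing to the mask, so partial-volume mixing is representable.
The formula as written divides by $\mathrm{WM}_{max}$ only; values outside
$[0,1]$ are clipped, the minimal fix that preserves the fraction reading.
The thresholds are "determined from the image"; here that means robust
percentiles of the in-mask intensities (5th for $\mathrm{GM}_{min}$, 98th
minus $\mathrm{GM}_{min}$ for $\mathrm{WM}_{max}$), configurable via
`estimate_thresholds()`.

**Augmentation.** One anatomy yields many: the normalized image is raised
to a random contrast exponent $r_1 \sim U(0.5, 2.5)$, up to six Gaussian
lesions (signed amplitudes in $\pm[0.05, 0.6]$, $\sigma$ = radius/2 — the
shape is a modeling choice, only "varying intensity, location, and size" is
prescribed) are added, and a rotation ($\pm 15^\circ$, bilinear, zero
fill) plus per-edge field-of-view truncation (0–40 pixels at 128, scaled
proportionally for smaller grids) is applied; the identical geometric
transform is applied to the WM/GM maps and mask. After interpolation the
mask is re-binarized at 0.5 (ties to 1) and the tissue fractions are
renormalized so WM+GM = mask holds exactly. The augmented image is
renormalized to maximum 1, since added lesions can push it past 1 and the
network consumes max-normalized inputs.

**Metabolite maps.** A high-resolution map is a random tissue mixture

$$\mathrm{HRSI} = r_2\,\mathrm{WM} + (1-r_2)\,\mathrm{GM} + B + r_3 L,$$

$r_2 \sim U(0,1)$, $r_3 \sim U(-1,1)$, $B$ a random linear bias ramp
(bounded at 0.15 in magnitude by default; any smooth low-order field would
do, only the anterior/posterior–left/right directionality is meaningful)
and $L$ the lesion field. The result is clipped at zero: metabolite signal
is nonnegative.

**Acquisition model.** The low-resolution map is the central
$N \times N$ block of the DC-centered 2-D DFT of the HRSI
($N \in \{16, 24, 32\}$ on a 128 grid), with i.i.d. circular complex
Gaussian noise added to the retained coefficients, inverse-transformed and
nearest-neighbor-upscaled back to the anatomy grid. Numerical conventions
that matter:

* The inverse transform is scaled so a constant image maps to the same
  constant at every $N$; noise percentages and errors are then comparable
  across resolutions. Under this scaling a per-coefficient k-space noise
  std of $\sigma_k = f \cdot \max(\mathrm{HRSI}) \cdot n^2/N$ produces an
  image-domain noise std of $f \cdot \max(\mathrm{HRSI})$ — $f$ is the
  user-facing "percent of maximum signal" knob (low 2–5%, medium 15–20%,
  high 30–40%).
* For even $N$ the block's $-N/2$ row and column have no $+N/2$ partner;
  they are zeroed. The pass-band is then conjugate-symmetric, the
  noise-free inverse is exactly real, and truncation followed by
  zero-filling is an exact orthogonal projection (the acceptance tests
  hold this to 1e-8 against a direct quadratic-time DFT).
* Noisy acquisitions are reconstructed as magnitude images (the physically
  available quantity); noise-free ones take the real part, which keeps the
  clean channel linear.
* Nearest-neighbor upscaling is pixel-center aligned
  (source index $\lfloor (i - 0.5) N/n \rfloor + 1$), which handles
  non-integer factors such as 128/24 without ties.

**The phantom.** Real T1w slices are replaced by a parametric digital
phantom (`generate_phantom()`): an elliptical brain containing a WM core
with a sinusoidally folded boundary (gyri-like), a GM rim, soft
partial-volume edges, WM rendered brighter than GM (plateaus 0.85/0.45)
under smooth shading and fine texture. The generator equations only need
an image with two-tissue contrast, so this removes any data dependency.
Users can substitute their own T1w slices and masks via `read_image()`;
the pipeline is identical downstream. What the phantom does *not* emulate:
CSF, skull/scalp signal, B0/B1 inhomogeneity, realistic cortical geometry — so
passing tests demonstrate correctness of the method, not clinical
performance on real anatomy.

## The network

`dunet()` builds the densely connected U-Net. Each "forward convolution"
is a 3×3 same-padded convolution producing `growth_maps` feature maps
(ReLU, dropout 0.1 in training) whose output is concatenated onto its
input; two such dense blocks form one resolution level. Three 2×2 max
poolings separate four levels (128 → 16 at the bottleneck with defaults);
the decoder mirrors them with stride-2 transposed convolutions, and each
decoder level concatenates the matching encoder level's full feature
stack. Because every concatenation carries its whole input forward, the
final 3×3 convolution at full resolution consumes every full-resolution
feature map produced anywhere in the network — the defining property of
the architecture. Max-pooled features are not re-upsampled into that
collection; a higher-resolution version of each already exists. This
concatenation topology is the package's single largest architectural
design choice — dense connectivity constrains which maps are carried, not
the exact wiring — and kernel size 3, two dense blocks per level, and the
transposed-convolution upsampler are conventional choices, all exposed in
`dunet_spec()`.

Inputs are the max-normalized T1w and upscaled LRSI (two channels);
the output is the metabolite map on the same normalized scale, with the
input map's maximum carried as the un-normalization factor. Weight
initialization is He-style, reproducible from an integer seed. The whole
network — im2col/GEMM convolutions, pooling, transposed convolutions and
their backward passes — is implemented in RcppArmadillo inside the
package; backpropagation is verified against numerical gradients in the
test suite.

## Training

`train_dunet()` follows a fixed-budget protocol: each epoch draws a fresh
set of generated triples (epoch-indexed sub-seeds; no case is ever seen
twice), the loss is $\sum_{i}\sum_{j} (O - \mathrm{HRSI})^2 / m^2$ with
$m$ the output side, optimized by Adam (rate $10^{-3}$, standard moments
$\beta_1 = 0.9, \beta_2 = 0.999$) with batch size 1 for the first two
epochs and 10 thereafter. There is no validation split or early stopping;
the last epoch is the model. The full-scale preset is 102 epochs × 1000
cases at 128×128 with 32 feature maps; the package's test and acceptance
runs use a scaled-down configuration — input 64×64, 16 growth maps,
16×16 native acquisitions (the same 4× super-resolution factor as 32×32
at 128), 10 epochs × 200 cases — chosen so a CPU-only run completes in
minutes while preserving every structural element of the protocol
(fresh-data epochs, batch schedule, loss, optimizer). Training noise defaults to
the low band (2–5%), matching the cleanest acquisitions the evaluation
sweeps consider; the band is exposed in `train_config()`.

## Spectral layer

The quantum-mechanical density-matrix simulation used by dedicated MRS
simulators is out of scope; each metabolite is a fixed multi-Lorentzian
template at literature chemical shifts (NAA 2.01; Cr 3.03/3.93; Ch 3.19;
Glu 2.35/3.75; Gln 2.45/3.77; mI 3.56 ppm) with configurable relative
amplitudes — order-of-magnitude plausible, not claimed to match any
particular acquisition. `simulate_basis()` synthesizes the time-domain
decaying complex exponentials on a 2000 Hz / 512-point axis at 3 T and
returns the DFT magnitude. Since the entire pipeline works in magnitude
spectra, the `fwhm_hz` parameter (default 8 Hz) specifies the FWHM of the
*magnitude* lineshape; the underlying decay rate is
$\pi \cdot \mathrm{FWHM}/\sqrt{3}$, the magnitude-mode Lorentzian being
$\sqrt{3}$ wider than the absorption mode at equal $T_2$. All bases are
zero-phase, so the map-weighted complex sum in `build_si_volume()`
coincides with the weighted sum of magnitudes for nonnegative maps — the
distinction would matter only if phases were ever introduced.
`pointwise_superres()` reconstructs a volume one spectral bin at a time
(max-normalize the bin's spatial map, reconstruct, un-normalize), so any
reconstructor with the 2-D contract — a trained `dunet`, an interpolation
baseline, a stub — lifts to spectra unchanged.

## Evaluation choices

* **Normalization before MSE.** Absolute error scales are unrecoverable
  across differently scaled maps, so every comparison divides both the
  reconstruction and the truth by the truth's maximum before applying the
  loss; every report records this convention.
* **Fair noise draws.** In `noise_sweep()` all methods see the *same*
  noisy acquisition per (case, band) — one draw, shared.
* **Ratio curves.** `ratio_vs_t1w()` bins in-mask voxels by T1w intensity
  (20 equal-width bins; bins with fewer than 5 voxels are dropped) and
  floors the denominator at $10^{-3}\cdot\max$ to keep near-zero Cr
  voxels from dominating; curve agreement is summarized by Pearson
  correlation of per-bin means over bins populated in both curves.
* **Degenerate inputs.** Empty masks, all-equal intensity images
  (zero-spread thresholds), >6 lesions, out-of-band peaks and shape
  mismatches raise immediate argument errors rather than propagating.

## Known limitations

The phantom's two-tissue anatomy is far simpler than brain; a network
trained on it will not transfer to in vivo data; for that, train on real
T1w slices supplied through `read_image()`. Singlet Lorentzian templates
ignore J-coupling multiplets, baseline, water/lipid residuals, and phase
errors. The acquisition model is 2-D single-coil with ideal spatial
encoding. The scaled-down training demonstrates the *direction* of the
comparison (learned reconstruction beats bicubic interpolation and its
own nearest-neighbor input at low noise) — not the absolute error levels
of a fully trained 102-epoch model.
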
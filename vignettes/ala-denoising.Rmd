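---
title: "Adaptive local averaging denoising: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive local averaging denoising: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aladenoise)
```

## The problem and the model

Real-world camera images carry a composite of sensor noise sources — photon
shot noise, dark current, readout noise, fixed-pattern noise, quantization —
whose statistics differ from the additive Gaussian noise most denoising
demonstrations use: the noise is signal-dependent and its level differs
between the three color channels. The filter implemented here is a
bio-inspired spatial-domain method modeled on the neural summation of
nocturnal insect vision, where lamina neurons pool signals from adjacent
photoreceptors, trading spatial resolution for signal-to-noise ratio.

The pipeline has two consecutive stages:

1. **Adaptive local averaging (ALA)** on the luminance plane. The color
   image is decomposed into YUV (full-range BT.601); only Y is filtered,
   chroma passes through untouched. For every pixel, a centered quadratic
   patch grows while the brightness variability inside it stays at or below
   a single global threshold $Th$; the pixel is replaced by the mean of the
   largest admissible patch. Near contours the admissible patch is small or
   empty (the pixel keeps its value), in homogeneous regions it is large —
   up to $41 \times 41$ at the defaults.

2. **Unsharp-mask sharpening** of the recombined RGB image, restoring the
   sharpness that spatial averaging costs:
   $\mathrm{out} = 1.6\,c - 0.6\,\mathrm{blur}(c)$ per channel, with a
   Gaussian blur of radius 5 pixels.

The single tuning parameter is derived from global image statistics of the
Y plane:

$$Th = 2\sigma + \mu / 60$$

where $\mu$ is the median brightness and $\sigma$ a Laplacian-based
estimate of the noise standard deviation. Everything else is fixed.

```{r example}
clean <- make_scene("blobs_texture", size = c(96, 96), seed = 11)
noisy <- add_noise(clean, model = "gaussian", sigma = 10, seed = 1)
res <- denoise_image(noisy, pipeline_config(sharpen = FALSE))
res$info$threshold
c(noisy = psnr_pair(clean, noisy), denoised = psnr_pair(clean, res$image))
```

## Parameters and their meaning

| Parameter | Default | Units | Role |
|---|---|---|---|
| `threshold` (Th) | auto: $2\sigma + \mu/60$ | gray values | variability bound for patch growth; the method's only tunable |
| `min_extent` / `max_extent` | 2 / 40 | pixels | patch side bounds; realized as window radii $r = 1 \dots 20$ |
| `variability_statistic` | `stddev` | — | population sd of the window (same scale as Th); `range` offered as alternative |
| `blur_radius` | 5 | pixels | unsharp-mask Gaussian radius; $\sigma_\mathrm{blur} = \mathrm{radius}/2$, truncated at $3\sigma$ |
| `gain` / `amount` | 1.6 / 0.6 | — | unsharp mix; `gain - amount = 1` makes constants fixed points and conserves the mean |
| `n_tiles` / halo | 4 / 20 | — / pixels | tiling layout; halo = maximum window radius guarantees seam-free stitching |

### Why σ is a *scaled* Laplacian statistic

The 4-neighbor Laplacian annihilates constant and affine intensity, so on
smooth image regions its response is essentially noise. Under i.i.d.
Gaussian noise of standard deviation $\sigma_n$ the response variance is
$20\sigma_n^2$, hence
$E|\nabla^2 Y| = \sigma_n\sqrt{40/\pi}$, and the package estimates

$$\hat\sigma = \sqrt{\pi/40}\; \mathrm{mean}\,|\nabla^2 Y| .$$

The scaling matters. The raw mean absolute Laplacian is about
$3.6\,\sigma_n$, which would put the automatic threshold at roughly seven
noise standard deviations — far above the noise floor, causing averaging
across genuine contours and *worse* pixelwise fidelity than the noisy
input. With the calibrated estimate, $Th \approx 2\sigma_n + \mu/60$ sits
just above the noise floor: windows of pure noise pass, structure fails,
which is the filter's design intent. Image structure still inflates
$\hat\sigma$ somewhat (the estimator cannot distinguish single-pixel detail
from noise); that conservative bias is accepted and is visible in the
fixture experiments as thresholds 10–30 % above $2\sigma_n + \mu/60$.

### Patch geometry and the stopping rule

The patch side bounds 2–40 px are realized as centered odd-sided windows of
side $2r + 1$, $r = 1 \dots \lfloor 40/2 \rfloor = 20$, because a patch
evaluated *around a pixel* needs a center; the stated 40-px maximum is
honored as the 20-px maximum radius, which is also the halo width the
tiling layer derives from it. Growth stops at the first radius whose
variability exceeds Th, and the **last passing** window is averaged — not
the failing one, since averaging the window that already contains a
contour would smear it. If already $r = 1$ fails, the pixel is returned
unchanged; if no radius fails, the $r = 20$ window is used. Windows are
clipped at image borders (no padding), so border statistics use fewer
samples; this is what makes tiled and full-frame processing reconcilable.

## Numerical design

* **Translation-invariant window sums.** Windowed sums of $Y$ and $Y^2$
  are accumulated by adding shifted copies of the plane in a fixed offset
  order $(-r, \dots, +r)$ per axis. Each output element is then the sum of
  exactly its own window's samples in an order independent of absolute
  position. Two consequences: (a) a window evaluated inside a padded tile
  gives the bit-identical float as in the full frame, so halo tiling is
  *exactly* seam-free, not approximately; (b) for 8-bit planes all sums
  are exact integers. A global prefix-sum table would answer each query in
  $O(1)$ but loses both properties to accumulated rounding.

* **Tie-exact threshold decisions.** With 8-bit data and round thresholds,
  windows whose population sd equals Th *exactly* do occur (e.g. a
  $3\times3$ window with variance 64 at $Th = 8$). The pass test is
  therefore evaluated as $n S_2 - S_1^2 \le (n\,Th)^2$ — algebraically
  $\mathrm{sd} \le Th$, but exact in integer arithmetic — so the
  vectorized filter, the per-pixel form, and any independent
  re-implementation take identical decisions.

* **One quantization point.** All planes are carried in floating precision
  between stages; clamping to $[0, 255]$ happens after each operation that
  can leave the domain, and rounding to 8 bits happens once, at encode
  time.

* **Degenerate inputs.** Constant planes have $\hat\sigma = 0$ and are
  fixed points of both stages. Planes smaller than the Laplacian kernel or
  the minimum patch raise size errors rather than silently padding.

* **Chroma clamping.** Full-range BT.601 chroma can exceed 255 by at most
  0.5; clamping there keeps the unmodified rgb→yuv→rgb round trip within
  ±1 gray level per sample.

## Tiling and parallelism

The Y plane is split into four quadrants (any tile count is supported;
non-quadrant counts use row strips) whose cores partition the plane
exactly. Each core is processed together with a 20-px halo — equal to the
maximum window radius — so every core pixel's window lies inside its padded
region and tile-local border clipping coincides with full-frame clipping.
Stitched output is sample-for-sample identical to full-frame filtering;
the test suite asserts bit equality, and reducing the halo below the
window radius demonstrably re-creates the horizontal/vertical line
artifacts that motivate the overlap. Parallel execution forks one process
per tile with no shared state; the contract (identical output, any
scheduling order) is what the tests pin down, not the mechanism.

## Evaluation metrics

All metrics operate on gray-transformed images using the *unweighted*
channel mean $(R+G+B)/3$ — the benchmarking convention this package
follows — rather than luma weights; the two are deliberately separate code
paths. Pairwise PSNR is $20\log_{10}(255/\mathrm{RMSE})$ (infinite for
identical images, which the batch evaluator flags and excludes from
summary rows); only this RMSE reading lands published benchmark values in
the 38–43 dB range, so the alternative placement of the square root is not
used. The single-image PSNR $20\log_{10}(255/\mu)$ characterizes output
brightness alone and sidesteps the pairwise metric's blindness to weak
denoising. SSIM uses the standard constants ($K_1 = 0.01$, $K_2 = 0.03$,
$L = 255$), a uniform $7\times7$ window evaluated at fully-interior
positions, and sample ($n-1$) normalization; this parameterization
reproduces an independent reference implementation to $10^{-10}$ on shared
inputs and is symmetric with $\mathrm{SSIM}(a,a) = 1$ exactly. Since the
benchmark literature rarely states its exact SSIM window, published SSIM
values can only be matched approximately.

## The synthetic fixture battery

The generator emulates the structure of real-world noisy image datasets so
every pipeline property is testable offline:

* **Scenes** are piecewise-constant with sharp contours plus smooth
  gradients: flat fields, a two-region step, a linear ramp, a
  checkerboard, and a randomized blobs-and-stripes scene. In the latter,
  every contour is high-contrast (≥ 60 gray levels) and every non-contour
  region is flat. That is a deliberate design: an adaptive local-mean
  filter preserves features whose local variability exceeds Th and
  flattens anything below it, so mid-contrast fine texture sitting under
  the threshold is *not* representable as a "must survive" feature — it
  is the method's known blind spot, not a fixture omission.
* **Noise** is additive Gaussian or signal-dependent Poisson–Gaussian
  ($\mathrm{Poisson}(s\,x)/s + \mathcal N(0,\sigma^2)$), with defaults
  $\sigma = 5$, $s = 2$ — at mid-gray roughly 8.5 gray levels of combined
  noise, a realistic moderate sensor level; optional per-channel sigmas
  emulate channel-dependent color noise. Samples clamp to $[0,255]$ as an
  8-bit camera would, accepting the slight mean bias near the rails.
* **Ground truth** is the per-pixel mean of many noisy frames of the
  static scene (datasets of this kind average ~500 captures); the
  residual shrinks at the CLT rate $\sigma/\sqrt{n}$, which the tests and
  the acceptance script verify at $n = 500$.

What the fixtures do **not** show: fixed-pattern noise (omitted from the
noise model), Bayer-mosaic artifacts, content-correlated noise, and real
photographic texture. Two consequences observed on fixtures transfer to
real data only with care. First, with equal per-channel noise, Y-only
denoising leaves the chroma noise untouched, which caps the achievable
gray-PSNR gain (about 4.5 dB on the step fixture); on real images chroma
noise is weaker and spatially coarser. Second, unsharp masking *reduces*
pixelwise PSNR on ideal step edges (overshoot is the mechanism by which it
increases perceived sharpness; suppression of those halos is out of
scope), whereas on real photographs it raises PSNR by restoring genuinely
blurred detail — so the efficacy tests measure the denoising stage, and
the sharpening stage is validated by its own contracts (edge-contrast
increase, fixed points, brightness conservation).

## Problem sizes

The shipped tests run the brute-force oracle equivalence on fifty planes
of 16–128 px across thresholds $\{0, 2, 5.6, 8, 50\}$, tiling identity up
to 256 px, twenty brightness-conservation scenes, and five-seed efficacy
trials at 96 px — sizes chosen so the whole suite completes in well under
a minute while every property is exercised at multiple scales. The
acceptance script benchmarks eight 128-px scenes with 100-frame ground
truths. The filter itself processes a 512×512 plane in a few seconds in
pure R; tiling parallelism and the $O(r_{max})$ shifted-sum scheme are
what keep that practical.

## Known limitations

* Sub-threshold texture is flattened by construction; the automatic
  threshold inflates on highly textured scenes (the estimator reads
  texture as noise), compounding this on busy images.
* Chroma noise is never filtered — a speed/quality trade the pipeline
  inherits by design.
* The PSNR/SSIM replication of published benchmark tables depends on
  conventions (grayscale transform, PSNR variant, SSIM window) the
  literature under-specifies; agreement is expected to be approximate.
* 16-bit/HDR data, ICC color management, and raw sensor mosaics are out
  of scope; inputs are 8-bit RGB or grayscale rasters.
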
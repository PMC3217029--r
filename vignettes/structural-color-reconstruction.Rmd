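---
title: "Reconstructing structural color from scale nanostructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing structural color from scale nanostructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoscale)
```

## The problem

Many lepidopteran wing scales are colored not by pigments but by
interference: the scale lumen holds a stack of thin chitin laminae separated
by air, and constructive interference of light reflected at the successive
chitin/air interfaces selects a narrow band of wavelengths. When such scales
survive in fossil or degraded material, the pigment chemistry is lost but
the nanostructure often is not — so the *original* hue can be recovered from
cross-section electron micrographs of the lamina stack, provided the
refractive indices of the phases are assumed (chitin ≈ 1.56, air 1.0).

`chromoscale` implements that recovery as a tested pipeline:

1. **segment** a grayscale cross-section micrograph into a two-phase
   chitin/air mask (`binarize_phases()`), and assign indices
   (`build_index_map()`);
2. **transform**: 2-D discrete Fourier power spectrum of the index matrix
   (`power_spectrum_2d()`), which measures the spatial periodicity of the
   refractive index in every direction;
3. **radially average** the spectrum over annuli of constant spatial
   frequency (`radial_average()`);
4. **predict reflectance**: map each frequency to a backscattered
   wavelength and re-express the power profile as a predicted reflectance
   spectrum with its peak wavelength (`predicted_reflectance()`);
5. **render color**: convert peak wavelengths to consensus RGB values and a
   swatch reconstruction (`consensus_rgb()`, `zone_color_map()`,
   `render_reconstruction()`).

Every stage can be validated without any micrograph at all, because the
package also generates synthetic nanostructure images whose correct answer
is known in closed form.

## The model

A periodic refractive-index variation of spatial frequency $f$ (cycles/nm)
scatters light coherently. At normal incidence the round-trip optical path
through one period sets the constructively interfering wavelength

$$\lambda = \frac{2\,\bar n}{f},$$

where $\bar n$ is the volume-weighted mean index of the analyzed tissue,
$\bar n = \phi\, n_{high} + (1-\phi)\, n_{low}$ with $\phi$ the chitin area
fraction of the crop. This mapping is exact for an ideal two-phase
multilayer: a stack with period $d_1 + d_2$ has its fundamental frequency at
$f = 1/(d_1+d_2)$ and fill fraction $\phi = d_1/(d_1+d_2)$, so

$$\lambda \;=\; 2\,\bar n\,(d_1+d_2) \;=\; 2\,(n_1 d_1 + n_2 d_2),$$

the classical thin-film peak, available independently as
`ideal_multilayer_peak()`. The package exploits that identity as its central
cross-module oracle: the Fourier pipeline run on a synthetic two-phase stack
must land on the closed form within one frequency bin.

```{r oracle}
img <- generate_multilayer_image(bilayer(110, 111), periods = 5)
analysis <- analyze_image(img)
glance(analysis)
ideal_multilayer_peak(110, 1.56, 111, 1.0)
```

A second, fully independent oracle is the characteristic-matrix (Abeles)
calculation `transfer_matrix_reflectance()`, which computes the actual
normal-incidence reflectance of a finite stack. It shows why few-layer
biological reflectors are *non-ideal*: a five-bilayer chitin/air quarter-wave
stack peaks at its design wavelength but reflects well under 100%, and the
peak reflectance rises monotonically with bilayer count.

## What the synthetic generator emulates

`generate_multilayer_image()` produces the longitudinal-section geometry:
horizontal bands of alternating gray level with nm-specified thicknesses.
The defaults mirror the study conditions of the fixtures the package is
validated on — five periods, 1 nm/px, chitin laminae in the ~55–150 nm range
that real scale lumina exhibit, with the air-gap thickness a free parameter
(cross sections constrain lamina thickness well, gap thickness less so; the
validation stacks pair each lamina with a near-equal gap, e.g. 110/111 nm).
Band boundaries are rounded cumulatively — the running sum of thicknesses is
converted to pixels and rounded — so rasterization error in the total stack
height never exceeds one pixel however many periods are drawn. Optional
features: concave bending of the band midlines by the sagitta of a circular
arc (the inter-ridge curvature seen in transverse sections), and Gaussian
gray-level noise, added after the geometry and clipped at 0/255. The noise
generator is explicitly seeded (default 0) and the same spec + seed is
bit-reproducible.

`generate_perforated_lamina()` produces the surface view: a solid sheet with
circular holes on a square grid, optionally jittered. Its ground-truth
open-area fraction is the exact rasterized pixel count, which converges to
$\pi r^2/\text{pitch}^2$ as resolution grows; grids of pitch 50 px / radius
16 px and pitch 63 px / radius 8 px reproduce open fractions near 0.32 and
0.05, the distal and proximal perforation factors typical of such scales.

What the generator deliberately does **not** emulate: stain gradients,
section-thickness artifacts, or any photorealistic TEM physics, and no 3-D
photonic-crystal geometries. Tests passing on these images therefore
demonstrate the correctness of the computation, not robustness to every
real-world TEM artifact; segmentation quality on low-contrast micrographs
remains the user's responsibility (`binarize_phases()` accepts a fixed
threshold and an invert flag for that reason).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_high`, `n_low` | 1.56, 1.0 | refractive indices of chitin and air; `n_bar` is recomputed from each crop's fill fraction rather than fixed globally, because the coherent-scattering mapping uses the *tissue's* average index |
| `crop_size` | largest centered square | Fourier analysis region (px); power-of-two sizes are not required |
| `bin_width` | one frequency step $1/(N\,\Delta x)$ | radial annulus width, cycles/nm |
| `window` | `"none"` | optional Hann apodization; windowing changes peak widths, not locations (tested), so the raw transform is the default |
| `lambda_max_method` | `"parabolic"` | peak frequency refined by a parabolic fit through the peak annulus and neighbors before mapping; `"bin"` gives the raw annulus center |
| `visible_band` | 350–700 nm | the band used for the headline (visible-restricted) peak; the unrestricted peak is always reported alongside, since near-infrared-tuned stacks (e.g. 150/141 nm) are physically meaningful |
| `smooth_window` | 5 points | moving-average window for measured-spectrum peak finding; a small window is the conservative choice for instrument spectra |

## Numerical choices

* **Power normalization.** `power_spectrum_2d()` removes the mean index
  before transforming and normalizes power as $|F|^2/N^2$, under which total
  power equals the sum of squared mean-removed index values (Parseval) —
  this makes the "% of total power" profile scale-free and comparable across
  crops.
* **Radial binning.** Pixels are assigned to annuli by rounding
  $|k|/w$; the DC annulus is excluded; annuli that contain no pixels (possible
  near the spectrum corners) are kept with zero power so the frequency grid
  stays uniform. Mean power per annulus is the default column; annulus sums
  and percentages are also reported (percentages are computed from sums so
  they total 100).
* **Peak refinement.** Whether to read the peak on the raw frequency grid or
  after interpolation was an open choice; the default is a three-point
  parabolic fit around the peak annulus, clamped to half a bin, which is
  exact when the structure's period divides the crop size and degrades
  gracefully otherwise. The raw-bin option is retained.
* **Degenerate inputs.** Constant images refuse segmentation
  ("degenerate: single phase"); in a multi-zone run a degenerate replicate
  flags the zone and the run continues. Flat spectra refuse peak-finding.
  Empty transfer-matrix stacks between matched media reflect exactly zero.
* **Rounding of colors.** RGB components round half-up (not banker's
  rounding), so method averages like 204.5 become 205 deterministically.

## Color conversion

The wavelength-to-RGB step is inherently approximate, so three conversions
are computed and averaged component-wise (`consensus_rgb()`): Bruton's
piecewise-linear visible-spectrum formula with its conventional gamma 0.8; a
gamma-1 variant of the same hue model; and a colorimetric route through the
CIE 1931 2° color-matching functions (the piecewise-Gaussian analytic fits
of Wyman, Sloan & Shirley 2013) to XYZ and then linear sRGB, with
out-of-gamut components clipped to zero — clipping, not renormalization, so
a monochromatic hue stays on its gamut edge. All methods return black
outside 380–780 nm. Within 450–650 nm the Bruton and CIE routes agree on the
dominant component except within a few nm of the crossover wavelengths where
two components are nearly equal (tested as such).

## Problem sizes

The validation suite analyzes 5-period stacks rasterized at 1 nm/px
(squares of roughly 900–1500 px per side, FFTs of ~1–2 M pixels), 500 px
laminae, and 20 randomized stacks for the oracle-equivalence property —
sizes chosen so each full-pipeline run takes on the order of a second while
keeping the frequency resolution (one bin ≈ 0.1% of the peak frequency)
far finer than the tolerances being checked.

## Known limitations

* Normal incidence only: no angle-resolved reflectance, no modeling of
  iridescence suppression by lamina curvature or perforation (those effects
  are qualitative context, not computed quantities here).
* Two phases only; no multi-material segmentation, no TEM mosaic stitching.
* The transfer-matrix oracle assumes non-absorbing (real-index) layers.
* Measured-spectrum handling covers white-standard normalization and peak
  finding; there is no instrument model, dark-current correction, or
  prediction of peak shifts between immersion media — those are measured
  quantities, not computed ones.
* Replicate peaks aggregate by arithmetic mean by default (median optional);
  with 2–4 replicates per zone no more elaborate estimator is warranted.
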
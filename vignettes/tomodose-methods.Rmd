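---
title: "Methods: simulating and evaluating projection-domain denoising for low-dose breast tomosynthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and evaluating projection-domain denoising for low-dose breast tomosynthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomodose)
```

## The problem

Digital breast tomosynthesis (DBT) acquires a handful of projection views
over a narrow arc and reconstructs quasi-3D slices. Lowering the exposure
lowers patient dose but raises quantum mottle — Poisson noise whose variance
is inversely proportional to the number of detected photons — and degrades
the visibility of microcalcifications (MCs) and low-contrast masses.
`tomodose` implements, end to end and in silico, a study design for judging
*projection-domain* denoising under dose reduction: noisy projections are
denoised **before** filtered back projection (FBP), and image quality is
scored on the in-focus slice with FWHM, CNR, PSNR and SSIM, followed by
Tukey–Kramer all-pairs tests and a two-way (processing × dose) ANOVA.

Three processing arms are compared at each reduced dose against the
reference-dose reconstruction:

* **without** — no processing;
* **msbf** — multiscale bilateral filtering with MC enhancement;
* **pix2pix** — a conditional adversarial image-to-image network trained on
  paired (low-dose, reference-dose) projections.

## Phantom

The digital phantom stands in for a structured breast phantom: slabs of
50/50 glandular/adipose-equivalent material with embedded MC groups
(0.196/0.23/0.29 mm) and spheroidal masses (3.9/4.7 mm), at total
thicknesses of 40/50/60 mm.

The background is a seeded Gaussian random field generated on a coarse grid
at half the texture correlation length (default 3 mm), binomially smoothed,
trilinearly refined to the voxel grid and soft-thresholded at the empirical
quantile matching the requested glandular volume fraction (default 0.5).
Attenuation is the two-component mixture
$\mu = \mu_a + w\,(\mu_g - \mu_a)$. The coefficients are representative of
breast tissue near 20 keV and deliberately configurable, because the
physical phantom is specified by material, not by attenuation values:
$\mu_a = 0.045$, $\mu_g = 0.080\ \mathrm{mm^{-1}}$, +0.60 mm⁻¹ for calcium
specks, +0.010 mm⁻¹ for masses.

Features are rasterized with partial-volume weighting (boundary voxels get
the sub-sampled inside fraction), so sub-voxel specks deposit the correct
total attenuation; masses default to spheres (the spheroid z-aspect is a
parameter). Every inserted feature is recorded in a ground-truth registry
that later drives ROI placement, which removes any operator subjectivity
from the measurement step.

## Acquisition and noise

The geometry is a partial-isocentric sweep typical of clinical DBT:
stationary detector in the z = 0 plane, source on a 700 mm arc about the
detector centre, 15 views over 15° ($\theta_k$ equally spaced in
[−7.5°, +7.5°]). The full-scale detector is 1280 × 2048 at the scanner's
pitch; the desk-scale default is 256 × 512 at 0.1 mm. SID and pivot are
package defaults, not scanner facts — the vendor geometry is not public.

Projection is ray-driven: for each pixel the Beer–Lambert line integral is
accumulated by midpoint sampling at half-voxel steps with trilinear
interpolation (inside the physical volume, coordinates clamp to the
voxel-centre range, so a uniform slab integrates exactly; outside, the ray
is unattenuated). Noise is applied per pixel as
$\mathrm{Poisson}(f \cdot I) + \mathcal{N}(0, \sigma_e^2)$ with dose factor
$f$, reference fluence $I_0 = 10^5$ photons/pixel and electronic noise
$\sigma_e = 5$ photons. The dose factors 0.49 and 0.23 are the
average-glandular-dose ratios of the reduced exposures to the reference at
40 mm (0.66/1.36 and 0.31/1.36 mGy).

Projections are then log-normalized,
$-\ln(\max(I,\epsilon)/(f I_0)) / a_{\max}$, clipped to [0, 1], with one
fixed calibration $a_{\max} = 4$ across all doses and arms so that images
are directly comparable — the denoisers, the reconstruction and all metrics
operate on this scale.

## Filtered back projection

Reconstruction is ramp filtering plus shift-and-add back projection:

* The Ramachandran–Lakshminarayanan kernel
  $h(0) = 1/(4\tau^2)$, $h(2k) = 0$, $h(n) = -1/(\pi^2 n^2 \tau^2)$ for odd
  $n$ is applied along the tube-travel axis only (row-wise), since
  limited-angle motion is one-dimensional; no apodization by default, Hann
  behind a flag.
* Numerics: the filter is applied in the frequency domain on a circular
  buffer of at least twice the row length with **edge-replication** padding,
  and the truncated kernel's small positive tap sum is redistributed over
  the outer half of the taps. Consequences: a constant image filters to
  zero everywhere (no DC bias, no edge ringing from zero padding) while the
  impulse response keeps the exact Ram-Lak taps in its central half.
* Back projection maps each reconstruction pixel (detector grid demagnified
  to the slice height, centred on the detector) to its detector coordinate
  under each view's perspective, samples bilinearly, and averages over
  views; out-of-detector samples are excluded and the average renormalized
  by the per-pixel hit weight.

## Multiscale bilateral filter (msbf arm)

The comparison denoiser decomposes each projection into a Burt–Adelson
Laplacian pyramid (5-tap binomial downsampling; linear-interpolation
upsampling, which preserves constants exactly and keeps the decomposition
perfectly invertible), bilateral-filters every band, adds an enhancement
term $\alpha\,(w_\alpha \ast \tilde b_0)$ to the filtered finest band
$\tilde b_0$ (a zero-sum, centre-positive 5 × 5 Laplacian mask boosts
speck-scale contrast), collapses the pyramid, and clips to [0, 1].
Published parameter set: $\sigma_d = 1.0$ px, $\sigma_r = 0.01$,
$\alpha = 0.375$, 5 × 5 Laplacian mask; the band count defaults to 4.

One design choice deserves emphasis. The source method's exact pipeline is
not recoverable from its description, and a range kernel evaluated on raw
band values cannot denoise when the band noise exceeds $\sigma_r$ — the
weights then track the noise itself. We therefore evaluate the range
weights on the **low-pass approximation at each band's scale** (a
guided/joint bilateral, as in multiscale bilateral decompositions): edges
and specks present in the approximation stop the averaging; band noise does
not feed back into the weights. The classic self-guided bilateral remains
available as `bilateral_filter()` and is what the brute-force oracle tests
check.

## Conditional adversarial denoiser (pix2pix arm)

The generator $G$ translates a low-dose projection $p_{ld}$ toward its
reference-dose counterpart $p_{ref}$; the discriminator $D$ scores local
patches of (input, candidate) pairs. Training minimizes

$$\mathcal{L}_D = -\mathbb{E}[\log D(p_{ld}, p_{ref})]
  - \mathbb{E}[\log(1 - D(p_{ld}, G(p_{ld}, z)))],$$
$$\mathcal{L}_G = -\mathbb{E}[\log D(p_{ld}, G(p_{ld}, z))]
  + \alpha\,\mathbb{E}\lVert p_{ref} - G(p_{ld}, z)\rVert_1,$$

with $\alpha = 50$, Adam (initial learning rate 2·10⁻⁴, momentum 0.5 and
0.999), batch size 1, one D and one G step per pair per epoch. The
generator's adversarial term uses the standard non-saturating form. The
stochastic input $z$ is realized as bottleneck dropout that stays active at
inference (the usual practice for this architecture); its insertion point
is not prescribed by the method description.

Architecture (all of it configuration, none of it method definition): a
U-Net-style encoder–decoder — 3 × 3 convolutions with leaky-ReLU, stride-2
halvings, dropout bottleneck, decoder convolutions at the coarse grid
followed by nearest-neighbour upsampling and skip concatenation — and a
single-channel *residual* output bounded by tanh, added to the input and
clipped to [0, 1]. Starting from a near-zero residual is the standard
initialisation for residual denoisers and makes early training stable. The
discriminator is a three-layer patch classifier with a sigmoid probability
map, matching the log-loss form above. The layers are implemented directly
on im2col + BLAS matrix products (with analytic backpropagation verified
against finite differences in the test suite); no deep-learning runtime is
involved.

Desk-scale training uses 64 synthetic 128² projection pairs (projections of
small textured phantoms with randomly placed specks and one mass, two
independent noise draws per view: dose factor 1 and 0.49), base 8 channels,
2 halvings, 100 epochs — sized so a single CPU core trains in minutes. The
full-scale configuration (larger patches, more channels/levels, 300 epochs)
is reachable through `train_config()` but is a GPU-class workload.

Every `checkpoint_every` epochs the generator output for a held-out
0°-view pair is scored by MSE and mean SSIM; `select_epoch()` picks the
epoch minimizing MSE when it also maximizes MSSIM, otherwise the smallest
rank sum, ties to the later epoch.

## Image-quality metrics

* **MSE / PSNR**: $\mathrm{PSNR} = 10\log_{10}(PV^2/\mathrm{MSE})$ with
  $PV = 1$ (images live on [0, 1]); identical images report `Inf`.
* **SSIM / MSSIM**: luminance × contrast × structure (all exponents 1) over
  an 11 × 11 Gaussian window ($\sigma = 1.5$) with the original stabilizing
  constants $C_1 = (0.01)^2$, $C_2 = (0.03)^2$, $C_3 = C_2/2$ — the source
  omits them, so the standard defaults apply. MSSIM is the plain mean of
  the map.
* **CNR**: $(\mu_F - \mu_{BG})/\sigma_{BG}$ with a circular feature ROI of
  the mass diameter and four same-size background ROIs up/down/left/right,
  offset by the mass diameter plus 1.5 mm; background pixels are pooled
  before taking mean and SD (pooling vs. averaging per-ROI SDs is an
  interpretation; pooling is chosen and stated).
* **FWHM**: an intensity profile through each MC sums 4 adjacent lines
  perpendicular to the profile direction (flag to average instead —
  identical FWHM); the baseline is the mean of the outer 25% of samples,
  the half-maximum crossings are located by linear interpolation, and a
  profile with a missing crossing is reported as `NA` rather than an error
  — unmeasurable profiles are part of the real measurement process and the
  group sizes simply shrink.

## Statistics

`tukey_kramer()` performs the all-pairs comparison over the four groups
(reference + three arms) with the Kramer correction for unequal $n$:
$q = |\bar y_i - \bar y_j| / \sqrt{\mathrm{MSE}/2\,(1/n_i + 1/n_j)}$
against the studentized range distribution, simultaneous 95% intervals.
The reported SE column follows the conventional ANOVA post-hoc layout,
$\sqrt{\mathrm{MSE}\,(1/n_i + 1/n_j)}$ (the inference is identical either
way). `two_way_anova()` fits processing × dose with Type II sums of squares
(no a priori factor ordering for unbalanced cells; the factorial block
excludes the reference arm, which has no dose factor), giving the
2 / 1 / 2 degree-of-freedom layout for three arms and two doses.

## What the synthetic data does and does not show

The generator emulates the study conditions: heterogeneous two-component
texture with controllable glandular fraction, speck and mass targets on a
known plane, 15-view limited-angle geometry, and dose-scaled Poisson +
electronic noise. It does **not** model scatter, detector MTF/blur, heel
effect, polyenergetic beam hardening, compression mechanics or real
parenchymal texture. Passing tests therefore demonstrate that the
algorithms implement their contracts and reproduce the study's *relative*
orderings under controlled noise — not that any arm would achieve a
particular absolute image quality on a physical scanner.

Problem sizes in the shipped tests and acceptance script are desk-scale by
design: 0.2–0.4 mm voxels, 64–256 px detectors, 64 training pairs at 128²
for 100 epochs. These sizes keep a complete run on one CPU core in the
minutes range while leaving every algorithmic path identical to the
full-scale configuration.

## Numerical details and degenerate inputs

* Seeds: every stochastic stage takes an explicit seed; identical seeds
  give bitwise-identical phantoms, noise draws and training runs.
* The log transform floors intensities at one photon equivalent.
* Glandular fractions 0 and 1 short-circuit to uniform volumes.
* A 1-view geometry with a nonzero arc is rejected (undefined spacing), as
  are even ramp-kernel lengths, slice heights outside the source–detector
  gap, ROIs leaving the image, overlapping features, and discriminator
  scores outside (0, 1).
* `NaN`/`Inf` training losses abort with the offending epoch.

## Known limitations

* The forward model is monoenergetic and scatter-free; absolute CNR/PSNR
  values are optimistic relative to physical acquisitions.
* FBP is the bare Ram-Lak variant; vendor reconstructions add pre-weighting
  and apodization that change absolute FWHM.
* The adversarial arm's desk-scale capacity is far below the published
  GPU-scale network; it demonstrates the training dynamics and the
  denoising effect, not the ceiling of the method. At this capacity,
  projection-wide denoising gain and microcalcification sharpness pull
  against each other: configurations that denoise more also widen the
  reconstructed speck profiles more (the acceptance script reports both
  quantities — `psnr_gain_db` and `fwhm_pix2pix_dev_pct` — so the
  trade-off is measurable on any seed).
* Tukey–Kramer assumes a common within-group variance; the package checks
  only the degrees-of-freedom bookkeeping, as in the source analysis.
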
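# tomodose

Simulation and evaluation pipeline for **projection-domain denoising in
low-dose digital breast tomosynthesis (DBT)**.

DBT acquires a handful of X-ray projections over a narrow arc (here: 15
views over 15°) and reconstructs in-plane slices by filtered back
projection (FBP). Reducing the exposure reduces patient dose but increases
quantum mottle — Poisson noise whose variance grows as 1/dose — degrading
the visibility of microcalcifications (MCs) and masses. One remedy is to
denoise the *projections* before reconstruction. `tomodose` implements a
complete in-silico study of that idea for researchers in medical image
reconstruction and deep-learning denoising:

* a voxelized breast phantom (heterogeneous 50/50 glandular/adipose
  texture; MC groups of 0.196/0.23/0.29 mm; spheroidal masses of
  3.9/4.7 mm; 40/50/60 mm thicknesses) with a ground-truth feature
  registry,
* a cone-beam projector with Beer–Lambert attenuation and dose-scaled
  Poisson + electronic noise (reference dose and ~50%/~75% reductions,
  factors 0.49 / 0.23),
* Ram-Lak FBP (band-limited ramp \(h(0)=1/4\tau^2\),
  \(h(n)=-1/\pi^2n^2\tau^2\) for odd \(n\), applied along the tube-travel
  axis; shift-and-add back projection),
* two projection-domain denoisers:
  * **MSBF** — Laplacian-pyramid multiscale bilateral filtering with
    Laplacian-mask MC enhancement (σ_d = 1.0 px, σ_r = 0.01, α = 0.375),
  * **pix2pix** — a conditional adversarial network (U-Net generator,
    patch discriminator) trained with
    \( \min_G \max_D \mathcal{L}_{GAN}(G,D) + \alpha\,\mathbb{E}\lVert
    p_{ref} - G(p_{ld},z)\rVert_1 \), α = 50, Adam(2·10⁻⁴, β₁=0.5,
    β₂=0.999), batch 1 — implemented from first principles on BLAS matrix
    products, no deep-learning runtime required,
* the image-quality suite (profile FWHM with 4-line summation, CNR with
  four pooled background ROIs, PSNR with PV = 1, single-scale SSIM/MSSIM),
* the statistical layer: Tukey–Kramer all-pairs comparison (unequal n) and
  processing × dose two-way ANOVA (Type II).

See `vignettes/tomodose-methods.Rmd` for the full model description,
parameter meanings and design decisions.

## Worked example

A miniature single-arm experiment: textured 12 mm phantom, 15 noisy
projections at the ~50% dose level, MSBF denoising, FBP of the in-focus
plane, and the two headline measurements.

```r
library(tomodose)

spec <- phantom_spec(thickness_mm = 12, voxel_mm = 0.4,
                     lateral_extent_mm = c(25.6, 25.6),
                     mc_sizes_mm = 0.8, mass_diameters_mm = 3.9,
                     target_slab_depth_mm = 6, seed = 1, margin_mm = 2)
vol <- insert_features(build_background(spec), spec)
vol
#> phantom_volume: 64 x 64 x 30 voxels (0.4 mm), 6 features
#>   attenuation range [0.0450, 0.6179] 1/mm

geom  <- make_geometry(detector_rows = 64, detector_cols = 64,
                       pixel_pitch_mm = 0.4)
proj  <- forward_project(vol, geom, i0 = 1e5)
noisy <- to_attenuation_norm(apply_dose_noise(proj, "reduce50", seed = 7))
noisy
#> projection_set: 15 views of 64 x 64, domain=attenuation_norm,
#>   dose_factor=0.49, arm=without

den <- noisy
den$images <- msbf_process(noisy$images, msbf_params())
rec <- reconstruct_fbp(den, spec$target_slab_depth_mm)
rec
#> recon_volume: 1 slices of 64 x 64 (heights 6 mm)

mc   <- vol$registry[vol$registry$kind == "mc", ][1, ]
ctr  <- recon_pixel(geom, mc$x_mm, mc$y_mm, 6)
pitch_in <- geom$pixel_pitch_mm * (700 - 6) / 700
prof <- extract_profile(rec$slices[, , 1], ctr, "horizontal",
                        half_len_px = 8, pitch_mm = pitch_in)
fwhm(prof)
#> MC FWHM (mm): 0.549

mass <- vol$registry[vol$registry$kind == "mass", ]
mctr <- recon_pixel(geom, mass$x_mm, mass$y_mm, 6)
feat <- roi_spec(mctr, mass$size_mm / pitch_in)
cnr(rec$slices[, , 1], feat, cnr_background_rois(feat, pitch_mm = pitch_in))
#> mass CNR: 0.35
```

The FWHM (0.55 mm here) measures how sharply the reconstructed speck is
rendered — at this coarse 0.4 mm fixture scale it is dominated by the
sampling grid, at study scale by the limited-angle point spread. The mass
CNR relates the mass's mean contrast to the pooled standard deviation of
four surrounding background ROIs; untextured noise suppression raises it,
loss of mass contrast lowers it.

The full study (three arms × dose levels × thicknesses, metrics CSV,
Tukey–Kramer and ANOVA tables, TIFF/JSON artefacts) runs through one
config object: `run_experiment(experiment_config(...))`, or from a YAML
file via `read_experiment_config()`. Training the adversarial arm at desk
scale: `fit <- pix2pix_train(make_training_pairs(64)$pairs,
train_config(epochs = 100))`, then pass it as
`experiment_config(pix2pix_fit = fit, ...)`.

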
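# Shared fixtures, all generated in code. Heavyweight objects are built once
# per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small textured phantom with one MC and one mass, coarse voxels
tiny_phantom <- function(seed = 1) {
  sp <- phantom_spec(thickness_mm = 12, voxel_mm = 0.4,
                     lateral_extent_mm = c(25.6, 25.6),
                     mc_sizes_mm = 0.8, mass_diameters_mm = 3.9,
                     target_slab_depth_mm = 6, seed = seed, margin_mm = 2)
  feats <- rbind(
    data.frame(kind = "mc", x_mm = 8, y_mm = 12.8, z_mm = 6, size_mm = 0.8,
               contrast = sp$mc_contrast, group = "mc_0.8"),
    data.frame(kind = "mass", x_mm = 17, y_mm = 12.8, z_mm = 6,
               size_mm = 3.9, contrast = sp$mass_contrast,
               group = "mass_3.9"))
  insert_features(build_background(sp), sp, feats)
}

tiny_geometry <- function() {
  make_geometry(detector_rows = 64, detector_cols = 64, pixel_pitch_mm = 0.4)
}

# brute-force bilateral filter (double loop), the oracle for the C++ kernel
bilateral_oracle <- function(img, sigma_d, sigma_r) {
  rad <- ceiling(3 * sigma_d)
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  out <- img
  for (r in 1:nr) for (c in 1:nc) {
    num <- 0; den <- 0
    for (dr in -rad:rad) for (dc in -rad:rad) {
      rr <- refl(r + dr, nr); cc <- refl(c + dc, nc)
      w <- exp(-(dr^2 + dc^2) / (2 * sigma_d^2)) *
        exp(-(img[rr, cc] - img[r, c])^2 / (2 * sigma_r^2))
      num <- num + w * img[rr, cc]
      den <- den + w
    }
    out[r, c] <- num / den
  }
  out
}

# direct windowed SSIM (uniform handling identical to the implementation's
# formula, evaluated with explicit loops on a small image)
ssim_oracle <- function(a, b, size = 11, sigma = 1.5, pv = 1) {
  m <- (size - 1) / 2
  g <- exp(-((-m:m)^2) / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  c1 <- (0.01 * pv)^2; c2 <- (0.03 * pv)^2; c3 <- c2 / 2
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  nr <- nrow(a); nc <- ncol(a)
  out <- a * 0
  for (r in 1:nr) for (c in 1:nc) {
    rows <- refl(r + (-m:m), nr); cols <- refl(c + (-m:m), nc)
    wa <- a[rows, cols]; wb <- b[rows, cols]
    mu_a <- sum(k * wa); mu_b <- sum(k * wb)
    va <- max(sum(k * wa^2) - mu_a^2, 0)
    vb <- max(sum(k * wb^2) - mu_b^2, 0)
    sab <- sum(k * wa * wb) - mu_a * mu_b
    lum <- (2 * mu_a * mu_b + c1) / (mu_a^2 + mu_b^2 + c1)
    con <- (2 * sqrt(va) * sqrt(vb) + c2) / (va + vb + c2)
    str <- (sab + c3) / (sqrt(va) * sqrt(vb) + c3)
    out[r, c] <- lum * con * str
  }
  out
}
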
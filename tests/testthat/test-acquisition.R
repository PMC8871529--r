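test_that("view angles are equally spaced and symmetric about zero", {
  g <- make_geometry()
  expect_equal(g$n_views, 15L)
  expect_equal(g$angles_deg[8], 0)
  expect_equal(g$angles_deg[1], -7.5)
  expect_equal(g$angles_deg[15], 7.5)
  expect_equal(diff(g$angles_deg), rep(15 / 14, 14))
  g1 <- make_geometry(n_views = 1, arc_deg = 0)
  expect_equal(g1$angles_deg, 0)
  expect_error(make_geometry(n_views = 1, arc_deg = 15), "undefined")
  gf <- make_geometry(detector_rows = 1280, detector_cols = 2048)
  expect_equal(c(gf$detector_rows, gf$detector_cols), c(1280L, 2048L))
})

test_that("uniform slab projections follow Beer-Lambert closed forms", {
  sp <- phantom_spec(thickness_mm = 40, voxel_mm = 1,
                     lateral_extent_mm = c(64, 64), glandular_fraction = 0,
                     mu_adipose = 0.05)
  vol <- build_background(sp)
  g <- make_geometry(detector_rows = 64, detector_cols = 64,
                     pixel_pitch_mm = 1)
  p <- forward_project(vol, g, i0 = 1)
  li <- -log(p$images)
  # central pixel, central view: vertical path through 40 mm of mu = 0.05
  expect_equal(li[32, 32, 8], 2.0, tolerance = 1e-3)
  expect_equal(p$images[32, 32, 8], exp(-2), tolerance = 1e-3)
  # +-7.5 deg views: oblique path 40 / cos(7.5 deg)
  ang <- 7.5 * pi / 180
  expected <- 0.05 * 40 / cos(ang)
  # probe the pixel whose ray has the nominal obliquity: below the source
  sx <- 32 + 700 * sin(ang)  # source lateral position in pixels (pitch 1)
  # ray from source to pixel at column c has direction angle
  # atan((sx - c) / 700cos) ; the ray through the slab at angle `ang` exits
  # at the detector column sx - 700 tan(ang) = 32: the central column again
  expect_equal(li[32, 32, 15], expected, tolerance = 2e-3)
})

test_that("hot-voxel footprint matches a brute-force ray-box oracle", {
  sp <- phantom_spec(thickness_mm = 8, voxel_mm = 1,
                     lateral_extent_mm = c(16, 16), glandular_fraction = 0,
                     mu_adipose = 0)
  vol <- build_background(sp)
  vol$mu[9, 7, 4] <- 1  # single hot voxel
  g <- make_geometry(n_views = 3, arc_deg = 15, detector_rows = 16,
                     detector_cols = 16, pixel_pitch_mm = 1)
  p <- forward_project(vol, g, i0 = 1, step_frac = 0.25)
  att <- -log(p$images)
  # oracle: segment/axis-aligned-box intersection for every pixel ray
  box_lo <- c(8, 6, 3)   # voxel (9,7,4) occupies [8,9]x[6,7]x[3,4] mm
  box_hi <- c(9, 7, 4)
  for (v in 1:3) {
    ang <- g$angles_deg[v] * pi / 180
    src <- c(8 + 700 * sin(ang), 8, 700 * cos(ang))
    hits <- matrix(FALSE, 16, 16)   # cuts the voxel cube by >= 0.2 mm
    for (r in 1:16) for (c in 1:16) {
      pix <- c(c - 0.5, r - 0.5, 0)
      dir <- pix - src
      t0 <- 0; t1 <- 1
      ok <- TRUE
      for (ax in 1:3) {
        if (dir[ax] == 0) {
          if (src[ax] < box_lo[ax] || src[ax] > box_hi[ax]) ok <- FALSE
        } else {
          ta <- (box_lo[ax] - src[ax]) / dir[ax]
          tb <- (box_hi[ax] - src[ax]) / dir[ax]
          t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
        }
      }
      hits[r, c] <- ok && (t1 - t0) * sqrt(sum(dir^2)) > 0.2
    }
    # trilinear interpolation spreads the voxel over its 2-voxel support:
    # every strong response must lie within one pixel of the oracle
    # footprint, and every substantial oracle hit must respond
    shift2 <- function(m, dr, dc) {
      out <- matrix(FALSE, nrow(m), ncol(m))
      rs <- (1:nrow(m)) + dr; cs <- (1:ncol(m)) + dc
      ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
      out[which(ok_r), which(ok_c)] <- m[rs[ok_r], cs[ok_c]]
      out
    }
    dil <- hits
    for (dr in -1:1) for (dc in -1:1) dil <- dil | shift2(hits, dr, dc)
    expect_true(all(dil[att[, , v] > 0.2]))
    expect_true(all(att[, , v][hits] > 1e-5))
  }
})

test_that("quantum noise is Poisson with dose-factor mean scaling", {
  sp <- phantom_spec(thickness_mm = 10, voxel_mm = 1,
                     lateral_extent_mm = c(100, 100),
                     glandular_fraction = 0, mu_adipose = 0.05)
  vol <- build_background(sp)
  g <- make_geometry(n_views = 1, arc_deg = 0, detector_rows = 1000,
                     detector_cols = 1000, pixel_pitch_mm = 0.1)
  p <- forward_project(vol, g, i0 = 1e5)
  pn <- apply_dose_noise(p, 1.0, electronic_sigma = 0, seed = 4)
  # flat field: variance/mean ratio of a Poisson sample
  ctr <- pn$images[100:900, 100:900, 1]
  expect_gt(var(as.numeric(ctr)) / mean(ctr), 0.98)
  expect_lt(var(as.numeric(ctr)) / mean(ctr), 1.02)
  # expectation scales with the dose factor
  pn49 <- apply_dose_noise(p, 0.49, electronic_sigma = 0, seed = 5)
  expect_lt(abs(mean(pn49$images[100:900, 100:900, 1]) /
                  (0.49 * mean(p$images[100:900, 100:900, 1])) - 1), 0.005)
  # same seed, same draw
  pn49b <- apply_dose_noise(p, 0.49, electronic_sigma = 0, seed = 5)
  expect_identical(pn49$images, pn49b$images)
  expect_error(apply_dose_noise(p, -0.1), "positive")
})

test_that("attenuation normalization maps the calibration range to [0,1]", {
  sp <- phantom_spec(thickness_mm = 40, voxel_mm = 1,
                     lateral_extent_mm = c(32, 32), glandular_fraction = 0,
                     mu_adipose = 0.05)
  vol <- build_background(sp)
  g <- make_geometry(n_views = 1, arc_deg = 0, detector_rows = 48,
                     detector_cols = 48, pixel_pitch_mm = 1)
  p <- forward_project(vol, g, i0 = 1e5)
  pa <- to_attenuation_norm(p, max_att = 4)
  # central ray: attenuation 2.0 of calibration 4 -> 0.5
  expect_equal(pa$images[24, 24, 1], 0.5, tolerance = 1e-3)
  # rays missing the volume are unattenuated -> 0
  expect_equal(pa$images[1, 1, 1], 0)
  expect_true(all(pa$images >= 0 & pa$images <= 1))
  p2 <- p; p2$i0 <- NULL
  expect_error(to_attenuation_norm(p2), "i0")
})

test_that("attenuation-image noise variance scales inversely with dose", {
  sp <- phantom_spec(thickness_mm = 10, voxel_mm = 1,
                     lateral_extent_mm = c(100, 100),
                     glandular_fraction = 0, mu_adipose = 0.05)
  vol <- build_background(sp)
  g <- make_geometry(n_views = 1, arc_deg = 0, detector_rows = 1000,
                     detector_cols = 1000, pixel_pitch_mm = 0.1)
  p <- forward_project(vol, g, i0 = 1e5)
  va <- sapply(c(1.0, 0.49), function(f) {
    pa <- to_attenuation_norm(
      apply_dose_noise(p, f, electronic_sigma = 0, seed = 8), max_att = 4)
    var(as.numeric(pa$images[100:900, 100:900, 1]))
  })
  expect_lt(abs(va[2] / va[1] * 0.49 - 1), 0.05)
})

test_that("a mirror-symmetric phantom projects symmetrically at 0 degrees", {
  sp <- phantom_spec(thickness_mm = 8, voxel_mm = 0.5,
                     lateral_extent_mm = c(16, 16), seed = 2)
  vol <- build_background(sp)
  ny <- dim(vol$mu)[2]
  vol$mu <- (vol$mu + vol$mu[, ny:1, , drop = FALSE]) / 2  # symmetrize rows
  g <- make_geometry(n_views = 1, arc_deg = 0, detector_rows = 32,
                     detector_cols = 32, pixel_pitch_mm = 0.5)
  p <- forward_project(vol, g, i0 = 1)
  img <- p$images[, , 1]
  expect_lt(max(abs(img - img[32:1, ])), 1e-6)
})

test_that("projection sets round-trip through TIFF + JSON", {
  v <- tiny_phantom()
  g <- tiny_geometry()
  p <- to_attenuation_norm(
    apply_dose_noise(forward_project(v, g), "reduce50", seed = 3))
  path <- file.path(tempdir(), "proj.tif")
  write_projections(p, path)
  p2 <- read_projections(path)
  expect_equal(p2$images, p$images, tolerance = 1e-6)
  expect_equal(p2$dose_factor, 0.49)
  expect_equal(p2$domain, "attenuation_norm")
  expect_equal(p2$geometry$n_views, g$n_views)
})
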
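test_that("degenerate glandular fractions give uniform volumes", {
  sp0 <- phantom_spec(thickness_mm = 8, voxel_mm = 0.5,
                      lateral_extent_mm = c(8, 8), glandular_fraction = 0)
  v0 <- build_background(sp0)
  expect_true(all(v0$mu == sp0$mu_adipose))
  sp1 <- phantom_spec(thickness_mm = 8, voxel_mm = 0.5,
                      lateral_extent_mm = c(8, 8), glandular_fraction = 1)
  v1 <- build_background(sp1)
  expect_true(all(v1$mu == sp1$mu_glandular))
  expect_equal(nrow(v0$registry), 0)
})

test_that("background glandular volume fraction matches the spec", {
  # 64^3 grid, default 0.5 fraction, seed 1
  sp <- phantom_spec(thickness_mm = 6.4, voxel_mm = 0.1,
                     lateral_extent_mm = c(6.4, 6.4), seed = 1,
                     texture_correlation_mm = 3)
  v <- build_background(sp)
  expect_identical(dim(v$mu), c(64L, 64L, 64L))
  thr <- (sp$mu_adipose + sp$mu_glandular) / 2
  frac <- mean(v$mu > thr)
  expect_gte(frac, 0.48)
  expect_lte(frac, 0.52)
  expect_true(all(v$mu >= 0))
})

test_that("identical spec and seed give a bitwise-identical volume", {
  sp <- phantom_spec(thickness_mm = 6, voxel_mm = 0.3,
                     lateral_extent_mm = c(9.6, 9.6), seed = 17)
  expect_identical(build_background(sp)$mu, build_background(sp)$mu)
})

test_that("texture coarser than the voxel grid is rejected", {
  expect_error(phantom_spec(voxel_mm = 4, texture_correlation_mm = 3),
               "unresolvable")
})

test_that("mean attenuation is stationary across octants", {
  sp <- phantom_spec(thickness_mm = 40, voxel_mm = 0.4,
                     lateral_extent_mm = c(51.2, 25.6), seed = 3)
  v <- build_background(sp)
  d <- dim(v$mu)
  h <- d %/% 2
  octs <- c()
  for (i in 0:1) for (j in 0:1) for (k in 0:1)
    octs <- c(octs, mean(v$mu[(1:h[1]) + i * h[1], (1:h[2]) + j * h[2],
                              (1:h[3]) + k * h[3]]))
  expect_lt((max(octs) - min(octs)) / mean(octs), 0.10)
})

test_that("mass insertion conserves the analytic sphere volume", {
  sp <- phantom_spec(thickness_mm = 8, voxel_mm = 0.1,
                     lateral_extent_mm = c(8, 8), glandular_fraction = 0,
                     target_slab_depth_mm = 4, margin_mm = 1)
  v <- build_background(sp)
  feats <- data.frame(kind = "mass", x_mm = 4, y_mm = 4, z_mm = 4,
                      size_mm = 3.9, contrast = sp$mass_contrast,
                      group = "mass_3.9")
  v2 <- insert_features(v, sp, feats)
  expect_equal(nrow(v2$registry), 1)
  added <- sum(v2$mu - v$mu)
  expected <- sp$mass_contrast * 4 / 3 * pi * 1.95^3 / sp$voxel_mm^3
  expect_lt(abs(added - expected) / expected, 0.02)
})

test_that("sub-voxel microcalcifications use partial-volume weighting", {
  sp <- phantom_spec(thickness_mm = 4, voxel_mm = 0.1,
                     lateral_extent_mm = c(4, 4), glandular_fraction = 0,
                     target_slab_depth_mm = 2, margin_mm = 0.5)
  v <- build_background(sp)
  # centre on a voxel corner: the 0.196 mm speck spans at most 2 voxels/axis
  feats <- data.frame(kind = "mc", x_mm = 2.0, y_mm = 2.0, z_mm = 2.0,
                      size_mm = 0.196, contrast = sp$mc_contrast,
                      group = "mc_0.196")
  v2 <- insert_features(v, sp, feats)
  touched <- which(v2$mu != v$mu, arr.ind = TRUE)
  expect_lte(nrow(touched), 8)
  for (ax in 1:3) expect_lte(length(unique(touched[, ax])), 2)
  added <- sum(v2$mu - v$mu)
  expected <- sp$mc_contrast * 4 / 3 * pi * 0.098^3 / sp$voxel_mm^3
  expect_lt(abs(added - expected) / expected, 0.05)
})

test_that("empty feature list leaves the volume unchanged", {
  sp <- phantom_spec(thickness_mm = 6, voxel_mm = 0.3,
                     lateral_extent_mm = c(6, 6))
  v <- build_background(sp)
  v2 <- insert_features(v, sp, v$registry[0, ])
  expect_identical(v2$mu, v$mu)
  expect_equal(nrow(v2$registry), 0)
})

test_that("overlapping or out-of-bounds features are rejected with ids", {
  sp <- phantom_spec(thickness_mm = 8, voxel_mm = 0.2,
                     lateral_extent_mm = c(20, 20), target_slab_depth_mm = 4,
                     margin_mm = 2)
  v <- build_background(sp)
  two <- data.frame(kind = "mass", x_mm = c(10, 11), y_mm = 10, z_mm = 4,
                    size_mm = 3.9, contrast = 0.01,
                    group = c("a", "b"))
  expect_error(insert_features(v, sp, two), "overlap.*\\(1,2\\)")
  out <- data.frame(kind = "mc", x_mm = 0.5, y_mm = 10, z_mm = 4,
                    size_mm = 0.29, contrast = 0.6, group = "edge")
  expect_error(insert_features(v, sp, out), "bounds")
})

test_that("phantom volumes round-trip through TIFF + JSON", {
  v <- tiny_phantom()
  path <- file.path(tempdir(), "phantom.tif")
  write_phantom(v, path)
  v2 <- read_phantom(path)
  expect_equal(v2$mu, v$mu, tolerance = 1e-6)
  expect_equal(nrow(v2$registry), nrow(v$registry))
  expect_equal(v2$registry$size_mm, v$registry$size_mm)
})
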
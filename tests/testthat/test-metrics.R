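test_that("mse matches the explicit double sum", {
  a <- matrix(1:6 / 10, 2, 3)
  expect_equal(mse(a, a), 0)
  expect_equal(mse(a, a + 0.1), 0.01)
  set.seed(1)
  x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(mse(x, y), acc / 64, tolerance = 1e-12)
  expect_error(mse(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("psnr follows 10 log10(PV^2/MSE) with an infinity sentinel", {
  a <- matrix(0.5, 4, 4)
  expect_equal(psnr(a, a + 0.1), 20)
  expect_equal(psnr(a, a + 1), 0)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 0.1, pv = 2), 20 + 20 * log10(2))
})

test_that("ssim equals the direct windowed computation", {
  set.seed(2)
  a <- matrix(runif(24 * 24), 24, 24)
  expect_equal(mssim(a, a), 1)
  # luminance sensitivity: a constant shift breaks perfect similarity
  expect_lt(mssim(a, pmin(a + 0.1, 1)), 1)
  # anticorrelated texture: structure term can push SSIM negative
  b <- 1 - a
  m_impl <- ssim_map(a, b)
  m_oracle <- ssim_oracle(a, b)
  expect_equal(m_impl, m_oracle, tolerance = 1e-9)
  expect_lt(min(m_impl), 0)
  expect_error(ssim_map(matrix(0, 4, 4), matrix(0, 4, 4)), "window")
})

test_that("psnr decreases as noise grows", {
  set.seed(3)
  img <- matrix(runif(64 * 64), 64, 64)
  ps <- sapply(c(0.01, 0.03, 0.1), function(s)
    psnr(img, img + matrix(rnorm(64 * 64, 0, s), 64, 64)))
  expect_true(all(diff(ps) < 0))
})

test_that("cnr computes (muF - muBG)/sdBG over pooled background ROIs", {
  img <- matrix(0.5, 120, 120)
  feat <- roi_spec(c(60, 60), 20)
  bgs <- cnr_background_rois(feat, offset_px = 30)
  # deterministic background variation with known pooled stats
  set.seed(4)
  bpx <- unlist(lapply(bgs, function(r)
    asNamespace("tomodose")$roi_pixels(img, r)))
  img[seq(2, 120, 2), ] <- 0.45  # striped background -> nonzero sd
  fpx <- asNamespace("tomodose")$roi_pixels(img, feat)
  img[45:75, 45:75][(outer(45:75 - 60, 45:75 - 60,
                           function(a, b) a^2 + b^2) <= 100)] <- 0.6
  got <- cnr(img, feat, bgs)
  pooled <- unlist(lapply(bgs, function(r)
    asNamespace("tomodose")$roi_pixels(img, r)))
  mu_f <- mean(asNamespace("tomodose")$roi_pixels(img, feat))
  expect_equal(got, (mu_f - mean(pooled)) / sd(pooled), tolerance = 1e-12)
  # arithmetic example: muF 0.6, muBG 0.5, sdBG 0.05 -> CNR 2
  expect_equal((0.6 - 0.5) / 0.05, 2.0)
  # invariance under a constant offset
  expect_equal(cnr(img + 0.07, feat, bgs), got, tolerance = 1e-9)
  # scaling background noise by k divides CNR by k (contrast fixed)
  img2 <- (img - mean(pooled)) * 2 + mean(pooled)
  feat_only <- abs(cnr(img2, feat, bgs))
  expect_equal(feat_only, abs(got), tolerance = 1e-9)  # contrast also doubled
  expect_error(cnr(matrix(0.5, 120, 120), feat, bgs), "degenerate")
})

test_that("feature ROI identical to background statistics gives CNR near 0", {
  set.seed(5)
  img <- matrix(rnorm(150 * 150, 0.5, 0.02), 150, 150)
  feat <- roi_spec(c(75, 75), 24)
  bgs <- cnr_background_rois(feat, offset_px = 36)
  expect_lt(abs(cnr(img, feat, bgs)), 0.25)
})

test_that("profile extraction sums the stated neighbouring lines", {
  set.seed(6)
  img <- matrix(runif(40 * 40), 40, 40)
  p <- extract_profile(img, c(20, 20), "horizontal", sum_width = 4,
                       half_len_px = 6)
  manual <- rep(0, 13)
  for (r in 19:22) manual <- manual + img[r, 14:26]
  expect_equal(p$profile, manual, tolerance = 1e-12)
  p1 <- extract_profile(img, c(20, 20), "vertical", sum_width = 1,
                        half_len_px = 6)
  expect_equal(p1$profile, img[14:26, 20], tolerance = 1e-12)
  pm <- extract_profile(img, c(20, 20), "horizontal", sum_width = 4,
                        half_len_px = 6, reduce = "mean")
  expect_equal(pm$profile, manual / 4, tolerance = 1e-12)
  expect_error(extract_profile(img, c(2, 20), "vertical", half_len_px = 6),
               "exits")
})

test_that("fwhm recovers closed forms for Gaussian and triangle peaks", {
  # Gaussian, sigma 0.2 mm sampled at 0.02 mm
  xs <- seq(-1, 1, by = 0.02)
  prof <- structure(list(profile = exp(-xs^2 / (2 * 0.2^2)),
                         pitch_mm = 0.02), class = "profile_measurement")
  expect_equal(fwhm(prof), 2 * sqrt(2 * log(2)) * 0.2, tolerance = 1e-3)
  # triangle of half-width w: FWHM = w
  tri <- pmax(0, 1 - abs(seq(-3, 3, by = 0.1)) / 1.5)
  expect_equal(fwhm(tri, pitch_mm = 0.1), 1.5, tolerance = 1e-6)
  # no crossing -> missing
  expect_true(is.na(fwhm(rep(1, 30), pitch_mm = 1)))
  ramp <- seq(0, 1, length.out = 30)  # peak at the border, no right crossing
  expect_true(is.na(fwhm(ramp, pitch_mm = 1)))
})

test_that("fwhm of a noisy Gaussian is unbiased within 5%", {
  xs <- seq(-1, 1, by = 0.02)
  clean <- exp(-xs^2 / (2 * 0.2^2))
  set.seed(7)
  est <- replicate(100, {
    fwhm(structure(list(profile = clean + rnorm(length(xs), 0, 0.02),
                        pitch_mm = 0.02), class = "profile_measurement"))
  })
  expect_lt(abs(mean(est, na.rm = TRUE) / (2 * sqrt(2 * log(2)) * 0.2) - 1),
            0.05)
})

test_that("reconstructed MC width is dose-invariant for noiseless input", {
  fx <- cached("tiny_noiseless", function() {
    v <- tiny_phantom()
    g <- tiny_geometry()
    list(vol = v, geom = g,
         p = to_attenuation_norm(forward_project(v, g, i0 = 1e5)))
  })
  # a pure exposure change without quantum noise: intensities scale by the
  # dose factor, normalization divides it out, the in-focus width is
  # geometry-driven and must not move
  pn <- forward_project(fx$vol, fx$geom, i0 = 1e5)
  p49 <- pn
  p49$images <- 0.49 * pn$images
  p49$dose_factor <- 0.49
  a100 <- to_attenuation_norm(pn)
  a49 <- to_attenuation_norm(p49)
  mc <- fx$vol$registry[fx$vol$registry$kind == "mc", ][1, ]
  ctr <- recon_pixel(fx$geom, mc$x_mm, mc$y_mm, 6)
  f <- sapply(list(a100, a49), function(p) {
    r <- reconstruct_fbp(p, 6)
    fwhm(extract_profile(r$slices[, , 1], ctr, "horizontal",
                         half_len_px = 6, pitch_mm = 0.4))
  })
  expect_false(any(is.na(f)))
  expect_lt(abs(f[2] / f[1] - 1), 0.05)
})
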
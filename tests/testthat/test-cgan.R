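ns <- asNamespace("tomodose")

small_cfg <- function(patch_px = 16L, ...) {
  train_config(patch_px = patch_px, gen_base_channels = 3L, gen_depth = 2L,
               disc_base_channels = 3L, seed = 3, ...)
}

test_that("generator and discriminator respect shape contracts", {
  cfg <- small_cfg(dropout_p = 0)
  m <- pix2pix_models(cfg)
  set.seed(4)
  x <- matrix(runif(256), 16, 16)
  out <- ns$g_forward(m$generator, x, cfg)$y
  expect_identical(dim(out), c(16L, 16L, 1L))
  expect_true(all(out >= 0 & out <= 1))
  s <- ns$d_forward(m$discriminator, ns$as_cube(x), ns$as_cube(x))$s
  expect_lt(prod(dim(s)[1:2]), 256)  # patch score map, not per-pixel
  expect_true(all(s > 0 & s < 1))
  expect_error(train_config(patch_px = 17L, gen_depth = 2L), "divisible")
})

test_that("model initialisation is reproducible under the seed", {
  m1 <- pix2pix_models(small_cfg())
  m2 <- pix2pix_models(small_cfg())
  expect_identical(m1$generator$enc0$W, m2$generator$enc0$W)
  expect_identical(m1$discriminator$c2$W, m2$discriminator$c2$W)
})

test_that("loss closed forms hold", {
  half <- array(0.5, c(4, 4, 1))
  ref <- matrix(0.3, 8, 8)
  # D = 0.5 everywhere: loss_D = -2 log 0.5 (nats)
  L <- gan_losses(half, half, ref, ref, alpha = 50)
  expect_equal(L$loss_d, 2 * log(2), tolerance = 1e-5)
  # perfect generator: L1 term vanishes
  expect_equal(L$l1, 0)
  # alpha = 0 leaves the pure adversarial generator term
  L0 <- gan_losses(half, half, ref + 0.1, ref, alpha = 0)
  expect_equal(L0$loss_g, L0$adv_g)
  expect_gt(gan_losses(half, half, ref + 0.1, ref, 50)$loss_g, L0$adv_g)
  expect_error(gan_losses(array(1.5, c(2, 2, 1)), half, ref, ref), "scores")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- small_cfg(dropout_p = 0)
  m <- pix2pix_models(cfg)
  set.seed(5)
  x <- matrix(runif(256), 16, 16)
  y <- matrix(runif(256), 16, 16)
  lossG <- function(g) mean(abs(y - ns$g_forward(g, x, cfg,
                                                 dropout = FALSE)$y[, , 1]))
  gf <- ns$g_forward(m$generator, x, cfg, dropout = FALSE)
  gy <- -sign(ns$as_cube(y) - gf$y) / length(gf$y)
  ga <- ns$g_backward(m$generator, gf$tape, gy, cfg)
  eps <- 1e-6
  for (probe in list(c("enc0"), c("bott"), c("out"))) {
    g2 <- m$generator
    i <- 5
    g2[[probe]]$W[i] <- g2[[probe]]$W[i] + eps
    num <- (lossG(g2) - lossG(m$generator)) / eps
    expect_equal(num, ga[[probe]]$W[i], tolerance = 1e-3)
  }
  g2 <- m$generator
  g2$dec[[1]]$W[3] <- g2$dec[[1]]$W[3] + eps
  num <- (lossG(g2) - lossG(m$generator)) / eps
  expect_equal(num, ga$dec[[1]]$W[3], tolerance = 1e-3)
  g2 <- m$generator
  g2$enc[[2]]$W[3] <- g2$enc[[2]]$W[3] + eps
  num <- (lossG(g2) - lossG(m$generator)) / eps
  expect_equal(num, ga$enc[[2]]$W[3], tolerance = 1e-3)
})

test_that("epoch selection follows the MSE/MSSIM rank rule", {
  # both optima coincide
  c1 <- data.frame(epoch = c(100, 200, 300), mse = c(3, 2, 1),
                   mssim = c(0.7, 0.8, 0.9))
  expect_equal(select_epoch(c1), 300)
  # single row
  expect_equal(select_epoch(data.frame(epoch = 40, mse = 1, mssim = 0.5)), 40)
  # rank conflict with equal sums resolves to the later epoch
  c2 <- data.frame(epoch = c(80, 90), mse = c(1, 2), mssim = c(0.8, 0.9))
  expect_equal(select_epoch(c2), 90)
  expect_error(select_epoch(NULL), "empty")
})

test_that("short training improves the identity dataset beyond a constant", {
  cfg <- small_cfg(epochs = 6L, checkpoint_every = 2L, patch_px = 32L)
  set.seed(6)
  img <- matrix(runif(32 * 32, 0.3, 0.7), 32, 32)
  pairs <- lapply(1:6, function(i) {
    m <- matrix(runif(32 * 32, 0.3, 0.7), 32, 32)
    list(low = m, ref = m)
  })
  fit <- pix2pix_train(pairs, cfg, val = list(low = img, ref = img))
  expect_s3_class(fit, "pix2pix_fit")
  expect_equal(nrow(fit$curve), 3)  # epochs 2, 4, 6
  best_mse <- min(fit$curve$mse)
  const_mse <- mse(img, matrix(0.5, 32, 32))
  expect_lt(best_mse, const_mse)
})

test_that("denoising preserves shapes for every view, trained or not", {
  cfg <- small_cfg(patch_px = 16L)
  m <- pix2pix_models(cfg)
  fit <- structure(list(config = cfg, generator = m$generator,
                        snapshots = list("1" = m$generator),
                        curve = data.frame(epoch = 1, mse = 1, mssim = 0),
                        best_epoch = 1,
                        losslog = data.frame(epoch = 1, loss_d = 1,
                                             loss_g = 1)),
                   class = "pix2pix_fit")
  g <- make_geometry(n_views = 15, detector_rows = 24, detector_cols = 40,
                     pixel_pitch_mm = 0.4)
  set.seed(8)
  p <- structure(list(images = array(runif(24 * 40 * 15), c(24, 40, 15)),
                      geometry = g, domain = "attenuation_norm",
                      dose_factor = 0.49, arm = "without"),
                 class = "projection_set")
  out <- denoise_projections(p, fit, seed = 2)
  expect_identical(dim(out$images), dim(p$images))
  expect_true(all(out$images >= 0 & out$images <= 1))
  expect_equal(out$arm, "pix2pix")
  expect_equal(out$dose_factor, 0.49)
  # deterministic under a fixed seed
  out2 <- denoise_projections(p, fit, seed = 2)
  expect_identical(out$images, out2$images)
})

test_that("stronger L1 weighting lowers the validation L1", {
  set.seed(9)
  pairs <- lapply(1:5, function(i) {
    m <- matrix(runif(16 * 16, 0.3, 0.7), 16, 16)
    list(low = m, ref = m)
  })
  val <- list(low = matrix(runif(256, 0.3, 0.7), 16, 16))
  val$ref <- val$low
  l1_of <- function(alpha) {
    cfg <- small_cfg(epochs = 8L, checkpoint_every = 8L, alpha_l1 = alpha)
    fit <- pix2pix_train(pairs, cfg, val = val)
    out <- predict(fit, val$low)
    mean(abs(val$ref - out))
  }
  expect_lt(l1_of(50), l1_of(0))
})

test_that("paired-dose training data is well-formed and reproducible", {
  tp <- make_training_pairs(n_pairs = 4, patch_px = 32, dose_factor = 0.49,
                            seed = 10, voxel_mm = 0.8, thickness_mm = 8,
                            n_views = 4)
  expect_length(tp$pairs, 4)
  for (pr in tp$pairs) {
    expect_identical(dim(pr$low), c(32L, 32L))
    expect_identical(dim(pr$ref), dim(pr$low))
    expect_true(all(pr$low >= 0 & pr$low <= 1))
  }
  tp2 <- make_training_pairs(n_pairs = 4, patch_px = 32, dose_factor = 0.49,
                             seed = 10, voxel_mm = 0.8, thickness_mm = 8,
                             n_views = 4)
  expect_identical(tp$pairs[[2]]$low, tp2$pairs[[2]]$low)
})

test_that("seeded training is reproducible run to run", {
  set.seed(20)
  pairs <- lapply(1:3, function(i) {
    m <- matrix(runif(256, 0.3, 0.7), 16, 16)
    list(low = pmin(pmax(m + rnorm(256, 0, 0.01), 0), 1), ref = m)
  })
  cfg <- small_cfg(epochs = 2L, checkpoint_every = 1L)
  f1 <- pix2pix_train(pairs, cfg, val = pairs[[1]])
  f2 <- pix2pix_train(pairs, cfg, val = pairs[[1]])
  expect_identical(f1$curve, f2$curve)
  expect_identical(f1$generator$out$W, f2$generator$out$W)
})

test_that("fits round-trip through checkpoint files", {
  cfg <- small_cfg()
  m <- pix2pix_models(cfg)
  fit <- structure(list(config = cfg, generator = m$generator,
                        snapshots = list("1" = m$generator),
                        curve = data.frame(epoch = 1, mse = 1, mssim = 0),
                        best_epoch = 1,
                        losslog = data.frame(epoch = 1, loss_d = 1,
                                             loss_g = 1)),
                   class = "pix2pix_fit")
  path <- file.path(tempdir(), "fit.rds")
  write_pix2pix(fit, path)
  f2 <- read_pix2pix(path)
  expect_identical(f2$generator, fit$generator)
  saveRDS(1:3, path)
  expect_error(read_pix2pix(path), "checkpoint")
})
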
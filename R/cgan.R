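#' Training configuration for the adversarial projection denoiser
#'
#' Conditional adversarial image-to-image network (pix2pix style): a U-Net
#' generator translating a low-dose projection to its reference-dose
#' counterpart, trained against a patch-based discriminator with the
#' adversarial + weighted-L1 objective. The published optimisation settings
#' are the defaults: L1 weight 50, Adam with initial learning rate 2e-4 and
#' momentum parameters (0.5, 0.999), batch size 1. The desk-scale defaults
#' (128-px patches, base 8 channels, 2 resolution halvings, 100 epochs) train
#' in minutes on one CPU core; the network size is configuration, not part of
#' the method definition.
#'
#' @param alpha_l1 weight of the L1 term in the generator objective.
#' @param lr initial Adam learning rate.
#' @param beta1,beta2 Adam momentum parameters.
#' @param batch_size images per optimisation step (1, as published).
#' @param epochs training epochs.
#' @param patch_px training patch side; must be divisible by `2^gen_depth`.
#' @param gen_base_channels channels of the first generator level.
#' @param gen_depth number of stride-2 halvings in the generator encoder.
#' @param disc_base_channels channels of the first discriminator level.
#' @param dropout_p bottleneck dropout probability; dropout is the stochastic
#'   input z of the generator and stays active at inference.
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @param checkpoint_every epochs between validation checkpoints.
#' @return object of class `pix2pix_config`.
#' @export
train_config <- function(alpha_l1 = 50, lr = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, batch_size = 1L, epochs = 100L,
                         patch_px = 128L, gen_base_channels = 8L,
                         gen_depth = 2L, disc_base_channels = 8L,
                         dropout_p = 0.5, seed = 1L,
                         checkpoint_every = 10L) {
  stopifnot(alpha_l1 >= 0, lr > 0, beta1 > 0, beta1 < 1, beta2 > 0,
            beta2 < 1, batch_size >= 1, epochs >= 1, patch_px >= 8,
            gen_base_channels >= 1, gen_depth >= 1, dropout_p >= 0,
            dropout_p < 1, checkpoint_every >= 1)
  if (patch_px %% 2^gen_depth != 0)
    stop("patch_px must be divisible by 2^gen_depth")
  structure(list(alpha_l1 = alpha_l1, lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patch_px = as.integer(patch_px),
                 gen_base_channels = as.integer(gen_base_channels),
                 gen_depth = as.integer(gen_depth),
                 disc_base_channels = as.integer(disc_base_channels),
                 dropout_p = dropout_p, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every)),
            class = "pix2pix_config")
}

#' Build the generator and discriminator parameter sets
#'
#' The generator is an encoder-decoder with skip connections (U-Net): 3x3
#' convolutions with leaky-ReLU, stride-2 halvings, a dropout bottleneck, and
#' nearest-neighbour upsampling in the decoder; the single-channel output is
#' a tanh-bounded residual added to the input and clipped to \[0, 1\]. The
#' discriminator scores local patches of the (input, candidate) pair: two
#' stride-2 convolutions and a 1-channel sigmoid head yield a probability
#' map over patches rather than one scalar per image.
#'
#' @param cfg a [train_config()].
#' @return list with elements `generator` and `discriminator` (nested lists
#'   of weight matrices/bias vectors), reproducible under `cfg$seed`.
#' @export
pix2pix_models <- function(cfg) {
  stopifnot(inherits(cfg, "pix2pix_config"))
  set.seed(cfg$seed)
  c0 <- cfg$gen_base_channels
  nd <- cfg$gen_depth
  g <- list(enc0 = conv_init(1, c0))
  g$enc <- lapply(seq_len(nd), function(l)
    conv_init(c0 * 2^(l - 1), c0 * 2^l))
  cN <- c0 * 2^nd
  g$bott <- conv_init(cN, cN)
  # decoder input at step l: bottleneck channels at the deepest level,
  # otherwise the skip-concatenated pair from the level below
  g$dec <- lapply(seq_len(nd), function(l)
    conv_init(if (l == nd) cN else c0 * 2^(l + 1), c0 * 2^(l - 1)))
  g$out <- conv_init(2 * c0, 1, gain = 0.01)  # near-zero initial residual
  dc <- cfg$disc_base_channels
  d <- list(c1 = conv_init(2, dc), c2 = conv_init(dc, 2 * dc),
            c3 = conv_init(2 * dc, 1))
  list(generator = g, discriminator = d)
}

# ---- generator forward/backward -------------------------------------------

g_forward <- function(g, x, cfg, dropout = TRUE) {
  nd <- cfg$gen_depth
  x3 <- as_cube(x)
  zs <- vector("list", nd + 1)
  acts <- vector("list", nd + 1)
  zs[[1]] <- conv_fwd(x3, g$enc0, 1L)
  acts[[1]] <- lrelu(zs[[1]])
  for (l in seq_len(nd)) {
    zs[[l + 1]] <- conv_fwd(acts[[l]], g$enc[[l]], 2L)
    acts[[l + 1]] <- lrelu(zs[[l + 1]])
  }
  zb <- conv_fwd(acts[[nd + 1]], g$bott, 1L)
  ab <- lrelu(zb)
  mask <- NULL
  if (dropout && cfg$dropout_p > 0) {
    mask <- (array(stats::runif(length(ab)), dim(ab)) > cfg$dropout_p) /
      (1 - cfg$dropout_p)
    ab <- ab * mask
  }
  # decoder: convolve at the coarse grid, then upsample and concatenate the
  # encoder skip at the finer grid (cheaper than convolving after upsampling)
  din <- zd <- ad <- vector("list", nd)
  cur <- ab
  for (l in rev(seq_len(nd))) {
    din[[l]] <- cur
    zd[[l]] <- conv_fwd(cur, g$dec[[l]], 1L)
    ad[[l]] <- lrelu(zd[[l]])
    cur <- cat_c(up2(ad[[l]]), acts[[l]])
  }
  zo <- conv_fwd(cur, g$out, 1L)
  res <- tanh(zo)
  y <- pmin(pmax(x3 + res, 0), 1)
  list(y = y,
       tape = list(x3 = x3, zs = zs, acts = acts, zb = zb, mask = mask,
                   din = din, zd = zd, ad = ad, catin = cur, res = res,
                   sum = x3 + res))
}

g_backward <- function(g, tape, gy, cfg) {
  nd <- cfg$gen_depth
  grads <- list()
  gsum <- as_cube(gy) * (tape$sum > 0 & tape$sum < 1)
  gres <- gsum * (1 - tape$res^2)
  r <- conv_bwd(tape$catin, g$out, gres, 1L)
  grads$out <- list(W = r$gW, b = r$gb)
  genc <- vector("list", nd + 1)   # grads w.r.t. encoder activations (skips)
  grads$dec <- vector("list", nd)
  gc <- r$gx
  nca <- dim(tape$ad[[1]])[3]
  gu <- gc[, , seq_len(nca), drop = FALSE]
  genc[[1]] <- gc[, , nca + seq_len(dim(gc)[3] - nca), drop = FALSE]
  for (l in seq_len(nd)) {
    gad <- up2_bwd(gu)
    gz <- lrelu_bwd(tape$zd[[l]], gad)
    r <- conv_bwd(tape$din[[l]], g$dec[[l]], gz, 1L)
    grads$dec[[l]] <- list(W = r$gW, b = r$gb)
    gprev <- r$gx
    if (l < nd) {
      nca <- dim(tape$ad[[l + 1]])[3]
      gu <- gprev[, , seq_len(nca), drop = FALSE]
      genc[[l + 1]] <- gprev[, , nca + seq_len(dim(gprev)[3] - nca),
                             drop = FALSE]
    } else {
      gab <- gprev
    }
  }
  if (!is.null(tape$mask)) gab <- gab * tape$mask
  gzb <- lrelu_bwd(tape$zb, gab)
  r <- conv_bwd(tape$acts[[nd + 1]], g$bott, gzb, 1L)
  grads$bott <- list(W = r$gW, b = r$gb)
  gacc <- r$gx
  grads$enc <- vector("list", nd)
  for (l in rev(seq_len(nd))) {
    ga <- gacc
    if (l < nd && !is.null(genc[[l + 1]])) ga <- ga + genc[[l + 1]]
    gz <- lrelu_bwd(tape$zs[[l + 1]], ga)
    r <- conv_bwd(tape$acts[[l]], g$enc[[l]], gz, 2L)
    grads$enc[[l]] <- list(W = r$gW, b = r$gb)
    gacc <- r$gx
  }
  ga0 <- gacc + genc[[1]]
  gz0 <- lrelu_bwd(tape$zs[[1]], ga0)
  r <- conv_bwd(tape$x3, g$enc0, gz0, 1L)
  grads$enc0 <- list(W = r$gW, b = r$gb)
  grads
}

# ---- discriminator forward/backward ---------------------------------------

d_forward <- function(d, cond, cand) {
  xin <- cat_c(cond, cand)
  z1 <- conv_fwd(xin, d$c1, 2L); a1 <- lrelu(z1)
  z2 <- conv_fwd(a1, d$c2, 2L); a2 <- lrelu(z2)
  z3 <- conv_fwd(a2, d$c3, 1L)
  s <- 1 / (1 + exp(-z3))
  list(s = s, tape = list(xin = xin, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                          z3 = z3, s = s))
}

d_backward <- function(d, tape, gs) {
  gz3 <- gs * tape$s * (1 - tape$s)
  r3 <- conv_bwd(tape$a2, d$c3, gz3, 1L)
  gz2 <- lrelu_bwd(tape$z2, r3$gx)
  r2 <- conv_bwd(tape$a1, d$c2, gz2, 2L)
  gz1 <- lrelu_bwd(tape$z1, r2$gx)
  r1 <- conv_bwd(tape$xin, d$c1, gz1, 2L)
  list(grads = list(c1 = list(W = r1$gW, b = r1$gb),
                    c2 = list(W = r2$gW, b = r2$gb),
                    c3 = list(W = r3$gW, b = r3$gb)),
       gxin = r1$gx)
}

add_grads <- function(a, b) {
  if (is.list(a)) return(mapply(add_grads, a, b, SIMPLIFY = FALSE))
  a + b
}

#' Adversarial and L1 losses of the conditional GAN
#'
#' Discriminator loss \eqn{-E[\log D(p_{ld}, p_{ref})] -
#' E[\log(1 - D(p_{ld}, G(p_{ld}, z)))]} and generator loss (non-saturating
#' adversarial term \eqn{-E[\log D(p_{ld}, G)]} plus `alpha` times the mean
#' absolute deviation from the reference). Scores must be probabilities.
#'
#' @param d_real discriminator score map on the (low-dose, reference) pair.
#' @param d_fake discriminator score map on the (low-dose, generated) pair.
#' @param fake generated image; `ref` the reference image.
#' @param ref reference-dose image.
#' @param alpha L1 weight.
#' @param eps numerical floor inside the logs.
#' @return list with `loss_d`, `loss_g`, `adv_g`, `l1`.
#' @export
gan_losses <- function(d_real, d_fake, fake, ref, alpha = 50, eps = 1e-7) {
  if (any(d_real <= 0 | d_real >= 1) || any(d_fake <= 0 | d_fake >= 1))
    stop("discriminator scores must lie strictly in (0, 1)")
  loss_d <- -mean(log(d_real + eps)) - mean(log(1 - d_fake + eps))
  l1 <- mean(abs(ref - fake))
  adv_g <- -mean(log(d_fake + eps))
  list(loss_d = loss_d, loss_g = adv_g + alpha * l1, adv_g = adv_g, l1 = l1)
}

#' Train the adversarial projection denoiser
#'
#' Alternating Adam steps on the discriminator and generator, batch size 1,
#' exactly one D and one G update per training pair per epoch. At every
#' checkpoint epoch the generator output for the held-out (0-degree view)
#' validation pair is scored by MSE and mean SSIM; the returned epoch curve
#' feeds [select_epoch()].
#'
#' @param pairs list of training pairs, each `list(low = , ref = )` with
#'   matrices on \[0, 1\].
#' @param cfg a [train_config()].
#' @param val validation pair (`list(low, ref)`); by default the last element
#'   of `pairs` is withheld for validation.
#' @return object of class `pix2pix_fit` with the selected generator weights,
#'   all checkpoint snapshots, the epoch curve and per-epoch loss log.
#' @export
pix2pix_train <- function(pairs, cfg = train_config(), val = NULL) {
  stopifnot(length(pairs) >= 1)
  if (is.null(val)) {
    if (length(pairs) < 2) stop("need at least 2 pairs when val is NULL")
    val <- pairs[[length(pairs)]]
    pairs <- pairs[-length(pairs)]
  }
  models <- pix2pix_models(cfg)
  g <- models$generator
  d <- models$discriminator
  sg <- adam_init(g)
  sd <- adam_init(d)
  tg <- td <- 0L
  n <- length(pairs)
  curve <- NULL
  snapshots <- list()
  losslog <- NULL
  eps <- 1e-7
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ld <- lg <- 0
    for (i in ord) {
      x <- pairs[[i]]$low
      y <- as_cube(pairs[[i]]$ref)
      gf <- g_forward(g, x, cfg, dropout = TRUE)
      fake <- gf$y
      # --- discriminator step
      dr <- d_forward(d, as_cube(x), y)
      df <- d_forward(d, as_cube(x), fake)
      np <- length(dr$s)
      gs_real <- -1 / (dr$s + eps) / np
      gs_fake <- 1 / (1 - df$s + eps) / np
      br <- d_backward(d, dr$tape, gs_real)
      bf <- d_backward(d, df$tape, gs_fake)
      gd <- add_grads(br$grads, bf$grads)
      td <- td + 1L
      up <- adam_step(d, gd, sd, cfg$lr, cfg$beta1, cfg$beta2, td)
      d <- up$p; sd <- up$s
      # --- generator step (through the updated discriminator)
      df2 <- d_forward(d, as_cube(x), fake)
      gs <- -1 / (df2$s + eps) / length(df2$s)
      bg <- d_backward(d, df2$tape, gs)
      gfake <- bg$gxin[, , 2, drop = FALSE]   # grad w.r.t. candidate channel
      gl1 <- -cfg$alpha_l1 * sign(y - fake) / length(fake)
      gg <- g_backward(g, gf$tape, gfake + gl1, cfg)
      tg <- tg + 1L
      up <- adam_step(g, gg, sg, cfg$lr, cfg$beta1, cfg$beta2, tg)
      g <- up$p; sg <- up$s
      L <- gan_losses(dr$s, df2$s, fake, y, cfg$alpha_l1)
      if (!is.finite(L$loss_d) || !is.finite(L$loss_g))
        stop("NaN/Inf loss at epoch ", ep, "; training aborted")
      ld <- ld + L$loss_d / n
      lg <- lg + L$loss_g / n
    }
    losslog <- rbind(losslog, data.frame(epoch = ep, loss_d = ld,
                                         loss_g = lg))
    if (ep %% cfg$checkpoint_every == 0 || ep == cfg$epochs) {
      out <- g_forward(g, val$low, cfg, dropout = TRUE)$y[, , 1]
      row <- data.frame(epoch = ep, mse = mse(val$ref, out),
                        mssim = mssim(val$ref, out))
      if (is.null(curve) || ep != utils::tail(curve$epoch, 1)) {
        curve <- rbind(curve, row)
        snapshots[[as.character(ep)]] <- g
      }
    }
  }
  best <- select_epoch(curve)
  structure(list(config = cfg, generator = snapshots[[as.character(best)]],
                 discriminator = d, snapshots = snapshots, curve = curve,
                 best_epoch = best, losslog = losslog),
            class = "pix2pix_fit")
}

#' @export
print.pix2pix_fit <- function(x, ...) {
  cat(sprintf(
    "pix2pix_fit: %d epochs (best %d by MSE/MSSIM rank), %d checkpoints\n",
    max(x$losslog$epoch), x$best_epoch, nrow(x$curve)))
  i <- match(x$best_epoch, x$curve$epoch)
  cat(sprintf("  validation at best epoch: MSE %.3g, MSSIM %.4f\n",
              x$curve$mse[i], x$curve$mssim[i]))
  invisible(x)
}

#' Select the optimisation epoch from a checkpoint curve
#'
#' Returns the epoch minimizing MSE when it coincides with the epoch
#' maximizing mean SSIM; otherwise the epoch with the smallest sum of the
#' two ranks (MSE ascending, MSSIM descending), ties resolved toward the
#' later epoch.
#'
#' @param curve data frame with columns `epoch`, `mse`, `mssim`.
#' @return the selected epoch (integer).
#' @export
select_epoch <- function(curve) {
  if (is.null(curve) || nrow(curve) == 0) stop("empty epoch curve")
  if (nrow(curve) == 1) return(curve$epoch[1])
  i_mse <- which.min(curve$mse)
  i_ss <- which.max(curve$mssim)
  if (i_mse == i_ss) return(curve$epoch[i_mse])
  score <- rank(curve$mse, ties.method = "min") +
    rank(-curve$mssim, ties.method = "min")
  cand <- which(score == min(score))
  curve$epoch[max(cand)]
}

# apply the generator to an arbitrarily sized image by tiling with overlap
# and uniform blending of overlapping patches
tile_generate <- function(g, img, cfg, dropout = TRUE) {
  pp <- cfg$patch_px
  nr <- nrow(img); nc <- ncol(img)
  if (nr == pp && nc == pp)
    return(g_forward(g, img, cfg, dropout = dropout)$y[, , 1])
  if (nr < pp || nc < pp)
    stop("image smaller than the generator patch size")
  step <- max(pp %/% 2, pp - 16L)
  starts <- function(n) unique(pmin(seq(1L, n, by = step), n - pp + 1L))
  acc <- matrix(0, nr, nc)
  wgt <- matrix(0, nr, nc)
  for (r0 in starts(nr)) for (c0 in starts(nc)) {
    rows <- r0:(r0 + pp - 1L); cols <- c0:(c0 + pp - 1L)
    acc[rows, cols] <- acc[rows, cols] +
      g_forward(g, img[rows, cols], cfg, dropout = dropout)$y[, , 1]
    wgt[rows, cols] <- wgt[rows, cols] + 1
  }
  acc / wgt
}

#' Denoise a projection set with a trained generator
#'
#' Applies the generator view by view (tiling with overlap blending when a
#' view exceeds the training patch size) and clips the output to \[0, 1\].
#' Dose metadata is preserved and the processing arm is set to `"pix2pix"`.
#' Dropout — the generator's stochastic input — remains active; set `seed`
#' for reproducible output.
#'
#' @param p `projection_set` in the normalized attenuation domain.
#' @param fit a `pix2pix_fit`.
#' @param which `"best"` (epoch selected by [select_epoch()]) or `"final"`.
#' @param seed RNG seed for the stochastic generator input.
#' @param dropout keep the stochastic bottleneck dropout active.
#' @return denoised `projection_set`.
#' @export
denoise_projections <- function(p, fit, which = c("best", "final"),
                                seed = 1L, dropout = TRUE) {
  stopifnot(inherits(p, "projection_set"), inherits(fit, "pix2pix_fit"))
  if (p$domain != "attenuation_norm")
    stop("denoising operates on attenuation-normalized projections")
  which <- match.arg(which)
  g <- if (which == "best") fit$generator else
    fit$snapshots[[length(fit$snapshots)]]
  set.seed(seed)
  out <- p
  for (v in seq_len(dim(p$images)[3]))
    out$images[, , v] <- tile_generate(g, p$images[, , v], fit$config,
                                       dropout = dropout)
  out$images <- pmin(pmax(out$images, 0), 1)
  out$arm <- "pix2pix"
  out
}

#' Predict method for pix2pix fits
#'
#' @param object a `pix2pix_fit`.
#' @param newdata a matrix, 3-D array of views, or `projection_set`.
#' @param ... passed to [denoise_projections()] for projection sets.
#' @return same container as `newdata`, denoised.
#' @export
predict.pix2pix_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "projection_set"))
    return(denoise_projections(newdata, object, ...))
  if (is.matrix(newdata))
    return(tile_generate(object$generator, newdata, object$config))
  stopifnot(length(dim(newdata)) == 3)
  out <- newdata
  for (v in seq_len(dim(newdata)[3]))
    out[, , v] <- tile_generate(object$generator, newdata[, , v],
                                object$config)
  out
}

#' Simulate paired low/reference-dose training projections
#'
#' Generates small textured phantoms with randomly placed microcalcification
#' specks and one mass each, forward-projects them over the acquisition arc,
#' and draws two independent noise realisations per view: the reference dose
#' (factor 1) and the reduced dose. Views become (low, ref) training pairs in
#' the normalized attenuation domain.
#'
#' @param n_pairs number of pairs to produce.
#' @param patch_px lateral size of the projections (pixels).
#' @param dose_factor reduced-dose factor for the low-dose member.
#' @param seed master seed.
#' @param i0 reference-dose photons per pixel.
#' @param voxel_mm phantom voxel size.
#' @param thickness_mm phantom thickness.
#' @param n_views views per phantom (each view yields one pair).
#' @param electronic_sigma electronic noise (photons).
#' @return list with `pairs` (list of `list(low, ref)`), `geometry`, and
#'   `clean` (noiseless attenuation-normalized views, for evaluation).
#' @export
make_training_pairs <- function(n_pairs = 64, patch_px = 128,
                                dose_factor = 0.49, seed = 1L, i0 = 1e5,
                                voxel_mm = 0.2, thickness_mm = 20,
                                n_views = 15, electronic_sigma = 5) {
  set.seed(seed)
  n_phantom <- ceiling(n_pairs / n_views)
  geom <- make_geometry(n_views = n_views,
                        detector_rows = patch_px, detector_cols = patch_px,
                        pixel_pitch_mm = voxel_mm)
  ext <- patch_px * voxel_mm
  pairs <- list()
  clean <- list()
  for (ph in seq_len(n_phantom)) {
    sp <- phantom_spec(thickness_mm = thickness_mm, voxel_mm = voxel_mm,
                       lateral_extent_mm = c(ext, ext),
                       texture_correlation_mm = 3,
                       seed = seed + 1000L * ph, margin_mm = 2)
    vol <- build_background(sp)
    feats <- random_feature_layout(sp, n_mc = 6, n_mass = 1,
                                   seed = seed + 1000L * ph + 1L)
    vol <- insert_features(vol, sp, feats)
    pn <- forward_project(vol, geom, i0 = i0)
    pref <- to_attenuation_norm(
      apply_dose_noise(pn, 1.0, electronic_sigma, seed = seed + 7L * ph))
    plow <- to_attenuation_norm(
      apply_dose_noise(pn, dose_factor, electronic_sigma,
                       seed = seed + 7L * ph + 3L))
    pcl <- to_attenuation_norm(within_noiseless(pn))
    for (v in seq_len(n_views)) {
      pairs[[length(pairs) + 1]] <- list(low = plow$images[, , v],
                                         ref = pref$images[, , v])
      clean[[length(clean) + 1]] <- pcl$images[, , v]
    }
    if (length(pairs) >= n_pairs) break
  }
  list(pairs = pairs[seq_len(n_pairs)], geometry = geom,
       clean = clean[seq_len(n_pairs)])
}

# noiseless projections carry dose_factor 1 and can be normalized directly
within_noiseless <- function(p) p

# random non-overlapping specks and masses on the target plane
random_feature_layout <- function(spec, n_mc = 6, n_mass = 1, seed = 1L) {
  set.seed(seed)
  lx <- spec$lateral_extent_mm[1]; ly <- spec$lateral_extent_mm[2]
  m <- spec$margin_mm
  rec <- NULL
  tries <- 0
  want <- data.frame(
    kind = c(rep("mc", n_mc), rep("mass", n_mass)),
    size = c(sample(spec$mc_sizes_mm, n_mc, replace = TRUE),
             sample(spec$mass_diameters_mm, n_mass, replace = TRUE)))
  for (i in seq_len(nrow(want))) {
    repeat {
      tries <- tries + 1
      if (tries > 1000) break
      x <- stats::runif(1, m + want$size[i], lx - m - want$size[i])
      y <- stats::runif(1, m + want$size[i], ly - m - want$size[i])
      if (is.null(rec) ||
          all(sqrt((rec$x_mm - x)^2 + (rec$y_mm - y)^2) >
              (rec$size_mm + want$size[i]) / 2 + 1)) {
        rec <- rbind(rec, data.frame(
          kind = want$kind[i], x_mm = x, y_mm = y,
          z_mm = spec$target_slab_depth_mm, size_mm = want$size[i],
          contrast = if (want$kind[i] == "mc") spec$mc_contrast else
            spec$mass_contrast,
          group = sprintf("%s_%g", want$kind[i], want$size[i])))
        break
      }
    }
  }
  rec
}

#' Save / load a trained denoiser fit
#'
#' Checkpoints are self-describing: the RDS archive holds the training
#' configuration, every checkpoint epoch's generator weights, the epoch
#' curve and the selected epoch.
#'
#' @param fit a `pix2pix_fit`.
#' @param path file path (`.rds`).
#' @return `write_pix2pix` returns `path` invisibly; `read_pix2pix` the fit.
#' @export
write_pix2pix <- function(fit, path) {
  stopifnot(inherits(fit, "pix2pix_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_pix2pix
#' @export
read_pix2pix <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "pix2pix_fit")) stop("not a pix2pix checkpoint file")
  fit
}
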
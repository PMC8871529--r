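#' Multiscale bilateral filter parameters
#'
#' Parameter set of the multiscale bilateral denoiser: Laplacian-pyramid
#' decomposition, per-band bilateral filtering and Laplacian-mask enhancement
#' of the finest band. Defaults follow the published parameterisation:
#' spatial sigma 1.0 px, range sigma 0.01 (of the \[0, 1\] attenuation
#' scale), enhancement weight 0.375 with a 5 x 5 Laplacian mask.
#'
#' @param sigma_d spatial (domain) Gaussian sigma in pixels.
#' @param sigma_r range Gaussian sigma in image units.
#' @param alpha weight of the high-frequency enhancement term.
#' @param w_alpha 5 x 5 enhancement mask (zero-sum, centre-positive
#'   Laplacian by default).
#' @param n_levels number of pyramid band levels.
#' @param scale_sigma_d divide `sigma_d` by `2^level` for coarser bands
#'   (default keeps a single sigma across bands).
#' @return object of class `msbf_params`.
#' @export
msbf_params <- function(sigma_d = 1.0, sigma_r = 0.01, alpha = 0.375,
                        w_alpha = NULL, n_levels = 4, scale_sigma_d = FALSE) {
  stopifnot(sigma_d > 0, sigma_r > 0, n_levels >= 1)
  if (is.null(w_alpha))
    w_alpha <- matrix(c(0, 0, -1, 0, 0,
                        0, -1, -2, -1, 0,
                        -1, -2, 16, -2, -1,
                        0, -1, -2, -1, 0,
                        0, 0, -1, 0, 0), 5, 5) / 16
  stopifnot(is.matrix(w_alpha), all(dim(w_alpha) == c(5, 5)))
  structure(list(sigma_d = sigma_d, sigma_r = sigma_r, alpha = alpha,
                 w_alpha = w_alpha, n_levels = as.integer(n_levels),
                 scale_sigma_d = scale_sigma_d), class = "msbf_params")
}

binomial5 <- c(1, 4, 6, 4, 1) / 16

pyr_down <- function(x) {
  k <- outer(binomial5, binomial5)
  g <- cpp_filter2(x, k)
  g[seq(1, nrow(g), by = 2), seq(1, ncol(g), by = 2), drop = FALSE]
}

# separable linear-interpolation upsampling to the parent level's size;
# constant images are preserved exactly and the pyramid stays exactly
# invertible (any upsampler does)
up_axis <- function(x, n) {
  m <- nrow(x)
  out <- matrix(0, n, ncol(x))
  out[seq(1, n, by = 2), ] <- x[seq_len(length(seq(1, n, by = 2))), ]
  ev <- seq(2, n, by = 2)
  lo <- (ev) / 2
  hi <- pmin(lo + 1, m)
  out[ev, ] <- (x[lo, , drop = FALSE] + x[hi, , drop = FALSE]) / 2
  out
}

pyr_up <- function(x, target_dim) {
  t(up_axis(t(up_axis(x, target_dim[1])), target_dim[2]))
}

#' Laplacian pyramid decomposition
#'
#' Standard Burt-Adelson pyramid: Gaussian downsampling by 2 with a 5-tap
#' binomial kernel; each band is the level minus the upsampled next level.
#' The decomposition is exactly invertible by [collapse_pyramid()].
#'
#' @param image numeric matrix.
#' @param n_levels number of band levels.
#' @return list with `bands` (list of matrices, finest first) and `residual`.
#' @export
laplacian_pyramid <- function(image, n_levels) {
  stopifnot(is.matrix(image), all(is.finite(image)), n_levels >= 1)
  if (min(dim(image)) < 2^n_levels)
    stop("image smaller than 2^n_levels; reduce n_levels")
  bands <- vector("list", n_levels)
  g <- image
  for (l in seq_len(n_levels)) {
    d <- pyr_down(g)
    bands[[l]] <- g - pyr_up(d, dim(g))
    g <- d
  }
  list(bands = bands, residual = g)
}

#' @rdname laplacian_pyramid
#' @param pyr a pyramid from [laplacian_pyramid()].
#' @export
collapse_pyramid <- function(pyr) {
  g <- pyr$residual
  for (l in rev(seq_along(pyr$bands)))
    g <- pyr$bands[[l]] + pyr_up(g, dim(pyr$bands[[l]]))
  g
}

#' Bilateral filter
#'
#' Classic bilateral filter: each output pixel is the normalized
#' Gaussian-weighted average of its neighbours, weighted jointly by spatial
#' distance (sigma `sigma_d`, window radius `ceiling(3 sigma_d)`) and range
#' difference (sigma `sigma_r`). Borders are reflect-padded.
#'
#' @param band numeric matrix.
#' @param sigma_d spatial sigma (pixels).
#' @param sigma_r range sigma (image units).
#' @return filtered matrix.
#' @export
bilateral_filter <- function(band, sigma_d, sigma_r) {
  stopifnot(is.matrix(band), all(is.finite(band)), sigma_d > 0, sigma_r > 0)
  cpp_bilateral(band, sigma_d, sigma_r)
}

#' Multiscale bilateral denoising of a projection image
#'
#' Decomposes the image into a Laplacian pyramid, bilateral-filters each band
#' level, adds `alpha` times the Laplacian-mask response of the filtered
#' finest band back to that band (microcalcification enhancement), collapses
#' the pyramid and clips to \[0, 1\]. The pyramid residual (the coarse
#' approximation) is left untouched. Deterministic.
#'
#' The range weights for each band are evaluated on the low-pass
#' approximation at that band's scale (a guided bilateral), as in multiscale
#' bilateral decompositions: edges and specks present in the approximation
#' stop the averaging, while band noise — which would defeat a range kernel
#' narrower than the noise itself — does not feed back into the weights.
#'
#' @param image attenuation-normalized projection image (matrix) or a 3-D
#'   array of views.
#' @param params an [msbf_params()].
#' @return processed image(s), same shape.
#' @export
msbf_process <- function(image, params = msbf_params()) {
  if (length(dim(image)) == 3) {
    out <- image
    for (v in seq_len(dim(image)[3]))
      out[, , v] <- msbf_process(image[, , v], params)
    return(out)
  }
  stopifnot(is.matrix(image), inherits(params, "msbf_params"))
  if (min(dim(image)) < 2^params$n_levels)
    stop("image smaller than 2^n_levels; reduce n_levels")
  # Laplacian pyramid, keeping the low-pass approximation at every scale:
  # the bilateral range term for each band is evaluated on that low-pass
  # (the band's own scale context), not on the noisy band values
  n <- params$n_levels
  bands <- lows <- vector("list", n)
  g <- image
  for (l in seq_len(n)) {
    d <- pyr_down(g)
    lows[[l]] <- pyr_up(d, dim(g))
    bands[[l]] <- g - lows[[l]]
    g <- d
  }
  pyr <- list(bands = bands, residual = g)
  for (l in seq_along(pyr$bands)) {
    sd_l <- if (params$scale_sigma_d) params$sigma_d / 2^(l - 1) else
      params$sigma_d
    sd_l <- max(sd_l, 1e-3)
    pyr$bands[[l]] <- cpp_bilateral_guided(pyr$bands[[l]], lows[[l]],
                                           sd_l, params$sigma_r)
  }
  if (params$alpha != 0)
    pyr$bands[[1]] <- pyr$bands[[1]] +
      params$alpha * cpp_filter2(pyr$bands[[1]], params$w_alpha)
  out <- collapse_pyramid(pyr)
  pmin(pmax(out, 0), 1)
}
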
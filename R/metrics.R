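#' Mean squared error between two images
#'
#' @param a,b numeric arrays of identical shape.
#' @return mean of squared differences.
#' @export
mse <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("shape mismatch")
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(PV^2 / MSE)} in dB, with peak value `pv = 1.0` for
#' single-precision image data on \[0, 1\]. Identical images yield `Inf`.
#'
#' @param a,b numeric arrays of identical shape.
#' @param pv peak signal value.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, pv = 1.0) {
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(pv^2 / m)
}

gaussian_kernel2 <- function(size = 11, sigma = 1.5) {
  m <- (size - 1) / 2
  g <- exp(-((-m:m)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity map and its mean
#'
#' Per-pixel SSIM as the product of luminance, contrast and structure terms
#' (exponents 1), computed over a local Gaussian window (11 x 11, sigma 1.5)
#' with the standard stabilizing constants `C1 = (0.01 PV)^2`,
#' `C2 = (0.03 PV)^2`, `C3 = C2 / 2`. `mssim` averages the map over all
#' pixels.
#'
#' @param a,b numeric matrices of identical shape, dynamic range `pv`.
#' @param pv dynamic range of the data.
#' @param window_size,window_sigma Gaussian window parameters.
#' @return `ssim_map`: matrix of per-pixel SSIM; `mssim`: scalar mean.
#' @export
ssim_map <- function(a, b, pv = 1.0, window_size = 11, window_sigma = 1.5) {
  stopifnot(is.matrix(a), identical(dim(a), dim(b)))
  if (window_size > min(dim(a)))
    stop("SSIM window larger than the image")
  k <- gaussian_kernel2(window_size, window_sigma)
  c1 <- (0.01 * pv)^2
  c2 <- (0.03 * pv)^2
  c3 <- c2 / 2
  mu_a <- cpp_filter2(a, k)
  mu_b <- cpp_filter2(b, k)
  va <- pmax(cpp_filter2(a * a, k) - mu_a^2, 0)
  vb <- pmax(cpp_filter2(b * b, k) - mu_b^2, 0)
  sab <- cpp_filter2(a * b, k) - mu_a * mu_b
  sa <- sqrt(va)
  sb <- sqrt(vb)
  lum <- (2 * mu_a * mu_b + c1) / (mu_a^2 + mu_b^2 + c1)
  con <- (2 * sa * sb + c2) / (va + vb + c2)
  str <- (sab + c3) / (sa * sb + c3)
  lum * con * str
}

#' @rdname ssim_map
#' @export
mssim <- function(a, b, pv = 1.0, window_size = 11, window_sigma = 1.5) {
  mean(ssim_map(a, b, pv, window_size, window_sigma))
}

#' Circular region-of-interest specification
#'
#' @param center length-2 numeric (row, col), 1-based pixel coordinates.
#' @param diameter_px ROI diameter in pixels (28 px for the 3.9 mm mass and
#'   40 px for the 4.7 mm mass at 0.14 mm in-plane sampling; scaled
#'   equivalents at other pitches).
#' @param role `"feature"` or `"background"`.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(center, diameter_px, role = c("feature", "background")) {
  role <- match.arg(role)
  stopifnot(length(center) == 2, diameter_px > 0)
  structure(list(center = as.numeric(center),
                 diameter_px = diameter_px, role = role), class = "roi_spec")
}

roi_pixels <- function(image, roi) {
  r0 <- roi$center[1]; c0 <- roi$center[2]; rad <- roi$diameter_px / 2
  rows <- max(1, floor(r0 - rad)):min(nrow(image), ceiling(r0 + rad))
  cols <- max(1, floor(c0 - rad)):min(ncol(image), ceiling(c0 + rad))
  if (r0 - rad < 0.5 || c0 - rad < 0.5 ||
      r0 + rad > nrow(image) + 0.5 || c0 + rad > ncol(image) + 0.5)
    stop("ROI not fully inside the image")
  sel <- outer(rows - r0, cols - c0, function(dr, dc) dr^2 + dc^2) <= rad^2
  image[rows, cols][sel]
}

#' Four background ROIs around a feature
#'
#' Background circles of the same diameter as the feature ROI, centred
#' up/down/left/right of the feature at `offset_px` from its centre.
#'
#' @param feature a [roi_spec()] with role `"feature"`.
#' @param offset_px centre-to-centre offset (defaults to the feature
#'   diameter plus 1.5 mm worth of pixels when `pitch_mm` is given).
#' @param pitch_mm in-plane pixel pitch used for the default offset.
#' @return list of four background [roi_spec()]s.
#' @export
cnr_background_rois <- function(feature, offset_px = NULL, pitch_mm = NULL) {
  if (is.null(offset_px)) {
    if (is.null(pitch_mm)) stop("give offset_px or pitch_mm")
    offset_px <- feature$diameter_px + 1.5 / pitch_mm
  }
  lapply(list(c(-offset_px, 0), c(offset_px, 0),
              c(0, -offset_px), c(0, offset_px)),
         function(o) roi_spec(feature$center + o, feature$diameter_px,
                              "background"))
}

#' Contrast-to-noise ratio with four pooled background ROIs
#'
#' \eqn{CNR = (\mu_{feature} - \mu_{BG}) / \sigma_{BG}} where the background
#' mean and standard deviation are computed over the pooled pixels of the
#' four background ROIs placed up, down, left and right of the feature.
#'
#' @param image numeric matrix (in-focus reconstructed slice).
#' @param feature a [roi_spec()].
#' @param backgrounds list of exactly four background [roi_spec()]s, e.g.
#'   from [cnr_background_rois()].
#' @return the CNR (scalar).
#' @export
cnr <- function(image, feature, backgrounds) {
  stopifnot(inherits(feature, "roi_spec"), length(backgrounds) == 4)
  mu_f <- mean(roi_pixels(image, feature))
  bg <- unlist(lapply(backgrounds, function(r) roi_pixels(image, r)))
  s <- stats::sd(bg)
  if (s == 0) stop("degenerate background: zero variance")
  (mu_f - mean(bg)) / s
}

#' Extract a summed intensity profile through a feature
#'
#' Sums `sum_width` adjacent image lines perpendicular to the profile
#' direction and returns the 1-D profile centred on the feature, the
#' standard microcalcification FWHM measurement layout (profiles parallel
#' and perpendicular to the tube-travel axis).
#'
#' @param image numeric matrix.
#' @param center length-2 (row, col) centre, 1-based (fractional allowed;
#'   rounded to the nearest line).
#' @param direction `"horizontal"` (profile along columns, the tube-travel
#'   axis) or `"vertical"` (along rows).
#' @param sum_width number of adjacent lines summed (4 as published); use
#'   `reduce = "mean"` to average instead (identical FWHM either way).
#' @param half_len_px profile half-length in pixels.
#' @param pitch_mm in-plane pixel pitch (mm) carried to [fwhm()].
#' @param reduce `"sum"` or `"mean"` across the adjacent lines.
#' @return object of class `profile_measurement`: `profile`, `direction`,
#'   `sum_width`, `pitch_mm`, `center_index`.
#' @export
extract_profile <- function(image, center, direction = c("horizontal",
                                                         "vertical"),
                            sum_width = 4, half_len_px = 15,
                            pitch_mm = 1, reduce = c("sum", "mean")) {
  direction <- match.arg(direction)
  reduce <- match.arg(reduce)
  r0 <- round(center[1]); c0 <- round(center[2])
  w0 <- -(ceiling(sum_width / 2) - 1)
  wines <- w0:(w0 + sum_width - 1)
  if (direction == "horizontal") {
    rows <- r0 + wines
    cols <- (c0 - half_len_px):(c0 + half_len_px)
    if (min(rows) < 1 || max(rows) > nrow(image) ||
        min(cols) < 1 || max(cols) > ncol(image))
      stop("profile window exits the image")
    block <- image[rows, cols, drop = FALSE]
    prof <- colSums(block)
  } else {
    cols <- c0 + wines
    rows <- (r0 - half_len_px):(r0 + half_len_px)
    if (min(rows) < 1 || max(rows) > nrow(image) ||
        min(cols) < 1 || max(cols) > ncol(image))
      stop("profile window exits the image")
    block <- image[rows, cols, drop = FALSE]
    prof <- rowSums(block)
  }
  if (reduce == "mean") prof <- prof / sum_width
  structure(list(profile = as.numeric(prof), direction = direction,
                 sum_width = sum_width, pitch_mm = pitch_mm,
                 center_index = half_len_px + 1),
            class = "profile_measurement")
}

#' Full width at half-maximum of a peaked profile
#'
#' The baseline is the mean of the two profile tails (outer 25% of samples);
#' the half-maximum level is baseline + (peak - baseline)/2; the two
#' half-maximum crossings around the peak are located by linear
#' interpolation. Returns the width in mm, or `NA` when a crossing is
#' missing on either side (unmeasurable profile — these occur in practice
#' and are recorded as missing rather than as errors).
#'
#' @param p a `profile_measurement` (or plain numeric vector, with
#'   `pitch_mm`).
#' @param pitch_mm pixel pitch override.
#' @return FWHM in mm, or `NA_real_`.
#' @export
fwhm <- function(p, pitch_mm = NULL) {
  if (inherits(p, "profile_measurement")) {
    prof <- p$profile
    if (is.null(pitch_mm)) pitch_mm <- p$pitch_mm
  } else {
    prof <- as.numeric(p)
    if (is.null(pitch_mm)) pitch_mm <- 1
  }
  n <- length(prof)
  if (n < 5) return(NA_real_)
  ntail <- max(1, floor(n * 0.25 / 2))
  baseline <- mean(c(prof[seq_len(ntail)], prof[n - seq_len(ntail) + 1]))
  ipk <- which.max(prof)
  peak <- prof[ipk]
  if (peak <= baseline) return(NA_real_)
  half <- baseline + (peak - baseline) / 2
  left <- NA_real_
  if (ipk > 1) for (i in ipk:2) {
    if (prof[i - 1] <= half && prof[i] > half) {
      left <- (i - 1) + (half - prof[i - 1]) / (prof[i] - prof[i - 1])
      break
    }
  }
  right <- NA_real_
  if (ipk < n) for (i in ipk:(n - 1)) {
    if (prof[i + 1] <= half && prof[i] > half) {
      right <- i + (prof[i] - half) / (prof[i] - prof[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * pitch_mm
}
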
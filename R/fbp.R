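#' Band-limited ramp (Ram-Lak) filter kernel
#'
#' Spatial taps of the Ramachandran-Lakshminarayanan kernel for detector
#' sampling pitch \eqn{\tau}: \eqn{h(0) = 1/(4\tau^2)}, zero at even offsets,
#' \eqn{h(n) = -1/(\pi^2 n^2 \tau^2)} at odd offsets.
#'
#' @param n_taps odd number of taps (centre tap plus symmetric wings).
#' @param pitch_mm detector pixel pitch \eqn{\tau} (mm).
#' @return numeric vector of length `n_taps`, centre at `(n_taps + 1) / 2`.
#' @examples
#' ramlak_kernel(5, 1)   # c(-1/pi^2, 0, 0.25, 0, -1/pi^2)
#' @export
ramlak_kernel <- function(n_taps, pitch_mm = 1) {
  stopifnot(n_taps >= 1, pitch_mm > 0)
  if (n_taps %% 2 == 0) stop("n_taps must be odd")
  m <- (n_taps - 1) / 2
  n <- -m:m
  h <- numeric(n_taps)
  h[n == 0] <- 1 / (4 * pitch_mm^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2 * pitch_mm^2)
  h
}

# Frequency response of the circularly-embedded Ram-Lak kernel at FFT length
# N. The truncated kernel's small positive tap sum (the infinite kernel sums
# to zero) is redistributed uniformly over the outer half of the taps, so the
# filter has an exactly zero DC response while the central taps — the part
# any impulse probes — remain the exact Ram-Lak coefficients.
ramlak_response <- function(N, pitch_mm, hann = FALSE) {
  h <- ramlak_kernel(N - 1, pitch_mm)
  hc <- numeric(N)
  m <- (N - 2) / 2
  hc[1] <- h[m + 1]
  hc[2:(m + 1)] <- h[(m + 2):(N - 1)]
  hc[(N - m + 1):N] <- h[1:m]
  off <- c(0:(N / 2), -(N / 2 - 1):-1)  # circular tap offsets
  outer_taps <- abs(off) > m / 2
  hc[outer_taps] <- hc[outer_taps] - sum(hc) / sum(outer_taps)
  H <- Re(stats::fft(hc))
  if (hann) {
    f <- off / N
    H <- H * 0.5 * (1 + cos(2 * pi * f))
  }
  H
}

#' Ramp-filter a projection image along the tube-travel axis
#'
#' Applies the Ram-Lak filter row-wise along the image columns (the
#' tube-travel axis) in the frequency domain, with zero padding to at least
#' twice the row length. The DC component of the output is suppressed, so a
#' constant image filters to zero. Limited-angle tomosynthesis only sweeps
#' the source along one axis, so the ramp acts along that axis alone.
#'
#' @param image matrix (rows x cols) or a 3-D array (rows x cols x views) in
#'   the normalized attenuation domain.
#' @param pitch_mm detector pixel pitch (mm).
#' @param hann apply a Hann apodization window on top of the bare ramp.
#' @return filtered image(s), same shape as the input.
#' @export
filter_projection <- function(image, pitch_mm = 1, hann = FALSE) {
  if (length(dim(image)) == 3) {
    out <- image
    for (v in seq_len(dim(image)[3]))
      out[, , v] <- filter_projection(image[, , v], pitch_mm, hann)
    return(out)
  }
  stopifnot(is.matrix(image))
  nc <- ncol(image)
  N <- 2^ceiling(log2(2 * nc))
  H <- ramlak_response(N, pitch_mm, hann)
  # edge-replication padding of the circular buffer: a constant image stays
  # constant around the wrap, so the DC-killed ramp sends it to ~0 everywhere
  X <- matrix(0, N, nrow(image))
  X[seq_len(nc), ] <- t(image)
  nr_pad <- N - nc
  n_hi <- ceiling(nr_pad / 2)
  X[nc + seq_len(n_hi), ] <- rep(X[nc, ], each = n_hi)
  if (nr_pad > n_hi)
    X[(nc + n_hi + 1):N, ] <- rep(X[1, ], each = nr_pad - n_hi)
  Xf <- stats::mvfft(X) * H
  Y <- Re(stats::mvfft(Xf, inverse = TRUE)) / N
  t(Y[seq_len(nc), , drop = FALSE])
}

#' Shift-and-add back projection onto in-plane slices
#'
#' For each requested height z and view, maps every reconstruction pixel to
#' its detector coordinate under the view's perspective (source on the arc,
#' detector stationary), samples the filtered projection with bilinear
#' interpolation and averages over views. The reconstruction grid is the
#' detector grid demagnified to the slice height and centred on the detector
#' centre. Out-of-detector samples are excluded and the average renormalized
#' by the per-pixel hit weight.
#'
#' @param p `projection_set` of (typically ramp-filtered) attenuation images.
#' @param geom `acq_geometry`; defaults to the set's own geometry.
#' @param slice_heights_mm heights (mm above detector) to reconstruct.
#' @return an object of class `recon_volume`: `slices`
#'   (rows x cols x heights), `slice_heights_mm`, `pixel_pitch_mm` (at the
#'   detector; in-plane pitch is demagnified per slice), and the geometry.
#' @export
backproject <- function(p, geom = p$geometry, slice_heights_mm) {
  stopifnot(inherits(p, "projection_set"), inherits(geom, "acq_geometry"),
            length(slice_heights_mm) >= 1)
  sid <- geom$source_to_detector_mm
  if (any(slice_heights_mm < 0 | slice_heights_mm >= sid))
    stop("slice heights must lie in the source-detector gap [0, SID)")
  cx <- geom$detector_cols * geom$pixel_pitch_mm / 2
  cy <- geom$detector_rows * geom$pixel_pitch_mm / 2
  ang <- geom$angles_deg * pi / 180
  bp <- cpp_backproject(p$images, dim(p$images), ang, sid,
                        geom$pixel_pitch_mm, cx, cy,
                        as.numeric(slice_heights_mm))
  hits <- cpp_backproject_hits(dim(p$images), ang, sid, geom$pixel_pitch_mm,
                               cx, cy, as.numeric(slice_heights_mm))
  slices <- bp / pmax(hits, .Machine$double.eps)
  slices[hits == 0] <- 0
  dim(slices) <- dim(bp)
  structure(list(slices = slices, slice_heights_mm = slice_heights_mm,
                 pixel_pitch_mm = geom$pixel_pitch_mm, geometry = geom,
                 arm = p$arm, dose_factor = p$dose_factor),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("recon_volume: %d slices of %d x %d (heights %s mm)\n",
              d[3], d[1], d[2],
              paste(signif(x$slice_heights_mm, 4), collapse = ", ")))
  invisible(x)
}

#' Filtered back projection reconstruction
#'
#' Convenience wrapper: Ram-Lak filtering of every view followed by
#' shift-and-add back projection.
#'
#' @inheritParams backproject
#' @param hann apply a Hann window on the ramp.
#' @return a `recon_volume`.
#' @export
reconstruct_fbp <- function(p, slice_heights_mm, geom = p$geometry,
                            hann = FALSE) {
  stopifnot(p$domain == "attenuation_norm")
  pf <- p
  pf$images <- filter_projection(p$images, geom$pixel_pitch_mm, hann)
  backproject(pf, geom, slice_heights_mm)
}

#' In-plane pixel position of a phantom feature at a slice height
#'
#' Maps a feature's physical (x, y) position to fractional (row, col) indices
#' of the demagnified reconstruction grid at height z.
#'
#' @param geom `acq_geometry`.
#' @param x_mm,y_mm feature position in the detector frame (phantom centred).
#' @param z_mm slice height.
#' @return numeric c(row, col), 1-based fractional indices.
#' @export
recon_pixel <- function(geom, x_mm, y_mm, z_mm) {
  demag <- (geom$source_to_detector_mm - z_mm) / geom$source_to_detector_mm
  ppx <- geom$pixel_pitch_mm * demag
  cx <- geom$detector_cols * geom$pixel_pitch_mm / 2
  cy <- geom$detector_rows * geom$pixel_pitch_mm / 2
  col <- (x_mm - cx) / ppx + geom$detector_cols / 2 + 0.5
  row <- (y_mm - cy) / ppx + geom$detector_rows / 2 + 0.5
  c(row = row, col = col)
}

#' Write a reconstruction volume as float TIFF + JSON sidecar
#' @param rv a `recon_volume`; @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_recon <- function(rv, path) {
  write_float_tiff(rv$slices, path, meta = list(
    kind = "recon_volume", slice_heights_mm = rv$slice_heights_mm,
    pixel_pitch_mm = rv$pixel_pitch_mm, arm = rv$arm,
    dose_factor = rv$dose_factor, geometry = unclass(rv$geometry)))
}
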
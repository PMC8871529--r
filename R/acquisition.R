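#' Tomosynthesis acquisition geometry
#'
#' Partial-isocentric geometry: the detector is stationary in the z = 0 plane
#' and the source travels on an arc of radius `source_to_detector_mm` about
#' the detector centre, spanning `arc_deg` degrees symmetrically about the
#' vertical. View angles are equally spaced,
#' \eqn{\theta_k = -\mathrm{arc}/2 + k\,\mathrm{arc}/(n-1)}. Defaults follow a
#' 15-view, 15-degree sweep; the full-scale detector is 1280 x 2048 pixels
#' while the reduced desk-scale grid is 256 x 512 at 0.1 mm pitch.
#'
#' @param n_views number of projection views.
#' @param arc_deg total angular range of the sweep, degrees.
#' @param source_to_detector_mm source-to-detector distance (mm).
#' @param source_pivot_height_mm height of the rotation centre above the
#'   detector (0 = rotation about the detector plane).
#' @param detector_rows,detector_cols detector grid; columns are the
#'   tube-travel axis.
#' @param pixel_pitch_mm detector pixel pitch (mm).
#' @param slice_heights_mm default reconstruction heights (mm).
#' @return an object of class `acq_geometry`.
#' @examples
#' g <- make_geometry()
#' g$angles_deg[8]   # central view at 0 degrees
#' @export
make_geometry <- function(n_views = 15, arc_deg = 15,
                          source_to_detector_mm = 700,
                          source_pivot_height_mm = 0,
                          detector_rows = 256, detector_cols = 512,
                          pixel_pitch_mm = 0.1,
                          slice_heights_mm = NULL) {
  stopifnot(n_views >= 1, arc_deg >= 0, source_to_detector_mm > 0,
            detector_rows >= 1, detector_cols >= 1, pixel_pitch_mm > 0)
  if (n_views == 1 && arc_deg > 0)
    stop("n_views = 1 with a nonzero arc has undefined view spacing")
  angles <- if (n_views == 1) 0 else
    seq(-arc_deg / 2, arc_deg / 2, length.out = n_views)
  structure(list(
    n_views = as.integer(n_views), arc_deg = arc_deg,
    angles_deg = angles,
    source_to_detector_mm = source_to_detector_mm,
    source_pivot_height_mm = source_pivot_height_mm,
    detector_rows = as.integer(detector_rows),
    detector_cols = as.integer(detector_cols),
    pixel_pitch_mm = pixel_pitch_mm,
    slice_heights_mm = slice_heights_mm
  ), class = "acq_geometry")
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat(sprintf(
    "acq_geometry: %d views over %.3g deg, SID %.4g mm, detector %d x %d @ %.3g mm\n",
    x$n_views, x$arc_deg, x$source_to_detector_mm, x$detector_rows,
    x$detector_cols, x$pixel_pitch_mm))
  invisible(x)
}

#' Study dose levels
#'
#' Reference exposure plus the two reduced levels used throughout the study.
#' The reduction factors 0.49 and 0.23 are the average-glandular-dose ratios
#' of the reduced exposures to the reference at 40 mm thickness (0.66/1.36
#' and 0.31/1.36); per-thickness overrides can be supplied downstream.
#'
#' @return data frame with columns `label` and `dose_factor`.
#' @export
dose_levels <- function() {
  data.frame(label = c("reference", "reduce50", "reduce75"),
             dose_factor = c(1.0, 0.49, 0.23),
             stringsAsFactors = FALSE)
}

resolve_dose <- function(dose) {
  dl <- dose_levels()
  if (is.character(dose)) {
    i <- match(dose, dl$label)
    if (is.na(i)) stop("unknown dose label: ", dose)
    return(dl[i, ])
  }
  if (is.numeric(dose)) {
    if (dose <= 0) stop("dose_factor must be positive")
    return(data.frame(label = sprintf("factor_%g", dose), dose_factor = dose))
  }
  stopifnot(is.data.frame(dose), all(c("label", "dose_factor") %in% names(dose)))
  if (dose$dose_factor <= 0) stop("dose_factor must be positive")
  dose
}

new_projection_set <- function(images, domain, geometry, i0, dose_factor = 1,
                               seed = NULL, noiseless = FALSE, arm = "without",
                               max_att = NA_real_) {
  structure(list(images = images, domain = domain, geometry = geometry,
                 i0 = i0, dose_factor = dose_factor, seed = seed,
                 noiseless = noiseless, arm = arm, max_att = max_att),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "projection_set: %d views of %d x %d, domain=%s, dose_factor=%.3g, arm=%s\n",
    d[3], d[1], d[2], x$domain, x$dose_factor, x$arm))
  invisible(x)
}

#' Forward-project a phantom over the acquisition arc
#'
#' Computes, for every view and detector pixel, the Beer-Lambert line
#' integral of the attenuation volume along the source-to-pixel ray (midpoint
#' sampling at `step_frac` voxel steps with trilinear interpolation) and
#' returns the noiseless intensity image \eqn{I = I_0 \exp(-\int \mu\,dl)}.
#' The volume is centred laterally on the detector and rests on it. Rays that
#' miss the volume are unattenuated.
#'
#' @param vol a `phantom_volume`.
#' @param geom an `acq_geometry`.
#' @param i0 incident photons per pixel at reference dose.
#' @param step_frac ray sampling step as a fraction of the voxel size.
#' @return a `projection_set` in the intensity domain (noiseless,
#'   dose_factor 1).
#' @export
forward_project <- function(vol, geom, i0 = 1e5, step_frac = 0.5) {
  stopifnot(inherits(vol, "phantom_volume"), inherits(geom, "acq_geometry"),
            i0 > 0, step_frac > 0)
  if (geom$source_to_detector_mm <= max(dim(vol$mu)[3] * vol$voxel_mm))
    stop("degenerate geometry: source at or below the phantom top")
  dims <- dim(vol$mu)
  cx <- geom$detector_cols * geom$pixel_pitch_mm / 2
  cy <- geom$detector_rows * geom$pixel_pitch_mm / 2
  origin <- c(cx - dims[1] * vol$voxel_mm / 2,
              cy - dims[2] * vol$voxel_mm / 2, 0)
  li <- cpp_forward_project(vol$mu, dim(vol$mu), vol$voxel_mm, origin,
                            geom$angles_deg * pi / 180,
                            geom$source_to_detector_mm,
                            geom$detector_rows, geom$detector_cols,
                            geom$pixel_pitch_mm, cx, cy, step_frac)
  new_projection_set(i0 * exp(-li), "intensity", geom, i0 = i0,
                     noiseless = TRUE)
}

#' Apply dose-dependent quantum and electronic noise
#'
#' Each noiseless intensity pixel is replaced by a Poisson draw with mean
#' `dose_factor * I` (quantum mottle, variance inversely proportional to
#' dose) plus zero-mean Gaussian electronic noise, clipped at zero.
#'
#' @param p noiseless intensity-domain `projection_set`.
#' @param dose a label from [dose_levels()], a numeric dose factor, or a
#'   one-row data frame with `label` and `dose_factor`.
#' @param electronic_sigma electronic noise standard deviation (photons).
#' @param seed integer seed recorded in the output.
#' @return an intensity-domain `projection_set` at the reduced dose.
#' @export
apply_dose_noise <- function(p, dose, electronic_sigma = 5, seed = 1L) {
  stopifnot(inherits(p, "projection_set"), p$domain == "intensity",
            isTRUE(p$noiseless))
  dose <- resolve_dose(dose)
  set.seed(seed)
  lam <- dose$dose_factor * p$images
  n <- length(lam)
  img <- stats::rpois(n, lam) +
    if (electronic_sigma > 0) stats::rnorm(n, 0, electronic_sigma) else 0
  img <- pmax(img, 0)
  dim(img) <- dim(p$images)
  out <- new_projection_set(img, "intensity", p$geometry, i0 = p$i0,
                            dose_factor = dose$dose_factor,
                            seed = as.integer(seed))
  out$dose_label <- dose$label
  out
}

#' Convert intensity projections to normalized attenuation images
#'
#' Pixels are log-transformed, \eqn{-\ln(\max(I,\epsilon)/(f\,I_0))} with
#' dose factor \eqn{f}, then affinely rescaled by a fixed geometry-wide
#' calibration (attenuation 0 maps to 0, `max_att` maps to 1, values
#' clipped), so images are comparable across dose levels and processing
#' arms, with single-precision data on \[0, 1\].
#'
#' @param p intensity-domain `projection_set` with known `i0`.
#' @param max_att calibration attenuation mapped to 1.0.
#' @param eps_photons floor (photon equivalents) guarding the log.
#' @return `projection_set` in the `attenuation_norm` domain.
#' @export
to_attenuation_norm <- function(p, max_att = 4, eps_photons = 1) {
  stopifnot(inherits(p, "projection_set"), p$domain == "intensity")
  if (is.null(p$i0) || !is.finite(p$i0)) stop("i0 missing; cannot normalize")
  att <- -log(pmax(p$images, eps_photons) / (p$dose_factor * p$i0))
  img <- pmin(pmax(att / max_att, 0), 1)
  dim(img) <- dim(p$images)
  out <- p
  out$images <- img
  out$domain <- "attenuation_norm"
  out$max_att <- max_att
  out
}

#' Write / read a projection set (multi-page float TIFF + JSON sidecar)
#'
#' @param p a `projection_set`.
#' @param path TIFF path, one page per view.
#' @return `write_projections` returns `path` invisibly; `read_projections`
#'   a `projection_set`.
#' @export
write_projections <- function(p, path) {
  g <- p$geometry
  write_float_tiff(p$images, path, meta = list(
    kind = "projection_set", domain = p$domain, i0 = p$i0,
    dose_factor = p$dose_factor, seed = p$seed, noiseless = p$noiseless,
    arm = p$arm, max_att = p$max_att,
    geometry = unclass(g)))
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  x <- read_float_tiff(path)
  m <- x$meta
  gfields <- m$geometry[names(m$geometry) %in% names(formals(make_geometry))]
  geom <- do.call(make_geometry, gfields)
  out <- new_projection_set(x$data, m$domain, geom, i0 = m$i0,
                            dose_factor = m$dose_factor,
                            seed = m$seed,
                            noiseless = isTRUE(m$noiseless), arm = m$arm,
                            max_att = if (is.null(m$max_att)) NA_real_
                                      else m$max_att)
  out
}
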
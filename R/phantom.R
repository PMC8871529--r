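#' Specify a heterogeneous breast phantom
#'
#' Describes a voxelized slab phantom emulating a commercial structured breast
#' phantom: a 50/50 glandular/adipose heterogeneous background with groups of
#' microcalcification (MC) specks and spheroidal masses embedded in a target
#' plane. The attenuation coefficients are representative of breast tissue
#' around 20 keV and are configurable; the defaults are
#' \eqn{\mu_a = 0.045\,\mathrm{mm}^{-1}} (adipose),
#' \eqn{\mu_g = 0.080\,\mathrm{mm}^{-1}} (glandular), +0.60 mm^-1 for calcium
#' specks and +0.010 mm^-1 for soft-tissue masses.
#'
#' The coordinate frame is right-handed with `z` the height above the detector
#' plane, voxel indices 0-based and voxel centers at `(i + 0.5) * voxel_mm`.
#' The first lateral axis (`x`, image columns) is the tube-travel direction.
#'
#' @param thickness_mm total phantom thickness, one of 40, 50 or 60 (other
#'   positive values are allowed for reduced-scale runs).
#' @param voxel_mm isotropic voxel size in mm.
#' @param lateral_extent_mm length-2 numeric, extent in mm along (x, y).
#' @param glandular_fraction volumetric glandular fraction in \[0, 1\].
#' @param texture_correlation_mm correlation length of the background texture.
#' @param mc_sizes_mm diameters of the MC groups (mm).
#' @param mass_diameters_mm diameters of the spheroidal masses (mm).
#' @param target_slab_depth_mm height of the feature plane above the phantom
#'   bottom; defaults to mid-thickness.
#' @param seed integer seed controlling the background texture.
#' @param margin_mm minimum clearance between features and the lateral border.
#' @param mu_adipose,mu_glandular background attenuation coefficients (1/mm).
#' @param mc_contrast,mass_contrast attenuation increments (1/mm) of the
#'   features over the local background.
#' @param mass_z_aspect ratio of the mass z semi-axis to its lateral semi-axis
#'   (1 = sphere).
#' @return an object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(thickness_mm = 40, voxel_mm = 0.4,
#'                      lateral_extent_mm = c(25.6, 25.6))
#' @export
phantom_spec <- function(thickness_mm = 40,
                         voxel_mm = 0.1,
                         lateral_extent_mm = c(51.2, 25.6),
                         glandular_fraction = 0.5,
                         texture_correlation_mm = 3,
                         mc_sizes_mm = c(0.196, 0.23, 0.29),
                         mass_diameters_mm = c(3.9, 4.7),
                         target_slab_depth_mm = thickness_mm / 2,
                         seed = 1L,
                         margin_mm = 3,
                         mu_adipose = 0.045,
                         mu_glandular = 0.080,
                         mc_contrast = 0.60,
                         mass_contrast = 0.010,
                         mass_z_aspect = 1.0) {
  stopifnot(thickness_mm > 0, voxel_mm > 0,
            length(lateral_extent_mm) == 2, all(lateral_extent_mm > 0),
            glandular_fraction >= 0, glandular_fraction <= 1,
            texture_correlation_mm > 0,
            target_slab_depth_mm > 0, target_slab_depth_mm < thickness_mm,
            mc_contrast > 0, mass_contrast > 0, mass_z_aspect > 0)
  if (voxel_mm > texture_correlation_mm)
    stop("voxel_mm exceeds texture_correlation_mm: texture is unresolvable")
  structure(list(
    thickness_mm = thickness_mm, voxel_mm = voxel_mm,
    lateral_extent_mm = lateral_extent_mm,
    glandular_fraction = glandular_fraction,
    texture_correlation_mm = texture_correlation_mm,
    mc_sizes_mm = mc_sizes_mm, mass_diameters_mm = mass_diameters_mm,
    target_slab_depth_mm = target_slab_depth_mm, seed = as.integer(seed),
    margin_mm = margin_mm, mu_adipose = mu_adipose,
    mu_glandular = mu_glandular, mc_contrast = mc_contrast,
    mass_contrast = mass_contrast, mass_z_aspect = mass_z_aspect
  ), class = "phantom_spec")
}

phantom_dims <- function(spec) {
  c(round(spec$lateral_extent_mm[1] / spec$voxel_mm),
    round(spec$lateral_extent_mm[2] / spec$voxel_mm),
    round(spec$thickness_mm / spec$voxel_mm))
}

#' Generate the heterogeneous phantom background
#'
#' Draws a seeded, spatially correlated Gaussian random field (white noise on
#' a coarse grid at half the texture correlation length, binomially smoothed,
#' trilinearly refined to the voxel grid), converts it to a glandular mixture
#' weight by a soft threshold placed at the empirical quantile matching the
#' requested glandular fraction, and maps the weight to attenuation
#' \eqn{\mu = \mu_a + w (\mu_g - \mu_a)}. The volumetric glandular fraction
#' (voxels with weight > 0.5) matches `spec$glandular_fraction` by
#' construction of the quantile threshold.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_volume`: list with `mu` (3-D array of
#'   linear attenuation, 1/mm), `voxel_mm`, `spec` and an empty feature
#'   `registry` data frame.
#' @export
build_background <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- phantom_dims(spec)
  gf <- spec$glandular_fraction
  if (gf == 0 || gf == 1) {
    mu <- array(if (gf == 0) spec$mu_adipose else spec$mu_glandular, dims)
    return(new_phantom_volume(mu, spec))
  }
  set.seed(spec$seed)
  # coarse grid at half the correlation length; binomial smoothing then
  # trilinear refinement gives a band-limited field at the right scale
  spacing <- spec$texture_correlation_mm / 2
  cdims <- pmax(4L, as.integer(ceiling(dims * spec$voxel_mm / spacing)) + 2L)
  field <- array(stats::rnorm(prod(cdims)), cdims)
  k <- c(1, 4, 6, 4, 1) / 16
  field <- smooth3_sep(field, k)
  field <- cpp_resize3(field, dim(field), as.integer(dims))
  thr <- stats::quantile(field, 1 - gf, names = FALSE)
  w <- stats::plogis((field - thr) / (0.15 * stats::sd(field)))
  mu <- spec$mu_adipose + w * (spec$mu_glandular - spec$mu_adipose)
  dim(mu) <- dims
  new_phantom_volume(mu, spec)
}

# separable 1-D smoothing of a 3-D array along each axis (reflected borders)
smooth3_sep <- function(x, k) {
  m <- (length(k) - 1L) / 2L
  conv_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (o in -m:m) {
      i <- seq_len(d[axis]) + o
      i[i < 1] <- 1 - i[i < 1]                          # reflect low edge
      i[i > d[axis]] <- 2 * d[axis] + 1 - i[i > d[axis]]  # reflect high edge
      sl <- switch(axis, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
                   a[, , i, drop = FALSE])
      out <- out + k[o + m + 1] * sl
    }
    out
  }
  for (ax in 1:3) x <- conv_axis(x, ax)
  x
}

new_phantom_volume <- function(mu, spec, registry = NULL) {
  if (is.null(registry))
    registry <- data.frame(kind = character(), x_mm = numeric(),
                           y_mm = numeric(), z_mm = numeric(),
                           size_mm = numeric(), contrast = numeric(),
                           group = character(), stringsAsFactors = FALSE)
  structure(list(mu = mu, voxel_mm = spec$voxel_mm, spec = spec,
                 registry = registry), class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  d <- dim(x$mu)
  cat(sprintf("phantom_volume: %d x %d x %d voxels (%.3g mm), %d features\n",
              d[1], d[2], d[3], x$voxel_mm, nrow(x$registry)))
  cat(sprintf("  attenuation range [%.4f, %.4f] 1/mm\n",
              min(x$mu), max(x$mu)))
  invisible(x)
}

#' Default feature layout for a phantom
#'
#' Lays out one 5-speck cross per MC size group along the tube-travel axis at
#' a quarter of the lateral depth, and the masses along the mid line, all on
#' the target plane `spec$target_slab_depth_mm`.
#'
#' @param spec a [phantom_spec()].
#' @param mc_arm_mm half-arm of the 5-speck cross (mm).
#' @return a data frame of feature records (kind, center in mm, size,
#'   contrast, group label).
#' @export
default_feature_layout <- function(spec, mc_arm_mm = 1.5) {
  lx <- spec$lateral_extent_mm[1]
  ly <- spec$lateral_extent_mm[2]
  z <- spec$target_slab_depth_mm
  rec <- list()
  n_mc <- length(spec$mc_sizes_mm)
  if (n_mc > 0) {
    xs <- lx * seq(0.18, 0.62, length.out = max(n_mc, 2))[seq_len(n_mc)]
    y_mc <- ly * 0.28
    for (i in seq_len(n_mc)) {
      cx <- xs[i]
      offs <- rbind(c(0, 0), c(-mc_arm_mm, 0), c(mc_arm_mm, 0),
                    c(0, -mc_arm_mm), c(0, mc_arm_mm))
      for (j in 1:5)
        rec[[length(rec) + 1]] <- data.frame(
          kind = "mc", x_mm = cx + offs[j, 1], y_mm = y_mc + offs[j, 2],
          z_mm = z, size_mm = spec$mc_sizes_mm[i],
          contrast = spec$mc_contrast,
          group = sprintf("mc_%g", spec$mc_sizes_mm[i]))
    }
  }
  n_ms <- length(spec$mass_diameters_mm)
  if (n_ms > 0) {
    xs <- lx * seq(0.35, 0.65, length.out = max(n_ms, 2))[seq_len(n_ms)]
    y_ms <- ly * 0.62
    for (i in seq_len(n_ms))
      rec[[length(rec) + 1]] <- data.frame(
        kind = "mass", x_mm = xs[i], y_mm = y_ms, z_mm = z,
        size_mm = spec$mass_diameters_mm[i], contrast = spec$mass_contrast,
        group = sprintf("mass_%g", spec$mass_diameters_mm[i]))
  }
  do.call(rbind, rec)
}

#' Insert microcalcifications and masses into a phantom volume
#'
#' Features are rasterized as spheres (masses optionally as oblate spheroids)
#' with partial-volume weighting: boundary voxels receive the sub-sampled
#' inside fraction of the attenuation increment, so sub-voxel specks are
#' representable. The ground-truth registry is extended with the exact
#' centers and sizes for later ROI placement.
#'
#' @param vol a `phantom_volume` from [build_background()].
#' @param spec the [phantom_spec()] (used for layout defaults and margins).
#' @param features optional data frame as returned by
#'   [default_feature_layout()]; when `NULL` the default layout is used.
#' @param nsub boundary-voxel sub-sampling factor per axis.
#' @return the modified `phantom_volume` with an updated registry.
#' @export
insert_features <- function(vol, spec = vol$spec, features = NULL, nsub = 8L) {
  stopifnot(inherits(vol, "phantom_volume"))
  if (is.null(features)) features <- default_feature_layout(spec)
  if (is.null(features) || nrow(features) == 0) return(vol)
  dims <- dim(vol$mu)
  ext <- c(dims[1], dims[2], dims[3]) * vol$voxel_mm
  r <- features$size_mm / 2
  inb <- features$x_mm - r >= spec$margin_mm &
    features$x_mm + r <= ext[1] - spec$margin_mm &
    features$y_mm - r >= spec$margin_mm &
    features$y_mm + r <= ext[2] - spec$margin_mm &
    features$z_mm - r >= 0 & features$z_mm + r <= ext[3]
  if (!all(inb))
    stop("features outside volume bounds/margin: rows ",
         paste(which(!inb), collapse = ", "))
  # pairwise overlap check on bounding spheres
  if (nrow(features) > 1) {
    ctr <- as.matrix(features[, c("x_mm", "y_mm", "z_mm")])
    dd <- as.matrix(stats::dist(ctr))
    lim <- outer(r, r, "+")
    diag(dd) <- Inf
    bad <- which(dd < lim, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad) > 0)
      stop("overlapping features: ",
           paste(sprintf("(%d,%d)", bad[, 1], bad[, 2]), collapse = " "))
  }
  mu <- vol$mu
  for (i in seq_len(nrow(features))) {
    za <- if (features$kind[i] == "mass") spec$mass_z_aspect else 1.0
    mu <- cpp_add_spheroid(mu, dim(mu), vol$voxel_mm,
                           c(features$x_mm[i], features$y_mm[i],
                             features$z_mm[i]),
                           features$size_mm[i] / 2, za,
                           features$contrast[i], as.integer(nsub))
  }
  dim(mu) <- dims
  vol$mu <- mu
  vol$registry <- rbind(vol$registry, features)
  vol
}

#' Write / read a phantom volume as float TIFF + JSON registry
#'
#' @param vol a `phantom_volume`.
#' @param path TIFF file path (pages are z-slices); the registry and spec go
#'   to `<path>.json`.
#' @return `write_phantom` returns `path` invisibly; `read_phantom` a
#'   `phantom_volume`.
#' @export
write_phantom <- function(vol, path) {
  write_float_tiff(vol$mu, path,
                   meta = list(kind = "phantom_volume",
                               voxel_mm = vol$voxel_mm,
                               spec = unclass(vol$spec),
                               registry = vol$registry))
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  x <- read_float_tiff(path)
  spec <- do.call(phantom_spec, x$meta$spec[names(x$meta$spec) %in%
                                              names(formals(phantom_spec))])
  reg <- as.data.frame(x$meta$registry)
  out <- new_phantom_volume(x$data, spec,
                            if (nrow(reg)) reg else NULL)
  out
}
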
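#' Configure a dose-reduction evaluation experiment
#'
#' Bundles every stage of the study design: phantom(s), acquisition
#' geometry, dose levels, processing arms, denoiser settings and seeds.
#' Defaults reproduce the desk-scale study: one thickness per run, 15 views
#' over 15 degrees, reference / 49% / 23% dose factors, and the three
#' processing arms compared against the reference-dose reconstruction.
#'
#' @param thicknesses_mm phantom thicknesses to run (subset of 40/50/60 at
#'   full scale; any positive values at reduced scale).
#' @param phantom_args named list of overrides passed to [phantom_spec()].
#' @param geometry_args named list of overrides passed to [make_geometry()].
#' @param dose_labels reduced dose levels to process (reference always runs).
#' @param arms processing arms, subset of `c("without", "msbf", "pix2pix")`.
#' @param msbf an [msbf_params()].
#' @param train a [train_config()] used if `pix2pix_fit` is `NULL`.
#' @param pix2pix_fit optional pre-trained `pix2pix_fit` reused across runs.
#' @param i0 reference-dose photons per pixel.
#' @param electronic_sigma electronic noise (photons).
#' @param max_att attenuation-normalization calibration.
#' @param seed master seed; all per-stage seeds derive from it.
#' @param out_dir directory for TIFF/CSV/JSON outputs (`NULL` = in-memory
#'   results only).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(thicknesses_mm = 40,
                              phantom_args = list(),
                              geometry_args = list(),
                              dose_labels = c("reduce50", "reduce75"),
                              arms = c("without", "msbf", "pix2pix"),
                              msbf = msbf_params(),
                              train = train_config(),
                              pix2pix_fit = NULL,
                              i0 = 1e5, electronic_sigma = 5, max_att = 4,
                              seed = 1L, out_dir = NULL) {
  stopifnot(all(arms %in% c("without", "msbf", "pix2pix")),
            all(dose_labels %in% dose_levels()$label))
  structure(list(thicknesses_mm = thicknesses_mm,
                 phantom_args = phantom_args, geometry_args = geometry_args,
                 dose_labels = dose_labels, arms = arms, msbf = msbf,
                 train = train, pix2pix_fit = pix2pix_fit, i0 = i0,
                 electronic_sigma = electronic_sigma, max_att = max_att,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [experiment_config()];
#' `msbf` and `train` sub-maps are passed to [msbf_params()] and
#' [train_config()].
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[names(y) %in% names(formals(experiment_config))]
  if (!is.null(y$msbf)) args$msbf <- do.call(msbf_params, y$msbf)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  do.call(experiment_config, args)
}

# physical detector-frame position of a registry feature (phantom centred
# laterally on the detector)
feature_positions <- function(vol, geom) {
  dims <- dim(vol$mu)
  cx <- geom$detector_cols * geom$pixel_pitch_mm / 2
  cy <- geom$detector_rows * geom$pixel_pitch_mm / 2
  ox <- cx - dims[1] * vol$voxel_mm / 2
  oy <- cy - dims[2] * vol$voxel_mm / 2
  reg <- vol$registry
  reg$x_det <- reg$x_mm + ox
  reg$y_det <- reg$y_mm + oy
  reg
}

measure_slice <- function(slice, vol, geom, z, arm, dose_label,
                          thickness, ref_slice = NULL) {
  reg <- feature_positions(vol, geom)
  demag <- (geom$source_to_detector_mm - z) / geom$source_to_detector_mm
  pitch_in <- geom$pixel_pitch_mm * demag
  rows <- list()
  add <- function(target, metric, direction, value)
    rows[[length(rows) + 1]] <<- data.frame(
      arm = arm, dose = dose_label, thickness_mm = thickness,
      target = target, direction = direction, metric = metric,
      value = value, stringsAsFactors = FALSE)
  mcs <- reg[reg$kind == "mc", , drop = FALSE]
  half_len <- max(5L, round(0.7 / pitch_in))
  for (i in seq_len(nrow(mcs))) {
    ctr <- recon_pixel(geom, mcs$x_det[i], mcs$y_det[i], z)
    for (dir in c("horizontal", "vertical")) {
      f <- tryCatch(fwhm(extract_profile(slice, ctr, dir,
                                         half_len_px = half_len,
                                         pitch_mm = pitch_in)),
                    error = function(e) NA_real_)
      add(mcs$group[i], "fwhm", dir, f)
    }
  }
  masses <- reg[reg$kind == "mass", , drop = FALSE]
  for (i in seq_len(nrow(masses))) {
    ctr <- recon_pixel(geom, masses$x_det[i], masses$y_det[i], z)
    dpx <- masses$size_mm[i] / pitch_in
    feat <- roi_spec(ctr, dpx)
    bg <- cnr_background_rois(feat, pitch_mm = pitch_in)
    v <- tryCatch(cnr(slice, feat, bg), error = function(e) NA_real_)
    add(masses$group[i], "cnr", "none", v)
  }
  if (!is.null(ref_slice)) {
    add("whole_image", "psnr", "none", psnr(ref_slice, slice))
    add("whole_image", "mssim", "none", mssim(ref_slice, slice))
  }
  do.call(rbind, rows)
}

#' Run the full evaluation experiment
#'
#' For every thickness: builds the phantom, simulates noiseless projections,
#' draws the reference-dose acquisition and its FBP reconstruction (the
#' comparator), then for each reduced dose level processes the *same* noisy
#' projections through each arm (no processing, multiscale bilateral
#' filtering, adversarial denoiser), reconstructs the in-focus target plane,
#' and measures FWHM per microcalcification (both directions), CNR per mass,
#' and PSNR/MSSIM against the reference reconstruction. FWHM values then
#' enter the Tukey-Kramer four-group comparison and the processing-by-dose
#' two-way ANOVA (reference arm excluded from the factorial block).
#'
#' @param cfg an [experiment_config()].
#' @param progress print per-stage progress lines.
#' @return list with `metrics` (tidy data frame), `stats` (per MC size:
#'   `tukey` and `anova` tables), `manifest` (seeds and provenance), and
#'   `fit` (the pix2pix fit used, if any). When `cfg$out_dir` is set, TIFF
#'   stacks, the metrics CSV and the manifest JSON are written there.
#' @export
run_experiment <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (progress) message(sprintf(...))
  t0 <- Sys.time()
  geom <- do.call(make_geometry, cfg$geometry_args)
  fit <- cfg$pix2pix_fit
  if ("pix2pix" %in% cfg$arms && is.null(fit)) {
    say("training pix2pix denoiser (desk scale)")
    tp <- make_training_pairs(n_pairs = 64, patch_px = cfg$train$patch_px,
                              dose_factor = 0.49, seed = cfg$seed + 900L,
                              i0 = cfg$i0,
                              electronic_sigma = cfg$electronic_sigma)
    fit <- pix2pix_train(tp$pairs, cfg$train)
  }
  metrics <- NULL
  manifest <- list(seed = cfg$seed, started = format(t0), stages = list())
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  for (ti in seq_along(cfg$thicknesses_mm)) {
    th <- cfg$thicknesses_mm[ti]
    say("thickness %g mm: phantom + projections", th)
    pargs <- cfg$phantom_args
    pargs$thickness_mm <- th
    pargs$seed <- cfg$seed + ti
    spec <- do.call(phantom_spec, pargs)
    vol <- insert_features(build_background(spec), spec)
    z <- spec$target_slab_depth_mm
    pn <- forward_project(vol, geom, i0 = cfg$i0)
    seed_ref <- cfg$seed + 1000L * ti
    pref <- to_attenuation_norm(
      apply_dose_noise(pn, "reference", cfg$electronic_sigma, seed_ref),
      cfg$max_att)
    rref <- reconstruct_fbp(pref, z)
    ref_slice <- rref$slices[, , 1]
    metrics <- rbind(metrics,
                     measure_slice(ref_slice, vol, geom, z, "reference",
                                   "reference", th))
    if (!is.null(out_dir)) {
      write_projections(pref, file.path(out_dir,
                                        sprintf("proj_t%g_reference.tif", th)))
      write_recon(rref, file.path(out_dir,
                                  sprintf("recon_t%g_reference.tif", th)))
    }
    for (di in seq_along(cfg$dose_labels)) {
      dl <- cfg$dose_labels[di]
      seed_noise <- cfg$seed + 1000L * ti + 10L * di
      plow <- to_attenuation_norm(
        apply_dose_noise(pn, dl, cfg$electronic_sigma, seed_noise),
        cfg$max_att)
      for (arm in cfg$arms) {
        say("thickness %g mm, %s, arm %s", th, dl, arm)
        parm <- switch(arm,
          without = plow,
          msbf = { q <- plow; q$images <- msbf_process(plow$images, cfg$msbf)
                   q$arm <- "msbf"; q },
          pix2pix = denoise_projections(plow, fit,
                                        seed = seed_noise + 5L))
        rarm <- reconstruct_fbp(parm, z)
        metrics <- rbind(metrics,
                         measure_slice(rarm$slices[, , 1], vol, geom, z,
                                       arm, dl, th, ref_slice))
        if (!is.null(out_dir)) {
          write_projections(parm, file.path(
            out_dir, sprintf("proj_t%g_%s_%s.tif", th, dl, arm)))
          write_recon(rarm, file.path(
            out_dir, sprintf("recon_t%g_%s_%s.tif", th, dl, arm)))
        }
        manifest$stages[[length(manifest$stages) + 1]] <-
          list(thickness = th, dose = dl, arm = arm, seed = seed_noise)
      }
    }
  }
  stats_out <- fwhm_statistics(metrics)
  manifest$finished <- format(Sys.time())
  manifest$metric_rows <- nrow(metrics)
  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(metrics = metrics, stats = stats_out, manifest = manifest, fit = fit)
}

#' Statistical comparison of FWHM measurements across arms
#'
#' For each microcalcification size: the Tukey-Kramer all-pairs comparison
#' over the four groups (reference plus the three low-dose arms, doses
#' pooled within arm) and the processing-by-dose two-way ANOVA over the
#' three low-dose arms.
#'
#' @param metrics tidy metrics data frame from [run_experiment()].
#' @return named list per MC target with elements `tukey` and `anova`
#'   (`NULL` when the design is incomplete).
#' @export
fwhm_statistics <- function(metrics) {
  f <- metrics[metrics$metric == "fwhm" & !is.na(metrics$value), ]
  if (nrow(f) == 0) return(list())
  out <- list()
  for (tg in unique(f$target)) {
    g <- f[f$target == tg, ]
    res <- list(tukey = NULL, anova = NULL)
    ns <- table(g$arm)
    if (length(ns) >= 2 && all(ns >= 2))
      res$tukey <- tukey_kramer(g$value, g$arm, mirror = TRUE)
    gl <- g[g$arm != "reference", ]
    if (nrow(gl) > 0 && nlevels(factor(gl$arm)) >= 2 &&
        nlevels(factor(gl$dose)) >= 2 &&
        all(table(gl$arm, gl$dose) > 1))
      res$anova <- tryCatch(two_way_anova(gl$value, gl$arm, gl$dose),
                            error = function(e) NULL)
    out[[tg]] <- res
  }
  out
}
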
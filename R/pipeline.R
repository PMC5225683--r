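# Full-series orchestration: preprocessing, dome detection, ribcage
# masking, seeding, random-walker segmentation, and diagnostics.

#' Pipeline configuration
#'
#' All tunable parameters of the segmentation pipeline with their
#' documented defaults. The object round-trips through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param window abdominal display window ([window_settings()]); the walker
#'   operates on window-clipped intensities when `use_window` is TRUE.
#' @param use_window segment on windowed intensities (default) rather than
#'   min-max normalized HU.
#' @param canny_sigma Gaussian sigma of the Canny detector (pixels).
#' @param hat_radius disc radius of the top-/bottom-hat enhancement.
#' @param background_hu fill value for removed background.
#' @param lung_hu_threshold HU below which a pixel counts as lung air.
#' @param lung_min_area smallest accepted lung component (pixels).
#' @param dome_decrease_fraction relative lung-area decrease of the dome
#'   rule (default 0.10).
#' @param last_slice_pixel_threshold in-range pixel count below which a
#'   slice ends the liver (default 100, calibrated on 512 x 512 slices).
#' @param intensity_k multiplier k of the `mean +/- k * deviation`
#'   liver-intensity test.
#' @param initial_liver_hu HU band accepted as liver before calibration.
#' @param bone_hu_threshold HU above which a pixel counts as bone.
#' @param rib_area_limits rib component pixel-count limits.
#' @param steep_decrease_fraction ribcage-interior area fraction below
#'   which the neighbor-centroid fallback triggers.
#' @param spline_samples samples of the closed ribcage spline (>= 360).
#' @param rw [rw_params()] for the random walker.
#' @param max_seeds_per_slice total per-slice seed budget (liver half,
#'   background half).
#' @param template_erosion_radius erosion of the lung template before
#'   initial liver seeding.
#' @param seed_erosion_radius erosion of the previous liver before
#'   propagated liver seeding.
#' @param seed_open_radius opening applied to the liver-candidate mask so
#'   no seed lands on an isolated band-passing noise pixel.
#' @param seed_dilation_radius dilation of the liver region excluded from
#'   background seeding.
#' @param lesion_min_area smallest intensity-outlier component seeded as a
#'   lesion.
#' @param lesion_min_hu lowest HU accepted as lesion tissue (air/lung
#'   attenuation inside the liver estimate is residual lung, not lesion).
#' @param lesion_enclosure_fraction minimum fraction of the ring around an
#'   outlier component that must be liver-like tissue; rejects boundary
#'   soft tissue that crept into the liver estimate.
#' @param lesion_core_radius an outlier component only counts as a lesion
#'   if it survives erosion by this radius (thin curvilinear outliers are
#'   enhancement rim artifacts along the boundary).
#' @param flip_lr patient-right is image-right (non-standard display).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = window_settings(40, 400),
                            use_window = TRUE,
                            canny_sigma = 1.0,
                            hat_radius = 5,
                            background_hu = -1000,
                            lung_hu_threshold = -400,
                            lung_min_area = 100,
                            dome_decrease_fraction = 0.10,
                            last_slice_pixel_threshold = 100,
                            intensity_k = 2,
                            initial_liver_hu = c(60, 180),
                            bone_hu_threshold = 200,
                            rib_area_limits = c(20, 2000),
                            steep_decrease_fraction = 0.7,
                            spline_samples = 360,
                            rw = rw_params(),
                            max_seeds_per_slice = 1200,
                            template_erosion_radius = 5,
                            seed_erosion_radius = 3,
                            seed_open_radius = 2,
                            seed_dilation_radius = 5,
                            lesion_min_area = 30,
                            lesion_min_hu = -200,
                            lesion_enclosure_fraction = 0.8,
                            lesion_core_radius = 2,
                            flip_lr = FALSE) {
  structure(list(
    window = window, use_window = use_window, canny_sigma = canny_sigma,
    hat_radius = hat_radius, background_hu = background_hu,
    lung_hu_threshold = lung_hu_threshold, lung_min_area = lung_min_area,
    dome_decrease_fraction = dome_decrease_fraction,
    last_slice_pixel_threshold = last_slice_pixel_threshold,
    intensity_k = intensity_k, initial_liver_hu = initial_liver_hu,
    bone_hu_threshold = bone_hu_threshold, rib_area_limits = rib_area_limits,
    steep_decrease_fraction = steep_decrease_fraction,
    spline_samples = spline_samples, rw = rw,
    max_seeds_per_slice = as.integer(max_seeds_per_slice),
    template_erosion_radius = template_erosion_radius,
    seed_erosion_radius = seed_erosion_radius,
    seed_open_radius = seed_open_radius,
    seed_dilation_radius = seed_dilation_radius,
    lesion_min_area = lesion_min_area, lesion_min_hu = lesion_min_hu,
    lesion_enclosure_fraction = lesion_enclosure_fraction,
    lesion_core_radius = lesion_core_radius,
    flip_lr = flip_lr
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$window <- unclass(x$window)
  x$rw <- unclass(x$rw)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$window <- do.call(window_settings, x$window)
  x$rw <- do.call(rw_params, x$rw)
  do.call(pipeline_config, x)
}

#' Segment the liver in a CT series
#'
#' Runs the full automatic pipeline on a loaded volume:
#' \enumerate{
#'   \item per-slice preprocessing (background removal, top-/bottom-hat
#'     enhancement, 3x3 median);
#'   \item right-lung detection and liver-dome localization from two
#'     consecutive >= 10 percent lung-area decreases;
#'   \item ribcage-interior masking from the closed B-spline through rib
#'     centroids (with the neighbor fallback);
#'   \item liver extent and intensity calibration from the two slices after
#'     the dome, with the dome-1 right-lung mask as template;
#'   \item slice-sequential seeding (initial at dome+1/dome+2, propagated
#'     from the previous segmentation elsewhere, lesion outliers seeded as
#'     their own label) and the multi-label random-walker Dirichlet solve;
#'     intensity statistics are recalibrated once at the middle slice;
#'   \item the dome slice itself is segmented last by one backward
#'     propagation from dome+1.
#' }
#' Slices before the dome and after the last liver slice are background.
#' The final liver mask is the union of the liver and lesion labels
#' (envelope semantics). A failed slice is marked in the diagnostics and
#' propagation falls back to the last good slice; the run continues.
#'
#' @param volume a [ct_volume()] in HU.
#' @param config a [pipeline_config()].
#' @param keep_probabilities retain per-label probability images per slice.
#' @return object of class `liver_segmentation`: `labels` (3D integer
#'   array: 0 background, 1 liver, 2 other organs, 3 lesions),
#'   `liver_mask` (3D logical envelope), `extent` ([estimate_liver_extent()]
#'   result), `diagnostics` (per-slice data.frame), `probabilities`
#'   (optional list), `config`.
#' @export
segment_series <- function(volume, config = pipeline_config(),
                           keep_probabilities = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  nz <- dim(volume$voxels)[1]
  body_masks <- vector("list", nz)
  slices <- vector("list", nz)
  for (z in seq_len(nz)) {
    pp <- preprocess_slice(volume$voxels[z, , ], config)
    body_masks[[z]] <- pp$mask
    slices[[z]] <- pp$slice
  }
  pvol <- ct_volume(simplify2array_slices(slices), spacing = volume$spacing)

  lungs <- detect_lungs(pvol, body_masks, lung_hu = config$lung_hu_threshold,
                        min_area = config$lung_min_area,
                        flip_lr = config$flip_lr)
  dome <- detect_liver_dome(lungs$area,
                            threshold = config$dome_decrease_fraction)
  if (is.na(dome))
    stop("pipeline aborted: liver dome not found (lung areas: ",
         paste(round(lungs$area), collapse = " "), ")")

  ribs <- ribcage_interiors(slices, body_masks, config)
  extent <- estimate_liver_extent(pvol, lungs, dome, ribs$interiors,
                                  body_masks, config)
  stats <- list(mean = extent$mean, deviation = extent$deviation)

  labels <- array(0L, dim(volume$voxels))
  probs_out <- if (keep_probabilities) vector("list", nz) else NULL
  diag <- data.frame(
    slice = seq_len(nz), lung_area = lungs$area,
    ribcage_area = ribs$areas, ribcage_fallback = ribs$fallback_used,
    seeds_liver = 0L, seeds_other = 0L, seeds_lesion = 0L,
    seeds_outside_body = 0L, residual = NA_real_, failed = FALSE,
    segmented = FALSE
  )

  prev_liver <- NULL
  fw <- if (extent$last >= dome + 1L) (dome + 1L):extent$last else integer(0)
  order_z <- c(fw, dome)   # forward pass, then the dome
  for (z in order_z) {
    backward <- z == dome
    if (backward)   # the dome is seeded from the slice just below it
      prev_liver <- labels[dome + 1L, , ] == 1L | labels[dome + 1L, , ] >= 3L
    sl <- slices[[z]]
    gm <- ribs$interiors[[z]]
    if (!any(gm)) { diag$failed[z] <- TRUE; next }
    sm <- if ((z %in% c(dome + 1L, dome + 2L) && !backward) ||
              is.null(prev_liver) || !any(prev_liver)) {
      place_initial_seeds(sl, extent$template, body_masks[[z]],
                          graph_mask = gm, stats = stats, config = config)
    } else {
      s <- propagate_seeds(prev_liver, sl, body_masks[[z]], graph_mask = gm,
                           stats = stats, config = config)
      if (isTRUE(attr(s, "empty_liver")))
        s <- place_initial_seeds(sl, extent$template, body_masks[[z]],
                                 graph_mask = gm, stats = stats,
                                 config = config)
      s
    }
    if (isTRUE(attr(sm, "empty_liver"))) {
      # nothing liver-like on this slice: label everything background
      diag$segmented[z] <- TRUE
      if (!backward) prev_liver <- NULL
      next
    }
    # lesions are sought strictly inside the current liver estimate; eroding
    # keeps the boundary halo from being mistaken for an outlier region
    if (!is.null(prev_liver) && any(prev_liver)) {
      liver_region <- disc_erode(prev_liver, config$seed_open_radius) & gm
      # only search a liver estimate large enough to host a lesion reliably;
      # in the thin caudal tip an outlier component is boundary halo
      if (sum(liver_region) >= 8 * config$lesion_min_area)
        sm <- seed_lesions(sm, sl, liver_region, stats, config)
    }

    img <- slice_display_intensity(sl, config)
    res <- tryCatch(
      random_walker(img, sm$seeds, params = config$rw, mask = gm),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning("slice ", z, " failed: ", conditionMessage(res))
      diag$failed[z] <- TRUE
      next     # propagation keeps the last good prev_liver
    }
    labels[z, , ] <- res$labels
    diag$segmented[z] <- TRUE
    diag$residual[z] <- res$residual
    diag$seeds_liver[z] <- sum(sm$seeds == 1L)
    diag$seeds_other[z] <- sum(sm$seeds == 2L)
    diag$seeds_lesion[z] <- sum(sm$seeds >= 3L)
    diag$seeds_outside_body[z] <- sum(sm$seeds > 0L & !body_masks[[z]])
    if (keep_probabilities) probs_out[[z]] <- probability_images(res$probs)
    if (!backward) prev_liver <- res$labels == 1L | res$labels >= 3L
    if (z == extent$middle) {
      # one-time recalibration at the biggest liver slice (eroded label,
      # so the boundary halo does not widen the band)
      core <- disc_erode(res$labels == 1L, config$seed_erosion_radius)
      lv <- sl[core]
      if (length(lv) > 10)
        stats <- list(mean = mean(lv), deviation = stats::sd(lv))
    }
  }

  structure(list(
    labels = labels,
    liver_mask = labels == 1L | labels >= 3L,
    extent = extent, lungs = lungs, diagnostics = diag,
    probabilities = probs_out, config = config
  ), class = "liver_segmentation")
}

#' @export
print.liver_segmentation <- function(x, ...) {
  cat(sprintf(
    "<liver_segmentation> dome %d, middle %d, last %d; liver voxels %d\n",
    x$extent$dome, x$extent$middle, x$extent$last, sum(x$liver_mask)))
  invisible(x)
}

# stack a list of matrices into a (slice, row, col) array
#' @keywords internal
simplify2array_slices <- function(slices) {
  arr <- array(0, c(length(slices), dim(slices[[1]])))
  for (z in seq_along(slices)) arr[z, , ] <- slices[[z]]
  arr
}
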
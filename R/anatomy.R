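# Lung detection, liver-dome localization from the caudal lung-area
# decrease, and liver extent (middle/last slice) estimation.

#' Detect the right lung on every slice
#'
#' Lungs are the low-attenuation (air-filled) components inside the body.
#' Per slice, connected components with HU below `lung_hu` are extracted;
#' the right lung is the largest component whose centroid lies in the
#' patient-right half (image-left under radiological display; set
#' `flip_lr = TRUE` for non-standard orientation).
#'
#' @param volume a [ct_volume()] (preprocessed HU values).
#' @param body_masks list of per-slice body masks.
#' @param lung_hu HU threshold below which a pixel counts as lung air.
#' @param min_area smallest component accepted as lung (pixels).
#' @param flip_lr patient-right is image-right instead of image-left.
#' @return object of class `lung_profile`: `area` (per-slice right-lung
#'   pixel counts), `midpoint` (n x 2 matrix of centroids, NA when absent),
#'   `masks` (list of right-lung masks).
#' @export
detect_lungs <- function(volume, body_masks, lung_hu = -400, min_area = 100,
                         flip_lr = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  nz <- dim(volume$voxels)[1]
  stopifnot(length(body_masks) == nz)
  area <- numeric(nz)
  midpoint <- matrix(NA_real_, nz, 2)
  masks <- vector("list", nz)
  for (z in seq_len(nz)) {
    sl <- volume$voxels[z, , ]
    body <- body_masks[[z]]
    masks[[z]] <- matrix(FALSE, nrow(sl), ncol(sl))
    if (!any(body)) next
    cand <- (sl < lung_hu) & body
    if (!any(cand)) next
    lab <- label_components(cand, connectivity = 8)
    st <- component_stats(lab)
    st <- st[st$area >= min_area, , drop = FALSE]
    if (nrow(st) == 0) next
    bidx <- arrayInd(which(body), dim(body))
    bc <- mean(bidx[, 2])
    right <- if (flip_lr) st$centroid_col > bc else st$centroid_col < bc
    st <- st[right, , drop = FALSE]
    if (nrow(st) == 0) next
    st <- st[which.max(st$area), , drop = FALSE]
    masks[[z]] <- lab == st$label
    area[z] <- st$area
    midpoint[z, ] <- c(st$centroid_row, st$centroid_col)
  }
  if (all(area == 0)) stop("no lung found in any slice; cannot initialize")
  structure(list(area = area, midpoint = midpoint, masks = masks),
            class = "lung_profile")
}

#' Locate the liver dome from the right-lung area profile
#'
#' Scanning superior to inferior, the liver dome is the first slice `i + 2`
#' such that the lung area dropped by at least `threshold` (relative) in
#' each of the two preceding consecutive transitions:
#' `area[i+1] <= (1 - threshold) * area[i]` and
#' `area[i+2] <= (1 - threshold) * area[i+1]`, with `area[i] > 0`.
#'
#' @param areas per-slice right-lung pixel counts, superior first.
#' @param threshold relative decrease (default 0.10, i.e. 10 percent).
#' @return slice index of the liver dome (1-based), or `NA_integer_` with a
#'   warning when no qualifying pair of decreases exists.
#' @export
detect_liver_dome <- function(areas, threshold = 0.10) {
  areas <- as.numeric(areas)
  if (sum(areas > 0) < 3) stop("need at least 3 slices with nonzero lung area")
  n <- length(areas)
  for (i in seq_len(max(0, n - 2))) {
    if (areas[i] <= 0) next
    if (areas[i + 1] <= (1 - threshold) * areas[i] &&
        areas[i + 2] <= (1 - threshold) * areas[i + 1])
      return(i + 2L)
  }
  warning("liver dome not found: no two consecutive ", threshold * 100,
          " percent lung-area decreases")
  NA_integer_
}

#' Middle/last liver slice from in-range pixel counts
#'
#' Pure rule applied to per-slice counts of liver-intensity pixels inside
#' the lung-template mask: the middle (biggest) liver slice is the count
#' argmax (earliest on ties); the last slice is the first slice after the
#' middle whose count falls below `last_threshold` (about 100 pixels on
#' standard 512 x 512 CT), or the final slice when none does.
#'
#' @param counts in-range pixel counts for slices `dome, dome+1, ...`.
#' @param dome slice index of the first count.
#' @param last_threshold pixel-count threshold for the last slice.
#' @return list `middle`, `last` (absolute slice indices).
#' @export
liver_extent_from_counts <- function(counts, dome, last_threshold = 100) {
  stopifnot(length(counts) >= 1, dome >= 1)
  middle <- dome + which.max(counts) - 1L      # which.max takes earliest tie
  after <- which(seq_along(counts) + dome - 1L > middle & counts < last_threshold)
  last <- if (length(after)) dome + after[1] - 1L else dome + length(counts) - 1L
  list(middle = as.integer(middle), last = as.integer(last))
}

#' Estimate the liver extent (middle and last slices) and intensity stats
#'
#' The two slices after the liver dome are segmented with the random walker
#' (dome-derived automatic seeds); liver mean and deviation are computed
#' from their liver labels. The right-lung mask of the slice just before
#' the dome then serves as a template masking all remaining slices, and the
#' per-slice count of pixels within `mean +/- k * deviation` drives the
#' middle/last slice rule of [liver_extent_from_counts()].
#'
#' @param volume preprocessed [ct_volume()].
#' @param lungs a [detect_lungs()] result.
#' @param dome liver dome slice index.
#' @param interiors per-slice ribcage interior masks (list over all slices).
#' @param body_masks per-slice body masks.
#' @param config a [pipeline_config()].
#' @return object of class `liver_extent`: `dome`, `middle`, `last`,
#'   `mean`, `deviation`, `template` (the dome-1 right-lung mask),
#'   `calibration_labels` (list of the two seeded segmentations, named by
#'   slice), `counts`.
#' @export
estimate_liver_extent <- function(volume, lungs, dome, interiors, body_masks,
                                  config = pipeline_config()) {
  nz <- dim(volume$voxels)[1]
  if (is.na(dome) || dome + 2 > nz)
    stop("extent estimation failed: dome+2 beyond volume (dome = ", dome, ")")
  if (dome < 2 || sum(lungs$masks[[dome - 1]]) == 0)
    stop("extent estimation failed: no right-lung template on slice before dome")
  template <- lungs$masks[[dome - 1]]

  calib <- list()
  hu_vals <- numeric(0)
  for (z in c(dome + 1L, dome + 2L)) {
    sl <- volume$voxels[z, , ]
    seeds <- place_initial_seeds(sl, template, body_masks[[z]],
                                 graph_mask = interiors[[z]], stats = NULL,
                                 config = config)
    img <- slice_display_intensity(sl, config)
    res <- random_walker(img, seeds$seeds, params = config$rw, mask = interiors[[z]])
    calib[[as.character(z)]] <- res$labels
    # erode the liver label before taking statistics so the partial-volume
    # halo at the boundary does not inflate the deviation
    core <- disc_erode(res$labels == 1L, config$seed_erosion_radius)
    if (!any(core)) core <- res$labels == 1L
    hu_vals <- c(hu_vals, sl[core])
  }
  if (length(hu_vals) < 10)
    stop("extent estimation failed: calibration slices produced no liver region")
  mu <- mean(hu_vals); sdev <- stats::sd(hu_vals)

  zs <- dome:nz
  counts <- vapply(zs, function(z) {
    sl <- volume$voxels[z, , ]
    inband <- template & sl >= mu - config$intensity_k * sdev &
      sl <= mu + config$intensity_k * sdev
    # count contiguous liver-like tissue, not isolated noise pixels
    sum(open_mask(inband, config$seed_open_radius))
  }, numeric(1))
  ext <- liver_extent_from_counts(counts, dome,
                                  last_threshold = config$last_slice_pixel_threshold)
  structure(list(dome = as.integer(dome), middle = ext$middle, last = ext$last,
                 mean = mu, deviation = sdev, template = template,
                 calibration_labels = calib, counts = counts),
            class = "liver_extent")
}

# display intensity used by the walker: windowed [0,1] by default, else
# min-max normalized HU
#' @keywords internal
slice_display_intensity <- function(slice, config) {
  if (isTRUE(config$use_window)) {
    apply_window(slice, config$window)
  } else {
    rng <- range(slice)
    if (diff(rng) == 0) matrix(0, nrow(slice), ncol(slice))
    else (slice - rng[1]) / diff(rng)
  }
}
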
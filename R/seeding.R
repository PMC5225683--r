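# Automatic seed placement: dome-derived initial seeds, slice-to-slice
# propagation from the previous segmentation, and lesion seeding.

#' Deterministic sub-grid sample of a pixel mask
#'
#' Picks pixels of `mask` lying on a regular (row, col) grid, choosing the
#' smallest stride whose sample stays within `cap`. Fully deterministic: no
#' randomness is involved, so repeated runs place identical seeds.
#'
#' @param mask logical matrix of candidate pixels.
#' @param cap maximum number of sampled pixels.
#' @return logical matrix of selected pixels (`sum(.) <= cap`).
#' @export
subgrid_sample <- function(mask, cap = 600) {
  mask <- mask != 0
  n <- sum(mask)
  if (n == 0L || cap <= 0) return(mask & FALSE)
  if (n <= cap) return(mask)
  idx <- which(mask)
  rc <- arrayInd(idx, dim(mask))
  r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
  s <- ceiling(sqrt(n / cap))
  repeat {
    keep <- (rc[, 1] - r0) %% s == 0 & (rc[, 2] - c0) %% s == 0
    if (sum(keep) <= cap) break
    s <- s + 1L
  }
  out <- mask & FALSE
  out[idx[keep]] <- TRUE
  out
}

#' Seed-map container
#' @keywords internal
new_seed_map <- function(seeds) {
  counts <- table(factor(seeds[seeds > 0L], levels = sort(unique(seeds[seeds > 0L]))))
  structure(list(seeds = seeds, counts = as.integer(counts),
                 labels = as.integer(names(counts))), class = "seed_map")
}

#' @export
print.seed_map <- function(x, ...) {
  cat("<seed_map>", sum(x$seeds > 0), "seeds:",
      paste(sprintf("label %d: %d", x$labels, x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Place initial liver and background seeds from the dome geometry
#'
#' Liver seeds: a regular sub-grid inside the eroded right-lung template,
#' restricted to pixels in the liver intensity range (`mean +/- k * sd`
#' once calibrated; before calibration, a generic contrast-enhanced liver
#' HU band). Background ("other organs") seeds: a sub-grid over body pixels
#' outside a dilation of that restricted liver-candidate region. Each side
#' is capped at half the per-slice seed budget and the two sets are
#' disjoint by construction.
#'
#' @param slice 2D HU matrix (preprocessed).
#' @param template right-lung template mask (slice just before the dome).
#' @param body_mask body mask for this slice.
#' @param graph_mask mask of pixels that will enter the walker graph
#'   (ribcage interior); seeds are confined to it.
#' @param stats optional list `mean`, `deviation` of calibrated liver HU;
#'   `NULL` before calibration.
#' @param config a [pipeline_config()].
#' @return a `seed_map` (labels: 1 = liver, 2 = other); all-zero seeds with
#'   attribute `empty_liver = TRUE` when no liver candidate exists.
#' @export
place_initial_seeds <- function(slice, template, body_mask, graph_mask = NULL,
                                stats = NULL, config = pipeline_config()) {
  if (is.null(graph_mask)) graph_mask <- body_mask
  half <- config$max_seeds_per_slice %/% 2L
  cand_region <- disc_erode(template, config$template_erosion_radius)
  band <- liver_band(slice, stats, config)
  liver_cand <- open_mask(cand_region & band & graph_mask & body_mask,
                          config$seed_open_radius)
  # shave the candidate rim so no seed sits on the partial-volume halo
  liver_cand <- disc_erode(liver_cand, 1)
  seeds <- matrix(0L, nrow(slice), ncol(slice))
  if (!any(liver_cand)) {
    sm <- new_seed_map(seeds)
    attr(sm, "empty_liver") <- TRUE
    return(sm)
  }
  liver_seeds <- subgrid_sample(liver_cand, half)
  other_cand <- body_mask & graph_mask &
    !disc_dilate(liver_cand, config$seed_dilation_radius)
  other_seeds <- subgrid_sample(other_cand, half)
  seeds[liver_seeds] <- 1L
  seeds[other_seeds] <- 2L
  new_seed_map(seeds)
}

# morphological opening: removes isolated band-passing noise pixels so no
# hard liver seed lands on a speckle
#' @keywords internal
open_mask <- function(mask, radius) {
  if (radius < 1) return(mask)
  disc_dilate(disc_erode(mask, radius), radius) & mask
}

# liver intensity acceptance band
#' @keywords internal
liver_band <- function(slice, stats, config) {
  if (is.null(stats)) {
    slice >= config$initial_liver_hu[1] & slice <= config$initial_liver_hu[2]
  } else {
    k <- config$intensity_k
    slice >= stats$mean - k * stats$deviation &
      slice <= stats$mean + k * stats$deviation
  }
}

#' Propagate seeds from the previous slice's segmentation
#'
#' Liver seeds: sub-grid over the eroded previous liver region, kept within
#' the calibrated intensity band (so a caudally shrinking liver does not
#' leave liver seeds on soft tissue). Background seeds: sub-grid over body
#' pixels outside a dilation of the previous liver region.
#'
#' @param prev_liver logical mask of the previous slice's liver label.
#' @param slice current 2D HU matrix (preprocessed).
#' @param body_mask,graph_mask as in [place_initial_seeds()].
#' @param stats calibrated liver intensity stats (`mean`, `deviation`).
#' @param config a [pipeline_config()].
#' @return a `seed_map`; attribute `empty_liver = TRUE` when the eroded
#'   previous liver leaves no candidate (caller should fall back to
#'   [place_initial_seeds()]).
#' @export
propagate_seeds <- function(prev_liver, slice, body_mask, graph_mask = NULL,
                            stats = NULL, config = pipeline_config()) {
  if (is.null(graph_mask)) graph_mask <- body_mask
  half <- config$max_seeds_per_slice %/% 2L
  core <- disc_erode(prev_liver, config$seed_erosion_radius)
  liver_cand <- open_mask(core & liver_band(slice, stats, config) &
                            graph_mask & body_mask, config$seed_open_radius)
  seeds <- matrix(0L, nrow(slice), ncol(slice))
  if (!any(liver_cand)) {
    sm <- new_seed_map(seeds)
    attr(sm, "empty_liver") <- TRUE
    return(sm)
  }
  liver_seeds <- subgrid_sample(liver_cand, half)
  other_cand <- body_mask & graph_mask &
    !disc_dilate(prev_liver, config$seed_dilation_radius)
  other_seeds <- subgrid_sample(other_cand, half)
  seeds[liver_seeds] <- 1L
  seeds[other_seeds] <- 2L
  new_seed_map(seeds)
}

#' Add lesion seeds inside the liver candidate region
#'
#' Connected intensity outliers inside the liver region (|HU - mean| >
#' k * deviation, component area at least `lesion_min_area`) receive seeds
#' under the lesion label (3). Lesion seeds share the liver half of the
#' per-slice budget, so the total stays within the cap; liver envelope
#' semantics merge label 3 back into the final liver mask.
#'
#' @param seed_map a `seed_map` to augment.
#' @param slice 2D HU matrix (preprocessed).
#' @param liver_region logical mask of the current liver candidate
#'   (e.g. the dilated previous liver).
#' @param stats calibrated liver intensity stats.
#' @param config a [pipeline_config()].
#' @return the augmented `seed_map`.
#' @export
seed_lesions <- function(seed_map, slice, liver_region, stats,
                         config = pipeline_config()) {
  stopifnot(inherits(seed_map, "seed_map"))
  if (is.null(stats) || !any(liver_region)) return(seed_map)
  k <- config$intensity_k
  # outliers must still look like tissue: air/lung attenuation inside the
  # candidate region is residual lung, not a lesion
  outlier <- liver_region & slice > config$lesion_min_hu &
    abs(slice - stats$mean) > k * stats$deviation
  if (!any(outlier)) return(seed_map)
  lab <- label_components(outlier, connectivity = 8)
  st <- component_stats(lab)
  st <- st[st$area >= config$lesion_min_area, , drop = FALSE]
  if (nrow(st) == 0) return(seed_map)
  # a lesion is enclosed by liver parenchyma: most of the ring around the
  # component must be liver-like, which rejects boundary soft tissue that
  # crept into the liver estimate
  band <- abs(slice - stats$mean) <= k * stats$deviation
  enclosed <- vapply(st$label, function(l) {
    comp <- lab == l
    ring <- disc_dilate(comp, 2) & !comp
    mean(band[ring]) >= config$lesion_enclosure_fraction
  }, logical(1))
  st <- st[enclosed, , drop = FALSE]
  if (nrow(st) == 0) return(seed_map)
  seeds <- seed_map$seeds
  half <- config$max_seeds_per_slice %/% 2L
  budget <- half - sum(seeds == 1L)         # lesions share the liver half
  if (budget <= 0) return(seed_map)
  per_comp <- max(1L, budget %/% nrow(st))
  for (i in seq_len(nrow(st))) {
    comp <- lab == st$label[i]
    # a lesion has a solid core; thin curvilinear outliers are enhancement
    # rim artifacts along the liver boundary, not lesions
    comp_core <- disc_erode(comp, config$lesion_core_radius)
    if (!any(comp_core)) next
    ls <- subgrid_sample(comp_core & seeds == 0L, min(per_comp, budget))
    seeds[ls] <- 3L
    budget <- budget - sum(ls)
    if (budget <= 0) break
  }
  new_seed_map(seeds)
}
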
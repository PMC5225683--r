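# Deterministic synthetic abdominal CT phantom with ground-truth masks.
# The phantom reproduces the geometric/statistical structure the pipeline
# keys on: air background, an elliptical body, two low-attenuation lungs
# whose axial area shrinks caudally with a sharp dome transition, ribs on
# an arc, a near-uniform liver below/within the right lung footprint, and
# optional low-attenuation lesions inside the liver.

#' Phantom specification
#'
#' Geometry is expressed in fractions of the in-plane image size (reference
#' 512 x 512), so the same spec generates consistent anatomy at reduced
#' resolutions. All defaults are the study conditions of the package's test
#' phantom; tissue HU values are plausible clinical means.
#'
#' @param shape volume dimensions `c(slices, rows, cols)`.
#' @param spacing voxel spacing (slice, row, col) in mm.
#' @param dome_slice slice where the liver appears and the two >= 10
#'   percent lung-area drops complete.
#' @param middle_slice widest liver slice.
#' @param last_slice most inferior slice containing liver.
#' @param lesions list of lesions, each `list(dz = slice range, offset =
#'   (row, col) offset from the liver center as a fraction of image size,
#'   radius = fraction of image size)`.
#' @param hu named list of tissue mean HU.
#' @param noise_sd named list of per-tissue Gaussian noise SD (HU).
#' @param rib_count ribs per slice.
#' @param rib_poor_slices slices on which only two ribs are generated
#'   (exercises the neighbor-centroid fallback).
#' @param seed RNG seed for the noise; recorded in the output metadata.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40, 512, 512),
                         spacing = c(2.5, 0.7, 0.7),
                         dome_slice = 12, middle_slice = 20, last_slice = 32,
                         lesions = list(),
                         hu = list(air = -1000, lung = -700, soft = 40,
                                   liver = 100, bone = 700, lesion = 40),
                         noise_sd = list(air = 5, lung = 10, soft = 10,
                                         liver = 15, bone = 30, lesion = 10),
                         rib_count = 10, rib_poor_slices = integer(0),
                         seed = 42) {
  stopifnot(length(shape) == 3, all(shape >= c(8, 32, 32)),
            dome_slice >= 4, dome_slice < middle_slice,
            middle_slice < last_slice, last_slice <= shape[1])
  spec <- structure(list(
    shape = as.integer(shape), spacing = spacing,
    dome_slice = as.integer(dome_slice),
    middle_slice = as.integer(middle_slice),
    last_slice = as.integer(last_slice),
    # body / lung / liver geometry (fractions of image rows, cols)
    body_center = c(0.5, 0.5), body_semi = c(150, 200) / 512,
    lung_right_center = c(210, 170) / 512,
    lung_left_center = c(210, 342) / 512,
    lung_semi = c(80, 62) / 512,
    lung_slow_shrink = 0.98,     # per-slice linear scale before the dome
    lung_drop = 0.885,           # linear scale of the two dome transitions
    lung_tail = 0.7,             # per-slice scale after the dome
    lung_last = as.integer(dome_slice + 1),
    liver_semi = c(56, 44) / 512,
    rib_ring_fraction = 0.92, rib_semi = c(7, 5) / 512,
    rib_count = as.integer(rib_count),
    rib_poor_slices = as.integer(rib_poor_slices),
    lesions = lesions, hu = hu, noise_sd = noise_sd, seed = seed
  ), class = "phantom_spec")
  spec$liver_anchors <- liver_anchor_scales(spec)
  validate_phantom_spec(spec)
  spec
}

# piecewise-linear liver in-plane scale anchors (slice, linear scale)
#' @keywords internal
liver_anchor_scales <- function(spec) {
  d <- spec$dome_slice; m <- spec$middle_slice; l <- spec$last_slice
  a <- rbind(
    c(d, 0.45),
    c(d + round((m - d) * 0.25), 0.75),
    c(m, 1.0),
    c(m + round((l - m) * 0.5), 0.78),
    c(l - 2, 0.38),
    c(l - 1, 0.22),
    c(l, 0.06)
  )
  # compressed geometries can collapse neighboring anchors onto one slice
  a <- a[order(a[, 1]), , drop = FALSE]
  a[!duplicated(a[, 1]), , drop = FALSE]
}

#' @keywords internal
validate_phantom_spec <- function(spec) {
  # every structure must sit inside the body ellipse: sample the structure's
  # boundary and evaluate the body-ellipse functional there
  chk <- function(center, semi, what) {
    th <- seq(0, 2 * pi, length.out = 361)
    br <- center[1] + semi[1] * sin(th) - spec$body_center[1]
    bc <- center[2] + semi[2] * cos(th) - spec$body_center[2]
    if (any((br / spec$body_semi[1])^2 + (bc / spec$body_semi[2])^2 > 1))
      stop("phantom spec invalid: ", what, " extends outside the body")
  }
  chk(spec$lung_right_center, spec$lung_semi, "right lung")
  chk(spec$lung_left_center, spec$lung_semi, "left lung")
  chk(spec$lung_right_center, spec$liver_semi, "liver")
  ring <- spec$rib_ring_fraction * spec$body_semi + spec$rib_semi
  if (any(ring > spec$body_semi))
    stop("phantom spec invalid: rib ring extends outside the body")
  invisible(spec)
}

#' Preset phantom specifications
#'
#' \describe{
#'   \item{healthy}{no lesions.}
#'   \item{single-lesion}{one central lesion.}
#'   \item{multi-lesion}{three lesions, one crossing the liver boundary.}
#'   \item{rib-poor-slice}{healthy anatomy, but one slice carries only two
#'     ribs, exercising the ribcage fallback.}
#'   \item{low-contrast}{liver mean within 20 HU of the surrounding soft
#'     tissue.}
#' }
#'
#' @param preset preset name.
#' @param shape volume dimensions; `c(40, 256, 256)` is the reduced size
#'   used by the package's own tests.
#' @param seed RNG seed.
#' @return a [phantom_spec()].
#' @export
phantom_preset <- function(preset = c("healthy", "single-lesion",
                                      "multi-lesion", "rib-poor-slice",
                                      "low-contrast"),
                           shape = c(40, 512, 512), seed = 42) {
  preset <- tryCatch(match.arg(preset), error = function(e)
    stop("unknown preset '", preset[1], "'; available: healthy, ",
         "single-lesion, multi-lesion, rib-poor-slice, low-contrast"))
  base <- list(shape = shape, seed = seed)
  spec <- switch(preset,
    "healthy" = phantom_spec(shape = shape, seed = seed),
    "single-lesion" = phantom_spec(shape = shape, seed = seed,
      lesions = list(
        list(dz = 17:23, offset = c(-10, -8) / 512, radius = 15 / 512))),
    "multi-lesion" = phantom_spec(shape = shape, seed = seed,
      lesions = list(
        list(dz = 17:23, offset = c(-10, -8) / 512, radius = 15 / 512),
        list(dz = 19:22, offset = c(20, 15) / 512, radius = 10 / 512),
        # centered near the liver edge at the widest slice: crosses the
        # liver boundary (difficult border-lesion scenario)
        list(dz = 18:22, offset = c(0, 44) / 512, radius = 12 / 512))),
    "rib-poor-slice" = phantom_spec(shape = shape, seed = seed,
      rib_poor_slices = 26L),
    "low-contrast" = phantom_spec(shape = shape, seed = seed,
      hu = list(air = -1000, lung = -700, soft = 40, liver = 55,
                bone = 700, lesion = 5))
  )
  attr(spec, "preset") <- preset
  spec
}

# per-slice linear scale of the lung ellipses (0 = absent)
#' @keywords internal
lung_scale <- function(spec, z) {
  if (z > spec$lung_last) return(0)
  s <- spec$lung_slow_shrink^(min(z, spec$dome_slice - 2L) - 1L)
  drops <- max(0L, min(z, spec$dome_slice) - (spec$dome_slice - 2L))
  s <- s * spec$lung_drop^drops
  tail <- max(0L, z - spec$dome_slice)
  s * spec$lung_tail^tail
}

# per-slice linear scale of the liver ellipse (0 = absent)
#' @keywords internal
liver_scale <- function(spec, z) {
  a <- spec$liver_anchors
  if (z < a[1, 1] || z > a[nrow(a), 1]) return(0)
  stats::approx(a[, 1], a[, 2], xout = z)$y
}

#' Generate a synthetic CT phantom volume with ground-truth masks
#'
#' Deterministic given `spec$seed`: voxel HU = tissue mean + Gaussian noise
#' with per-tissue SD. Returns the volume and ground-truth masks for every
#' structure; the liver mask includes lesion voxels (envelope semantics).
#'
#' @param spec a [phantom_spec()].
#' @return list: `volume` ([ct_volume()]), `masks` (3D logical arrays:
#'   `liver`, `lung_right`, `lung_left`, `ribs`, `lesions`, `body`),
#'   `areas` (data.frame of per-slice analytic and rasterized right-lung
#'   and liver areas), `spec` (echo, seed included).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$shape[1]; nr <- spec$shape[2]; nc <- spec$shape[3]
  dim2 <- c(nr, nc)
  px <- function(frac) frac * c(nr, nc)   # fractional -> pixel units

  mean_map <- array(spec$hu$air, spec$shape)
  sd_map <- array(spec$noise_sd$air, spec$shape)
  masks <- list(liver = array(FALSE, spec$shape),
                lung_right = array(FALSE, spec$shape),
                lung_left = array(FALSE, spec$shape),
                ribs = array(FALSE, spec$shape),
                lesions = array(FALSE, spec$shape),
                body = array(FALSE, spec$shape))
  areas <- data.frame(slice = seq_len(nz), lung_right_analytic = 0,
                      lung_right_pixels = 0, liver_analytic = 0,
                      liver_pixels = 0)

  body_c <- px(spec$body_center); body_s <- px(spec$body_semi)
  rl_c <- px(spec$lung_right_center); ll_c <- px(spec$lung_left_center)

  for (z in seq_len(nz)) {
    smean <- matrix(spec$hu$air, nr, nc)
    ssd <- matrix(spec$noise_sd$air, nr, nc)
    body <- ellipse_mask(dim2, body_c, body_s)
    smean[body] <- spec$hu$soft; ssd[body] <- spec$noise_sd$soft

    ls <- lung_scale(spec, z)
    lung_r <- lung_l <- matrix(FALSE, nr, nc)
    if (ls > 0) {
      semi <- px(spec$lung_semi) * ls
      lung_r <- ellipse_mask(dim2, rl_c, semi)
      lung_l <- ellipse_mask(dim2, ll_c, semi)
      areas$lung_right_analytic[z] <- pi * prod(semi)
    }

    vs <- liver_scale(spec, z)
    liver <- matrix(FALSE, nr, nc)
    if (vs > 0) {
      semi <- px(spec$liver_semi) * vs
      liver <- ellipse_mask(dim2, rl_c, semi)
      areas$liver_analytic[z] <- pi * prod(semi)
    }
    # the liver dome displaces lung air as the stack descends
    lung_r <- lung_r & !liver
    lung_l <- lung_l & !liver
    smean[lung_r | lung_l] <- spec$hu$lung
    ssd[lung_r | lung_l] <- spec$noise_sd$lung
    smean[liver] <- spec$hu$liver; ssd[liver] <- spec$noise_sd$liver

    lesion_all <- matrix(FALSE, nr, nc)
    for (le in spec$lesions) {
      if (!(z %in% le$dz)) next
      ctr <- rl_c + px(le$offset)
      rad <- le$radius * max(nr, nc)
      lm <- ellipse_mask(dim2, ctr, c(rad, rad)) & liver  # clipped to liver
      lesion_all <- lesion_all | lm
    }
    smean[lesion_all] <- spec$hu$lesion
    ssd[lesion_all] <- spec$noise_sd$lesion

    ribs <- matrix(FALSE, nr, nc)
    nrib <- spec$rib_count
    keep <- if (z %in% spec$rib_poor_slices) c(1L, 1L + nrib %/% 2L) else seq_len(nrib)
    angles <- seq(0, 2 * pi, length.out = nrib + 1L)[-(nrib + 1L)] + pi / nrib
    ring <- spec$rib_ring_fraction * body_s
    for (i in keep) {
      ctr <- body_c + c(ring[1] * sin(angles[i]), ring[2] * cos(angles[i]))
      ribs <- ribs | ellipse_mask(dim2, ctr, px(spec$rib_semi))
    }
    # ribs own their pixels (body wall overlays in-plane organ ellipses)
    ribs <- ribs & body
    lung_r <- lung_r & !ribs; lung_l <- lung_l & !ribs
    liver <- liver & !ribs; lesion_all <- lesion_all & !ribs
    smean[ribs] <- spec$hu$bone; ssd[ribs] <- spec$noise_sd$bone

    mean_map[z, , ] <- smean
    sd_map[z, , ] <- ssd
    masks$body[z, , ] <- body
    masks$lung_right[z, , ] <- lung_r
    masks$lung_left[z, , ] <- lung_l
    masks$liver[z, , ] <- liver | lesion_all   # envelope includes lesions
    masks$lesions[z, , ] <- lesion_all
    masks$ribs[z, , ] <- ribs
    areas$lung_right_pixels[z] <- sum(lung_r)
    areas$liver_pixels[z] <- sum(liver)
  }

  noise <- with_seed(spec$seed, array(rnorm(prod(spec$shape)), spec$shape))
  vox <- mean_map + noise * sd_map
  list(volume = ct_volume(vox, spacing = spec$spacing),
       masks = masks, areas = areas, spec = spec)
}
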
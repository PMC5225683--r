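# Ribcage masking: rib centroid detection, closed B-spline fit through the
# centroids via De Boor's recursion, and interior masking.

#' Detect rib centroids on one slice
#'
#' High-attenuation connected components inside the body within plausible
#' rib size limits are reduced to their centroids, ordered by polar angle
#' around the body centroid (so the closed spline winds once around the
#' cage). Touching ribs merge into a single component by construction.
#'
#' @param slice 2D HU matrix.
#' @param body_mask logical body mask from [remove_background()].
#' @param bone_hu HU threshold above which a pixel counts as bone.
#' @param area_limits length-2 vector, component pixel-count limits.
#' @return object of class `rib_centroids`: `points` (n x 2 matrix of
#'   (row, col) centroids in angular order), `center` (body centroid),
#'   `sufficient` (TRUE when >= 4 centroids were found).
#' @export
detect_rib_centroids <- function(slice, body_mask, bone_hu = 200,
                                 area_limits = c(20, 2000)) {
  stopifnot(is.matrix(slice), all(dim(slice) == dim(body_mask)))
  if (!any(body_mask)) {
    return(structure(list(points = matrix(numeric(0), 0, 2),
                          center = c(NA_real_, NA_real_), sufficient = FALSE),
                     class = "rib_centroids"))
  }
  bone <- (slice > bone_hu) & body_mask
  lab <- label_components(bone, connectivity = 8)
  st <- component_stats(lab)
  st <- st[st$area >= area_limits[1] & st$area <= area_limits[2], , drop = FALSE]
  bidx <- which(body_mask)
  brc <- arrayInd(bidx, dim(body_mask))
  center <- c(mean(brc[, 1]), mean(brc[, 2]))
  pts <- as.matrix(st[, c("centroid_row", "centroid_col"), drop = FALSE])
  if (nrow(pts) > 0) {
    ang <- atan2(pts[, 1] - center[1], pts[, 2] - center[2])
    pts <- pts[order(ang), , drop = FALSE]
  }
  dimnames(pts) <- NULL
  structure(list(points = pts, center = center, sufficient = nrow(pts) >= 4),
            class = "rib_centroids")
}

#' Evaluate a B-spline curve point by De Boor's recursion
#'
#' Standard triangular De Boor scheme for a spline of degree `p` with knot
#' vector `knots` and control points `ctrl` (one per row), evaluated at
#' parameter `u` inside the valid domain.
#'
#' @param u parameter value.
#' @param degree spline degree p.
#' @param knots non-decreasing knot vector of length `nrow(ctrl) + p + 1`.
#' @param ctrl control-point matrix (n x d).
#' @return length-d point on the curve.
#' @export
deboor_point <- function(u, degree, knots, ctrl) {
  n <- nrow(ctrl)
  stopifnot(length(knots) == n + degree + 1)
  # knot span: largest k with knots[k] <= u < knots[k+1]
  k <- findInterval(u, knots, rightmost.closed = FALSE)
  k <- min(max(k, degree + 1L), n)
  d <- ctrl[(k - degree):k, , drop = FALSE]
  for (r in seq_len(degree)) {
    for (jj in (degree + 1):(r + 1)) {     # work backwards through the row
      i <- k - degree + jj - 1L
      denom <- knots[i + degree - r + 1L] - knots[i]
      alpha <- if (denom == 0) 0 else (u - knots[i]) / denom
      d[jj, ] <- (1 - alpha) * d[jj - 1L, ] + alpha * d[jj, ]
    }
  }
  d[degree + 1L, ]
}

#' Fit a closed B-spline through rib centroids
#'
#' Periodic (closed) B-spline of the given degree through the angularly
#' ordered centroids: the control polygon is wrapped by `degree` points, a
#' uniform knot vector applied, and the curve evaluated by De Boor's
#' recursion at `samples` parameters covering one full period. The interior
#' is rasterized from the sampled closed polyline with the even-odd rule.
#'
#' @param centroids a `rib_centroids` object or an n x 2 matrix of (row,
#'   col) points in angular order (n >= 4).
#' @param degree spline degree (default 3, a cubic).
#' @param samples number of curve samples (>= 360 for masking).
#' @param dim image dimensions for the interior mask; omit to skip
#'   rasterization.
#' @return object of class `ribcage_curve`: `curve` (closed sampled
#'   polyline, first point repeated at the end), `interior` (logical mask or
#'   NULL), `degree`, `control` points.
#' @export
fit_ribcage_spline <- function(centroids, degree = 3, samples = 360, dim = NULL) {
  pts <- if (inherits(centroids, "rib_centroids")) centroids$points else centroids
  pts <- as.matrix(pts)
  if (nrow(pts) < 4) stop("insufficient centroids: need >= 4, got ", nrow(pts))
  if (nrow(unique(pts)) < 3 || qr(sweep(pts, 2, colMeans(pts)))$rank < 2)
    stop("degenerate centroid set: points are collinear")
  n <- nrow(pts)
  ctrl <- rbind(pts, pts[seq_len(degree), , drop = FALSE])  # wrap for periodicity
  m <- nrow(ctrl)
  knots <- 0:(m + degree)                 # uniform; valid domain [degree, m]
  us <- seq(degree, n + degree, length.out = samples + 1L)[-(samples + 1L)]
  curve <- t(vapply(us, deboor_point, numeric(2),
                    degree = degree, knots = knots, ctrl = ctrl))
  curve <- rbind(curve, curve[1, ])       # explicitly closed
  interior <- if (!is.null(dim)) polygon_mask(curve, dim) else NULL
  structure(list(curve = curve, interior = interior, degree = degree,
                 control = ctrl, knots = knots),
            class = "ribcage_curve")
}

#' Mask a slice to the ribcage interior
#'
#' Pixels outside the closed ribcage curve are set to air (-1000 HU),
#' discarding the intercostal muscle bulk and everything outside the cage.
#'
#' @param slice 2D HU matrix.
#' @param curve a [fit_ribcage_spline()] result with an interior mask.
#' @param background_hu fill value for exterior pixels.
#' @return masked HU matrix.
#' @export
mask_inside_ribcage <- function(slice, curve, background_hu = -1000) {
  stopifnot(inherits(curve, "ribcage_curve"), !is.null(curve$interior),
            all(dim(slice) == dim(curve$interior)))
  out <- slice
  out[!curve$interior] <- background_hu
  out
}

#' Pool centroids from neighboring slices (rib-poor fallback)
#'
#' When a slice lacks ribs (or its fitted interior collapses), the rib
#' centroids detected on the previous and next slices are overlaid and the
#' spline refitted from their union.
#'
#' @param neighbors list of `rib_centroids` from adjacent slices.
#' @return a combined `rib_centroids` object (angularly re-ordered).
#' @export
fallback_centroids <- function(neighbors) {
  neighbors <- Filter(function(x) inherits(x, "rib_centroids") && nrow(x$points) > 0,
                      neighbors)
  if (length(neighbors) == 0L)
    return(structure(list(points = matrix(numeric(0), 0, 2),
                          center = c(NA_real_, NA_real_), sufficient = FALSE),
                     class = "rib_centroids"))
  pts <- do.call(rbind, lapply(neighbors, function(x) x$points))
  centers <- do.call(rbind, lapply(neighbors, function(x) x$center))
  center <- colMeans(centers)
  ang <- atan2(pts[, 1] - center[1], pts[, 2] - center[2])
  pts <- pts[order(ang), , drop = FALSE]
  structure(list(points = pts, center = center, sufficient = nrow(pts) >= 4),
            class = "rib_centroids")
}

#' Ribcage interior masks for a slice range
#'
#' Runs centroid detection and spline fitting per slice, applying the
#' neighbor-centroid fallback whenever a slice has too few centroids or its
#' interior area drops steeply (below `steep_fraction` of the previous
#' slice's interior). Slices with no usable centroids anywhere pass through
#' unmasked (interior = whole body mask) with a warning.
#'
#' @param slices list of processed HU matrices.
#' @param body_masks list of body masks, same length.
#' @param config a [pipeline_config()].
#' @return list with `interiors` (logical masks), `fallback_used` (logical
#'   vector), `areas` (interior pixel counts).
#' @export
ribcage_interiors <- function(slices, body_masks, config = pipeline_config()) {
  nz <- length(slices)
  cents <- vector("list", nz)
  for (z in seq_len(nz))
    cents[[z]] <- detect_rib_centroids(slices[[z]], body_masks[[z]],
                                       bone_hu = config$bone_hu_threshold,
                                       area_limits = config$rib_area_limits)
  interiors <- vector("list", nz)
  fallback_used <- logical(nz)
  areas <- numeric(nz)
  dims <- dim(slices[[1]])
  prev_area <- NA_real_
  for (z in seq_len(nz)) {
    cz <- cents[[z]]
    fit_one <- function(cc) {
      if (!cc$sufficient) return(NULL)
      tryCatch(fit_ribcage_spline(cc, samples = config$spline_samples, dim = dims),
               error = function(e) NULL)
    }
    cur <- fit_one(cz)
    need_fallback <- is.null(cur)
    if (!need_fallback && !is.na(prev_area)) {
      a <- sum(cur$interior)
      if (a < config$steep_decrease_fraction * prev_area) need_fallback <- TRUE
    }
    if (need_fallback) {
      nb <- list()
      if (z > 1) nb <- c(nb, list(cents[[z - 1]]))
      if (z < nz) nb <- c(nb, list(cents[[z + 1]]))
      pooled <- fallback_centroids(c(nb, list(cz)))
      alt <- fit_one(pooled)
      if (!is.null(alt)) {
        cur <- alt
        fallback_used[z] <- TRUE
      }
    }
    if (is.null(cur)) {
      warning("slice ", z, ": no usable rib centroids; slice passes unmasked")
      interiors[[z]] <- body_masks[[z]]
    } else {
      interiors[[z]] <- cur$interior & body_masks[[z]]
    }
    areas[z] <- sum(interiors[[z]])
    if (areas[z] > 0) prev_area <- areas[z]
  }
  list(interiors = interiors, fallback_used = fallback_used, areas = areas)
}
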
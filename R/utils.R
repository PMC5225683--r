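#' @import methods
#' @importFrom stats median rnorm
#' @importFrom utils head tail
NULL

#' Shift a matrix by a pixel offset
#'
#' Returns a matrix of the same shape whose entry at (r, c) holds the value of
#' `x` at (r + dr, c + dc), with out-of-bounds positions set to `fill`. Used
#' to vectorize neighborhood operations (median network, non-maximum
#' suppression, graph edge construction).
#'
#' @param x numeric matrix.
#' @param dr,dc integer row/column offset.
#' @param fill value for positions whose source falls outside `x`.
#' @return matrix of `dim(x)`.
#' @keywords internal
shift_mat <- function(x, dr, dc, fill = 0) {
  m <- nrow(x); n <- ncol(x)
  out <- matrix(fill, m, n)
  r1 <- max(1L, 1L - dr); r2 <- min(m, m - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(n, n - dc)
  if (r1 > r2 || c1 > c2) return(out)
  out[r1:r2, c1:c2] <- x[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  out
}

#' Label connected components of a binary mask
#'
#' Connected-component labelling with a selectable neighborhood. EBImage's
#' `bwlabel` is 4-connected; region selection in this pipeline is defined with
#' 8-connectivity, so components are derived from the pixel adjacency graph.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   raster (column-major) order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  mask <- mask != 0
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nid <- matrix(0L, nrow(mask), ncol(mask))
  nid[idx] <- seq_along(idx)
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- lapply(offsets, function(off) {
    nb <- shift_mat(nid, off[1], off[2], fill = 0L)
    keep <- which(nid > 0L & nb > 0L)
    cbind(nid[keep], nb[keep])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber so components appear in raster order of their first pixel
  first <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first]] <- seq_len(sum(first))
  lab[idx] <- renum[memb]
  lab
}

#' Pixel statistics of labelled components
#'
#' @param lab integer label matrix from [label_components()].
#' @return data.frame with one row per component: `label`, `area`,
#'   `centroid_row`, `centroid_col`.
#' @keywords internal
component_stats <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), area = integer(),
                      centroid_row = numeric(), centroid_col = numeric()))
  rc <- arrayInd(idx, dim(lab))
  l <- lab[idx]
  area <- tabulate(l)
  data.frame(
    label = seq_along(area),
    area = area,
    centroid_row = as.numeric(tapply(rc[, 1], l, mean)),
    centroid_col = as.numeric(tapply(rc[, 2], l, mean))
  )
}

#' Binary erosion / dilation with a disc element
#' @keywords internal
disc_erode <- function(mask, radius) {
  if (radius < 1) return(mask != 0)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::erode(mask != 0, k) > 0
}

#' @rdname disc_erode
#' @keywords internal
disc_dilate <- function(mask, radius) {
  if (radius < 1) return(mask != 0)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::dilate(mask != 0, k) > 0
}

#' Rasterize a closed polygon into a pixel mask (even-odd rule)
#'
#' Pixel centers are tested with the crossing-number (even-odd) rule against
#' the closed polyline `poly`.
#'
#' @param poly two-column matrix of (row, col) vertices; closed implicitly
#'   (last vertex joined to the first).
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return logical matrix, TRUE inside the polygon.
#' @export
polygon_mask <- function(poly, dim) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, length(dim) == 2)
  m <- dim[1]; n <- dim[2]
  # drop duplicated closing vertex if present
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  nv <- nrow(poly)
  if (nv < 3) return(matrix(FALSE, m, n))
  r1 <- max(1L, floor(min(poly[, 1]))); r2 <- min(m, ceiling(max(poly[, 1])))
  c1 <- max(1L, floor(min(poly[, 2]))); c2 <- min(n, ceiling(max(poly[, 2])))
  out <- matrix(FALSE, m, n)
  if (r1 > r2 || c1 > c2) return(out)
  pr <- rep(r1:r2, times = c2 - c1 + 1L)           # point rows (y)
  pc <- rep(c1:c2, each = r2 - r1 + 1L)            # point cols (x)
  inside <- logical(length(pr))
  j <- nv
  for (i in seq_len(nv)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- (yi > pr) != (yj > pr)
    if (any(crosses)) {
      xint <- xi + (pr[crosses] - yi) * (xj - xi) / (yj - yi)
      flip <- pc[crosses] < xint
      inside[crosses][flip] <- !inside[crosses][flip]
    }
    j <- i
  }
  out[cbind(pr[inside], pc[inside])] <- TRUE
  out
}

#' Evaluate code with a temporary RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Filled-ellipse pixel mask
#'
#' @param dim `c(nrow, ncol)`.
#' @param center `(row, col)` center.
#' @param semi `(row, col)` semi-axes in pixels.
#' @keywords internal
ellipse_mask <- function(dim, center, semi) {
  if (any(semi <= 0)) return(matrix(FALSE, dim[1], dim[2]))
  r <- ((seq_len(dim[1]) - center[1]) / semi[1])^2
  c <- ((seq_len(dim[2]) - center[2]) / semi[2])^2
  outer(r, c, `+`) <= 1
}
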
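# Per-slice preprocessing: background/table removal via Canny-bounded body
# detection, morphological edge enhancement, and 3x3 median denoising.

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis thresholding. When `high` is `NULL` the high threshold is
#' derived from Otsu's method on the gradient-magnitude histogram and the
#' low threshold set to `low_frac * high`.
#'
#' @param x numeric matrix (any intensity scale).
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @param high optional high hysteresis threshold on gradient magnitude.
#' @param low_frac low threshold as a fraction of the high threshold.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(x, sigma = 1.0, high = NULL, low_frac = 0.4) {
  stopifnot(is.matrix(x), nrow(x) >= 3, ncol(x) >= 3)
  xs <- gaussian_blur(x, sigma)
  gx <- conv3(xs, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))   # d/dcol
  gy <- conv3(xs, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3))   # d/drow
  mag <- sqrt(gx^2 + gy^2)
  # tolerance relative to the intensity scale: convolution round-off on a
  # constant slice must not masquerade as gradient
  mag[mag <= 1e-9 * max(1, max(abs(xs)))] <- 0
  if (all(mag == 0)) return(matrix(FALSE, nrow(x), ncol(x)))
  # non-maximum suppression: quantize gradient direction to 4 sectors
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  nb <- list(
    `0` = list(c(0L, 1L), c(0L, -1L)),    # horizontal gradient -> cols
    `1` = list(c(1L, 1L), c(-1L, -1L)),
    `2` = list(c(1L, 0L), c(-1L, 0L)),    # vertical gradient -> rows
    `3` = list(c(1L, -1L), c(-1L, 1L))
  )
  keep <- matrix(FALSE, nrow(x), ncol(x))
  for (s in 0:3) {
    o <- nb[[as.character(s)]]
    m1 <- shift_mat(mag, o[[1]][1], o[[1]][2], fill = 0)
    m2 <- shift_mat(mag, o[[2]][1], o[[2]][2], fill = 0)
    keep <- keep | (sector == s & mag >= m1 & mag >= m2)
  }
  nms <- mag * keep
  if (is.null(high)) {
    mx <- max(nms)
    if (mx == 0) return(matrix(FALSE, nrow(x), ncol(x)))
    nz <- nms[nms > 0] / mx
    high <- tryCatch(EBImage::otsu(matrix(nz, nrow = 1), range = c(0, 1)) * mx,
                     error = function(e) 0.2 * mx)
  }
  low <- low_frac * high
  strong <- nms >= high
  weak <- nms >= low
  if (!any(strong)) return(strong)
  lab <- label_components(weak, connectivity = 8)
  keep_labels <- unique(lab[strong])
  lab %in% setdiff(keep_labels, 0L) & weak
}

# separable Gaussian convolution with replicate padding
#' @keywords internal
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h):h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pass <- function(m, along_rows) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      d <- i - h - 1L
      out <- out + k[i] * (if (along_rows) shift_replicate(m, d, 0L)
                           else shift_replicate(m, 0L, d))
    }
    out
  }
  pass(pass(x, TRUE), FALSE)
}

# shift with replicate (clamped) border
#' @keywords internal
shift_replicate <- function(x, dr, dc) {
  m <- nrow(x); n <- ncol(x)
  ri <- pmin(pmax(seq_len(m) + dr, 1L), m)
  ci <- pmin(pmax(seq_len(n) + dc, 1L), n)
  x[ri, ci, drop = FALSE]
}

# 3x3 convolution (correlation) with replicate border
#' @keywords internal
conv3 <- function(x, K) {
  out <- matrix(0, nrow(x), ncol(x))
  for (dr in -1:1) for (dc in -1:1) {
    w <- K[dr + 2, dc + 2]
    if (w != 0) out <- out + w * shift_replicate(x, dr, dc)
  }
  out
}

#' Remove the imaging table and background from a CT slice
#'
#' Body boundaries are found with a Canny edge detector; edge gaps are
#' closed morphologically, interior holes filled, and the largest
#' 8-connected filled region kept as the body. Everything outside the body
#' is set to air (-1000 HU). A slice with no detectable body (e.g. pure
#' air) yields an all-zero mask rather than an error, so series processing
#' continues.
#'
#' @param slice 2D HU matrix.
#' @param sigma Canny smoothing sigma.
#' @param close_radius radius of the closing applied to the edge map before
#'   hole filling.
#' @param background_hu fill value for non-body pixels.
#' @return list with `mask` (logical body mask, one filled component) and
#'   `slice` (HU matrix with non-body pixels set to `background_hu`).
#' @export
remove_background <- function(slice, sigma = 1.0, close_radius = 2,
                              background_hu = -1000) {
  stopifnot(is.matrix(slice), length(slice) > 0)
  edges <- canny_edges(slice, sigma = sigma)
  out <- slice
  if (!any(edges)) {
    out[] <- background_hu
    return(list(mask = matrix(FALSE, nrow(slice), ncol(slice)), slice = out))
  }
  closed <- disc_dilate(edges, close_radius)
  filled <- EBImage::fillHull(closed) > 0
  filled <- disc_erode(filled, close_radius)   # undo the dilation bias
  lab <- label_components(filled, connectivity = 8)
  if (max(lab) == 0L) {
    out[] <- background_hu
    return(list(mask = matrix(FALSE, nrow(slice), ncol(slice)), slice = out))
  }
  areas <- tabulate(lab[lab > 0L])
  body <- lab == which.max(areas)
  body <- EBImage::fillHull(body) > 0
  out[!body] <- background_hu
  list(mask = body, slice = out)
}

#' Morphological edge enhancement (top-hat plus, bottom-hat minus)
#'
#' Adds the white top-hat (small bright detail) to the slice and subtracts
#' the black bottom-hat (small dark detail), sharpening edges before
#' segmentation: `slice + tophat(slice) - bottomhat(slice)` under a disc
#' structuring element.
#'
#' @param slice 2D numeric matrix.
#' @param radius disc element radius in pixels (>= 1).
#' @return enhanced matrix, same shape.
#' @export
enhance_edges <- function(slice, radius = 5) {
  stopifnot(is.matrix(slice), radius >= 1)
  k <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  # EBImage grayscale morphology expects intensities roughly in [0,1];
  # rescale, operate, and map back so HU inputs are handled exactly.
  lo <- min(slice); hi <- max(slice)
  if (hi == lo) return(slice)   # constant slice: both hats are zero
  s01 <- (slice - lo) / (hi - lo)
  th <- EBImage::whiteTopHat(s01, k)
  bh <- EBImage::blackTopHat(s01, k)
  slice + (th - bh) * (hi - lo)
}

#' 3x3 median filter with in-bounds border handling
#'
#' Replaces each pixel by the median of its 3x3 neighborhood; border pixels
#' take the median of the in-bounds part of the neighborhood. Interior
#' pixels are computed with a vectorized compare-exchange sorting network,
#' so the filter is exact (no histogram approximation) and fast.
#'
#' @param slice 2D numeric matrix, at least 3x3.
#' @return filtered matrix, same shape.
#' @export
denoise_median <- function(slice) {
  stopifnot(is.matrix(slice), nrow(slice) >= 3, ncol(slice) >= 3)
  m <- nrow(slice); n <- ncol(slice)
  inner <- slice[2:(m - 1), 2:(n - 1), drop = FALSE]
  # nine shifted views of the interior
  v <- vector("list", 9L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    v[[k]] <- slice[(2:(m - 1)) + dr, (2:(n - 1)) + dc, drop = FALSE]
  }
  # data-oblivious insertion sort on the 9 planes (compare-exchange network)
  for (i in 2:9) {
    for (j in i:2) {
      a <- v[[j - 1L]]; b <- v[[j]]
      v[[j - 1L]] <- pmin(a, b)
      v[[j]] <- pmax(a, b)
    }
  }
  out <- slice
  out[2:(m - 1), 2:(n - 1)] <- v[[5L]]
  # border ring: direct median over the in-bounds neighborhood
  border <- rbind(
    cbind(1L, seq_len(n)), cbind(m, seq_len(n)),
    cbind(2:(m - 1), 1L), cbind(2:(m - 1), n)
  )
  for (p in seq_len(nrow(border))) {
    r <- border[p, 1]; c <- border[p, 2]
    rr <- max(1L, r - 1L):min(m, r + 1L)
    cc <- max(1L, c - 1L):min(n, c + 1L)
    out[r, c] <- median(slice[rr, cc])
  }
  out
}

#' Preprocess one slice: background removal, enhancement, median denoising
#'
#' The stage order follows the pipeline definition: table/background
#' removal, then top-hat/bottom-hat enhancement, then the 3x3 median.
#'
#' @param slice 2D HU matrix.
#' @param config a [pipeline_config()].
#' @return list `mask` (body mask), `slice` (processed HU matrix).
#' @export
preprocess_slice <- function(slice, config = pipeline_config()) {
  bg <- remove_background(slice, sigma = config$canny_sigma,
                          background_hu = config$background_hu)
  if (!any(bg$mask)) return(bg)
  enh <- enhance_edges(bg$slice, radius = config$hat_radius)
  enh[!bg$mask] <- config$background_hu
  med <- denoise_median(enh)
  med[!bg$mask] <- config$background_hu
  list(mask = bg$mask, slice = med)
}
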
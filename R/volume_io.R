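#' CT volume container
#'
#' A `ct_volume` holds an ordered axial stack of CT slices in Hounsfield
#' units (HU), indexed `[slice, row, col]` with slice 1 the most superior,
#' together with the voxel spacing in millimetres.
#'
#' @param voxels 3D numeric array `(slice, row, col)` of HU intensities.
#' @param spacing numeric length-3: (slice thickness, row spacing, col
#'   spacing) in mm; all strictly positive.
#' @param superior_first logical; TRUE once slices are ordered
#'   superior-to-inferior (the canonical order; loaders re-sort).
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), superior_first = TRUE) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (slice, row, col)")
  structure(
    list(voxels = voxels, spacing = spacing,
         superior_first = isTRUE(superior_first)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d slices of %d x %d, spacing %.3g x %.3g x %.3g mm, HU range [%s, %s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              format(min(x$voxels)), format(max(x$voxels))))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' Extract one axial slice as a (row, col) matrix
#' @param volume a [ct_volume()].
#' @param z slice index (1 = most superior).
#' @export
get_slice <- function(volume, z) {
  stopifnot(inherits(volume, "ct_volume"))
  volume$voxels[z, , ]
}

#' Convert stored DICOM pixel values to Hounsfield units
#'
#' HU = slope * stored + intercept, the linear rescale every CT series
#' declares in its metadata.
#'
#' @param stored numeric stored pixel values.
#' @param slope,intercept rescale slope and intercept.
#' @export
#' @examples
#' stored_to_hu(1024, slope = 1, intercept = -1024)  # 0 HU
stored_to_hu <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Load a CT series into a canonical HU volume
#'
#' Reads a NIfTI volume (`.nii` / `.nii.gz`) into a [ct_volume()]: axial
#' slices along the canonical first axis, superior-to-inferior, spacing
#' taken from the header. Set `slice_order = "inferior-first"` for files
#' stored foot-to-head; slices are then reversed on load.
#'
#' DICOM directory input is not supported by this build; supply the series
#' converted to NIfTI.
#'
#' @param path file path.
#' @param format `"nifti"` (default, also auto-detected from the extension)
#'   or `"dicom-dir"` (rejected with an informative error).
#' @param slice_order `"superior-first"` or `"inferior-first"` describing
#'   the on-disk slice order.
#' @return a [ct_volume()].
#' @export
load_ct_series <- function(path, format = c("nifti", "dicom-dir"),
                           slice_order = c("superior-first", "inferior-first")) {
  format <- match.arg(format)
  slice_order <- match.arg(slice_order)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "dicom-dir" || dir.exists(path))
    stop("DICOM directory input is not supported; convert the series to NIfTI ",
         "(e.g. with dcm2niix) and load the .nii/.nii.gz file")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3)
    stop("expected a 3D volume, got array of dim ", paste(dim(arr), collapse = "x"))
  pd <- attr(img, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(img)
  pd <- abs(as.numeric(pd[seq_len(3)]))
  pd[pd == 0 | !is.finite(pd)] <- 1
  # NIfTI stores (x=col, y=row, z=slice); canonical order is (slice, row, col)
  vox <- aperm(arr, c(3, 2, 1))
  if (slice_order == "inferior-first")
    vox <- vox[rev(seq_len(dim(vox)[1])), , , drop = FALSE]
  ct_volume(vox, spacing = c(pd[3], pd[2], pd[1]), superior_first = TRUE)
}

#' Window settings for CT display
#'
#' @param level window level (center) in HU.
#' @param width window width in HU; must be positive.
#' @export
window_settings <- function(level = 40, width = 400) {
  stopifnot(is.numeric(level), is.numeric(width))
  if (width <= 0) stop("window width must be > 0")
  structure(list(level = level, width = width), class = "window_settings")
}

#' Apply display windowing to a volume or slice
#'
#' Maps HU to display intensities in \[0, 1\]: values at or below
#' `level - width/2` map to 0, values at or above `level + width/2` map to 1,
#' with a linear ramp in between. The default (level 40 HU, width 400 HU) is
#' the common abdominal soft-tissue window.
#'
#' @param x a [ct_volume()], or a numeric array/matrix of HU values.
#' @param window a [window_settings()].
#' @return array of the same shape with values in \[0, 1\].
#' @export
apply_window <- function(x, window = window_settings()) {
  stopifnot(inherits(window, "window_settings"))
  v <- if (inherits(x, "ct_volume")) x$voxels else x
  lo <- window$level - window$width / 2
  out <- (v - lo) / window$width
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Write a mask or label volume as NIfTI
#'
#' Writes an integer label volume with the geometry of a reference
#' [ct_volume()]; the canonical (slice, row, col) order is permuted back to
#' NIfTI (x, y, z) so a round-trip through [load_ct_series()] reproduces the
#' array bit-exactly.
#'
#' @param mask 3D integer/logical array, same shape as `reference`.
#' @param reference [ct_volume()] supplying spacing/geometry.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"uint8"` fits label maps.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, reference, path, datatype = "uint8") {
  stopifnot(inherits(reference, "ct_volume"))
  mask <- if (is.logical(mask)) array(as.integer(mask), dim(mask)) else mask
  if (!identical(dim(mask), dim(reference$voxels)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match reference shape ",
         paste(dim(reference$voxels), collapse = "x"))
  arr <- aperm(mask, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  sp <- reference$spacing
  RNifti::pixdim(img) <- c(sp[3], sp[2], sp[1])
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a HU volume as NIfTI (phantom output, probability maps)
#' @inheritParams write_mask
#' @param volume [ct_volume()] or 3D array.
#' @param spacing used when `volume` is a bare array.
#' @export
write_volume <- function(volume, path, spacing = c(1, 1, 1),
                         datatype = "float") {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$voxels; sp <- volume$spacing
  } else {
    arr <- volume; sp <- spacing
  }
  img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
  RNifti::pixdim(img) <- c(sp[3], sp[2], sp[1])
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a label/mask volume written by [write_mask()]
#' @param path NIfTI file.
#' @return 3D integer array in canonical (slice, row, col) order.
#' @export
read_mask <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  storage.mode(arr) <- "integer"
  aperm(arr, c(3, 2, 1))
}
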
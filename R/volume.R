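#' @useDynLib ctvseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ctv_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ctv_error")))
}

#' Construct a volume
#'
#' A volume is a 3-D scalar array together with its voxel spacing (mm) and
#' the world coordinate of voxel `(1,1,1)` (the origin).  Arrays are held in
#' the package's canonical orientation: axis 1 increases left to right,
#' axis 2 anterior to posterior, axis 3 inferior to superior, so that axial
#' slices are `data[, , k]` stacked along the superior-inferior direction.
#'
#' @param data 3-D numeric array.
#' @param spacing numeric(3), voxel size in mm; all components positive.
#' @param origin numeric(3), world position (mm) of the centre of the first
#'   voxel.
#' @return An object of class `ctv_volume`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    ctv_stop("ctv_error_format", "volume data must have exactly 3 axes")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    ctv_stop("ctv_error_parameter", "spacing must be 3 positive values")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ctv_volume")
}

#' Construct a binary label map
#'
#' A label map shares the grid (shape, spacing, origin) of its volume and
#' holds values in \{0, 1\}.
#'
#' @param data 3-D array coercible to 0/1 integers.
#' @inheritParams as_volume
#' @return An object of class `ctv_labelmap` (also a `ctv_volume`).
#' @export
as_labelmap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    ctv_stop("ctv_error_format", "label map values must be 0 or 1")
  v <- as_volume(array(as.integer(data), dim(data)), spacing, origin)
  class(v) <- c("ctv_labelmap", class(v))
  v
}

is_labelmap <- function(x) inherits(x, "ctv_labelmap")

#' @export
print.ctv_volume <- function(x, ...) {
  kind <- if (is_labelmap(x)) "label map" else "volume"
  cat(sprintf("<ctv %s> %s voxels @ (%s) mm, origin (%s) mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = ", "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ctv_volume <- function(x) dim(x$data)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Define a region of interest
#'
#' An ROI is a target grid: a world centre, voxel counts and voxel spacing.
#' Its world extent is `size_vox * spacing_mm`, centred at `center_mm`;
#' the grid origin (centre of the first voxel) is therefore
#' `center_mm - (size_vox - 1) / 2 * spacing_mm`.
#'
#' @param center_mm numeric(3) world centre.
#' @param size_vox integer(3) voxel counts, all at least 1.
#' @param spacing_mm numeric(3) voxel size in mm.
#' @return An object of class `ctv_roi`.
#' @export
roi_spec <- function(center_mm, size_vox, spacing_mm) {
  size_vox <- as.integer(size_vox)
  if (any(size_vox < 1L))
    ctv_stop("ctv_error_parameter", "ROI size_vox must all be >= 1")
  if (any(spacing_mm <= 0))
    ctv_stop("ctv_error_parameter", "ROI spacing must be positive")
  structure(list(center_mm = as.numeric(center_mm), size_vox = size_vox,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "ctv_roi")
}

roi_origin <- function(roi) roi$center_mm - (roi$size_vox - 1) / 2 * roi$spacing_mm

#' ROI matching a volume's own grid
#' @param volume a `ctv_volume`.
#' @return A `ctv_roi` reproducing the volume's grid exactly.
#' @export
roi_of_volume <- function(volume) {
  d <- dim(volume$data)
  roi_spec(volume$origin + (d - 1) / 2 * volume$spacing, d, volume$spacing)
}

#' World coordinates of the geometric centre of a volume
#' @param volume a `ctv_volume`.
#' @return numeric(3) world point in mm.
#' @export
volume_center <- function(volume) {
  volume$origin + (dim(volume$data) - 1) / 2 * volume$spacing
}

#' Resample a volume onto an ROI grid
#'
#' Interpolates the volume at the voxel centres of the ROI grid.  Sample
#' points outside the source extent are filled with 0.  Label maps must use
#' nearest-neighbour mode so the output stays binary.
#'
#' @param volume a `ctv_volume` or `ctv_labelmap`.
#' @param roi a `ctv_roi` target grid.
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @return A volume (or label map) on the ROI grid.
#' @export
resample <- function(volume, roi, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (is_labelmap(volume) && mode != "nearest")
    ctv_stop("ctv_error_parameter", "label maps must be resampled with mode = 'nearest'")
  org <- roi_origin(roi)
  out <- resample_grid(as.numeric(volume$data), dim(volume$data),
                       volume$spacing, volume$origin,
                       roi$size_vox, roi$spacing_mm, org,
                       mode == "nearest")
  dim(out) <- roi$size_vox
  if (is_labelmap(volume)) as_labelmap(out, roi$spacing_mm, org)
  else as_volume(out, roi$spacing_mm, org)
}
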
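#' Extract overlapping 3-D blocks from an ROI volume
#'
#' Slides a 128 x 128 x `depth_b` window along the superior-inferior axis
#' only, with the given stride, producing
#' `floor((D - depth_b) / stride) + 1` blocks for ROI depth `D >= depth_b`.
#' A shallower ROI is reflect-padded along SI up to `depth_b` and yields a
#' single block; the padded slices are flagged so fusion can exclude them.
#'
#' @param roi_volume a `ctv_volume` on the ROI grid.
#' @param depth_b block depth in slices (default 15).
#' @param stride SI step between consecutive blocks (default 1).
#' @return A `ctv_blockset`: `blocks` (list of 3-D arrays), `si_starts`
#'   (1-based start slice of each block), `depth_b`, `roi_shape`,
#'   `valid_z` (logical per ROI slice, `FALSE` for reflect padding).
#' @export
extract_blocks <- function(roi_volume, depth_b = 15L, stride = 1L) {
  if (stride < 1L || depth_b < 1L)
    ctv_stop("ctv_error_parameter", "depth_b and stride must be >= 1")
  x <- roi_volume$data
  D <- dim(x)[3]
  valid_z <- rep(TRUE, max(D, depth_b))
  if (D < depth_b) {
    pad <- depth_b - D
    mirror <- if (D > 1L) rev(seq_len(D - 1L)) else 1L
    refl <- rep(mirror, length.out = pad)
    x <- array(c(x, x[, , refl, drop = FALSE]), c(dim(x)[1:2], depth_b))
    valid_z <- c(rep(TRUE, D), rep(FALSE, pad))
    D <- depth_b
  }
  starts <- seq(1L, D - depth_b + 1L, by = stride)
  blocks <- lapply(starts, function(s) x[, , s:(s + depth_b - 1L), drop = FALSE])
  structure(list(blocks = blocks, si_starts = as.integer(starts),
                 depth_b = as.integer(depth_b), stride = as.integer(stride),
                 roi_shape = dim(x), valid_z = valid_z,
                 spacing = roi_volume$spacing, origin = roi_volume$origin),
            class = "ctv_blockset")
}

#' @export
length.ctv_blockset <- function(x) length(x$blocks)

#' Predict and threshold every block
#'
#' Each block is predicted independently (order preserved) and thresholded
#' to a binary map.
#'
#' @param model a 3-D `ctv_model` matching the block shape.
#' @param blocks a `ctv_blockset`.
#' @param t probability threshold (default 0.5).
#' @param dropout_active keep dropout on (Monte-Carlo sampling).
#' @return List of binary arrays, one per block.
#' @export
predict_blocks <- function(model, blocks, t = 0.5, dropout_active = FALSE) {
  lapply(blocks$blocks, function(b) {
    p <- predict_map(model, b, dropout_active = dropout_active)
    threshold_map(p, t)
  })
}

fuse_counts <- function(predictions, si_starts, roi_shape, depth_b) {
  votes <- array(0L, roi_shape)
  cover <- array(0L, roi_shape)
  for (i in seq_along(predictions)) {
    zz <- si_starts[i]:(si_starts[i] + depth_b - 1L)
    votes[, , zz] <- votes[, , zz] + predictions[[i]]
    cover[, , zz] <- cover[, , zz] + 1L
  }
  list(votes = votes, cover = cover)
}

fusion_grid <- function(blocks) list(spacing = blocks$spacing, origin = blocks$origin)

apply_valid <- function(mask, valid_z) {
  if (!all(valid_z)) mask[, , !valid_z] <- 0L
  mask
}

#' Union fusion of block predictions
#'
#' A voxel is CTV iff at least one covering block predicted it CTV.
#' Reflect-padded slices are excluded from the output.
#'
#' @param blocks the `ctv_blockset` the predictions came from.
#' @param predictions list of binary arrays from [predict_blocks()].
#' @return CTV label map on the ROI grid.
#' @export
fuse_union <- function(blocks, predictions) {
  if (length(predictions) == 0) ctv_stop("ctv_error_parameter", "no predictions to fuse")
  fc <- fuse_counts(predictions, blocks$si_starts, blocks$roi_shape, blocks$depth_b)
  out <- apply_valid(array(as.integer(fc$votes > 0L), blocks$roi_shape), blocks$valid_z)
  g <- fusion_grid(blocks)
  as_labelmap(out[, , seq_along(blocks$valid_z)[blocks$valid_z], drop = FALSE],
              g$spacing, g$origin)
}

#' Majority-vote fusion of block predictions
#'
#' A voxel is CTV iff strictly more than half of the blocks covering it
#' predicted CTV; the cover count varies near the SI edges and padded
#' slices are excluded.
#'
#' @inheritParams fuse_union
#' @return CTV label map on the ROI grid.
#' @export
fuse_majority <- function(blocks, predictions) {
  if (length(predictions) == 0) ctv_stop("ctv_error_parameter", "no predictions to fuse")
  fc <- fuse_counts(predictions, blocks$si_starts, blocks$roi_shape, blocks$depth_b)
  out <- apply_valid(array(as.integer(fc$votes * 2L > fc$cover), blocks$roi_shape),
                     blocks$valid_z)
  g <- fusion_grid(blocks)
  as_labelmap(out[, , seq_along(blocks$valid_z)[blocks$valid_z], drop = FALSE],
              g$spacing, g$origin)
}

#' Resample an ROI mask to the native grid
#'
#' Nearest-neighbour resampling of the fused ROI mask onto the grid of the
#' native volume; voxels outside the ROI footprint become 0.
#'
#' @param roi_mask label map on the ROI grid.
#' @param native the native `ctv_volume` whose grid to map onto.
#' @return Label map on the native grid.
#' @export
to_native <- function(roi_mask, native) {
  resample(roi_mask, roi_of_volume(native), "nearest")
}
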
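#' Centroid of a label map
#'
#' Unweighted mean of the world coordinates of the foreground voxel
#' centres.
#'
#' @param mask a non-empty `ctv_labelmap`.
#' @return numeric(3) world point in mm.
#' @export
centroid <- function(mask) {
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0)
    ctv_stop("ctv_error_value", "centroid of an empty mask is undefined")
  unname(mask$origin + (colMeans(idx) - 1) * mask$spacing)
}

#' Estimate the CTV centre from the bladder centroid
#'
#' The CTV centre is taken `offset_mm` posterior to the bladder centroid
#' (default 39 mm, the population mean offset), leaving the left-right and
#' superior-inferior components unchanged.
#'
#' @param bladder_centroid numeric(3) world point (mm).
#' @param offset_mm posterior offset in mm (default 39).
#' @return numeric(3) estimated CTV centre.
#' @export
estimate_ctv_center <- function(bladder_centroid, offset_mm = 39) {
  bladder_centroid + c(0, offset_mm, 0)
}

#' Keep the largest connected component
#'
#' 26-connectivity in 3-D (8-connectivity for single-slice masks).  Ties
#' resolve to the first-labelled component.
#'
#' @param mask a `ctv_labelmap`.
#' @return A label map containing only the largest component (unchanged if
#'   empty).
#' @export
largest_component <- function(mask) {
  lab <- cc_label(as.integer(mask$data), dim(mask$data))
  if (max(lab) <= 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  as_labelmap(array(as.integer(lab == keep), dim(mask$data)),
              mask$spacing, mask$origin)
}

#' Remove small 2-D components
#'
#' Morphological cleaning of a detection slice: every 8-connected
#' component with fewer than `min_area_px` pixels is removed.
#'
#' @param mask2d binary matrix.
#' @param min_area_px minimum component area in pixels (default 50).
#' @return Cleaned binary matrix.
#' @export
clean_detection <- function(mask2d, min_area_px = 50L) {
  if (min_area_px < 0) ctv_stop("ctv_error_parameter", "min_area_px must be >= 0")
  if (min_area_px == 0 || !any(mask2d > 0)) return(mask2d)
  d <- dim(mask2d)
  lab <- cc_label(as.integer(mask2d), c(d, 1L))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  out <- matrix(as.integer(matrix(lab, d[1]) %in% keep & mask2d > 0), d[1], d[2])
  out
}

#' Segment the bladder (stage 1)
#'
#' Crops and resamples the preprocessed volume to the coarse bladder grid
#' (94 x 94 x 50 voxels at 3.0 x 3.0 x 3.2 mm, centred at the volume's
#' geometric centre), predicts with the 3-D network, thresholds, keeps the
#' largest 26-connected component and resamples the mask back to the
#' native grid.
#'
#' @param volume a preprocessed `ctv_volume` (see [preprocess_volume()]).
#' @param model a 3-D `ctv_model` trained for bladder segmentation.
#' @param t probability threshold (default 0.5).
#' @return Bladder label map on the native grid.
#' @export
segment_bladder <- function(volume, model, t = 0.5) {
  roi <- bladder_roi_for(volume)
  crop <- resample(volume, roi)
  prob <- predict_map(model, crop)
  mask <- threshold_map(prob, t)
  if (sum(mask$data) == 0)
    ctv_stop("ctv_error_localization",
             "bladder segmentation is empty: cannot localize the CTV")
  mask <- largest_component(mask)
  resample(mask, roi_of_volume(volume), "nearest")
}

#' Detect the superior-inferior CTV span (stage 2)
#'
#' Crops every axial slice to a 128 x 128 window at 1 x 1 mm centred at
#' the estimated CTV centre, segments it with the 2-D attention network,
#' thresholds, removes small false positives, and marks the slice positive
#' iff any pixel remains.  The span is the longest run of positive slices
#' tolerating gaps of at most `max_gap` slices; its first and last
#' positive slices delimit the CTV.
#'
#' @param volume a preprocessed `ctv_volume`.
#' @param ctv_center numeric(3) estimated CTV centre (world mm).
#' @param model a 2-D `ctv_model` (attention U-Net).
#' @param t probability threshold.
#' @param min_area_px cleaning threshold (see [clean_detection()]).
#' @param max_gap largest tolerated gap inside a run (default 2 slices).
#' @return A `ctv_span` list: `positive` (logical per slice), `span`
#'   (first, last), `cleaned` (list of 2-D masks).
#' @export
detect_ctv_span <- function(volume, ctv_center, model, t = 0.5,
                            min_area_px = 50L, max_gap = 2L) {
  nz <- dim(volume$data)[3]
  positive <- logical(nz)
  cleaned <- vector("list", nz)
  for (k in seq_len(nz)) {
    zk <- volume$origin[3] + (k - 1) * volume$spacing[3]
    roi <- roi_spec(c(ctv_center[1], ctv_center[2], zk),
                    c(128L, 128L, 1L), c(1, 1, volume$spacing[3]))
    slice <- resample(volume, roi)$data[, , 1]
    prob <- predict_map(model, slice)
    m <- clean_detection(threshold_map(prob, t), min_area_px)
    cleaned[[k]] <- m
    positive[k] <- any(m > 0)
  }
  pos <- which(positive)
  if (length(pos) == 0)
    ctv_stop("ctv_error_localization",
             "no axial slice contains CTV: span detection failed")
  span <- longest_run(pos, max_gap)
  structure(list(positive = positive, span = span, cleaned = cleaned),
            class = "ctv_span")
}

# Longest run of indices tolerating gaps <= max_gap; returns c(first, last)
# of the positives inside the winning run (most positives; first on ties).
longest_run <- function(pos, max_gap = 2L) {
  breaks <- which(diff(pos) > max_gap + 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(pos))
  counts <- ends - starts + 1L
  w <- which.max(counts)
  c(pos[starts[w]], pos[ends[w]])
}

#' Build the CTV-specific ROI (stage 2 output)
#'
#' In-plane 128 x 128 at 1 x 1 mm centred at the estimated CTV centre; the
#' superior-inferior extent covers the detected span plus `margin_slices`
#' on both sides, resampled to a 1.6 mm slice pitch, with the depth
#' clamped below at 15 (the block depth).
#'
#' @param volume the native `ctv_volume` (provides slice world positions).
#' @param ctv_center numeric(3) estimated CTV centre (world mm).
#' @param span integer(2), first and last native slice index of the CTV.
#' @param margin_slices extra slices on each side (default 2).
#' @param si_spacing ROI slice pitch in mm (default 1.6).
#' @return A `ctv_roi` with spacing (1, 1, 1.6) mm.
#' @export
build_roi <- function(volume, ctv_center, span, margin_slices = 2L,
                      si_spacing = 1.6) {
  if (length(span) != 2L || span[2] < span[1])
    ctv_stop("ctv_error_parameter", "span must be a non-empty (first, last) slice range")
  z1 <- volume$origin[3] + (span[1] - 1) * volume$spacing[3]
  z2 <- volume$origin[3] + (span[2] - 1) * volume$spacing[3]
  span_mm <- (span[2] - span[1] + 1L) * volume$spacing[3]
  depth <- max(15L, as.integer(ceiling(span_mm / si_spacing)) + 2L * margin_slices)
  roi_spec(c(ctv_center[1], ctv_center[2], (z1 + z2) / 2),
           c(128L, 128L, depth), c(1, 1, si_spacing))
}
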
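check_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    ctv_stop("ctv_error_shape", "masks are not on the same grid")
}

#' Dice similarity coefficient
#'
#' `2 |A intersect M| / (|A| + |M|)` by voxel counts.
#'
#' @param auto,manual label maps on the same grid, not both empty.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(auto, manual) {
  check_same_grid(auto, manual)
  na <- sum(auto$data); nm <- sum(manual$data)
  if (na + nm == 0)
    ctv_stop("ctv_error_value", "DSC of two empty masks is undefined")
  2 * sum(auto$data & manual$data) / (na + nm)
}

#' Absolute volume difference
#'
#' `| |A| - |M| | * voxel_volume`, reported in cm^3.
#'
#' @param auto,manual label maps on the same grid.
#' @return Non-negative volume difference in cm^3.
#' @export
avd <- function(auto, manual) {
  check_same_grid(auto, manual)
  vox_cm3 <- prod(auto$spacing) / 1000
  abs(sum(auto$data) - sum(manual$data)) * vox_cm3
}

#' Mask volume in cm^3
#' @param mask a label map.
#' @return Foreground volume in cm^3.
#' @export
mask_volume_cm3 <- function(mask) sum(mask$data) * prod(mask$spacing) / 1000

surface_points <- function(mask) {
  surf <- surface_mask(as.integer(mask$data), dim(mask$data))
  idx <- which(array(surf, dim(mask$data)), arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' 95th-percentile Hausdorff distance
#'
#' Surface voxels are foreground voxels with a background face-neighbour.
#' Both directed sets of nearest-surface distances (world mm, anisotropic
#' spacing respected) are pooled and the 95th percentile (linear
#' interpolation) of the pooled set is returned, making the metric
#' symmetric in its arguments.
#'
#' @param auto,manual non-empty label maps on the same grid.
#' @param percentile percentile of the pooled distances (default 95).
#' @return Distance in mm.
#' @export
hd95 <- function(auto, manual, percentile = 95) {
  check_same_grid(auto, manual)
  if (sum(auto$data) == 0 || sum(manual$data) == 0)
    ctv_stop("ctv_error_value", "HD95 requires two non-empty masks")
  A <- surface_points(auto)
  M <- surface_points(manual)
  d <- c(directed_surface_dists(A, M), directed_surface_dists(M, A))
  as.numeric(stats::quantile(d, percentile / 100, type = 7))
}

#' Pearson correlation between volumes and scores
#'
#' @param volumes,scores equal-length numeric vectors (length >= 3) with
#'   nonzero variance.
#' @return Pearson product-moment correlation coefficient.
#' @export
volume_score_correlation <- function(volumes, scores) {
  if (length(volumes) != length(scores) || length(volumes) < 3)
    ctv_stop("ctv_error_value", "need equal-length vectors of at least 3 values")
  if (stats::sd(volumes) == 0 || stats::sd(scores) == 0)
    ctv_stop("ctv_error_value", "correlation is undefined for constant input")
  stats::cor(volumes, scores)
}

#' Two-sided paired t-test
#'
#' Classical paired t-test on per-case differences with a significance
#' flag at `alpha`.
#'
#' @param scores_a,scores_b equal-length numeric vectors (length >= 2).
#' @param alpha significance level (default 0.05).
#' @return List with `t`, `p` and `significant`.
#' @export
paired_test <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 2)
    ctv_stop("ctv_error_value", "need equal-length vectors of at least 2 values")
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, significant = FALSE))
    ctv_stop("ctv_error_value", "paired t-test undefined for constant nonzero differences")
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Evaluate one segmentation against its reference
#'
#' @param auto,manual label maps on the same grid.
#' @return List with `dsc`, `avd_cm3`, `hd95_mm`.
#' @export
evaluate_case <- function(auto, manual) {
  list(dsc = dsc(auto, manual), avd_cm3 = avd(auto, manual),
       hd95_mm = hd95(auto, manual))
}

#' Evaluate a cohort of segmentation pairs
#'
#' Computes the per-case metrics for every (auto, manual) pair and a
#' mean +/- SD summary.  Failing cases (e.g. empty masks) are recorded
#' with `NA` metrics rather than aborting the cohort.
#'
#' @param pairs list of `list(auto = , manual = )` pairs; names become
#'   case ids.
#' @param csv_path optional path to write the per-case table plus summary.
#' @return List with `table` (per-case data.frame) and `summary`
#'   (data.frame of mean and SD per metric).
#' @export
evaluate_cohort <- function(pairs, csv_path = NULL) {
  ids <- names(pairs) %||% sprintf("case_%03d", seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    r <- tryCatch(evaluate_case(pairs[[i]]$auto, pairs[[i]]$manual),
                  ctv_error = function(e) list(dsc = NA_real_, avd_cm3 = NA_real_,
                                               hd95_mm = NA_real_))
    data.frame(id = ids[i], dsc = r$dsc, avd_cm3 = r$avd_cm3,
               hd95_mm = r$hd95_mm, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("dsc", "avd_cm3", "hd95_mm"),
    mean = c(mean(tab$dsc, na.rm = TRUE), mean(tab$avd_cm3, na.rm = TRUE),
             mean(tab$hd95_mm, na.rm = TRUE)),
    sd = c(stats::sd(tab$dsc, na.rm = TRUE), stats::sd(tab$avd_cm3, na.rm = TRUE),
           stats::sd(tab$hd95_mm, na.rm = TRUE)))
  if (!is.null(csv_path)) {
    utils::write.csv(tab, csv_path, row.names = FALSE)
    utils::write.csv(summ, sub("(\\.csv)?$", "_summary.csv", csv_path),
                     row.names = FALSE)
  }
  list(table = tab, summary = summ)
}
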
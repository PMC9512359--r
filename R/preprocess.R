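#' Histogram equalization
#'
#' Global histogram equalization computed over the whole 3-D volume using a
#' fixed number of intensity bins.  The mapping is the empirical CDF of the
#' binned intensities, so it is monotone non-decreasing in the input
#' intensity and the output lies in \[0, 1\].  A constant volume is
#' returned unchanged in shape with all values mapped through its single
#' bin (a constant output).
#'
#' @param volume a `ctv_volume`.
#' @param bins number of histogram bins (default 256).
#' @param slicewise if `TRUE`, equalize each axial slice independently
#'   instead of the whole volume.
#' @return An equalized `ctv_volume` with intensities in \[0, 1\].
#' @export
histogram_equalize <- function(volume, bins = 256L, slicewise = FALSE) {
  eq <- function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(array(1, dim(x)))
    br <- seq(rng[1], rng[2], length.out = bins + 1L)
    idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(idx, nbins = bins)
    cdf <- cumsum(counts) / length(x)
    array(cdf[idx], dim(x))
  }
  out <- if (slicewise) {
    d <- volume$data
    for (k in seq_len(dim(d)[3])) d[, , k] <- eq(volume$data[, , k, drop = FALSE])
    d
  } else eq(volume$data)
  as_volume(out, volume$spacing, volume$origin)
}

#' Min-max intensity normalization
#'
#' Affine rescaling of intensities so that the minimum maps to 0 and the
#' maximum to 1.  A constant volume maps to all zeros.
#'
#' @param volume a `ctv_volume`.
#' @return A normalized `ctv_volume` with intensities in \[0, 1\].
#' @export
normalize_intensity <- function(volume) {
  rng <- range(volume$data)
  out <- if (rng[1] == rng[2]) array(0, dim(volume$data))
         else (volume$data - rng[1]) / (rng[2] - rng[1])
  as_volume(out, volume$spacing, volume$origin)
}

#' Standard intensity preprocessing
#'
#' Histogram equalization followed by min-max normalization to \[0, 1\],
#' applied to the native volume before any cropping.
#'
#' @inheritParams histogram_equalize
#' @return A preprocessed `ctv_volume`.
#' @export
preprocess_volume <- function(volume, bins = 256L, slicewise = FALSE) {
  normalize_intensity(histogram_equalize(volume, bins = bins, slicewise = slicewise))
}
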